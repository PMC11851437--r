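# small in-code fixtures shared across tests

# occurrence tibble from a named list of species vectors
occ_from_sets <- function(sets, era = NULL) {
  species <- sort(unique(unlist(sets)))
  rows <- lapply(names(sets), function(s) {
    as.integer(species %in% sets[[s]])
  })
  out <- tibble::as_tibble(do.call(rbind, rows), .name_repair = ~species)
  out <- dplyr::bind_cols(tibble::tibble(site = names(sets)), out)
  validate_occurrence(out, era = era)
}

# trait tibble from a named list of 0/1 vectors (one per trait)
traits_from_cols <- function(species, ...) {
  cols <- list(...)
  out <- tibble::tibble(species = species)
  for (nm in names(cols)) out[[nm]] <- as.integer(cols[[nm]])
  validate_traits(out)
}

# two-equal-segment network with one barrier
two_segment_network <- function(passability = 0, year = -Inf) {
  river_network(
    tibble::tibble(id = c("A", "B"), length_km = c(10, 10), rank = 1),
    tibble::tibble(from = "A", to = "B", passability = passability, year = year)
  )
}

# random chain network for property sweeps
random_chain_network <- function(n, seed) {
  set.seed(seed)
  segs <- tibble::tibble(id = sprintf("S%02d", 1:n),
                         length_km = runif(n, 5, 200), rank = 1)
  barr <- tibble::tibble(from = segs$id[-n], to = segs$id[-1],
                         passability = sample(c(0, 0.25, runif(1)), n - 1, TRUE),
                         year = sample(1970:2015, n - 1, TRUE))
  river_network(segs, barr)
}

planted_metrics <- c("NFM", "PF", "HYF", "CUF", "LAF", "SIF", "FLF", "SPF")
mixed_metrics <- c("EF", "EUF", "DRF")
screening_candidates <- c(planted_metrics, mixed_metrics)
planted_directions <- tibble::tibble(
  metric = planted_metrics,
  direction = c("increase", "decrease", "increase", "decrease",
                "increase", "increase", "increase", "increase")
)
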