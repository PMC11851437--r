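#' Validate a site-by-species occurrence table
#'
#' An occurrence table is a tibble whose first column, `site`, holds unique
#' site identifiers and whose remaining columns are species with binary 0/1
#' incidence. Validation enforces: strictly binary cells, unique site and
#' species identifiers, and at least one species present at every site.
#'
#' @param occ A data frame: `site` column plus one 0/1 column per species.
#' @param era Optional label, `"historical"` or `"current"`, attached as an
#'   attribute.
#' @return The validated occurrence tibble (values coerced to integer), with
#'   attribute `era` if supplied.
#' @export
validate_occurrence <- function(occ, era = NULL) {
  occ <- tibble::as_tibble(occ)
  if (!"site" %in% names(occ)) {
    abort("occurrence table must have a 'site' column")
  }
  occ$site <- as.character(occ$site)
  if (anyDuplicated(occ$site)) {
    abort(paste0("duplicate site identifiers: ",
                 paste(unique(occ$site[duplicated(occ$site)]), collapse = ", ")))
  }
  sp <- setdiff(names(occ), "site")
  if (length(sp) == 0L) abort("occurrence table has no species columns")
  if (anyDuplicated(sp)) {
    abort(paste0("duplicate species identifiers: ",
                 paste(unique(sp[duplicated(sp)]), collapse = ", ")))
  }
  m <- as.matrix(occ[sp])
  bad <- which(!(m %in% c(0, 1)) | is.na(m))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(m)) + 1L
    abort(sprintf(
      "non-binary value %s at site '%s', species '%s' (%d offending cell%s)",
      format(m[bad[1]]), occ$site[i], sp[j], length(bad),
      if (length(bad) > 1) "s" else ""))
  }
  rs <- rowSums(m)
  if (any(rs < 1)) {
    abort(paste0("site(s) with no species present: ",
                 paste(occ$site[rs < 1], collapse = ", ")))
  }
  occ[sp] <- lapply(occ[sp], as.integer)
  if (!is.null(era)) {
    era <- match.arg(era, c("historical", "current"))
    attr(occ, "era") <- era
  }
  occ
}

#' Read or write an occurrence table
#'
#' CSV layout: first column site identifiers, remaining columns species,
#' cells 0/1 (comma-separated, UTF-8). The first column may be named
#' anything; it is renamed `site`.
#'
#' @param path Path to a CSV file.
#' @param era `"historical"` or `"current"`.
#' @return `read_occurrence()`: a validated occurrence tibble.
#' @export
read_occurrence <- function(path, era = c("historical", "current")) {
  era <- match.arg(era)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "site"
  validate_occurrence(x, era = era)
}

#' @rdname read_occurrence
#' @param occ A validated occurrence tibble.
#' @export
write_occurrence <- function(occ, path) {
  readr::write_csv(occ, path)
  invisible(path)
}

#' Validate a species-by-trait table
#'
#' @param traits Data frame: `species` column plus one 0/1 column per trait.
#'   Trait names must come from [trait_vocabulary()]; unknown names are
#'   rejected.
#' @return Validated trait tibble (integer values).
#' @export
validate_traits <- function(traits) {
  traits <- tibble::as_tibble(traits)
  if (!"species" %in% names(traits)) abort("trait table must have a 'species' column")
  traits$species <- as.character(traits$species)
  if (anyDuplicated(traits$species)) abort("duplicate species in trait table")
  tn <- setdiff(names(traits), "species")
  unknown <- setdiff(tn, trait_vocabulary())
  if (length(unknown)) {
    abort(paste0("unknown trait name(s): ", paste(unknown, collapse = ", "),
                 "; allowed names are given by trait_vocabulary()"))
  }
  m <- as.matrix(traits[tn])
  if (any(!(m %in% c(0, 1)) | is.na(m))) abort("trait values must be 0 or 1")
  traits[tn] <- lapply(traits[tn], as.integer)
  traits
}

#' @rdname validate_traits
#' @param path Path to a CSV file (first column species, then traits).
#' @export
read_traits <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "species"
  validate_traits(x)
}

#' @rdname validate_traits
#' @export
write_traits <- function(traits, path) {
  readr::write_csv(traits, path)
  invisible(path)
}

#' Read site metadata
#'
#' Site metadata carry the habitat class and the environmental covariates
#' used by the driver analysis: a `site` column, `habitat_type` (`"NRAD"`,
#' a natural free-flowing reach between adjacent dams, or `"TR"`, a
#' transitional region in a reservoir), the length of natural lotic reach,
#' and numeric covariate columns (e.g. GDP, LUR, WA, VR, TEM, PRE, DWN,
#' ALT, NRAD, HT, CTP).
#'
#' @param path Path to a CSV file.
#' @return A tibble with `site` as character and `habitat_type` as factor
#'   with levels `NRAD`, `TR` (ordinal encoding NRAD = 1, TR = 2).
#' @export
read_site_metadata <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "site"
  x$site <- as.character(x$site)
  if ("habitat_type" %in% names(x)) {
    x$habitat_type <- factor(x$habitat_type, levels = c("NRAD", "TR"))
    if (anyNA(x$habitat_type)) abort("habitat_type must be 'NRAD' or 'TR'")
  }
  if ("natural_reach_km" %in% names(x) && any(x$natural_reach_km < 0)) {
    abort("natural_reach_km must be non-negative")
  }
  tibble::as_tibble(x)
}

# occurrence tibble -> 0/1 matrix with site rownames
occ_matrix <- function(occ) {
  m <- as.matrix(occ[setdiff(names(occ), "site")])
  rownames(m) <- occ$site
  storage.mode(m) <- "integer"
  m
}

#' Trait-percentage metric values
#'
#' For each site and each requested trait, the percentage of species present
#' at the site that possess the trait:
#' \deqn{100 \times |\{s \in S_i : x_{s,m} = 1\}| / |S_i|}
#' where \eqn{S_i} is the species set of site \eqn{i}. Percentages are kept
#' at full precision; round only when reporting.
#'
#' @param occ Occurrence tibble (see [validate_occurrence()]).
#' @param traits Trait tibble (see [validate_traits()]). Every species in
#'   `occ` must appear; missing species are an error, not a silent drop.
#' @param metrics Character vector of trait names to compute; defaults to
#'   all traits in `traits`.
#' @return Tibble: `site` column plus one numeric column per metric, values
#'   in \[0, 100\].
#' @export
#' @examples
#' occ <- tibble::tibble(site = "a", sp1 = 1L, sp2 = 1L, sp3 = 0L)
#' tr <- tibble::tibble(species = c("sp1", "sp2", "sp3"),
#'                      CUF = c(1L, 0L, 1L))
#' metric_values(occ, tr)  # 50% of the two present species are CUF
metric_values <- function(occ, traits, metrics = NULL) {
  occ <- validate_occurrence(occ)
  traits <- validate_traits(traits)
  metrics <- metrics %||% setdiff(names(traits), "species")
  missing_m <- setdiff(metrics, names(traits))
  if (length(missing_m)) {
    abort(paste0("metric(s) not in trait table: ", paste(missing_m, collapse = ", ")))
  }
  om <- occ_matrix(occ)
  missing_sp <- setdiff(colnames(om), traits$species)
  if (length(missing_sp)) {
    abort(paste0("species missing from trait table: ",
                 paste(head(missing_sp, 10), collapse = ", "),
                 if (length(missing_sp) > 10) sprintf(" (and %d more)", length(missing_sp) - 10)))
  }
  tm <- as.matrix(traits[metrics])
  rownames(tm) <- traits$species
  tm <- tm[colnames(om), , drop = FALSE]
  pct <- 100 * (om %*% tm) / rowSums(om)
  out <- tibble::as_tibble(pct)
  dplyr::bind_cols(tibble::tibble(site = occ$site), out)
}
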