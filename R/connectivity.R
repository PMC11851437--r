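#' Build a river network of segments and barriers
#'
#' A river network is a set of segments (length in km, river rank) joined at
#' junctions. Each barrier sits on the junction between two segments and
#' carries a passability \eqn{p_m \in [0, 1]} (0 for a complete barrier,
#' 0.25 for one equipped with a fish passage, by convention) and the year it
#' was commissioned; before that year it does not impede movement. Junctions
#' not listed in `barriers` are free (passability 1). By default segments
#' are assumed to form a single mainstem chain in the order given; pass
#' `edges` for other tree topologies.
#'
#' @param segments Data frame: `id`, `length_km` (> 0), `rank` (>= 1;
#'   defaults to 1).
#' @param barriers Optional data frame: `from`, `to` (segment ids),
#'   `passability` in \[0, 1\] (default 0), `year` (default `-Inf`, i.e.
#'   always active).
#' @param edges Optional data frame of junctions (`from`, `to`); defaults to
#'   the chain of consecutive segments. Barrier junctions are added
#'   automatically.
#' @return Object of class `fibir_network`: list with `segments`,
#'   `barriers`, `edges`, the igraph `graph`, and the rank-weighted total
#'   length `L`.
#' @export
#' @examples
#' segs <- tibble::tibble(id = c("up", "down"), length_km = c(10, 10), rank = 1)
#' barr <- tibble::tibble(from = "up", to = "down", passability = 0, year = 2000)
#' net <- river_network(segs, barr)
#' rci_static(net)  # 25 for each segment
river_network <- function(segments, barriers = NULL, edges = NULL) {
  segments <- tibble::as_tibble(segments)
  if (!all(c("id", "length_km") %in% names(segments))) {
    abort("segments need 'id' and 'length_km' columns")
  }
  segments$id <- as.character(segments$id)
  if (anyDuplicated(segments$id)) abort("duplicate segment ids")
  if (!"rank" %in% names(segments)) segments$rank <- 1
  if (any(segments$length_km <= 0)) abort("segment lengths must be positive")
  if (any(segments$rank < 1)) abort("segment ranks must be >= 1")

  if (is.null(edges)) {
    n <- nrow(segments)
    edges <- if (n > 1) {
      tibble::tibble(from = segments$id[-n], to = segments$id[-1])
    } else {
      tibble::tibble(from = character(), to = character())
    }
  } else {
    edges <- tibble::as_tibble(edges)[, c("from", "to")]
  }

  if (is.null(barriers)) {
    barriers <- tibble::tibble(from = character(), to = character(),
                               passability = double(), year = double())
  } else {
    barriers <- tibble::as_tibble(barriers)
    if (!all(c("from", "to") %in% names(barriers))) {
      abort("barriers need 'from' and 'to' columns")
    }
    if (!"passability" %in% names(barriers)) barriers$passability <- 0
    if (!"year" %in% names(barriers)) barriers$year <- -Inf
    if (any(barriers$passability < 0 | barriers$passability > 1)) {
      abort("passability must lie in [0, 1]")
    }
    bad <- setdiff(c(barriers$from, barriers$to), segments$id)
    if (length(bad)) abort(paste0("barrier references unknown segment(s): ",
                                  paste(unique(bad), collapse = ", ")))
    # junctions named only in barriers are edges too
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    missing_e <- !key(barriers$from, barriers$to) %in% key(edges$from, edges$to)
    if (any(missing_e)) {
      edges <- dplyr::bind_rows(edges, barriers[missing_e, c("from", "to")])
    }
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = segments["id"])
  if (nrow(segments) > 1 && !igraph::is_connected(g)) {
    abort("segment graph is disconnected when barriers are ignored")
  }
  L <- sum(2 * segments$rank * segments$length_km)
  structure(list(segments = segments, barriers = barriers, edges = edges,
                 graph = g, L = L),
            class = "fibir_network")
}

#' @export
print.fibir_network <- function(x, ...) {
  cat(sprintf("<fibir_network> %d segments (L = %.1f rank-weighted km), %d barriers\n",
              nrow(x$segments), x$L, nrow(x$barriers)))
  invisible(x)
}

# barriers active in a given year, as an edge-keyed passability lookup
active_barriers <- function(network, year) {
  b <- network$barriers[network$barriers$year <= year, , drop = FALSE]
  if (!nrow(b)) return(stats::setNames(numeric(), character()))
  key <- paste(pmin(b$from, b$to), pmax(b$from, b$to))
  tapply(b$passability, key, prod)  # several barriers on one junction multiply
}

#' Passability between two segments
#'
#' The product \eqn{p_{ij} = \prod_m p_m} of the passabilities of all
#' barriers on the unique path between segments `i` and `j` that are
#' commissioned by `year`. The empty product gives \eqn{p_{ii} = 1}.
#'
#' @param network A [river_network()].
#' @param i,j Segment ids.
#' @param year Evaluation year; barriers act from their commissioning year
#'   inclusive. Default `Inf` (all barriers active).
#' @return Passability in \[0, 1\].
#' @export
passability <- function(network, i, j, year = Inf) {
  stopifnot(inherits(network, "fibir_network"))
  ids <- network$segments$id
  if (!i %in% ids || !j %in% ids) abort("unknown segment id")
  if (i == j) return(1)
  act <- active_barriers(network, year)
  path <- igraph::shortest_paths(network$graph, from = i, to = j,
                                 output = "vpath")$vpath[[1]]
  v <- names(path)
  if (length(v) < 2) abort("segments are not connected")
  p <- 1
  for (k in seq_len(length(v) - 1L)) {
    key <- paste(min(v[k], v[k + 1L]), max(v[k], v[k + 1L]))
    if (key %in% names(act)) p <- p * act[[key]]
  }
  p
}

#' Static river connectivity index
#'
#' For each segment \eqn{i}, with weights \eqn{w_i = 2 r_i l_i / L} and
#' \eqn{L = \sum_i 2 r_i l_i}:
#' \deqn{RCI_i = 100 \sum_j w_i w_j p_{ij}}
#' including the self term \eqn{p_{ii} = 1}. A single free segment scores
#' 100; every barrier (or any passability drop) can only lower the index.
#'
#' @inheritParams passability
#' @return Tibble: `segment`, `weight`, `rci`.
#' @export
rci_static <- function(network, year = Inf) {
  stopifnot(inherits(network, "fibir_network"))
  segs <- network$segments
  if (network$L <= 0) abort("total rank-weighted length must be positive")
  w <- 2 * segs$rank * segs$length_km / network$L
  n <- nrow(segs)
  P <- diag(1, n)
  dimnames(P) <- list(segs$id, segs$id)
  if (n > 1) {
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      P[a, b] <- P[b, a] <- passability(network, segs$id[a], segs$id[b], year)
    }
  }
  tibble::tibble(segment = segs$id, weight = w,
                 rci = 100 * as.vector(w * (P %*% w)))
}

#' Time-weighted river connectivity index (TRCI)
#'
#' Averages the static index over an evaluation window of `t` years,
#' \deqn{TRCI_i = \frac{1}{t} \sum_{k=1}^{t} RCI_i(k),}
#' with each barrier active only from its commissioning year onward. The
#' window conventionally starts in the commissioning year of the first
#' cascade station, so earlier (undammed) years contribute the free-flowing
#' index.
#'
#' @param network A [river_network()].
#' @param years Vector of evaluation years (k = 1..t); defaults to the span
#'   from the earliest barrier year to the latest.
#' @return Object of class `fibir_trci`: list with `trci` (tibble `segment`,
#'   `trci`), `by_year` (tibble `year`, `segment`, `rci`) and `years`.
#' @export
trci <- function(network, years = NULL) {
  stopifnot(inherits(network, "fibir_network"))
  if (is.null(years)) {
    if (!nrow(network$barriers)) abort("supply 'years' when the network has no barriers")
    years <- seq(min(network$barriers$year), max(network$barriers$year))
  }
  if (!length(years)) abort("no evaluation years")
  by_year <- purrr::map_dfr(years, function(y) {
    dplyr::mutate(rci_static(network, year = y)[c("segment", "rci")], year = y,
                  .before = 1)
  })
  avg <- by_year |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(trci = mean(.data$rci), .groups = "drop")
  avg <- avg[match(network$segments$id, avg$segment), ]
  structure(list(trci = avg, by_year = by_year, years = years),
            class = "fibir_trci")
}

#' @export
print.fibir_trci <- function(x, ...) {
  cat(sprintf("<fibir_trci> %d segments averaged over %d years (%s-%s)\n",
              nrow(x$trci), length(x$years), min(x$years), max(x$years)))
  print(x$trci)
  invisible(x)
}

#' Ordinal cumulative-time connectivity class (CTP)
#'
#' Dense rank of the per-segment TRCI (1 = least connected; ties share a
#' rank). The rank is invariant under strictly monotone transforms of TRCI
#' and is the ordinal covariate fed to the driver analysis.
#'
#' @param result A [trci()] result.
#' @return Tibble: `segment`, `trci`, `ctp`.
#' @export
ctp_ordinal <- function(result) {
  stopifnot(inherits(result, "fibir_trci"))
  dplyr::mutate(result$trci, ctp = dplyr::dense_rank(.data$trci))
}
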