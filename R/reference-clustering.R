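#' Z-score standardisation of an occurrence table
#'
#' Centres and scales each species column to mean 0 and unit *population*
#' variance (divisor n, so a balanced 0/1 column maps to -1/+1). Constant
#' (zero-variance) columns carry no information for clustering and are
#' dropped; their names are reported in the `dropped` attribute and a
#' message.
#'
#' @param occ Occurrence tibble.
#' @return Tibble: `site` plus standardised numeric feature columns, with
#'   attribute `dropped` naming removed constant columns.
#' @export
standardize_occurrence <- function(occ) {
  occ <- validate_occurrence(occ)
  m <- occ_matrix(occ)
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2, mu)^2))
  keep <- sdev > 0
  if (!any(keep)) abort("all species columns are constant; nothing to standardize")
  dropped <- colnames(m)[!keep]
  if (length(dropped)) {
    message(sprintf("dropped %d constant species column(s): %s%s",
                    length(dropped), paste(head(dropped, 5), collapse = ", "),
                    if (length(dropped) > 5) ", ..." else ""))
  }
  z <- sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")
  out <- dplyr::bind_cols(tibble::tibble(site = occ$site), tibble::as_tibble(z))
  attr(out, "dropped") <- dropped
  out
}

# numeric feature matrix from a tibble with optional site column
feature_matrix <- function(data) {
  data <- tibble::as_tibble(data)
  ids <- if ("site" %in% names(data)) data$site else as.character(seq_len(nrow(data)))
  m <- as.matrix(data[vapply(data, is.numeric, logical(1))])
  rownames(m) <- ids
  m
}

#' Hopkins clustering-tendency statistic
#'
#' Compares nearest-neighbour distances of real data probes with those of
#' uniform reference probes drawn in the data bounding box:
#' \deqn{H = \frac{\sum_i r_i'}{\sum_i r_i + \sum_i r_i'}}
#' where \eqn{r_i} is the distance from a sampled real row to its nearest
#' *other* real row and \eqn{r_i'} the distance from a uniform pseudo-point
#' to its nearest real row (Euclidean). \eqn{H \approx 0.5} indicates no
#' cluster structure; values towards 1 (tight clusters: real probes have
#' short neighbour distances) or 0 indicate clustering tendency worth
#' pursuing.
#'
#' @param data Data frame or matrix of numeric features (a `site` column is
#'   ignored), e.g. the output of [standardize_occurrence()].
#' @param n Number of probes; default `ceiling(0.3 * nrow)`, clipped to
#'   `[2, nrow - 1]`.
#' @param seed Optional integer seed for probe sampling.
#' @return Object of class `fibir_hopkins`: list with `H`, `n`, and the
#'   intermediate distance sets `r` (data probes) and `r_prime` (reference
#'   probes).
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(runif(200), ncol = 2)
#' hopkins_statistic(x, n = 20, seed = 1)$H  # ~0.5 for uniform data
hopkins_statistic <- function(data, n = NULL, seed = NULL) {
  m <- if (is.matrix(data)) data else feature_matrix(data)
  storage.mode(m) <- "double"
  N <- nrow(m)
  if (N < 3) abort("need at least 3 rows for the Hopkins statistic")
  n <- n %||% ceiling(0.3 * N)
  n <- max(2L, min(as.integer(n), N - 1L))
  lo <- apply(m, 2, min); hi <- apply(m, 2, max)
  if (all(hi - lo == 0)) abort("degenerate data: all rows identical")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(N, n)
  D <- as.matrix(dist(m))
  diag(D) <- Inf
  r <- apply(D[idx, , drop = FALSE], 1, min)
  ref <- vapply(seq_along(lo), function(j) runif(n, lo[j], hi[j]), numeric(n))
  r_prime <- vapply(seq_len(n), function(i) {
    sqrt(min(colSums((t(m) - ref[i, ])^2)))
  }, numeric(1))
  if (sum(r) + sum(r_prime) == 0) abort("degenerate data: all distances zero")
  structure(list(H = sum(r_prime) / (sum(r) + sum(r_prime)),
                 n = n, r = unname(r), r_prime = r_prime),
            class = "fibir_hopkins")
}

#' @export
print.fibir_hopkins <- function(x, ...) {
  cat(sprintf("Hopkins statistic H = %.4f (n = %d probes)\n", x$H, x$n))
  cat("H near 0.5: no clustering tendency; towards 0/1: clusterable\n")
  invisible(x)
}

#' Jaccard similarity between sites
#'
#' \eqn{S(a, b) = |A \cap B| / |A \cup B|} on the species sets of each pair
#' of sites.
#'
#' @param occ Occurrence tibble with at least two sites.
#' @return Symmetric similarity matrix with unit diagonal, site names on
#'   both dimensions.
#' @export
jaccard_similarity <- function(occ) {
  occ <- validate_occurrence(occ)
  m <- occ_matrix(occ)
  if (nrow(m) < 2) abort("need at least 2 sites")
  d <- vegan::vegdist(m, method = "jaccard", binary = TRUE)
  s <- 1 - as.matrix(d)
  diag(s) <- 1
  dimnames(s) <- list(rownames(m), rownames(m))
  s
}

#' Hierarchical clustering of sites on a similarity matrix
#'
#' Agglomerative clustering on distance `1 - similarity`. Average linkage
#' (UPGMA) is the default, the conventional pairing with Jaccard similarity
#' in community ecology.
#'
#' @param similarity Symmetric similarity matrix in \[0, 1\] with unit
#'   diagonal (e.g. [jaccard_similarity()]).
#' @param k Number of groups, between 1 and the number of sites.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return Object of class `fibir_clusters`: list with `assignment` (tibble
#'   `site`, `group`), `k`, `similarity`, `tree` (the hclust object) and
#'   `linkage`.
#' @export
cluster_sites <- function(similarity, k, linkage = "average") {
  s <- as.matrix(similarity)
  if (nrow(s) != ncol(s) || any(abs(s - t(s)) > 1e-8)) {
    abort("similarity must be a symmetric matrix")
  }
  if (any(s < -1e-8 | s > 1 + 1e-8)) abort("similarity entries must lie in [0, 1]")
  n <- nrow(s)
  if (k < 1 || k > n) abort(sprintf("k must lie in [1, %d]", n))
  tree <- hclust(as.dist(1 - s), method = linkage)
  grp <- cutree(tree, k = k)
  sites <- rownames(s) %||% as.character(seq_len(n))
  structure(list(
    assignment = tibble::tibble(site = sites, group = unname(grp)),
    k = as.integer(k), similarity = s, tree = tree, linkage = linkage
  ), class = "fibir_clusters")
}

#' @export
print.fibir_clusters <- function(x, ...) {
  cat(sprintf("<fibir_clusters> %d sites in %d groups (%s linkage)\n",
              nrow(x$assignment), x$k, x$linkage))
  print(x$assignment, n = 5)
  invisible(x)
}

#' Gap-statistic selection of the number of cluster groups
#'
#' Runs [cluster::clusGap()] with hierarchical clustering (Euclidean
#' distance, configurable linkage) against `B` uniform reference data sets
#' drawn over each feature's observed range, and picks k by the
#' first-local-max-within-one-SE rule (`"Tibs2001SEmax"`): the smallest k
#' with \eqn{\mathrm{gap}(k) \ge \mathrm{gap}(k+1) - \mathrm{SE}(k+1)}.
#'
#' @param data Site-feature table (e.g. [standardize_occurrence()]) or
#'   numeric matrix.
#' @param k_max Largest k to evaluate (at most the number of rows).
#' @param B Number of uniform reference replicates (>= 10).
#' @param seed Optional seed.
#' @param linkage Linkage for the inner hierarchical clustering.
#' @return Object of class `fibir_gap`: list with the chosen `k`, a `table`
#'   tibble (k, logW, E_logW, gap, SE_sim), and `B`.
#' @export
optimal_k <- function(data, k_max, B = 100, seed = NULL, linkage = "average") {
  m <- if (is.matrix(data)) data else feature_matrix(data)
  if (nrow(m) < 3) abort("need at least 3 sites to select a cluster count")
  if (k_max > nrow(m)) abort("k_max cannot exceed the number of sites")
  if (k_max < 1) abort("k_max must be >= 1")
  if (B < 10) abort("B must be >= 10")
  if (k_max == 1) {
    return(structure(list(k = 1L, table = tibble::tibble(
      k = 1L, logW = NA_real_, E_logW = NA_real_, gap = NA_real_, SE_sim = NA_real_
    ), B = as.integer(B)), class = "fibir_gap"))
  }
  if (!is.null(seed)) set.seed(seed)
  hc_cut <- function(x, k) list(cluster = cutree(hclust(dist(x), method = linkage), k = k))
  gp <- cluster::clusGap(m, FUNcluster = hc_cut, K.max = k_max, B = B,
                         spaceH0 = "original", verbose = FALSE)
  tab <- gp$Tab
  khat <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"], method = "Tibs2001SEmax")
  structure(list(
    k = as.integer(khat),
    table = tibble::tibble(k = seq_len(k_max), logW = tab[, "logW"],
                           E_logW = tab[, "E.logW"], gap = tab[, "gap"],
                           SE_sim = tab[, "SE.sim"]),
    B = as.integer(B)
  ), class = "fibir_gap")
}

#' @export
print.fibir_gap <- function(x, ...) {
  cat(sprintf("<fibir_gap> k = %d selected (B = %d uniform references)\n", x$k, x$B))
  invisible(x)
}

#' Pool cluster-group species lists into reference values
#'
#' For each cluster group, the reference species pool is the union of the
#' member sites' historical species sets; the reference value
#' \eqn{R_{group}} of each metric is the trait percentage computed on that
#' pooled list (not the average of site values).
#'
#' @param occ_hist Historical occurrence tibble.
#' @param solution A [cluster_sites()] result, or a tibble with `site` and
#'   `group` columns.
#' @param traits Trait tibble.
#' @param metrics Metrics to compute (default: all traits).
#' @return Object of class `fibir_reference_set`: list with `values` (tibble
#'   group x metrics), `pool_sizes` (tibble `group`, `n_species`), `pools`
#'   (named list of species vectors), and `assignment`.
#' @export
pool_references <- function(occ_hist, solution, traits, metrics = NULL) {
  occ_hist <- validate_occurrence(occ_hist)
  assignment <- if (inherits(solution, "fibir_clusters")) solution$assignment
                else tibble::as_tibble(solution)
  if (!all(c("site", "group") %in% names(assignment))) {
    abort("solution must provide 'site' and 'group'")
  }
  missing_s <- setdiff(occ_hist$site, assignment$site)
  if (length(missing_s)) {
    abort(paste0("sites without group assignment: ", paste(missing_s, collapse = ", ")))
  }
  m <- occ_matrix(occ_hist)
  groups <- sort(unique(assignment$group))
  pools <- lapply(groups, function(g) {
    members <- assignment$site[assignment$group == g]
    pooled <- colSums(m[members, , drop = FALSE]) > 0
    colnames(m)[pooled]
  })
  names(pools) <- as.character(groups)
  empty <- vapply(pools, length, integer(1)) == 0
  if (any(empty)) abort(paste0("empty species pool for group(s): ",
                               paste(groups[empty], collapse = ", ")))
  pooled_occ <- dplyr::bind_cols(
    tibble::tibble(site = as.character(groups)),
    tibble::as_tibble(t(vapply(pools, function(p) {
      as.integer(colnames(m) %in% p)
    }, integer(ncol(m)))), .name_repair = ~colnames(m))
  )
  vals <- metric_values(pooled_occ, traits, metrics)
  names(vals)[1] <- "group"
  vals$group <- groups
  structure(list(
    values = vals,
    pool_sizes = tibble::tibble(group = groups,
                                n_species = unname(vapply(pools, length, integer(1)))),
    pools = pools,
    assignment = assignment
  ), class = "fibir_reference_set")
}

#' @export
print.fibir_reference_set <- function(x, ...) {
  cat(sprintf("<fibir_reference_set> %d groups; pooled species counts: %s\n",
              nrow(x$pool_sizes), paste(x$pool_sizes$n_species, collapse = ", ")))
  print(x$values, n = 8)
  invisible(x)
}
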