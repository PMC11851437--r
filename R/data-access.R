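#' Published reference values of the eight sensitive metrics
#'
#' The reference-value table of the Xijiang River mainstem assessment:
#' eight sensitive trait-percentage metrics (NFM, PF, HYF, CUF, LAF, SIF,
#' FLF, SPF) by eight cluster groups of sampling sites (values in %, one
#' decimal). Shipped as a plain-CSV fixture; useful for checking summary
#' statistics and for scoring examples.
#'
#' @return Tibble: `metric` plus one column per cluster group.
#' @export
#' @examples
#' ref <- reference_values_xijiang()
#' rowMeans(ref[-1])  # per-metric mean reference values
reference_values_xijiang <- function() {
  path <- system.file("extdata", "xijiang_reference_values.csv",
                      package = "fibir", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Habitat classification of the twelve Xijiang mainstem sites
#'
#' Site ids, habitat class (NRAD: natural free-flowing reach between
#' adjacent dams; TR: transitional region in a reservoir) and the length of
#' natural lotic reach between dams (km).
#'
#' @return Tibble: `site`, `habitat_type`, `natural_reach_km`.
#' @export
sites_xijiang <- function() {
  read_site_metadata(system.file("extdata", "xijiang_sites.csv",
                                 package = "fibir", mustWork = TRUE))
}
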