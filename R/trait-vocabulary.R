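#' Controlled vocabulary of ecological traits
#'
#' The 25 binary ecological traits used to build candidate metrics. Each
#' metric is the percentage of species at a site possessing the trait.
#' Abbreviations follow the usual bioassessment shorthand: e.g. `EF` endemic
#' fish, `CUF` rheophilic (current-loving) fish, `HYF` hydrostatic (lentic)
#' fish, `DRF` drifting-egg fish, `SPF` fish with specialised spawning modes.
#'
#' @return Character vector of the 25 trait codes, in canonical order.
#' @seealso [trait_families()] for the mutually exclusive trait families.
#' @export
#' @examples
#' trait_vocabulary()
trait_vocabulary <- function() {
  c("EF", "SF", "MF", "DF", "EFM", "NFM", "HFM", "CF", "OF", "HF", "PF",
    "FZ", "MIF", "HYF", "EUF", "CUF", "TAF", "CYF", "LAF", "FUF", "SIF",
    "FLF", "DRF", "STF", "SPF")
}

#' Mutually exclusive trait families
#'
#' Four trait families partition the species pool: every species carries
#' exactly one trait from each family (mouth position, water-column
#' position, body form, egg type). The remaining traits are free binary
#' attributes.
#'
#' @return Named list of character vectors, one per family.
#' @export
#' @examples
#' trait_families()
trait_families <- function() {
  list(
    mouth_position = c("EFM", "NFM", "HFM"),
    water_column   = c("SF", "MF", "DF"),
    body_form      = c("TAF", "CYF", "LAF", "FUF"),
    egg_type       = c("SIF", "FLF", "DRF", "STF")
  )
}

# traits not in any partition family
free_traits <- function() {
  setdiff(trait_vocabulary(), unlist(trait_families(), use.names = FALSE))
}

#' Long trait labels
#'
#' @return Named character vector mapping trait codes to descriptions.
#' @export
trait_labels <- function() {
  c(EF  = "endemic fish",
    SF  = "surface (pelagic) fish",
    MF  = "midwater fish",
    DF  = "demersal fish",
    EFM = "superior-mouth fish",
    NFM = "terminal-mouth fish",
    HFM = "inferior-mouth fish",
    CF  = "carnivorous fish",
    OF  = "omnivorous fish",
    HF  = "herbivorous fish",
    PF  = "planktivorous fish",
    FZ  = "benthivorous fish",
    MIF = "migratory fish",
    HYF = "hydrostatic (lentic) fish",
    EUF = "eurytopic fish",
    CUF = "rheophilic (lotic) fish",
    TAF = "dorsoventrally flattened fish",
    CYF = "cylindrical fish",
    LAF = "laterally compressed fish",
    FUF = "fusiform fish",
    SIF = "benthic (sinking) egg fish",
    FLF = "pelagic (floating) egg fish",
    DRF = "drifting-egg fish",
    STF = "adhesive (sticky) egg fish",
    SPF = "fish with special spawning modes")
}
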