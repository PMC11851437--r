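#' Default persistence effects of the ecological traits
#'
#' Log-odds shifts in species persistence per unit disturbance intensity,
#' used by [simulate_occurrence()]. Negative values depress persistence of
#' species carrying the trait under disturbance (rheophilic, planktivorous,
#' migratory, and other flow-dependent guilds); positive values favour it
#' (lentic, generalist-spawning guilds, whose share of the community grows
#' as flow-dependent species drop out). Traits listed in `mixed_traits` of
#' [scenario_config()] have the sign of their effect alternate across sites,
#' planting a spatially inconsistent ("mixed-trend") response.
#'
#' @return Named numeric vector over a subset of [trait_vocabulary()];
#'   unlisted traits have effect 0.
#' @export
default_trait_effects <- function() {
  c(PF = -5, CUF = -5, MIF = -3, CF = -1, FZ = -1, HF = -1, DF = -1,
    NFM = 3.5, HYF = 3.5, LAF = 3, SIF = 6, FLF = 6, SPF = 6,
    EF = 4, EUF = 5, DRF = 4)
}

# base prevalence targets for the 25 traits (partition families sum to 1)
default_trait_targets <- function() {
  c(EFM = 0.32, NFM = 0.23, HFM = 0.45,
    SF = 0.25, MF = 0.30, DF = 0.45,
    TAF = 0.08, CYF = 0.20, LAF = 0.52, FUF = 0.20,
    SIF = 0.05, FLF = 0.05, DRF = 0.25, STF = 0.65,
    EF = 0.35, CF = 0.30, OF = 0.40, HF = 0.12, PF = 0.09,
    FZ = 0.15, MIF = 0.12, HYF = 0.39, EUF = 0.57, CUF = 0.28, SPF = 0.03)
}

# loadings of each trait on the latent flow-dependence axis
# (positive = trait concentrates in rheophilic specialists)
default_trait_loadings <- function() {
  c(NFM = -1, HFM = 0.5, TAF = 0.5, CYF = 0.5, LAF = -1,
    SIF = -0.5, FLF = -0.5,
    PF = 1.2, FZ = 0.5, MIF = 1.8, HYF = -2, CUF = 2, SPF = -1)
}

#' Configure a synthetic disturbance scenario
#'
#' Bundles every knob of the synthetic community generator. Defaults emulate
#' the study system the package targets: 12 sites on a dammed river
#' mainstem, a regional pool of 139 species carrying 25 binary traits,
#' 8 reference cluster groups, and substantial post-development disturbance
#' at every site, strongest downstream. One seed fixes all downstream
#' randomness.
#'
#' @param n_sites,n_species,n_groups Community dimensions. `n_species`
#'   must be at least 20.
#' @param disturbance Per-site disturbance intensity in \[0, 1\]; recycled to
#'   `n_sites`. The default, a gradient from 0.45 to 0.95, represents
#'   post-development pressure that is substantial everywhere and strongest
#'   downstream, mirroring the longitudinal decline of biotic integrity
#'   along a cascade of reservoirs.
#' @param trait_effects Named persistence log-odds shifts per unit
#'   disturbance; see [default_trait_effects()].
#' @param mixed_traits Traits whose effect sign alternates across sites
#'   (planted mixed-trend metrics, expected to be discarded by the
#'   sensitivity screen).
#' @param baseline_persistence Persistence probability of a neutral species
#'   at zero disturbance.
#' @param global_loss Community-wide persistence log-odds penalty per unit
#'   disturbance (controls total species loss).
#' @param pool_rate Probability that a regional species enters a given
#'   cluster group's pool.
#' @param site_rate Probability that a pool species occurs at a given member
#'   site historically.
#' @param widespread_traits Traits marking ubiquitous generalist guilds:
#'   carriers occur at every site and persist almost surely (their
#'   percentage metrics can then only rise as other species drop out).
#' @param n_exotic Number of exotic species added to current assemblages
#'   (0 = off; establishment probability scales with disturbance).
#' @param barrier_years Commissioning years of the barriers on the
#'   simulated mainstem chain (length `n_sites - 1`, recycled).
#' @param eval_year Final year of the connectivity evaluation window.
#' @param seed Integer seed fixing all generator randomness.
#' @return An object of class `fibir_scenario` (a named list).
#' @export
#' @examples
#' cfg <- scenario_config(seed = 1)
#' scn <- simulate_scenario(cfg)
#' names(scn)
scenario_config <- function(n_sites = 12,
                            n_species = 139,
                            n_groups = 8,
                            disturbance = seq(0.45, 0.95, length.out = n_sites),
                            trait_effects = default_trait_effects(),
                            mixed_traits = c("EF", "EUF", "DRF"),
                            baseline_persistence = 0.98,
                            global_loss = 3,
                            pool_rate = 0.85,
                            site_rate = 0.95,
                            widespread_traits = c("SIF", "FLF", "SPF"),
                            n_exotic = 0,
                            barrier_years = c(1968, 1975, 1981, 1992, 1995,
                                              2001, 2004, 2006, 2009, 2014, 2020),
                            eval_year = 2023,
                            seed = 1) {
  if (n_species < 20) abort("n_species must be >= 20")
  if (n_groups > n_sites) abort("n_groups cannot exceed n_sites")
  disturbance <- rep_len(disturbance, n_sites)
  if (any(disturbance < 0 | disturbance > 1)) abort("disturbance must lie in [0, 1]")
  unknown <- setdiff(names(trait_effects), trait_vocabulary())
  if (length(unknown)) abort(paste0("unknown trait(s) in trait_effects: ",
                                    paste(unknown, collapse = ", ")))
  structure(list(
    n_sites = n_sites, n_species = n_species, n_groups = n_groups,
    disturbance = disturbance,
    trait_effects = trait_effects, mixed_traits = mixed_traits,
    baseline_persistence = baseline_persistence, global_loss = global_loss,
    pool_rate = pool_rate, site_rate = site_rate,
    widespread_traits = widespread_traits,
    trait_targets = default_trait_targets(),
    trait_loadings = default_trait_loadings(),
    n_exotic = n_exotic,
    barrier_years = rep_len(barrier_years, max(1L, n_sites - 1L)),
    eval_year = eval_year,
    seed = as.integer(seed)
  ), class = "fibir_scenario")
}

#' @export
print.fibir_scenario <- function(x, ...) {
  cat(sprintf("<fibir_scenario> %d sites, %d species, %d groups, seed %d\n",
              x$n_sites, x$n_species, x$n_groups, x$seed))
  cat(sprintf("  disturbance %.2f-%.2f; %d trait effects; mixed: %s\n",
              min(x$disturbance), max(x$disturbance),
              length(x$trait_effects), paste(x$mixed_traits, collapse = ", ")))
  invisible(x)
}

#' Simulate a regional species-by-trait pool
#'
#' Species traits are drawn around a latent flow-dependence axis
#' \eqn{u \sim N(0,1)}: partition-family cells (mouth position, water
#' column, body form, egg type) are multinomial with probabilities tilted by
#' \eqn{u}, and free traits are Bernoulli with logit rate
#' \eqn{\mathrm{logit}(q_t) + a_t u}. Positive loadings concentrate a trait
#' in rheophilic specialists, so flow-dependent traits co-occur the way they
#' do in real faunas (and as the redundancy screen presumes).
#'
#' @param cfg A [scenario_config()].
#' @return A validated trait tibble (`species` + 25 trait columns).
#' @export
#' @details Because a non-zero loading pulls the marginal prevalence of a
#'   trait towards 50%, intercepts (and partition-cell weights) are
#'   calibrated numerically against the standard-normal latent axis so that
#'   expected marginals equal the configured targets.
simulate_pool <- function(cfg) {
  stopifnot(inherits(cfg, "fibir_scenario"))
  set.seed(cfg$seed)
  n <- cfg$n_species
  u <- rnorm(n)
  voc <- trait_vocabulary()
  tr <- matrix(0L, n, length(voc),
               dimnames = list(sprintf("sp%03d", seq_len(n)), voc))
  q <- cfg$trait_targets
  a <- cfg$trait_loadings
  loading <- function(t) if (t %in% names(a)) a[[t]] else 0
  ug <- qnorm(seq(0.0005, 0.9995, length.out = 401))  # latent-axis quadrature
  for (fam in trait_families()) {
    w <- vapply(fam, function(t) q[[t]], numeric(1))
    tilt <- vapply(fam, loading, numeric(1))
    # calibrate cell weights so expected marginals hit the targets
    for (it in 1:50) {
      prg <- vapply(seq_along(fam), function(j) w[j] * exp(tilt[j] * ug), numeric(length(ug)))
      prg <- prg / rowSums(prg)
      w <- w * (vapply(fam, function(t) q[[t]], numeric(1)) / colMeans(prg))
      w <- w / sum(w)
    }
    pr <- vapply(seq_along(fam), function(j) w[j] * exp(tilt[j] * u), numeric(n))
    pr <- pr / rowSums(pr)
    cell <- vapply(seq_len(n), function(i) sample(fam, 1L, prob = pr[i, ]), character(1))
    for (t in fam) tr[cell == t, t] <- 1L
  }
  for (t in free_traits()) {
    # calibrate the intercept against the latent axis
    cc <- qlogis(q[[t]])
    for (it in 1:50) cc <- cc + qlogis(q[[t]]) - qlogis(mean(plogis(cc + loading(t) * ug)))
    p <- plogis(cc + loading(t) * u)
    tr[, t] <- as.integer(runif(n) < p)
  }
  out <- dplyr::bind_cols(tibble::tibble(species = rownames(tr)),
                          tibble::as_tibble(tr))
  validate_traits(out)
}

# per-species persistence effect vector at one site, centred so that the
# community-mean effect is zero (intensity controls mortality; effects
# control which guilds die)
site_effects <- function(cfg, trait_mat, site_index) {
  voc <- colnames(trait_mat)
  eff <- setNames(numeric(length(voc)), voc)
  fixed <- setdiff(names(cfg$trait_effects), cfg$mixed_traits)
  eff[fixed] <- cfg$trait_effects[fixed]
  # distinct alternation patterns keep the three mixed trends out of phase
  pats <- list(rep(c(1, -1), length.out = cfg$n_sites),
               rep(c(1, 1, -1, -1), length.out = cfg$n_sites),
               rep(c(-1, 1, 1, -1), length.out = cfg$n_sites))
  for (k in seq_along(cfg$mixed_traits)) {
    m <- cfg$mixed_traits[k]
    sgn <- pats[[((k - 1L) %% 3L) + 1L]][site_index]
    eff[m] <- sgn * abs(cfg$trait_effects[[m]] %||% 0)
  }
  e <- as.vector(trait_mat %*% eff)
  e - mean(e)
}

#' Simulate historical and current occurrence matrices
#'
#' Historical occupancy: sites in the same cluster group draw from a shared
#' group species pool (each regional species enters a pool with probability
#' `pool_rate`, each pool species occurs at a member site with probability
#' `site_rate`; widespread-guild species occur everywhere). Current
#' occupancy: each historically present species persists with probability
#' \deqn{\mathrm{logit}^{-1}\!\big(\mathrm{logit}(b) + d_s\,(e_i - g)\big)}
#' where \eqn{b} is the baseline persistence, \eqn{d_s} the site's
#' disturbance intensity, \eqn{g} the community-wide loss coefficient, and
#' \eqn{e_i} the species' centred trait-effect sum. Optional exotic species
#' establish in current assemblages with probability proportional to
#' disturbance.
#'
#' @param cfg A [scenario_config()].
#' @param traits Trait tibble from [simulate_pool()] (regenerated from `cfg`
#'   if omitted).
#' @return Named list with `historical` and `current` occurrence tibbles and
#'   `groups`, a tibble of the true site-to-group assignment.
#' @export
simulate_occurrence <- function(cfg, traits = NULL) {
  stopifnot(inherits(cfg, "fibir_scenario"))
  traits <- traits %||% simulate_pool(cfg)
  tm <- as.matrix(traits[setdiff(names(traits), "species")])
  rownames(tm) <- traits$species
  set.seed(cfg$seed + 1L)
  n <- nrow(tm)
  wide <- rowSums(tm[, cfg$widespread_traits, drop = FALSE]) > 0
  grp <- sort(rep_len(seq_len(cfg$n_groups), cfg$n_sites))
  pools <- lapply(seq_len(cfg$n_groups), function(g) {
    wide | (runif(n) < cfg$pool_rate)
  })
  sites <- sprintf("S%02d", seq_len(cfg$n_sites))
  draw_site <- function(s) {
    for (try in 1:2) {
      occ <- pools[[grp[s]]] & (wide | runif(n) < cfg$site_rate)
      if (any(occ)) return(occ)
    }
    abort(sprintf("site %s empty after resampling; raise site_rate", sites[s]))
  }
  hist_m <- vapply(seq_len(cfg$n_sites), draw_site, logical(n))
  cur_m <- hist_m
  for (s in seq_len(cfg$n_sites)) {
    e <- site_effects(cfg, tm, s)
    p <- plogis(qlogis(cfg$baseline_persistence) +
                  cfg$disturbance[s] * (e - cfg$global_loss))
    p[wide] <- pmax(p[wide], 0.998)
    keep <- runif(n) < p
    if (!any(hist_m[, s] & keep)) keep <- runif(n) < p  # resample once
    if (!any(hist_m[, s] & keep)) {
      abort(sprintf("site %s lost all species under disturbance", sites[s]))
    }
    cur_m[, s] <- hist_m[, s] & keep
  }
  as_occ <- function(m, era) {
    out <- dplyr::bind_cols(tibble::tibble(site = sites),
                            tibble::as_tibble(t(m) * 1L))
    validate_occurrence(out, era = era)
  }
  historical <- as_occ(hist_m, "historical")
  current <- as_occ(cur_m, "current")
  if (cfg$n_exotic > 0) {
    ex <- matrix(0L, cfg$n_sites, cfg$n_exotic,
                 dimnames = list(NULL, sprintf("ex%03d", seq_len(cfg$n_exotic))))
    for (s in seq_len(cfg$n_sites)) {
      ex[s, ] <- as.integer(runif(cfg$n_exotic) < 0.6 * cfg$disturbance[s])
    }
    current <- dplyr::bind_cols(current, tibble::as_tibble(ex))
    current <- validate_occurrence(current, era = "current")
  }
  list(historical = historical, current = current,
       groups = tibble::tibble(site = sites, group = grp))
}

# exotic species trait rows: lentic generalist profile
exotic_traits <- function(cfg, n_exotic) {
  voc <- trait_vocabulary()
  tr <- matrix(0L, n_exotic, length(voc),
               dimnames = list(sprintf("ex%03d", seq_len(n_exotic)), voc))
  tr[, "NFM"] <- 1L; tr[, "MF"] <- 1L; tr[, "LAF"] <- 1L; tr[, "STF"] <- 1L
  tr[, c("HYF", "EUF", "OF")] <- 1L
  dplyr::bind_cols(tibble::tibble(species = rownames(tr)), tibble::as_tibble(tr))
}

#' Simulate site metadata with environmental covariates
#'
#' Produces the 11 covariates consumed by the driver analysis: human
#' pressure (GDP, LUR, CTP) and environmental filtering (WA, VR, TEM, PRE,
#' NRAD, HT, DWN, ALT). Environmental covariates follow the longitudinal
#' structure of a large subtropical river (altitude falls, temperature and
#' runoff rise downstream); the human-pressure covariates GDP and LUR are
#' coupled to the configured disturbance intensities (GDP negatively, land
#' use positively), so driver analyses on simulated scenarios have a
#' recoverable human-pressure signal. CTP is the dense rank of the
#' time-weighted connectivity index of the simulated network.
#'
#' @param cfg A [scenario_config()].
#' @param network Optional [river_network()]; simulated from `cfg` if omitted.
#' @return Tibble with `site`, `habitat_type`, and covariate columns.
#' @export
simulate_metadata <- function(cfg, network = NULL) {
  stopifnot(inherits(cfg, "fibir_scenario"))
  network <- network %||% simulate_network(cfg)
  set.seed(cfg$seed + 2L)
  n <- cfg$n_sites
  pos <- seq(0, 1, length.out = n)  # upstream -> downstream
  res <- trci(network, years = seq(min(network$barriers$year), cfg$eval_year))
  ctp <- ctp_ordinal(res)$ctp
  tibble::tibble(
    site = sprintf("S%02d", seq_len(n)),
    habitat_type = factor(ifelse(seq_len(n) %% 2 == 0, "TR", "NRAD"),
                          levels = c("NRAD", "TR")),
    GDP = round(exp(2 + 2.5 * (1 - cfg$disturbance) + rnorm(n, 0, 0.25)), 1),
    LUR = round(pmin(0.95, 0.05 + 0.4 * cfg$disturbance + runif(n, 0, 0.08)), 3),
    WA = round(exp(1 + 1.5 * pos + rnorm(n, 0, 0.4)), 1),
    VR = round(exp(3 + 2.5 * pos + rnorm(n, 0, 0.2)), 0),
    TEM = round(15 + 7 * pos + rnorm(n, 0, 0.5), 1),
    PRE = round(1100 + 700 * pos + rnorm(n, 0, 80), 0),
    NRAD = round(network$segments$length_km, 1),
    HT = ifelse(seq_len(n) %% 2 == 0, 2L, 1L),
    DWN = round(0.2 + 0.6 * runif(n), 3),
    ALT = round(pmax(1, 1100 * (1 - pos)^1.5 + 20 + rnorm(n, 0, 15)), 0),
    CTP = as.integer(ctp)
  )
}

#' Simulate a dammed mainstem river network
#'
#' A chain of `n_sites` first-order segments separated by barriers with the
#' configured commissioning years. Most barriers are complete (passability
#' 0); the two most recent have fish-passage facilities (passability 0.25).
#'
#' @param cfg A [scenario_config()].
#' @return A [river_network()].
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "fibir_scenario"))
  set.seed(cfg$seed + 3L)
  n <- cfg$n_sites
  segs <- tibble::tibble(
    id = sprintf("S%02d", seq_len(n)),
    length_km = round(exp(runif(n, log(6), log(350))), 1),
    rank = 1
  )
  yrs <- sort(rep_len(cfg$barrier_years, n - 1L))
  barr <- tibble::tibble(
    from = segs$id[-n], to = segs$id[-1],
    passability = c(rep(0, n - 3L), 0.25, 0.25)[seq_len(n - 1L)],
    year = yrs
  )
  river_network(segs, barr)
}

#' Simulate a complete scenario bundle
#'
#' Runs [simulate_pool()], [simulate_occurrence()], [simulate_network()] and
#' [simulate_metadata()] under one seed.
#'
#' @param cfg A [scenario_config()].
#' @return Named list: `traits`, `historical`, `current`, `groups`,
#'   `network`, `metadata`, `config`.
#' @export
simulate_scenario <- function(cfg = scenario_config()) {
  traits <- simulate_pool(cfg)
  if (cfg$n_exotic > 0) {
    traits <- validate_traits(dplyr::bind_rows(traits, exotic_traits(cfg, cfg$n_exotic)))
  }
  occ <- simulate_occurrence(cfg, traits)
  network <- simulate_network(cfg)
  metadata <- simulate_metadata(cfg, network)
  list(traits = traits, historical = occ$historical, current = occ$current,
       groups = occ$groups, network = network, metadata = metadata,
       config = cfg)
}

#' Write a scenario bundle to a directory of CSV files
#'
#' @param scn Result of [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scn, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(scn$historical, file.path(dir, "occurrence_historical.csv"))
  readr::write_csv(scn$current, file.path(dir, "occurrence_current.csv"))
  readr::write_csv(scn$traits, file.path(dir, "traits.csv"))
  readr::write_csv(scn$metadata, file.path(dir, "site_metadata.csv"))
  readr::write_csv(scn$groups, file.path(dir, "true_groups.csv"))
  readr::write_csv(scn$network$segments, file.path(dir, "segments.csv"))
  readr::write_csv(scn$network$barriers, file.path(dir, "barriers.csv"))
  invisible(dir)
}
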