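# Two-endmember mixing simulator. A thaumarchaeotal endmember is
# constructed to sit exactly on the ring-index/TEX86 core-top calibration
# at a target temperature; an MG-II endmember is enriched in GDGTs with
# 1-4 cyclopentane rings and carries no crenarchaeol. Linear pool mixing
# plus Dirichlet compositional noise and lognormal qPCR noise emulate a
# salinity-gradient transect in which the MG-II share of the GDGT pool
# tracks the MG-II share of archaeal 16S copies.

#' Specification of the thaumarchaeotal endmember
#'
#' The endmember is built backwards from the calibration: a target
#' temperature fixes the TEX86 value, `tex_pool_share` percent of the
#' profile is allocated to the TEX86 denominator compounds (GDGT-1/2/3 and
#' the crenarchaeol regioisomer), the numerator weights split the TEX86
#' numerator among GDGT-2, GDGT-3 and the regioisomer, and crenarchaeol is
#' then solved for so that RI_1 lands exactly on the core-top parabola.
#'
#' @param temperature Target temperature, degrees Celsius (must invert to a
#'   TEX86 in (0, 1]).
#' @param tex_pool_share Percent of the profile allocated to the TEX86
#'   compounds.
#' @param numerator_weights Length-3 non-negative weights (GDGT-2, GDGT-3,
#'   regioisomer) summing to 1.
#' @param g4_share Percent allocated to GDGT-4 (trace in thaumarchaeotal
#'   pools).
#' @return A list with class `thaum_endmember_spec`.
#' @export
thaum_endmember_spec <- function(temperature, tex_pool_share = 30,
                                 numerator_weights = c(0.55, 0.25, 0.20),
                                 g4_share = 0.5) {
  stopifnot(length(numerator_weights) == 3, all(numerator_weights >= 0),
            abs(sum(numerator_weights) - 1) <= 1e-9,
            tex_pool_share > 0, tex_pool_share < 100,
            g4_share >= 0, g4_share < 100)
  structure(list(temperature = temperature,
                 tex_pool_share = tex_pool_share,
                 numerator_weights = numerator_weights,
                 g4_share = g4_share),
            class = "thaum_endmember_spec")
}

#' Specification of the MG-II endmember
#'
#' A ring-enriched profile over GDGT-0..4 with no crenarchaeol (MG-II is
#' not taken to be a crenarchaeol source) and, by default, no regioisomer.
#' The true GDGT composition of MG-II is unresolved pending a pure culture;
#' these weights are an explicit modelling assumption, not a measurement.
#'
#' @param ring_weights Length-5 non-negative weights over GDGT-0..4 summing
#'   to 1.
#' @param cren_iso_share Percent allocated to the crenarchaeol regioisomer.
#' @return A list with class `mgii_endmember_spec`.
#' @export
mgii_endmember_spec <- function(ring_weights = c(0.20, 0.35, 0.20, 0.15, 0.10),
                                cren_iso_share = 0) {
  stopifnot(length(ring_weights) == 5, all(ring_weights >= 0),
            abs(sum(ring_weights) - 1) <= 1e-9,
            cren_iso_share >= 0, cren_iso_share < 100)
  structure(list(ring_weights = ring_weights,
                 cren_iso_share = cren_iso_share),
            class = "mgii_endmember_spec")
}

#' Construct the thaumarchaeotal endmember profile
#'
#' Inverts the temperature calibration to the target TEX86 `t*`, allocates
#' the TEX86 compounds, solves crenarchaeol from the RI_1 parabola and puts
#' the remainder in GDGT-0, so that by construction `tex86(profile) = t*`
#' and `ring_index_1(profile) = predicted_ri(t*)` (delta-RI = 0).
#'
#' @param spec A [thaum_endmember_spec()].
#' @param cal A [calibration_params()].
#' @return A one-row [gdgt_profile()].
#' @export
thaum_endmember <- function(spec, cal = calibration_params()) {
  stopifnot(inherits(spec, "thaum_endmember_spec"))
  t_star <- cal$log_base^((spec$temperature - cal$intercept) / cal$slope)
  if (!is.finite(t_star) || t_star <= 0 || t_star > 1) {
    stop(sprintf("temperature %.3g degC inverts to TEX86 = %.3g, outside (0, 1]",
                 spec$temperature, t_star), call. = FALSE)
  }
  S <- spec$tex_pool_share
  w <- spec$numerator_weights
  g1 <- (1 - t_star) * S
  g2 <- t_star * S * w[1]
  g3 <- t_star * S * w[2]
  cren_iso <- t_star * S * w[3]
  g4 <- spec$g4_share
  cren <- (100 * predicted_ri(t_star, cal) -
             g1 - 2 * g2 - 3 * g3 - 4 * cren_iso) / 4
  if (cren < 0) {
    stop("infeasible endmember: solved crenarchaeol abundance is negative; ",
         "reduce tex_pool_share or raise the temperature", call. = FALSE)
  }
  g0 <- 100 - (g1 + g2 + g3 + g4 + cren + cren_iso)
  if (g0 < 0) {
    stop("infeasible endmember: GDGT-0 share is negative; ",
         "reduce tex_pool_share or g4_share", call. = FALSE)
  }
  gdgt_profile(g0 = g0, g1 = g1, g2 = g2, g3 = g3, g4 = g4,
               cren = cren, cren_iso = cren_iso, tol = 1e-6)
}

#' Construct the MG-II endmember profile
#'
#' @param spec A [mgii_endmember_spec()].
#' @return A one-row [gdgt_profile()] with `cren = 0`.
#' @export
mgii_endmember <- function(spec = mgii_endmember_spec()) {
  stopifnot(inherits(spec, "mgii_endmember_spec"))
  scale <- 100 - spec$cren_iso_share
  w <- spec$ring_weights * scale
  gdgt_profile(g0 = w[1], g1 = w[2], g2 = w[3], g3 = w[4], g4 = w[5],
               cren = 0, cren_iso = spec$cren_iso_share, tol = 1e-6)
}

#' Linear two-endmember mixture of GDGT profiles
#'
#' Componentwise `(1 - f) * thaum + f * mgii`; normalized inputs stay
#' normalized, and any index linear in the abundances (the ring indices)
#' mixes linearly too.
#'
#' @param f Mixing fraction(s) in `[0, 1]` (the MG-II share of the pool).
#' @param thaum,mgii One-row GDGT profiles.
#' @return A GDGT profile with `length(f)` rows.
#' @export
mix_profiles <- function(f, thaum, mgii) {
  stopifnot(all(f >= 0), all(f <= 1))
  a <- as.numeric(as.data.frame(thaum)[1, gdgt_cols])
  b <- as.numeric(as.data.frame(mgii)[1, gdgt_cols])
  m <- outer(1 - f, a) + outer(f, b)
  colnames(m) <- gdgt_cols
  as_gdgt_profile(as.data.frame(m), tol = 1e-6)
}

#' Transect simulation settings
#'
#' @param f_values Per-sample MG-II mixing fractions in `[0, 1)`. `f` is
#'   both the MG-II share of the GDGT pool and its share of archaeal 16S
#'   copies; lipid-per-cell and gene-copy-number disparities are folded
#'   into the qPCR noise term.
#' @param archaea_mean_log10 log10 mean archaeal 16S abundance (copies/L).
#' @param dirichlet_concentration Compositional noise concentration (larger
#'   = less noise; `Inf` switches noise off).
#' @param qpcr_sigma_log10 SD of the lognormal (base-10) qPCR noise.
#' @param seed Integer seed; all draws derive from it.
#' @return A list with class `transect_config`.
#' @export
transect_config <- function(f_values, archaea_mean_log10 = 9,
                            dirichlet_concentration = 500,
                            qpcr_sigma_log10 = 0.1, seed = 1) {
  stopifnot(length(f_values) >= 1, all(f_values >= 0), all(f_values < 1),
            dirichlet_concentration > 0, qpcr_sigma_log10 >= 0)
  structure(list(f_values = as.numeric(f_values),
                 n_samples = length(f_values),
                 archaea_mean_log10 = archaea_mean_log10,
                 dirichlet_concentration = dirichlet_concentration,
                 qpcr_sigma_log10 = qpcr_sigma_log10,
                 seed = as.integer(seed)),
            class = "transect_config")
}

# Dirichlet draw around a mean composition (percent rows). Zero components
# stay exactly zero (gamma with shape 0).
.rdirichlet_pct <- function(mean_pct, concentration) {
  if (!is.finite(concentration)) return(mean_pct)
  m <- as.matrix(mean_pct)
  draws <- matrix(stats::rgamma(length(m), shape = concentration * m / 100),
                  nrow = nrow(m))
  sums <- rowSums(draws)
  bad <- sums <= 0  # vanishingly unlikely; keep the mean if it happens
  draws[bad, ] <- m[bad, ]
  out <- 100 * draws / rowSums(draws)
  colnames(out) <- colnames(m)
  out
}

.substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * k) %% 2147483647L)
}

#' Simulate a two-endmember transect dataset
#'
#' For each sample `i`: the noiseless mixture at `f_i` is perturbed by a
#' Dirichlet draw (independently per lipid pool, so CL / total-IPL /
#' phospho-IPL differ only by noise); the archaeal 16S abundance is drawn
#' lognormally around `archaea_mean_log10`; the MG-II abundance is
#' `f_i * archaea_16s` perturbed by lognormal qPCR noise. Fully
#' reproducible from the seed; per-pool and qPCR draws use substreams
#' derived deterministically from it.
#'
#' @param cfg A [transect_config()].
#' @param thaum A [thaum_endmember_spec()].
#' @param mgii A [mgii_endmember_spec()].
#' @param cal A [calibration_params()].
#' @return A [gdgt_dataset()] with profiles and computed indices for all
#'   three pools, gene abundances, and the true mixing fraction in
#'   `samples$f_true`.
#' @export
simulate_transect <- function(cfg,
                              thaum = thaum_endmember_spec(temperature = 25),
                              mgii = mgii_endmember_spec(),
                              cal = calibration_params()) {
  stopifnot(inherits(cfg, "transect_config"))
  em_thaum <- thaum_endmember(thaum, cal)
  em_mgii <- mgii_endmember(mgii)
  f <- cfg$f_values
  n <- cfg$n_samples
  mixture <- mix_profiles(f, em_thaum, em_mgii)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)

  profiles <- dplyr::bind_rows(lapply(seq_along(pool_levels), function(k) {
    set.seed(.substream_seed(cfg$seed, k))
    noisy <- .rdirichlet_pct(as.data.frame(mixture)[gdgt_cols],
                             cfg$dirichlet_concentration)
    out <- tibble::as_tibble(as.data.frame(noisy))
    out$sample_id <- sprintf("syn_%03d", seq_len(n))
    out$pool <- pool_levels[k]
    out[c("sample_id", "pool", gdgt_cols)]
  }))

  set.seed(.substream_seed(cfg$seed, 0))
  archaea <- 10^(stats::rnorm(n, cfg$archaea_mean_log10,
                              cfg$qpcr_sigma_log10))
  mgii_counts <- f * archaea *
    10^(stats::rnorm(n, 0, cfg$qpcr_sigma_log10))

  samples <- tibble::tibble(
    sample_id = sprintf("syn_%03d", seq_len(n)),
    station = "synthetic",
    water_type = "mixing",
    f_true = f,
    archaea_16s = archaea,
    mgii_16s = mgii_counts)
  ds <- gdgt_dataset(samples, profiles = profiles,
                     provenance = sprintf(
                       "simulated two-endmember transect (seed %d)", cfg$seed),
                     tol = 1e-6)
  compute_dataset_indices(ds)
}
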