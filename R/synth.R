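# Seeded synthetic-data generators.  Each emulates the statistical
# structure one analysis stage assumes (two-state CD basis mixture, skewed
# emission peak, Hill-type hemolysis, two-fold-quantized MIC table, planted
# linear SAR), so every stage is testable without external data.  All
# randomness flows from an explicit seed; the caller's RNG state is never
# touched.

#' Configuration for the synthetic-data generators
#'
#' Defaults state the emulated world once: a CD acquisition at 45 uM,
#' 0.2 cm path and 11 residues; instrument-level CD noise small against the
#' ~3e4 deg cm^2 dmol^-1 helix signal; 1% multiplicative fluorescence noise;
#' steep (Hill ~ 4) hemolysis curves with HC50 spanning the 8-256 ug/mL
#' range that brackets observed MHCs (16-128); MIC log2-potencies centered
#' at 1.5 (about 2.8 ug/mL, the potency scale of the family) with 0.8 log2
#' units of spread; and a planted hemolysis-vs-helicity line spanning
#' roughly 10-90% over helical fractions 0.55-0.95.
#'
#' @param seed Integer seed (mandatory).
#' @param n_peptides Number of peptides emulated (default 11).
#' @param cd_noise_sd Additive CD noise, deg cm^2 dmol^-1.
#' @param fluor_noise_frac Multiplicative emission noise as a fraction of
#'   the local intensity.
#' @param hemolysis_hill Hill coefficient of synthetic hemolysis curves.
#' @param hemolysis_hc50_range `c(min, max)` ug/mL for drawn HC50 values.
#' @param mic_log2_mean,mic_log2_sd Normal parameters of the latent log2
#'   MIC potency.
#' @param planted_sar_slope,planted_sar_intercept,sar_noise_sd Planted
#'   linear relation (hemolysis % per unit helical fraction) and its
#'   Gaussian noise.
#' @param concentration_M,path_cm,n_residues CD acquisition metadata used to
#'   convert model ellipticities back to instrument mdeg.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_peptides = 11,
                         cd_noise_sd = 200,
                         fluor_noise_frac = 0.01,
                         hemolysis_hill = 4,
                         hemolysis_hc50_range = c(8, 256),
                         mic_log2_mean = 1.5,
                         mic_log2_sd = 0.8,
                         planted_sar_slope = 200,
                         planted_sar_intercept = -100,
                         sar_noise_sd = 4,
                         concentration_M = 45e-6,
                         path_cm = 0.2,
                         n_residues = 11) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(cd_noise_sd >= 0, fluor_noise_frac >= 0, sar_noise_sd >= 0,
            mic_log2_sd >= 0, hemolysis_hill > 0,
            all(hemolysis_hc50_range > 0))
  structure(as.list(environment()), class = "synth_config")
}

#' Two-state CD basis spectra
#'
#' Gaussian-band model bases used by [synth_cd()]: the helix basis `B_H` has
#' negative bands at 208 and 222 nm and a positive band near 193 nm, with
#' amplitudes tied so that `B_H(222)` equals the finite-length helix limit
#' `-42500 * (1 - 3/n)`; the coil basis `B_C` is a negative band near 198 nm
#' offset so that `B_C(222) = +640`, the coil baseline of
#' [helical_fraction()].  A mixture `f*B_H + (1-f)*B_C` therefore satisfies
#' `helical_fraction(theta(222), n) == f` exactly in the noiseless case, and
#' all mixtures cross where `B_H == B_C` (the isodichroic point, near
#' 204 nm for these bands).
#'
#' @param lambda Wavelengths, nm.
#' @param n_residues Peptide length.
#' @return List with numeric vectors `helix` and `coil`
#'   (deg cm^2 dmol^-1).
#' @export
cd_two_state_basis <- function(lambda, n_residues = 11) {
  g <- function(l, c, s) exp(-(l - c)^2 / (2 * s^2))
  th <- .CD_THETA_HELIX_INF * (1 - .CD_HELIX_K / n_residues)
  a193 <- -1.8 * th
  a208 <- 0.95 * th
  # solve the 222 nm amplitude so the basis hits the helix limit exactly
  a222 <- th - a193 * g(222, 193, 5.5) - a208 * g(222, 208, 5)
  helix <- a193 * g(lambda, 193, 5.5) + a208 * g(lambda, 208, 5) +
    a222 * g(lambda, 222, 6)
  a198 <- -21000
  c0 <- .CD_THETA_COIL - a198 * g(222, 198, 7)
  coil <- a198 * g(lambda, 198, 7) + c0
  list(helix = helix, coil = coil)
}

#' Synthesize a raw CD spectrum from a helix fraction
#'
#' Two-state mixture `f*B_H + (1-f)*B_C` of the [cd_two_state_basis()]
#' bases plus Gaussian noise (sd `config$cd_noise_sd`, in ellipticity
#' units), converted back to instrument millidegrees with the config's
#' concentration / path / residue count so that [normalize_ellipticity()]
#' round-trips.
#'
#' @param f_helix Helical fraction in `[0, 1]`.
#' @param config A [synth_config()].
#' @param seed Seed override (default `config$seed`).
#' @param grid Wavelength grid, nm.
#' @return A [raw_cd_spectrum()].
#' @export
synth_cd <- function(f_helix, config, seed = config$seed,
                     grid = seq(190, 260, by = 0.5)) {
  stopifnot(inherits(config, "synth_config"))
  if (f_helix < 0 || f_helix > 1) stop("f_helix must lie in [0, 1]")
  basis <- cd_two_state_basis(grid, config$n_residues)
  theta <- f_helix * basis$helix + (1 - f_helix) * basis$coil
  theta <- theta + with_local_seed(seed,
                                   rnorm(length(grid), 0, config$cd_noise_sd))
  raw_cd_spectrum(grid,
                  theta * 10 * config$concentration_M * config$path_cm *
                    config$n_residues,
                  config$concentration_M, config$path_cm, config$n_residues,
                  solvent = sprintf("synthetic f=%.3g", f_helix))
}

#' Synthesize a tryptophan emission spectrum
#'
#' Split-Gaussian peak (narrower on the blue side, broader on the red side,
#' the usual asymmetry of tryptophan emission) whose mode equals
#' `lambda_max_true` in the noiseless limit, on the 300-450 nm grid at
#' 0.2 nm, with multiplicative Gaussian noise of relative sd
#' `config$fluor_noise_frac`.
#'
#' @param lambda_max_true True emission maximum, nm, strictly inside
#'   (300, 450).
#' @param config A [synth_config()].
#' @param seed Seed override (default `config$seed`).
#' @param label Spectrum label.
#' @return An [emission_spectrum()].
#' @export
synth_emission <- function(lambda_max_true, config, seed = config$seed,
                           label = "synthetic") {
  stopifnot(inherits(config, "synth_config"))
  if (lambda_max_true <= 300 || lambda_max_true >= 450) {
    stop("lambda_max_true must lie strictly inside the 300-450 nm band")
  }
  grid <- seq(300, 450, by = 0.2)
  sigma <- ifelse(grid < lambda_max_true, 12, 18)
  shape <- 1000 * exp(-(grid - lambda_max_true)^2 / (2 * sigma^2))
  noise <- with_local_seed(seed,
                           rnorm(length(grid), 0, config$fluor_noise_frac))
  emission_spectrum(grid, pmax(0, shape * (1 + noise)), label = label)
}

#' Synthesize a Hill-type hemolysis curve
#'
#' `H(c) = 100 / (1 + (hc50 / c)^hill)` evaluated on a two-fold
#' concentration series.  Deterministic: hemolysis extents are triplicate
#' averages in practice, and the threshold logic is what needs testing.
#'
#' @param hc50 Concentration of half-maximal lysis, ug/mL.
#' @param hill Hill coefficient (> 0).
#' @param series Tested concentrations (default the two-fold series 1-128).
#' @param peptide_id Label.
#' @return A [hemolysis_curve()].
#' @export
synth_hemolysis <- function(hc50, hill, series = 2^(0:7),
                            peptide_id = "synthetic") {
  stopifnot(hc50 > 0, hill > 0)
  h <- 100 / (1 + (hc50 / series)^hill)
  hemolysis_curve(peptide_id, series, h)
}

#' Synthesize a two-fold-quantized MIC table
#'
#' Latent log2 potencies are drawn per cell from
#' `Normal(mic_log2_mean, mic_log2_sd)`, rounded up to the next integer
#' power of two (a two-fold dilution series reports the first inhibiting
#' well) and clipped to the tested 1-128 ug/mL range.  The panel mirrors
#' the usual structure: 4 Gram-positive strains, 5 Gram-negative strains
#' and one "other" (multidrug-resistant) strain excluded from GM summaries.
#'
#' @param config A [synth_config()].
#' @param seed Seed override (default `config$seed`).
#' @return A [mic_table()] with peptides `W1..Wn`.
#' @export
synth_mic_table <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  gram <- c(rep("positive", 4), rep("negative", 5), "other")
  n_s <- length(gram)
  n_p <- config$n_peptides
  pot <- with_local_seed(seed,
                         matrix(rnorm(n_s * n_p, config$mic_log2_mean,
                                      config$mic_log2_sd), n_s, n_p))
  mic <- matrix(2^pmin(7, pmax(0, ceiling(pot))), n_s, n_p)
  rownames(mic) <- c(paste0("GP", 1:4), paste0("GN", 1:5), "MDR1")
  colnames(mic) <- paste0("W", seq_len(n_p))
  mic_table(mic, gram)
}

#' Synthesize a SAR table with a planted linear relation
#'
#' Helical fractions are spread evenly over 0.55-0.95 (the helicity range a
#' TFE-folded family typically spans) and the hemolysis response follows
#' `planted_sar_slope * f + planted_sar_intercept` plus Gaussian noise of
#' sd `sar_noise_sd`.
#'
#' @param config A [synth_config()].
#' @param seed Seed override (default `config$seed`).
#' @return A [sar_table()] with parameter column `helical_fraction`; the
#'   planted slope/intercept are attached as attribute `"planted"`.
#' @export
synth_sar_table <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_peptides
  f <- seq(0.55, 0.95, length.out = n)
  y <- config$planted_sar_slope * f + config$planted_sar_intercept +
    with_local_seed(seed, rnorm(n, 0, config$sar_noise_sd))
  out <- sar_table(paste0("W", seq_len(n)), y,
                   data.frame(helical_fraction = f))
  attr(out, "planted") <- c(slope = config$planted_sar_slope,
                            intercept = config$planted_sar_intercept)
  out
}
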