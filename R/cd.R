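# Circular dichroism: normalization of raw mdeg signals to mean residue
# molar ellipticity, interpolation, single-wavelength helicity estimation,
# the [theta]222 x [theta]208 product and isodichroic-point detection.

# single-wavelength helicity estimator constants (deg cm^2 dmol^-1)
.CD_THETA_COIL <- 640       # coil baseline at 222 nm
.CD_THETA_HELIX_INF <- -42500  # infinite-length helix limit at 222 nm
.CD_HELIX_K <- 3            # finite-length correction: theta_n = inf*(1 - k/n)

#' Raw CD spectrum (instrument units)
#'
#' @param wavelengths Strictly monotone wavelength grid, nm.
#' @param signal_mdeg CD signal in millidegrees, same length.
#' @param concentration_M Peptide concentration, mol/L.
#' @param path_cm Cuvette path length, cm.
#' @param n_residues Number of residues (for per-residue normalization).
#' @param solvent Free-text solvent label (e.g. `"50% TFE"`).
#' @param blank Optional raw blank spectrum on the same grid, subtracted at
#'   construction (solvent-signal subtraction).
#' @return Object of class `raw_cd_spectrum`.
#' @export
raw_cd_spectrum <- function(wavelengths, signal_mdeg, concentration_M,
                            path_cm, n_residues, solvent = "",
                            blank = NULL) {
  stopifnot(length(wavelengths) == length(signal_mdeg),
            length(wavelengths) >= 2)
  d <- diff(wavelengths)
  if (!(all(d > 0) || all(d < 0))) stop("wavelength grid must be strictly monotone")
  if (is.null(concentration_M) || is.null(path_cm) || is.null(n_residues) ||
      concentration_M <= 0 || path_cm <= 0 || n_residues <= 0) {
    stop("missing or non-positive metadata (concentration_M, path_cm, n_residues)")
  }
  if (!is.null(blank)) {
    stopifnot(inherits(blank, "raw_cd_spectrum"))
    if (!isTRUE(all.equal(blank$wavelengths, wavelengths))) {
      stop("blank spectrum must share the sample wavelength grid")
    }
    signal_mdeg <- signal_mdeg - blank$signal_mdeg
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 signal_mdeg = as.numeric(signal_mdeg),
                 concentration_M = concentration_M, path_cm = path_cm,
                 n_residues = as.integer(n_residues), solvent = solvent),
            class = "raw_cd_spectrum")
}

#' Normalize a raw CD signal to mean residue molar ellipticity
#'
#' \deqn{[\theta]_\lambda = \theta_\lambda(\mathrm{mdeg}) /
#'   (10 \cdot C(\mathrm{M}) \cdot l(\mathrm{cm}) \cdot N_{res})}
#' in deg cm^2 dmol^-1.  The transform is linear and invertible given the
#' metadata; [denormalize_ellipticity()] is its exact inverse.
#'
#' @param raw A [raw_cd_spectrum()].
#' @return Object of class `cd_spectrum` with fields `wavelengths`, `theta`
#'   and the acquisition metadata.
#' @export
normalize_ellipticity <- function(raw) {
  stopifnot(inherits(raw, "raw_cd_spectrum"))
  theta <- raw$signal_mdeg /
    (10 * raw$concentration_M * raw$path_cm * raw$n_residues)
  structure(list(wavelengths = raw$wavelengths, theta = theta,
                 concentration_M = raw$concentration_M,
                 path_cm = raw$path_cm, n_residues = raw$n_residues,
                 solvent = raw$solvent),
            class = "cd_spectrum")
}

#' @rdname normalize_ellipticity
#' @param spectrum A `cd_spectrum`.
#' @export
denormalize_ellipticity <- function(spectrum) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  raw_cd_spectrum(spectrum$wavelengths,
                  spectrum$theta * 10 * spectrum$concentration_M *
                    spectrum$path_cm * spectrum$n_residues,
                  spectrum$concentration_M, spectrum$path_cm,
                  spectrum$n_residues, spectrum$solvent)
}

#' Ellipticity at an arbitrary wavelength
#'
#' Linear interpolation between bracketing grid points; exact at grid points.
#'
#' @param spectrum A `cd_spectrum`.
#' @param wavelength Query wavelength(s), nm; must lie within the grid range.
#' @return Mean residue molar ellipticity, deg cm^2 dmol^-1.
#' @export
cd_value_at <- function(spectrum, wavelength) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  rng <- range(spectrum$wavelengths)
  if (any(wavelength < rng[1] | wavelength > rng[2])) {
    stop(sprintf("wavelength outside the measured range [%g, %g] nm",
                 rng[1], rng[2]))
  }
  approx(spectrum$wavelengths, spectrum$theta, xout = wavelength,
         method = "linear", ties = "ordered")$y
}

#' Resample a CD spectrum onto a regular grid
#'
#' Linear interpolation onto an ascending grid with the given step (default
#' 0.5 nm, the usual acquisition resolution), restricted to the measured
#' range.  Family operations such as [isodichroic_point()] require a shared
#' grid.
#'
#' @param spectrum A `cd_spectrum`.
#' @param step Grid step, nm.
#' @param range Optional `c(min, max)` to clip the grid.
#' @return A `cd_spectrum` on the new grid.
#' @export
resample_cd <- function(spectrum, step = 0.5, range = NULL) {
  rng <- base::range(spectrum$wavelengths)
  if (!is.null(range)) rng <- c(max(rng[1], range[1]), min(rng[2], range[2]))
  grid <- seq(ceiling(rng[1] / step) * step, floor(rng[2] / step) * step,
              by = step)
  out <- spectrum
  out$wavelengths <- grid
  out$theta <- cd_value_at(spectrum, grid)
  out
}

#' Helical fraction from the 222 nm ellipticity
#'
#' Closed-form single-wavelength estimator
#' \deqn{f = \frac{[\theta]_{222} - \theta_{coil}}
#'   {\theta_{helix}^{\infty}(1 - k/n) - \theta_{coil}}}
#' with \eqn{\theta_{coil} = +640}, \eqn{\theta_{helix}^{\infty} = -42500}
#' and \eqn{k = 3} (finite-length correction), clipped to `[0, 1]`.  This is
#' the standard Chen/Rohl-style estimate and documents the constants rather
#' than delegating to a neural-network deconvolution.
#'
#' @param theta_222 Mean residue molar ellipticity at 222 nm.
#' @param n_residues Peptide length (>= 4).
#' @return Helical fraction in `[0, 1]`.
#' @examples
#' helical_fraction(-25000, 11)   # 0.813
#' @export
helical_fraction <- function(theta_222, n_residues) {
  stopifnot(n_residues >= 4)
  full <- .CD_THETA_HELIX_INF * (1 - .CD_HELIX_K / n_residues)
  f <- (theta_222 - .CD_THETA_COIL) / (full - .CD_THETA_COIL)
  pmin(1, pmax(0, f))
}

#' Product of the 222 and 208 nm ellipticities
#'
#' A model-free helicity surrogate: both troughs deepen with helix content,
#' so for negative values the product grows as helicity grows.  Sign is
#' preserved (no absolute values).
#'
#' @param theta_222,theta_208 Mean residue molar ellipticities.
#' @return The plain product, (deg cm^2 dmol^-1)^2.
#' @export
theta_product <- function(theta_222, theta_208) {
  theta_222 * theta_208
}

#' Scalar CD summary of a spectrum
#'
#' @param spectrum A `cd_spectrum`.
#' @return One-row data.frame: `theta_222`, `theta_208`, `theta_203`,
#'   `theta_product`, `helical_fraction`.
#' @export
cd_summary <- function(spectrum) {
  t222 <- cd_value_at(spectrum, 222)
  t208 <- cd_value_at(spectrum, 208)
  t203 <- cd_value_at(spectrum, 203)
  data.frame(theta_222 = t222, theta_208 = t208, theta_203 = t203,
             theta_product = theta_product(t222, t208),
             helical_fraction = helical_fraction(t222, spectrum$n_residues))
}

#' Isodichroic point of a spectrum family
#'
#' For a two-state (coil/helix) equilibrium, spectra recorded along the
#' transition all cross where the two basis spectra are equal.  The detector
#' returns the wavelength in `window` minimizing the across-spectra standard
#' deviation of the ellipticity, or `NA` if that minimum deviation exceeds
#' `tol_frac` times the median absolute ellipticity there (no credible
#' crossing).  Ties break to the lowest wavelength.
#'
#' @param spectra List of >= 3 `cd_spectrum` objects on a common grid
#'   (resample with [resample_cd()] first; differing grids are an error).
#' @param window `c(min, max)` search window, nm (default 195-215).
#' @param tol_frac Acceptance tolerance as a fraction of the median
#'   `abs(theta)` at the candidate wavelength (default 0.10).
#' @return Wavelength in nm, or `NA_real_` if no isodichroic point is found.
#' @export
isodichroic_point <- function(spectra, window = c(195, 215), tol_frac = 0.10) {
  stopifnot(length(spectra) >= 3)
  grid <- spectra[[1]]$wavelengths
  for (s in spectra[-1]) {
    if (!isTRUE(all.equal(s$wavelengths, grid))) {
      stop("spectra are on different wavelength grids; resample_cd() them first")
    }
  }
  sel <- grid >= window[1] & grid <= window[2]
  if (!any(sel)) stop("search window outside the common grid")
  mat <- vapply(spectra, function(s) s$theta[sel], numeric(sum(sel)))
  sds <- apply(mat, 1, sd)
  i <- which.min(sds)  # which.min ties break to the first (lowest wavelength)
  scale <- median(abs(mat[i, ]))
  if (scale > 0 && sds[i] > tol_frac * scale) return(NA_real_)
  grid[sel][i]
}
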