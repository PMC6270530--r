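# Activity indices: geometric-mean MIC (GM), hemolysis normalization,
# minimal hemolytic concentration (MHC) and pseudo-therapeutic index
# TI' = MHC / GM.

#' MIC table (strains x peptides)
#'
#' Container for a minimal-inhibitory-concentration panel from a two-fold
#' dilution series.  Out-of-range cells (reported as e.g. ">128") are carried
#' as explicit bound markers, never as the numeric bound.
#'
#' @param mic Numeric matrix, rows = strains, columns = peptides, ug/mL.
#' @param gram Character vector per strain: `"positive"`, `"negative"` or
#'   `"other"` (e.g. a multidrug-resistant strain kept out of GM summaries).
#' @param censored Logical matrix, same shape: `TRUE` where the cell is a
#'   "greater than" bound at the stored value.
#' @return Object of class `mic_table`.
#' @export
mic_table <- function(mic, gram, censored = NULL) {
  mic <- as.matrix(mic)
  stopifnot(is.numeric(mic), nrow(mic) == length(gram))
  if (is.null(censored)) censored <- matrix(FALSE, nrow(mic), ncol(mic))
  stopifnot(identical(dim(censored), dim(mic)))
  dimnames(censored) <- dimnames(mic)
  gram <- match.arg(gram, c("positive", "negative", "other"),
                    several.ok = TRUE)
  if (any(!is.na(mic) & mic <= 0)) stop("MIC values must be > 0")
  if (any(is.na(mic))) stop("missing MIC cells must be explicit bound markers")
  structure(list(mic = mic, gram = gram, censored = censored,
                 peptide_ids = colnames(mic), strain_ids = rownames(mic)),
            class = "mic_table")
}

#' Geometric mean of MIC values
#'
#' Computed in the log2 domain (exact on power-of-two dilution series):
#' `2^mean(log2(x))`.  Out-of-range (censored) values cannot enter a
#' geometric mean and raise an error.
#'
#' @param mics Positive finite MICs in ug/mL.
#' @param censored Optional logical; any `TRUE` is an error.
#' @return Geometric mean in ug/mL (unrounded).
#' @examples
#' geometric_mean_mic(c(1, 1, 1, 2))   # 1.189..., prints as 1.2
#' @export
geometric_mean_mic <- function(mics, censored = NULL) {
  if (length(mics) == 0) stop("cannot take the geometric mean of no MICs")
  if (!is.null(censored) && any(censored)) {
    stop("out-of-range MIC markers cannot enter a geometric mean")
  }
  if (any(!is.finite(mics) | mics <= 0)) {
    stop("all MICs must be finite and > 0")
  }
  2^mean(log2(mics))
}

#' Percent hemolysis from absorbances
#'
#' Relative to the 100% lysis control (Triton X-100) after blank subtraction:
#' `100 * (A_sample - A_blank) / (A_triton - A_blank)`.
#'
#' @param a_sample,a_blank,a_triton Absorbances (e.g. at 550 nm).
#' @return Percent hemolysis.
#' @export
hemolysis_percent <- function(a_sample, a_blank, a_triton) {
  if (any(a_triton <= a_blank)) {
    stop("degenerate control: Triton absorbance must exceed the blank")
  }
  100 * (a_sample - a_blank) / (a_triton - a_blank)
}

#' Hemolysis dose-response curve
#'
#' @param peptide_id Identifier.
#' @param concentrations Strictly ascending tested concentrations, ug/mL
#'   (typically the two-fold series 1..128).
#' @param hemolysis_percent Percent lysis at each concentration; small
#'   negatives from blank subtraction are tolerated (values in `[-5, 105]`).
#' @return Object of class `hemolysis_curve`.
#' @export
hemolysis_curve <- function(peptide_id, concentrations, hemolysis_percent) {
  stopifnot(length(concentrations) == length(hemolysis_percent),
            length(concentrations) >= 1)
  if (any(diff(concentrations) <= 0)) {
    stop("concentrations must be strictly ascending")
  }
  if (any(hemolysis_percent < -5 | hemolysis_percent > 105)) {
    stop("hemolysis percent outside the plausible [-5, 105] range")
  }
  structure(list(peptide_id = peptide_id,
                 concentrations = as.numeric(concentrations),
                 hemolysis_percent = as.numeric(hemolysis_percent)),
            class = "hemolysis_curve")
}

#' Minimal hemolytic concentration
#'
#' The lowest tested concentration producing strictly more than `threshold`
#' percent hemolysis (default 5%).  If no tested concentration exceeds the
#' threshold, the result is an explicit "greater than max tested" bound.
#'
#' @param curve A [hemolysis_curve()].
#' @param threshold Percent hemolysis cut-off (default 5).
#' @return List with `value` (ug/mL; the max tested concentration when
#'   censored), `censored` (logical) and `label` (e.g. `"32"` or `">128"`).
#' @export
mhc <- function(curve, threshold = 5) {
  stopifnot(inherits(curve, "hemolysis_curve"))
  hit <- which(curve$hemolysis_percent > threshold)
  if (length(hit)) {
    v <- curve$concentrations[hit[1]]
    list(value = v, censored = FALSE, label = format(v))
  } else {
    v <- max(curve$concentrations)
    list(value = v, censored = TRUE, label = paste0(">", format(v)))
  }
}

#' Pseudo-therapeutic index TI' = MHC / GM
#'
#' Selectivity index between bacterial and human cells.  The division uses
#' the unrounded geometric mean (128 / 2.378... = 53.8; dividing by the
#' rounded 2.4 would not reproduce tabulated values).  A censored MHC
#' (">max") yields a lower bound, flagged via the `"lower_bound"` attribute.
#'
#' @param mhc_value Numeric MHC in ug/mL, or the list returned by [mhc()].
#' @param gm_value Unrounded geometric-mean MIC, ug/mL.
#' @return Dimensionless TI' (attribute `lower_bound` set when the MHC was a
#'   bound).
#' @export
pseudo_therapeutic_index <- function(mhc_value, gm_value) {
  censored <- FALSE
  if (is.list(mhc_value)) {
    censored <- isTRUE(mhc_value$censored)
    mhc_value <- mhc_value$value
  }
  if (!is.finite(gm_value) || gm_value <= 0) {
    stop("GM must be finite and > 0")
  }
  ti <- mhc_value / gm_value
  if (censored) attr(ti, "lower_bound") <- TRUE
  ti
}

#' Summarize activity: GM per Gram group, MHC and TI' per peptide
#'
#' Assembles, for every peptide of a MIC panel: geometric-mean MICs over the
#' Gram-positive strains, the Gram-negative strains and their union (strains
#' labeled `"other"` never enter), the MHC, and the three TI' values from the
#' unrounded GMs.
#'
#' @param table A [mic_table()].
#' @param curves Optional list of [hemolysis_curve()] (one per peptide), from
#'   which MHCs are computed at `threshold`.
#' @param mhc_values Alternatively, a named numeric vector of MHCs (ug/mL);
#'   names are peptide ids.  Exactly one of `curves` / `mhc_values` required.
#' @param threshold Percent hemolysis threshold for [mhc()].
#' @return data.frame with columns `peptide_id`, `gm_gram_positive`,
#'   `gm_gram_negative`, `gm_all`, `mhc`, `mhc_censored`,
#'   `ti_prime_positive`, `ti_prime_negative`, `ti_prime_all` (TI' columns
#'   are lower bounds where `mhc_censored`).
#' @export
summarize_activity <- function(table, curves = NULL, mhc_values = NULL,
                               threshold = 5) {
  stopifnot(inherits(table, "mic_table"))
  ids <- table$peptide_ids
  if (is.null(ids)) stop("MIC table has no peptide ids (column names)")
  if (is.null(curves) == is.null(mhc_values)) {
    stop("supply exactly one of 'curves' or 'mhc_values'")
  }
  if (!is.null(curves)) {
    ms <- lapply(curves, mhc, threshold = threshold)
    names(ms) <- vapply(curves, `[[`, "", "peptide_id")
  } else {
    ms <- lapply(mhc_values, function(v) list(value = v, censored = FALSE))
    names(ms) <- names(mhc_values)
  }
  missing <- setdiff(ids, names(ms))
  if (length(missing)) {
    stop("no hemolysis data for peptides: ", paste(missing, collapse = ", "))
  }
  pos <- table$gram == "positive"
  neg <- table$gram == "negative"
  gm_or_na <- function(x, cens) {
    if (length(x) == 0) NA_real_ else geometric_mean_mic(x, cens)
  }
  res <- lapply(ids, function(id) {
    col <- table$mic[, id]
    cen <- table$censored[, id]
    gm_p <- gm_or_na(col[pos], cen[pos])
    gm_n <- gm_or_na(col[neg], cen[neg])
    gm_a <- geometric_mean_mic(col[pos | neg], cen[pos | neg])
    m <- ms[[id]]
    data.frame(peptide_id = id,
               gm_gram_positive = gm_p, gm_gram_negative = gm_n, gm_all = gm_a,
               mhc = m$value, mhc_censored = isTRUE(m$censored),
               ti_prime_positive = m$value / gm_p,
               ti_prime_negative = m$value / gm_n,
               ti_prime_all = m$value / gm_a,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
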