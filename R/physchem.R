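# Sequence-level physicochemical descriptors: mean hydrophobicity,
# Eisenberg-style hydrophobic moment, polar angle, average mass, net charge
# and Trp-absorbance concentration.

# average (not monoisotopic) residue masses, Da; water and amide-group deltas
.AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.AA_MONO_MASS <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
.MASS_WATER <- c(average = 18.01524, mono = 18.010565)
# amidation replaces the C-terminal OH by NH2
.MASS_AMIDE_DELTA <- c(average = -0.98476, mono = -0.98402)

.TRP_EPSILON_280 <- 5500  # M^-1 cm^-1, molar absorptivity of tryptophan

.seq_chars <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  strsplit(toupper(sequence), "")[[1]]
}

.check_residues <- function(chars, known, what = "residue") {
  bad <- which(!(chars %in% known))
  if (length(bad)) {
    stop(sprintf("unknown %s '%s' at position %d", what, chars[bad[1]], bad[1]))
  }
  invisible(chars)
}

#' Hydrophobicity scales
#'
#' Loads a per-residue hydrophobicity scale by name (from the tables shipped
#' with the package) or from a two-column text file (code, value; `#`
#' comments allowed).  The packaged `"eisenberg-consensus"` scale is the
#' Eisenberg normalized consensus scale.
#'
#' @param name Scale name (`"eisenberg-consensus"`) or path to a scale file.
#' @return Object of class `hydrophobicity_scale`: list with `name` and
#'   `values` (named numeric vector over the 20 standard residues).
#' @examples
#' sc <- hydrophobicity_scale("eisenberg-consensus")
#' sc$values[["W"]]
#' @export
hydrophobicity_scale <- function(name = "eisenberg-consensus") {
  path <- if (file.exists(name)) {
    name
  } else {
    p <- system.file("extdata", "scales",
                     paste0(gsub("-", "_", name), ".tsv"), package = "helamp")
    if (p == "") stop("unknown hydrophobicity scale '", name, "'")
    p
  }
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    col.names = c("code", "value"),
                    colClasses = c("character", "numeric"))
  values <- setNames(tab$value, toupper(tab$code))
  missing <- setdiff(names(.AA_AVG_MASS), names(values))
  if (length(missing)) {
    stop("scale '", name, "' missing residues: ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(values))) stop("scale '", name, "' has non-finite values")
  structure(list(name = if (file.exists(name)) basename(name) else name,
                 values = values),
            class = "hydrophobicity_scale")
}

#' Mean residue hydrophobicity
#'
#' Arithmetic mean of the per-residue scale values, the descriptor usually
#' written H in amphipathic-helix structure-activity work.
#'
#' @param sequence One-letter amino-acid string.
#' @param scale A [hydrophobicity_scale()].
#' @return Dimensionless mean hydrophobicity.
#' @export
mean_hydrophobicity <- function(sequence, scale = hydrophobicity_scale()) {
  chars <- .seq_chars(sequence)
  .check_residues(chars, names(scale$values))
  mean(scale$values[chars])
}

#' Hydrophobic moment of an ideal helix
#'
#' The Eisenberg hydrophobic moment: the magnitude of the vector sum of the
#' per-residue hydrophobicities placed at helical-wheel angles, divided by
#' the number of residues,
#' \deqn{\mu_H = \frac{1}{N}\sqrt{\left(\sum_i h_i \sin\delta(i-1)\right)^2 +
#'   \left(\sum_i h_i \cos\delta(i-1)\right)^2}.}
#' Residue `i` contributes phase `delta * (i - 1)`, matching [wheel_angles()];
#' a constant phase offset leaves the magnitude unchanged.
#'
#' @inheritParams mean_hydrophobicity
#' @param delta Degrees per residue (default 100, ideal alpha-helix).
#' @return Dimensionless per-residue hydrophobic moment (>= 0).
#' @export
hydrophobic_moment <- function(sequence, scale = hydrophobicity_scale(),
                               delta = 100) {
  chars <- .seq_chars(sequence)
  .check_residues(chars, names(scale$values))
  h <- scale$values[chars]
  phi <- (seq_along(h) - 1) * delta * pi / 180
  sqrt(sum(h * sin(phi))^2 + sum(h * cos(phi))^2) / length(h)
}

#' Polar angle of the cationic face
#'
#' Angular span of the cationic arc in the helical wheel: the circular
#' distance from its clockwise-most to its counterclockwise-most member
#' angle.  For the 11-residue L5K5W family this is 120 or 140 degrees
#' depending on the interface position.
#'
#' @param peptide A `designed_peptide` passing [validate_amphipathic()].
#' @return Polar angle in degrees.
#' @export
polar_angle <- function(peptide) {
  chk <- validate_amphipathic(peptide)
  if (!chk$valid) {
    stop("polar angle undefined for non-amphipathic peptide: ", chk$diagnostic)
  }
  seqv <- strsplit(peptide$sequence, "")[[1]]
  kang <- sort(peptide$wheel$angles[seqv == peptide$formula$cationic])
  gaps <- diff(c(kang, kang[1] + 360))
  # contiguous arc: its span is the full circle minus the largest gap
  360 - max(gaps)
}

#' Peptide molecular mass
#'
#' Sum of residue masses plus water; C-terminal amidation replaces the
#' hydroxyl by an amino group (net -0.98 Da).  Average isotopic masses by
#' default, matching how peptide masses are usually quoted (e.g. 1410 Da for
#' amidated KKLLKWLKKLL); monoisotopic behind a flag.
#'
#' @param sequence One-letter amino-acid string.
#' @param c_terminal_amide Logical; is the C-terminus amidated?
#' @param monoisotopic Use monoisotopic instead of average masses.
#' @return Mass in Da.
#' @export
molecular_mass <- function(sequence, c_terminal_amide = FALSE,
                           monoisotopic = FALSE) {
  chars <- .seq_chars(sequence)
  tab <- if (monoisotopic) .AA_MONO_MASS else .AA_AVG_MASS
  kind <- if (monoisotopic) "mono" else "average"
  .check_residues(chars, names(tab))
  m <- sum(tab[chars]) + .MASS_WATER[[kind]]
  if (isTRUE(c_terminal_amide)) m <- m + .MASS_AMIDE_DELTA[[kind]]
  m
}

#' Net charge at neutral pH (integer counting model)
#'
#' +1 per lysine/arginine side chain, -1 per aspartate/glutamate, +1 for the
#' free N-terminal amine, -1 for a free C-terminal carboxylate (0 when
#' amidated).  Histidine counts 0.  No pKa titration: the model treats
#' charge as a constant integer, which is how it is used in
#' amphipathic-helix design work.  Note that under this counting an amidated
#' K5-containing undecapeptide carries +6, not the +7 sometimes quoted when
#' the terminal amine is double-counted.
#'
#' @inheritParams molecular_mass
#' @return Integer net charge.
#' @export
net_charge <- function(sequence, c_terminal_amide = FALSE) {
  chars <- .seq_chars(sequence)
  .check_residues(chars, names(.AA_AVG_MASS))
  side <- sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E"))
  as.integer(side + 1L - if (isTRUE(c_terminal_amide)) 0L else 1L)
}

#' Peptide concentration from tryptophan absorbance
#'
#' Beer-Lambert with the tryptophan molar absorptivity of 5500 M^-1 cm^-1 at
#' 280 nm: `c = A280 / (5500 * n_trp * path)`.  Applicable only to peptides
#' containing tryptophan.
#'
#' @param a280 Absorbance at 280 nm (>= 0).
#' @param path Cuvette path length in cm.
#' @param n_trp Number of tryptophan residues (>= 1).
#' @return Concentration in mol/L.
#' @export
concentration_from_absorbance <- function(a280, path = 1, n_trp = 1) {
  stopifnot(a280 >= 0, path > 0)
  if (n_trp < 1) stop("method inapplicable: peptide has no tryptophan")
  a280 / (.TRP_EPSILON_280 * n_trp * path)
}

#' Full physicochemical profile of a designed peptide
#'
#' @param peptide A `designed_peptide`.
#' @param scale A [hydrophobicity_scale()].
#' @return One-row data.frame with id, sequence, length, mean hydrophobicity,
#'   hydrophobic moment, polar angle, molecular mass and net charge.
#' @export
physchem_profile <- function(peptide, scale = hydrophobicity_scale()) {
  data.frame(
    id = peptide$id,
    sequence = peptide$sequence,
    length = nchar(peptide$sequence),
    scale = scale$name,
    mean_hydrophobicity = mean_hydrophobicity(peptide$sequence, scale),
    hydrophobic_moment = hydrophobic_moment(peptide$sequence, scale,
                                            delta = peptide$wheel$delta),
    polar_angle = polar_angle(peptide),
    molecular_mass = molecular_mass(peptide$sequence, peptide$c_terminal_amide),
    net_charge = net_charge(peptide$sequence, peptide$c_terminal_amide),
    stringsAsFactors = FALSE)
}
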