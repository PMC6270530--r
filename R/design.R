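#' Helical wheel geometry
#'
#' Places residue `i` (1-based) of an ideal alpha-helix at angle
#' `(i - 1) * delta` modulo 360 on the wheel projection, the convention under
#' which residue 1 sits at 0 degrees and angles grow counterclockwise when
#' the helix is viewed from the N-terminus.
#'
#' @param n Number of residues (>= 2).
#' @param delta Rotation per residue in degrees, in (0, 360).  The ideal
#'   alpha-helix value of 100 (3.6 residues per turn) is the default.
#' @return An object of class `wheel_geometry`: a list with `n_residues`,
#'   `delta` and `angles` (degrees in `[0, 360)`, indexed by position).
#' @details Geometries in which two positions fall on the same angle are
#'   rejected: the face-partition rule used by [design_isomer()] is undefined
#'   when angles collide (e.g. 19 residues at 100 degrees revisit 0).
#' @seealso [design_isomer()], [polar_angle()]
#' @examples
#' wheel_angles(11)$angles   # 0, 100, 200, ... mod 360
#' @export
wheel_angles <- function(n, delta = 100) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 2, n == round(n))
  stopifnot(is.numeric(delta), length(delta) == 1, delta > 0, delta < 360)
  angles <- ((seq_len(n) - 1) * delta) %% 360
  if (anyDuplicated(round(angles, 9))) {
    stop("ambiguous wheel geometry: positions ",
         paste(which(duplicated(round(angles, 9)) |
                       duplicated(round(angles, 9), fromLast = TRUE)),
               collapse = ", "),
         " share wheel angles; the face-partition rule is undefined")
  }
  structure(list(n_residues = as.integer(n), delta = delta, angles = angles),
            class = "wheel_geometry")
}

#' Peptide composition formula for perfectly amphipathic design
#'
#' A formula such as L5K5W: `m` copies of one hydrophobic residue, `m` copies
#' of one cationic residue and a single interface residue, total length
#' `2m + 1`.  Perfect amphipathy requires the even hydrophobic/cationic
#' split, so uneven formulas are rejected.
#'
#' @param hydrophobic One-letter code of the hydrophobic residue (default "L").
#' @param cationic One-letter code of the cationic residue (default "K").
#' @param interface One-letter code of the interface residue (default "W").
#' @param m Count of hydrophobic (= cationic) residues (default 5).
#' @return Object of class `peptide_formula`.
#' @examples
#' peptide_formula()            # L5K5W, 11 residues
#' parse_formula("L5K5W")
#' @export
peptide_formula <- function(hydrophobic = "L", cationic = "K",
                            interface = "W", m = 5) {
  stopifnot(is.character(hydrophobic), nchar(hydrophobic) == 1,
            is.character(cationic), nchar(cationic) == 1,
            is.character(interface), nchar(interface) == 1,
            m >= 1, m == round(m))
  if (length(unique(c(hydrophobic, cationic, interface))) != 3) {
    stop("hydrophobic, cationic and interface residues must be distinct letters")
  }
  structure(list(hydrophobic = hydrophobic, cationic = cationic,
                 interface = interface, m = as.integer(m),
                 n = as.integer(2 * m + 1)),
            class = "peptide_formula")
}

#' @rdname peptide_formula
#' @param text Formula string like `"L5K5W"` (hydrophobic letter + count,
#'   cationic letter + count, interface letter; counts must be equal).
#' @export
parse_formula <- function(text) {
  m <- regmatches(text, regexec("^([A-Z])([0-9]+)([A-Z])([0-9]+)([A-Z])$", text))[[1]]
  if (length(m) == 0) {
    stop("cannot parse formula '", text, "'; expected e.g. 'L5K5W'")
  }
  if (m[3] != m[5]) {
    stop("formula '", text, "' is not perfectly amphipathic: ",
         "hydrophobic count ", m[3], " != cationic count ", m[5])
  }
  peptide_formula(hydrophobic = m[2], cationic = m[4], interface = m[6],
                  m = as.integer(m[3]))
}

format_formula <- function(formula) {
  paste0(formula$hydrophobic, formula$m, formula$cationic, formula$m,
         formula$interface)
}

#' Design one perfectly amphipathic isomer
#'
#' Constructs the unique sequence of the given composition whose helical-wheel
#' projection has the interface residue (tryptophan, by default) at
#' `trp_position`, the `m` hydrophobic residues on the arc counterclockwise of
#' it (increasing wheel angle) and the `m` cationic residues on the arc
#' clockwise of it.  The interface residue therefore sits between the end of
#' the cationic (lysyl) arc and the start of the hydrophobic (leucyl) arc.
#'
#' @param formula A [peptide_formula()].
#' @param trp_position Sequence position (1-based) of the interface residue.
#' @param geometry A [wheel_angles()] geometry; defaults to the ideal helix
#'   wheel for the formula's length.
#' @param c_terminal_amide Carried as metadata (affects mass and charge only);
#'   default `TRUE`.
#' @return Object of class `designed_peptide` with fields `sequence`,
#'   `trp_position`, `c_terminal_amide`, `formula`, `wheel` and `id`
#'   (`"W<p>"`).
#' @examples
#' design_isomer(peptide_formula(), 6)$sequence   # "KKLLKWLKKLL"
#' @export
design_isomer <- function(formula, trp_position,
                          geometry = wheel_angles(formula$n),
                          c_terminal_amide = TRUE) {
  stopifnot(inherits(formula, "peptide_formula"),
            inherits(geometry, "wheel_geometry"))
  n <- formula$n
  if (geometry$n_residues != n) {
    stop("geometry has ", geometry$n_residues, " positions but formula needs ", n)
  }
  if (!(trp_position %in% seq_len(n))) {
    stop("trp_position must be in [1, ", n, "], got ", trp_position)
  }
  ang <- geometry$angles
  rest <- setdiff(seq_len(n), trp_position)
  # offset of each remaining position counterclockwise from the interface
  off <- (ang[rest] - ang[trp_position]) %% 360
  ord <- rest[order(off)]
  seqv <- character(n)
  seqv[trp_position] <- formula$interface
  seqv[ord[seq_len(formula$m)]] <- formula$hydrophobic
  seqv[ord[formula$m + seq_len(formula$m)]] <- formula$cationic
  pep <- structure(list(sequence = paste(seqv, collapse = ""),
                        trp_position = as.integer(trp_position),
                        c_terminal_amide = isTRUE(c_terminal_amide),
                        formula = formula,
                        wheel = geometry,
                        id = paste0("W", trp_position)),
                   class = "designed_peptide")
  chk <- validate_amphipathic(pep)
  if (!chk$valid) {
    stop("internal design failure: ", chk$diagnostic)
  }
  pep
}

#' @export
print.designed_peptide <- function(x, ...) {
  cat(sprintf("<designed_peptide> %s  %s%s  (%s, interface at %d)\n",
              x$id, x$sequence, if (x$c_terminal_amide) "-amide" else "",
              format_formula(x$formula), x$trp_position))
  invisible(x)
}

#' Enumerate the full isomer family of a formula
#'
#' One designed peptide per interface position 1..n; for L5K5W this is the
#' 11-member undecapeptide family W1..W11.
#'
#' @inheritParams design_isomer
#' @return List of `designed_peptide`, names `"W1"`.. `"Wn"`.
#' @examples
#' fam <- enumerate_family(peptide_formula())
#' vapply(fam, `[[`, "", "sequence")
#' @export
enumerate_family <- function(formula, geometry = wheel_angles(formula$n),
                             c_terminal_amide = TRUE) {
  peps <- lapply(seq_len(formula$n), design_isomer, formula = formula,
                 geometry = geometry, c_terminal_amide = c_terminal_amide)
  names(peps) <- vapply(peps, `[[`, "", "id")
  peps
}

# circular contiguity: TRUE iff the positions in `subset` are consecutive in
# the circular angle ordering of all positions
.arc_contiguous <- function(angles, subset) {
  ord <- order(angles)             # circular order of all positions
  memb <- ord %in% subset
  # count transitions FALSE->TRUE around the circle; contiguous iff exactly 1
  trans <- sum(memb != c(memb[-1], memb[1]))
  trans == 2
}

#' Validate perfect amphipathy of a designed peptide
#'
#' Checks, on the helical wheel, that (a) the cationic residues occupy one
#' contiguous circular arc, (b) the hydrophobic residues occupy the
#' complementary contiguous arc, and (c) the interface residue's angle lies
#' strictly between the counterclockwise end of the cationic arc and the
#' clockwise start of the hydrophobic arc.
#'
#' @param peptide A `designed_peptide` (or a list with `sequence`, `formula`,
#'   `wheel` fields).
#' @return List with `valid` (logical) and `diagnostic` (character; `""` when
#'   valid, otherwise names the first violated condition).
#' @examples
#' p <- design_isomer(peptide_formula(), 6)
#' validate_amphipathic(p)$valid                 # TRUE
#' @export
validate_amphipathic <- function(peptide) {
  formula <- peptide$formula
  geometry <- peptide$wheel
  seqv <- strsplit(peptide$sequence, "")[[1]]
  fail <- function(msg) list(valid = FALSE, diagnostic = msg)
  if (length(seqv) != geometry$n_residues) {
    return(fail(sprintf("length mismatch: sequence has %d residues, wheel %d",
                        length(seqv), geometry$n_residues)))
  }
  counts <- table(factor(seqv, levels = c(formula$hydrophobic,
                                          formula$cationic,
                                          formula$interface)))
  if (counts[formula$hydrophobic] != formula$m ||
      counts[formula$cationic] != formula$m ||
      counts[formula$interface] != 1L ||
      sum(counts) != length(seqv)) {
    return(fail(sprintf("composition mismatch: expected %s", format_formula(formula))))
  }
  ang <- geometry$angles
  kpos <- which(seqv == formula$cationic)
  lpos <- which(seqv == formula$hydrophobic)
  wpos <- which(seqv == formula$interface)
  if (!.arc_contiguous(ang, kpos)) {
    return(fail("cationic residues do not form one contiguous wheel arc"))
  }
  if (!.arc_contiguous(ang, lpos)) {
    return(fail("hydrophobic residues do not form one contiguous wheel arc"))
  }
  # reading counterclockwise from the interface residue, the full circle must
  # be: interface, hydrophobic arc, cationic arc
  ord <- order((ang - ang[wpos]) %% 360)   # starts at wpos (offset 0)
  types <- seqv[ord]
  expected <- c(formula$interface,
                rep(formula$hydrophobic, formula$m),
                rep(formula$cationic, formula$m))
  if (!identical(types, expected)) {
    return(fail(paste("interface residue does not sit between the cationic",
                      "arc end and the hydrophobic arc start")))
  }
  list(valid = TRUE, diagnostic = "")
}
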