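# Shared fixtures and independent oracles.

# wrap an arbitrary sequence string as a designed_peptide (no construction
# rule involved), so the validator can be exercised on hand-built cases
make_peptide <- function(sequence, formula = peptide_formula(),
                         amide = TRUE) {
  n <- nchar(sequence)
  trp <- as.integer(regexpr(formula$interface, sequence, fixed = TRUE))
  structure(list(sequence = sequence,
                 trp_position = trp,
                 c_terminal_amide = amide,
                 formula = formula,
                 wheel = wheel_angles(n),
                 id = paste0("W", trp)),
            class = "designed_peptide")
}

# exhaustive-search oracle: all C(2m, m) hydrophobic/cationic placements for
# a fixed interface position, filtered by the amphipathy validator; the
# design rule must coincide with the unique survivor
brute_force_design <- function(formula, trp_position,
                               geometry = wheel_angles(formula$n)) {
  n <- formula$n
  rest <- setdiff(seq_len(n), trp_position)
  combos <- utils::combn(rest, formula$m)
  hits <- character()
  for (j in seq_len(ncol(combos))) {
    seqv <- rep(formula$cationic, n)
    seqv[trp_position] <- formula$interface
    seqv[combos[, j]] <- formula$hydrophobic
    s <- paste(seqv, collapse = "")
    pep <- structure(list(sequence = s, trp_position = trp_position,
                          c_terminal_amide = TRUE, formula = formula,
                          wheel = geometry, id = "x"),
                     class = "designed_peptide")
    if (validate_amphipathic(pep)$valid) hits <- c(hits, s)
  }
  hits
}

# hydrophobicity scale built directly from a named value vector (all 20
# residues filled with `fill` unless overridden)
toy_scale <- function(..., fill = 0) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  values <- setNames(rep(fill, 20), aa)
  over <- c(...)
  values[names(over)] <- over
  structure(list(name = "toy", values = values),
            class = "hydrophobicity_scale")
}

# frozen copy of the Eisenberg consensus values used for hand-summed
# oracles, independent of the packaged scale file
EISENBERG <- c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
               Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
               L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
               S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08)
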