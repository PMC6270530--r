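# Readers and writers shared by all stages: tagged FASTA for designed
# families, header+two-column spectrum files, and the CSV schemas for MIC
# panels, hemolysis curves and NMR shifts.  Packaged reference fixtures for
# the L5K5W undecapeptide panel are exposed via l5k5w_* loaders.

#' Write / read a designed peptide family as FASTA
#'
#' Headers carry key-value tags after the id, e.g.
#' `>W6|amide=yes|trp=6|formula=L5K5W`.  Reading parses the tags when
#' present and rebuilds `designed_peptide` objects (tag-less records default
#' to amidated, with the interface position located from the sequence).
#'
#' @param peptides List of `designed_peptide`.
#' @param path Output / input file path.
#' @return `write_peptide_fasta()` returns `path` invisibly;
#'   `read_peptide_fasta()` returns a list of `designed_peptide`.
#' @export
write_peptide_fasta <- function(peptides, path) {
  seqs <- vapply(peptides, `[[`, "", "sequence")
  names(seqs) <- vapply(peptides, function(p) {
    paste0(p$id,
           "|amide=", if (p$c_terminal_amide) "yes" else "no",
           "|trp=", p$trp_position,
           "|formula=", format_formula(p$formula))
  }, "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_peptide_fasta
#' @export
read_peptide_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA file: ", path)
    return(list())
  }
  headers <- names(set)
  ids <- vapply(strsplit(headers, "|", fixed = TRUE), `[[`, "", 1)
  if (anyDuplicated(ids)) {
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lapply(seq_along(set), function(i) {
    seqv <- toupper(as.character(set[[i]]))
    if (grepl("[^A-Z]", seqv)) {
      stop("illegal sequence character in record ", i, " ('", ids[i], "')")
    }
    tags <- strsplit(headers[i], "|", fixed = TRUE)[[1]][-1]
    kv <- strsplit(tags, "=", fixed = TRUE)
    tagmap <- setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
    formula <- if ("formula" %in% names(tagmap)) {
      parse_formula(tagmap[["formula"]])
    } else {
      peptide_formula(m = (nchar(seqv) - 1) / 2)
    }
    trp <- if ("trp" %in% names(tagmap)) {
      as.integer(tagmap[["trp"]])
    } else {
      regexpr(formula$interface, seqv, fixed = TRUE)[1]
    }
    structure(list(sequence = seqv,
                   trp_position = trp,
                   c_terminal_amide = !identical(tagmap[["amide"]], "no"),
                   formula = formula,
                   wheel = wheel_angles(nchar(seqv)),
                   id = ids[i]),
              class = "designed_peptide")
  })
}

#' Write / read a spectrum text file
#'
#' Plain-text format shared by CD and fluorescence data: a block of
#' `# key: value` metadata lines followed by two whitespace-separated
#' columns (wavelength_nm, signal).
#'
#' @param x A `raw_cd_spectrum` or `emission_spectrum`.
#' @param path File path.
#' @return `write_spectrum_file()` returns `path` invisibly;
#'   `read_spectrum_file()` returns the reconstructed object (class chosen
#'   by the `type` metadata line).
#' @export
write_spectrum_file <- function(x, path) {
  if (inherits(x, "raw_cd_spectrum")) {
    meta <- c(type = "cd_mdeg",
              concentration_M = format(x$concentration_M, digits = 12),
              path_cm = format(x$path_cm, digits = 12),
              n_residues = x$n_residues, solvent = x$solvent)
    sig <- x$signal_mdeg
  } else if (inherits(x, "emission_spectrum")) {
    meta <- c(type = "emission", label = x$label, solvent = x$solvent)
    sig <- x$intensity
  } else {
    stop("unsupported spectrum object of class ", class(x)[1])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  writeLines(sprintf("%.6g %.10g", x$wavelengths, sig), con)
  invisible(path)
}

#' @rdname write_spectrum_file
#' @export
read_spectrum_file <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines, regexec("^#\\s*([^:]+):\\s*(.*)$", meta_lines))
  meta <- setNames(vapply(kv, `[[`, "", 3), trimws(vapply(kv, `[[`, "", 2)))
  dat <- read.table(text = grep("^#", lines, value = TRUE, invert = TRUE),
                    col.names = c("wavelength", "signal"))
  getm <- function(key, default = NULL) {
    if (key %in% names(meta)) meta[[key]] else
      default %||% stop("spectrum file lacks a '", key, "' metadata line")
  }
  type <- getm("type")
  if (type == "cd_mdeg") {
    raw_cd_spectrum(dat$wavelength, dat$signal,
                    concentration_M = as.numeric(getm("concentration_M")),
                    path_cm = as.numeric(getm("path_cm")),
                    n_residues = as.integer(getm("n_residues")),
                    solvent = getm("solvent", ""))
  } else if (type == "emission") {
    emission_spectrum(dat$wavelength, dat$signal,
                      label = getm("label", ""),
                      solvent = getm("solvent", ""))
  } else {
    stop("unknown spectrum type '", type, "' in ", path)
  }
}

.parse_bounded <- function(cells, where) {
  cells <- trimws(as.character(cells))
  censored <- grepl("^>", cells)
  values <- suppressWarnings(as.numeric(sub("^>", "", cells)))
  bad <- which(!is.finite(values))
  if (length(bad)) {
    stop("unparseable numeric cell '", cells[bad[1]], "' at ", where[bad[1]])
  }
  list(values = values, censored = censored)
}

#' Read a MIC panel CSV
#'
#' Schema: one row per strain; columns `strain`, `gram`
#' (`positive|negative|other`) and one column per peptide, with cells in
#' ug/mL or `">128"`-style bound markers.
#'
#' @param path CSV path.
#' @return A [mic_table()].
#' @export
read_mic_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, comment.char = "#",
                 stringsAsFactors = FALSE)
  for (col in c("strain", "gram")) {
    if (!col %in% names(df)) stop("MIC CSV lacks required column '", col, "'")
  }
  pep_cols <- setdiff(names(df), c("strain", "gram"))
  if (length(pep_cols) == 0) stop("MIC CSV has no peptide columns")
  n <- nrow(df)
  vals <- matrix(NA_real_, n, length(pep_cols),
                 dimnames = list(df$strain, pep_cols))
  cens <- matrix(FALSE, n, length(pep_cols),
                 dimnames = list(df$strain, pep_cols))
  for (j in seq_along(pep_cols)) {
    p <- .parse_bounded(df[[pep_cols[j]]],
                        sprintf("row %d, column '%s'", seq_len(n), pep_cols[j]))
    vals[, j] <- p$values
    cens[, j] <- p$censored
  }
  mic_table(vals, df$gram, cens)
}

#' Read hemolysis dose-response CSV (long format)
#'
#' Schema: columns `peptide`, `concentration_ug_ml`, `hemolysis_percent`.
#'
#' @param path CSV path.
#' @return Named list of [hemolysis_curve()], one per peptide.
#' @export
read_hemolysis_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("peptide", "concentration_ug_ml", "hemolysis_percent")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("hemolysis CSV lacks required column(s): ", paste(miss, collapse = ", "))
  }
  curves <- lapply(split(df, df$peptide), function(d) {
    d <- d[order(d$concentration_ug_ml), ]
    hemolysis_curve(d$peptide[1], d$concentration_ug_ml, d$hemolysis_percent)
  })
  curves[unique(df$peptide)]
}

#' Read an NMR chemical-shift CSV
#'
#' Schema: columns `peptide`, `residue`, `delta_Ha_ppm`; returns the input
#' augmented with `secondary_shift_ppm` and `helical_flag` via
#' [secondary_shift()].
#'
#' @param path CSV path.
#' @param reference_rc Random-coil reference, ppm.
#' @return data.frame.
#' @export
read_nmr_csv <- function(path, reference_rc = 4.7) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("peptide", "residue", "delta_Ha_ppm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("NMR CSV lacks required column(s): ", paste(miss, collapse = ", "))
  }
  ss <- lapply(df$delta_Ha_ppm, secondary_shift, reference_rc = reference_rc)
  df$secondary_shift_ppm <- vapply(ss, `[[`, 0, "secondary_shift")
  df$helical_flag <- vapply(ss, `[[`, TRUE, "helical_flag")
  df
}

#' Packaged L5K5W reference fixtures
#'
#' Transcriptions of the published activity panel for the 11-member L5K5W
#' undecapeptide family: `l5k5w_mic_table()` returns the MIC panel (four
#' Gram-positive strains, five Gram-negative strains and the MRSA strain
#' labeled `"other"`); `l5k5w_reference_summary()` returns the tabulated
#' (rounded) GM, MHC and TI' values as printed, for comparison against
#' [summarize_activity()].  Note the known internal inconsistency of the
#' published W6 column: its printed Gram-positive and combined GMs (2.8,
#' 3.2) do not follow from its printed MICs (which give 2.4, 2.9).
#'
#' @return `l5k5w_mic_table()`: a [mic_table()];
#'   `l5k5w_reference_summary()`: a data.frame with columns `peptide_id`,
#'   `gm_gram_positive`, `gm_gram_negative`, `gm_all`, `mhc`,
#'   `ti_prime_positive`, `ti_prime_negative`, `ti_prime_all`.
#' @export
l5k5w_mic_table <- function() {
  read_mic_csv(system.file("extdata", "l5k5w_mic_panel.csv",
                           package = "helamp"))
}

#' @rdname l5k5w_mic_table
#' @export
l5k5w_reference_summary <- function() {
  gm <- read.csv(system.file("extdata", "l5k5w_reference_gm.csv",
                             package = "helamp"),
                 comment.char = "#", stringsAsFactors = FALSE)
  ti <- read.csv(system.file("extdata", "l5k5w_reference_mhc_ti.csv",
                             package = "helamp"),
                 comment.char = "#", stringsAsFactors = FALSE)
  merge(gm, ti, by = "peptide_id", sort = FALSE)
}
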