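test_that("mean hydrophobicity is the arithmetic scale mean", {
  expect_equal(mean_hydrophobicity("KLWKL", toy_scale(fill = 1)), 1)
  sc <- hydrophobicity_scale("eisenberg-consensus")
  expect_equal(mean_hydrophobicity("KW", sc), (-1.5 + 0.81) / 2)
  # hand-summed oracle from the frozen table
  expect_equal(mean_hydrophobicity("KKLLKWLKKLL", sc),
               sum(EISENBERG[strsplit("KKLLKWLKKLL", "")[[1]]]) / 11)
  expect_error(mean_hydrophobicity("KXZ", sc), "position 2")
  # linearity in the scale
  sc2 <- sc
  sc2$values <- 3 * sc$values
  expect_equal(mean_hydrophobicity("KKLLKWLKKLL", sc2),
               3 * mean_hydrophobicity("KKLLKWLKKLL", sc))
})

test_that("hydrophobic moment matches the vector-sum definition", {
  sc <- hydrophobicity_scale("eisenberg-consensus")
  # independent brute-force summation oracle
  h <- EISENBERG[strsplit("KKLLKWLKKLL", "")[[1]]]
  phi <- (0:10) * 100 * pi / 180
  oracle <- sqrt(sum(h * sin(phi))^2 + sum(h * cos(phi))^2) / 11
  expect_equal(hydrophobic_moment("KKLLKWLKKLL", sc), oracle)

  # perfectly segregated two-residue case: h = (1, -1) at 180 degrees
  seg <- toy_scale(A = 1, V = -1)
  expect_equal(hydrophobic_moment("AV", seg, delta = 180), 1)

  # exact cancellation needs the wheel to close (N * delta = k * 360):
  # 18 residues at 100 degrees span 5 full turns
  expect_equal(hydrophobic_moment(strrep("L", 18), sc, delta = 100), 0,
               tolerance = 1e-12)
  # at N = 11 the wheel does not close; the residual is small but nonzero
  mu11 <- hydrophobic_moment(strrep("L", 11), sc, delta = 100)
  expect_gt(mu11, 0)
  expect_lt(mu11, 0.03)
})

test_that("moment is invariant under closed-wheel rotation and sign flip", {
  sc <- hydrophobicity_scale("eisenberg-consensus")
  rotate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    paste(c(ch[-seq_len(k)], ch[seq_len(k)]), collapse = "")
  }
  set.seed(11)
  for (rep in 1:5) {
    s <- paste(sample(names(EISENBERG), 18, replace = TRUE), collapse = "")
    mu <- hydrophobic_moment(s, sc, delta = 100)
    for (k in c(1, 7)) {
      expect_equal(hydrophobic_moment(rotate(s, k), sc, delta = 100), mu)
    }
    neg <- sc
    neg$values <- -sc$values
    expect_equal(hydrophobic_moment(s, neg, delta = 100), mu)
  }
})

test_that("family-level descriptors behave as composition isomers", {
  fam <- enumerate_family(peptide_formula())
  pa <- vapply(fam, polar_angle, 0)
  expect_setequal(unique(pa), c(120, 140))
  expect_equal(unname(pa[c("W6", "W10")]), c(120, 140))
  mass <- vapply(fam, function(p) molecular_mass(p$sequence, TRUE), 0)
  expect_equal(max(mass) - min(mass), 0)
  sc <- hydrophobicity_scale("eisenberg-consensus")
  mu <- vapply(fam, function(p) hydrophobic_moment(p$sequence, sc), 0)
  expect_lt(sd(mu) / mean(mu), 0.05)   # small dispersion across isomers
  # polar angle is undefined off the amphipathic manifold
  expect_error(polar_angle(make_peptide("KKKKKLLLLLW")), "amphipathic")
})

test_that("mass model reproduces reference values", {
  expect_equal(molecular_mass("G"), 75.07, tolerance = 1e-4)
  expect_equal(round(molecular_mass("KKLLKWLKKLL", c_terminal_amide = TRUE)),
               1410)
  # amidation is a fixed -0.98 Da group swap
  expect_equal(molecular_mass("KWLK", TRUE) - molecular_mass("KWLK", FALSE),
               -0.98476)
  expect_lt(molecular_mass("KKLLKWLKKLL", TRUE, monoisotopic = TRUE),
            molecular_mass("KKLLKWLKKLL", TRUE))
  expect_error(molecular_mass("KBX"), "unknown")
})

test_that("integer charge counting model", {
  expect_equal(net_charge("LLLLL"), 0L)                      # +N, -C
  expect_equal(net_charge("K", c_terminal_amide = TRUE), 2L)
  # 5 Lys + free N-terminus on an amidated peptide: +6 under this model
  expect_equal(net_charge("KKLLKWLKKLL", c_terminal_amide = TRUE), 6L)
  expect_equal(net_charge("KDKE", TRUE), 1L)
})

test_that("Trp absorbance concentration follows Beer-Lambert", {
  expect_equal(concentration_from_absorbance(0, 1, 1), 0)
  expect_equal(concentration_from_absorbance(0.055, 1, 1), 10e-6)
  expect_equal(concentration_from_absorbance(0.11, 0.5, 2), 20e-6)
  expect_error(concentration_from_absorbance(0.1, 1, 0), "inapplicable")
})
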