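test_that("geometric mean MIC is exact on two-fold series", {
  expect_equal(geometric_mean_mic(c(2, 2, 2, 2)), 2)
  expect_equal(round(geometric_mean_mic(c(1, 1, 1, 2)), 1), 1.2)  # 2^(5/4)/2
  expect_equal(round(geometric_mean_mic(c(4, 4, 4, 4, 8)), 1), 4.6)
  expect_error(geometric_mean_mic(numeric()), "no MICs")
  expect_error(geometric_mean_mic(c(2, 0)), "> 0")
  expect_error(geometric_mean_mic(c(2, 128), censored = c(FALSE, TRUE)),
               "out-of-range")
})

test_that("GM is scale-equivariant and bounded by its inputs", {
  set.seed(42)
  for (rep in 1:20) {
    x <- 2^sample(0:7, 6, replace = TRUE)
    k <- runif(1, 0.1, 10)
    g <- geometric_mean_mic(x)
    expect_equal(geometric_mean_mic(k * x), k * g)
    expect_gte(g, min(x))
    expect_lte(g, max(x))
  }
})

test_that("hemolysis normalization against Triton control", {
  expect_equal(hemolysis_percent(1.05, 0.05, 1.05), 100)
  expect_equal(hemolysis_percent(0.05, 0.05, 1.05), 0)
  expect_equal(hemolysis_percent(0.55, 0.05, 1.05), 50)
  expect_error(hemolysis_percent(0.5, 1, 0.9), "degenerate")
})

test_that("MHC is the first strict threshold exceedance on the grid", {
  series <- 2^(0:7)
  none <- hemolysis_curve("p", series, rep(0, 8))
  m <- mhc(none)
  expect_true(m$censored)
  expect_equal(m$value, 128)
  expect_equal(m$label, ">128")

  grid <- hemolysis_curve("p", c(16, 32, 64), c(4.9, 5.1, 40))
  expect_equal(mhc(grid)$value, 32)
  first <- hemolysis_curve("p", c(1, 2), c(6, 80))
  expect_equal(mhc(first)$value, 1)

  # monotone in the threshold
  cv <- hemolysis_curve("p", series, c(0, 1, 3, 6, 20, 60, 90, 99))
  prev <- -Inf
  for (th in c(1, 5, 10, 50, 95)) {
    v <- mhc(cv, threshold = th)$value
    expect_gte(v, prev)
    prev <- v
  }
  expect_error(hemolysis_curve("p", c(2, 1), c(0, 0)), "ascending")
  expect_error(hemolysis_curve("p", c(1, 2), c(0, 200)), "plausible")
})

test_that("TI' uses the unrounded GM", {
  gm_pos <- geometric_mean_mic(c(2, 2, 2, 4))
  expect_equal(round(pseudo_therapeutic_index(128, gm_pos), 1), 53.8)
  expect_equal(round(pseudo_therapeutic_index(16, gm_pos), 1), 6.7)
  # dividing by the display-rounded GM would give 53.3, not the tabulated 53.8
  expect_equal(round(128 / round(gm_pos, 1), 1), 53.3)
  expect_equal(pseudo_therapeutic_index(2, 2), 1)
  expect_error(pseudo_therapeutic_index(128, 0), "GM")
  lb <- pseudo_therapeutic_index(list(value = 128, censored = TRUE), gm_pos)
  expect_true(attr(lb, "lower_bound"))
})

test_that("summarize_activity assembles GM/MHC/TI per gram group", {
  # single peptide, single strain
  t1 <- mic_table(matrix(2, 1, 1, dimnames = list("s", "P1")), "positive")
  s1 <- summarize_activity(t1, mhc_values = c(P1 = 2))
  expect_equal(s1$gm_gram_positive, 2)
  expect_equal(s1$ti_prime_positive, 1)

  # 3-peptide synthetic panel vs spreadsheet-style oracle
  mic <- matrix(c(2, 4, 2, 8,
                  1, 1, 2, 2,
                  4, 8, 16, 8), 4, 3,
                dimnames = list(c("gp1", "gp2", "gn1", "gn2"),
                                c("A", "B", "C")))
  tab <- mic_table(mic, c("positive", "positive", "negative", "negative"))
  curves <- list(
    hemolysis_curve("A", 2^(0:7), c(0, 0, 0, 0, 2, 10, 40, 90)),
    hemolysis_curve("B", 2^(0:7), rep(0, 8)),
    hemolysis_curve("C", 2^(0:7), c(0, 2, 6, 30, 70, 95, 99, 100)))
  s <- summarize_activity(tab, curves = curves)
  expect_equal(s$gm_gram_positive, c(sqrt(2 * 4), sqrt(1), sqrt(4 * 8)))
  expect_equal(s$gm_gram_negative, c(sqrt(2 * 8), sqrt(2 * 2), sqrt(16 * 8)))
  expect_equal(s$gm_all,
               c((2 * 4 * 2 * 8)^0.25, (1 * 1 * 2 * 2)^0.25,
                 (4 * 8 * 16 * 8)^0.25))
  expect_equal(s$mhc, c(32, 128, 4))
  expect_equal(s$mhc_censored, c(FALSE, TRUE, FALSE))
  expect_equal(s$ti_prime_all, s$mhc / s$gm_all)

  # peptides without hemolysis data are reported, not silently dropped
  expect_error(summarize_activity(tab, curves = curves[1:2]), "C")
  expect_error(summarize_activity(tab), "exactly one")
})

test_that("strains labeled 'other' never enter GM or TI'", {
  mic <- matrix(c(2, 2, 128), 3, 1,
                dimnames = list(c("gp", "gn", "mdr"), "P"))
  with_other <- mic_table(mic, c("positive", "negative", "other"))
  s <- summarize_activity(with_other, mhc_values = c(P = 64))
  expect_equal(s$gm_all, 2)         # the 128 'other' cell is excluded
  expect_equal(s$ti_prime_all, 32)
})

test_that("packaged panel reproduces tabulated GM and TI except W6", {
  tab <- l5k5w_mic_table()
  ref <- l5k5w_reference_summary()
  s <- summarize_activity(tab, mhc_values = setNames(ref$mhc, ref$peptide_id))
  expect_equal(s$peptide_id, ref$peptide_id)
  not_w6 <- s$peptide_id != "W6"
  for (col in c("gm_gram_positive", "gm_gram_negative", "gm_all",
                "ti_prime_positive", "ti_prime_negative", "ti_prime_all")) {
    expect_equal(round(s[[col]][not_w6], 1), ref[[col]][not_w6],
                 info = col)
  }
  # the documented W6 inconsistency: computed values differ from tabulated
  expect_equal(round(s$gm_gram_positive[!not_w6], 1), 2.4)
  expect_false(isTRUE(all.equal(round(s$gm_gram_positive[!not_w6], 1),
                                ref$gm_gram_positive[!not_w6])))
})
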