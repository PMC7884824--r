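# masslib: formula arithmetic, adduct m/z, ppm matching, neutral losses

test_that("parse_formula handles counts, repeats, round trips and errors", {
  expect_equal(parse_formula("C4H6O5"), c(C = 4L, H = 6L, O = 5L))
  expect_equal(parse_formula("H2O"), c(H = 2L, O = 1L))
  expect_equal(parse_formula("C15H10O4"), c(C = 15L, H = 10L, O = 4L))
  # repeated symbols sum; serializer canonicalizes to Hill order
  expect_equal(parse_formula("CH3COOH"), parse_formula("C2H4O2"))
  expect_equal(format_formula(parse_formula("O5H6C4")), "C4H6O5")
  for (f in c("C4H6O5", "C15H10O4", "ClNa", "C5H9NO4S"))
    expect_equal(format_formula(parse_formula(f)), f)
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C4Xx2"), "unknown element")
  expect_error(parse_formula("C0"), "positive")
})

test_that("monoisotopic_mass matches frozen reference sums and is additive", {
  expect_identical(monoisotopic_mass(c(C = 1L)), 12)
  # frozen from independent NIST atomic-mass sums
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-4 / 18)
  expect_equal(monoisotopic_mass("C4H6O5"), 134.021523, tolerance = 1e-4 / 134)
  expect_error(monoisotopic_mass(character(0)))
  set.seed(42)
  els <- names(element_masses())
  for (i in 1:25) {
    f1 <- setNames(sample(1:20, 3), sample(els, 3))
    f2 <- setNames(sample(1:20, 3), sample(els, 3))
    merged <- tapply(c(f1, f2), names(c(f1, f2)), sum)
    expect_equal(monoisotopic_mass(f1) + monoisotopic_mass(f2),
                 monoisotopic_mass(merged), tolerance = 1e-9 / 100)
  }
})

test_that("adduct_mz follows the charged-species convention", {
  # frozen: 134.021523 - 1.007276 and 254.057909 + 1.007276
  expect_equal(adduct_mz("C4H6O5", "[M-H]-"), 133.014247, tolerance = 1e-3 / 133)
  expect_equal(adduct_mz("C15H10O4", "[M+H]+"), 255.065185, tolerance = 1e-3 / 255)
  # [M]+ is the molecule minus one electron
  expect_equal(adduct_mz("C15H10O4", "[M]+"),
               monoisotopic_mass("C15H10O4") - 0.00054858,
               tolerance = 1e-6)
  expect_error(adduct_mz("H2O", "[M+X]+"), "unknown adduct")
  # both formate and acetate rules ship in the negative-mode set
  expect_true(all(c("[M+HCOO]-", "[M+CH3COO]-") %in% default_adducts()$name))
})

test_that("ppm_error definition, sign convention and antisymmetry", {
  expect_identical(ppm_error(100, 100), 0)
  expect_equal(ppm_error(100.001, 100), 10)
  expect_error(ppm_error(100, 0), "positive")
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 50, 1500); b <- runif(1, 50, 1500)
    # antisymmetry up to the scale swap: (a-b)/b = -((b-a)/a) * (a/b)
    expect_equal(ppm_error(a, b), -ppm_error(b, a) * (a / b), tolerance = 1e-9)
  }
})

test_that("annotate_peaks equals the brute-force oracle on random libraries", {
  rules <- default_adducts()
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(5:50, 1)
    lib <- data.frame(
      id = sprintf("c%02d", 1:n), name = sprintf("cmp %d", 1:n),
      formula = vapply(1:n, function(i)
        format_formula(c(C = sample(4:30, 1), H = sample(4:40, 1),
                         O = sample(1:10, 1))), ""),
      stringsAsFactors = FALSE)
    npk <- sample(3:10, 1)
    # peaks near true adduct values plus decoys
    ri <- sample(nrow(rules), npk, replace = TRUE)
    ci <- sample(n, npk, replace = TRUE)
    mz <- vapply(seq_len(npk), function(i)
      adduct_mz(lib$formula[ci[i]], rules[ri[i], ]), 0) *
      (1 + rnorm(npk, 0, 4) / 1e6)
    peaks <- data.frame(rt_min = runif(npk, 0, 20), mz = mz,
                        polarity = rules$polarity[ri], stringsAsFactors = FALSE)
    got <- annotate_peaks(peaks, lib, rules, tol = 10)
    want <- bf_annotate(peaks, lib, rules, tol = 10)
    # same (peak, compound, adduct) hit set
    expect_setequal(paste(got$peak, got$compound_id, got$adduct),
                    paste(want$peak, want$compound_id, want$adduct))
    expect_true(all(abs(got$ppm_error) <= 10))
    # per peak, sorted by |ppm| ascending
    for (pk in unique(got$peak))
      expect_false(is.unsorted(abs(got$ppm_error[got$peak == pk])))
  }
})

test_that("annotate_peaks edge cases: empty library, polarity, scan range", {
  lib <- data.frame(id = "c1", name = "x", formula = "C4H6O5")
  pk <- data.frame(rt_min = 1, mz = 133.0142, polarity = "neg")
  expect_warning(res <- annotate_peaks(pk, lib[0, ]), "empty")
  expect_equal(nrow(res), 0)
  # matching polarity only
  pk_pos <- transform(pk, polarity = "pos")
  expect_equal(nrow(annotate_peaks(pk_pos, lib)), 0)
  expect_equal(nrow(annotate_peaks(pk, lib)), 1)
  # optional scan-range check, off by default
  pk2 <- data.frame(rt_min = 1, mz = 30, polarity = "neg")
  expect_silent(annotate_peaks(pk2, lib))
  expect_warning(annotate_peaks(rbind(pk, pk2), lib, scan_range = c(50, 1500)),
                 "scan range")
})

test_that("neutral-loss annotation reproduces flavonoid fragmentation", {
  pos <- annotate_neutral_losses(255, c(227, 199))
  expect_equal(pos$nominal_loss, c(28L, 56L))
  expect_equal(pos$loss_name, c("CO", "2CO"))
  neg <- annotate_neutral_losses(253, c(209, 197))
  expect_equal(neg$nominal_loss, c(44L, 56L))
  expect_equal(neg$loss_name, c("CO2", "2CO"))
  # exact-mass data matches in the exact pass
  ex <- annotate_neutral_losses(255.0652, 255.0652 - 27.99491)
  expect_equal(ex$loss_name, "CO")
  expect_equal(ex$match_type, "exact")
})

test_that("neutral-loss annotator flags unmatched, checks bounds, order-invariant", {
  same <- annotate_neutral_losses(200, 200)
  expect_equal(same$nominal_loss, 0L)
  expect_equal(same$match_type, "none")
  expect_error(annotate_neutral_losses(100, 101), "exceeds")
  frs <- c(227, 199, 237, 211.05)
  a <- annotate_neutral_losses(255, frs)
  b <- annotate_neutral_losses(255, rev(frs))
  expect_equal(a[order(a$fragment_mz), -1], b[order(b$fragment_mz), -1],
               ignore_attr = TRUE)
  # nominal loss rounds half away from zero
  expect_equal(annotate_neutral_losses(100, 81.5)$nominal_loss, 19L)
})
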