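th <- ilft_thresholds()

test_that("FIB-4 matches hand-evaluated values and scaling laws", {
  expect_equal(compute_fib4(61, 60, 40, 150), 3.858, tolerance = 0.001)
  expect_equal(compute_fib4(35, 25, 25, 250), 0.700, tolerance = 1e-12)
  # homogeneity: doubling platelets exactly halves the score
  expect_equal(compute_fib4(50, 40, 60, 400),
               compute_fib4(50, 40, 60, 200) / 2)
  expect_true(is.na(compute_fib4(50, 40, 0, 200)))
  expect_true(is.na(compute_fib4(50, 40, 60, 0)))
  expect_true(is.na(compute_fib4(50, NA, 60, 200)))
})

test_that("NFS matches the published linear formula", {
  expect_equal(compute_nfs(50, 32, TRUE, 40, 50, 200, 40), -0.135,
               tolerance = 0.001)
  # dysglycaemia contributes exactly +1.13
  expect_equal(compute_nfs(50, 32, TRUE, 40, 50, 200, 40) -
                 compute_nfs(50, 32, FALSE, 40, 50, 200, 40), 1.13)
  # +100 platelets lowers the score by exactly 1.3
  expect_equal(compute_nfs(50, 32, TRUE, 40, 50, 200, 40) -
                 compute_nfs(50, 32, TRUE, 40, 50, 300, 40), 1.3)
  expect_true(is.na(compute_nfs(50, NA, TRUE, 40, 50, 200, 40)))
})

test_that("ELF matches the pinned calibration", {
  expect_equal(compute_elf(20, 8, 100), 8.204, tolerance = 0.001)
  expect_identical(elf_band(compute_elf(20, 8, 100)), "moderate")
  # at unit log arguments the score is the sum of the coefficients
  expect_equal(compute_elf(exp(1), exp(1), exp(1)),
               2.278 + 0.851 + 0.751 + 0.394, tolerance = 1e-12)
  expect_error(compute_elf(0, 8, 100), class = "ilft_validation_error")
  expect_error(compute_elf(20, -1, 100), class = "ilft_validation_error")
})

test_that("score formulas agree with direct-formula oracles on random inputs", {
  set.seed(42)
  n <- 10000
  age <- runif(n, 18, 90); ast <- runif(n, 5, 400); alt <- runif(n, 1, 400)
  plt <- runif(n, 20, 600)
  got <- vapply(seq_len(n), function(i)
    compute_fib4(age[i], ast[i], alt[i], plt[i]), 0)
  expect_equal(got, age * ast / (plt * sqrt(alt)), tolerance = 1e-9)

  ha <- runif(n, 1, 500); pi3 <- runif(n, 1, 60); ti <- runif(n, 10, 1500)
  got <- vapply(seq_len(n), function(i) compute_elf(ha[i], pi3[i], ti[i]), 0)
  expect_equal(got, 2.278 + 0.851 * log(ha) + 0.751 * log(pi3) +
                 0.394 * log(ti), tolerance = 1e-9)
})

test_that("ELF staging uses exactly the half-open printed boundaries", {
  eps <- 1e-9
  expect_identical(elf_band(7.7 - eps), "absent_mild")
  expect_identical(elf_band(7.7), "moderate")
  expect_identical(elf_band(9.8 - eps), "moderate")
  expect_identical(elf_band(9.8), "severe")
  expect_identical(elf_band(11.3 - eps), "severe")
  expect_identical(elf_band(11.3), "cirrhosis")
  fa <- assess_fibrosis("indeterminate", 13 - eps)
  expect_false(fa$urgent_prognosis)
  fa <- assess_fibrosis("indeterminate", 13)
  expect_true(fa$urgent_prognosis)
  expect_identical(fa$elf_band, "cirrhosis")
})

test_that("indirect banding merges FIB-4 and NFS by maximum severity", {
  expect_identical(band_indirect(0.70, use_nfs = FALSE), "low")
  expect_identical(band_indirect(3.86, use_nfs = FALSE), "high")
  expect_identical(band_indirect(2.00, use_nfs = FALSE), "indeterminate")
  # low FIB-4 cannot rescue an indeterminate NFS
  expect_identical(band_indirect(1.10, -0.135, use_nfs = TRUE), "indeterminate")
  expect_identical(band_indirect(1.10, 1.0, use_nfs = TRUE), "high")
  expect_identical(band_indirect(1.10, -2.0, use_nfs = TRUE), "low")
  # rule-in FIB-4 can never band low, whatever NFS says
  expect_identical(band_indirect(3.0, -2.0, use_nfs = TRUE), "high")
  expect_identical(band_indirect(NA, use_nfs = FALSE), "not_computable")
  expect_identical(band_indirect(1.1, NA, use_nfs = TRUE), "not_computable")
})

test_that("fibrosis assessment resolves the indeterminate zone with ELF", {
  expect_identical(assess_fibrosis("indeterminate", 8.5)$final_category,
                   "indeterminate_resolved_low")
  expect_identical(assess_fibrosis("indeterminate", 10.2)$final_category,
                   "significant_fibrosis")
  urg <- assess_fibrosis("indeterminate", 13.4)
  expect_identical(urg$final_category, "significant_fibrosis")
  expect_true(urg$urgent_prognosis)
  expect_identical(assess_fibrosis("low")$final_category,
                   "no_significant_fibrosis")
  expect_identical(assess_fibrosis("indeterminate")$final_category,
                   "indeterminate_unresolved")
  # fail-safe: a high indirect band is never overridden by a low ELF
  expect_identical(assess_fibrosis("high", 8.0)$final_category,
                   "significant_fibrosis")
  # not computable reflexes and resolves like indeterminate, keeping its flag
  nc <- assess_fibrosis("not_computable", 10.0)
  expect_identical(nc$final_category, "significant_fibrosis")
  expect_identical(nc$indirect_band, "not_computable")
  expect_identical(assess_fibrosis("not_computable")$final_category,
                   "indeterminate_unresolved")
  # protocol violation: ELF with a low indirect band
  expect_error(assess_fibrosis("low", 8.0), class = "ilft_validation_error")
})

test_that("the final category is monotone in ELF", {
  sev <- c(no_significant_fibrosis = 0, indeterminate_resolved_low = 0,
           indeterminate_unresolved = 1, significant_fibrosis = 2)
  for (band in c("indeterminate", "high")) {
    elfs <- c(5, 7.7, 9, 9.8, 11.3, 12.9, 13, 15)
    cats <- vapply(elfs, function(e)
      assess_fibrosis(band, e)$final_category, "")
    urg <- vapply(elfs, function(e)
      assess_fibrosis(band, e)$urgent_prognosis, NA)
    expect_true(all(diff(sev[cats]) >= 0), info = band)
    expect_true(all(diff(urg) >= 0), info = band)
  }
})
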