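test_that("malignancy alert boundaries are strict", {
  expect_true(malignancy_alert(55, 180, 450))
  expect_false(malignancy_alert(40, 180, 450))   # "over 40" is strict
  expect_false(malignancy_alert(41, 130, 450))   # ALP strict >
  expect_false(malignancy_alert(55, 180, 400))   # platelets strict >
  expect_true(malignancy_alert(41, 131, 401))
  expect_false(malignancy_alert(55, 180, NA))    # unmeasured never alerts
})

test_that("representative records map to their published outcome codes", {
  # alcohol flag, negative screen, ruled-out fibrosis
  r <- classify_record(make_record(alt = 80, alcohol_over_14 = TRUE))
  expect_identical(outcome_codes(r), "iL05")
  expect_identical(r$record_referral, "none")

  # metabolic syndrome with significant fibrosis
  r <- classify_record(make_record(alt = 80, metabolic_syndrome = TRUE,
                                   age = 60, ast = 46, platelets = 165,
                                   ha = 150, piiinp = 15, timp1 = 300))
  expect_identical(outcome_codes(r), "iL16")
  expect_identical(r$record_referral, "routine")

  # abnormal ALT below 250, negative screen, no flags
  r <- classify_record(make_record(alt = 80))
  expect_identical(outcome_codes(r), "iL15")

  # limited bilirubin tier with the Gilbert pattern
  r <- classify_record(make_record(bilirubin_total = 40, direct_bilirubin = 6,
                                   haptoglobin = 1.2))
  expect_identical(r$tier, "limited_bilirubin")
  expect_identical(outcome_codes(r), "iL06")

  # one request, two outcomes: A1AT deficiency plus presumed ALD
  r <- classify_record(make_record(alt = 80, a1at = 0.8,
                                   alcohol_over_14 = TRUE))
  expect_setequal(outcome_codes(r), c("iL01", "iL05"))
  expect_identical(r$record_referral, "phenotype_dependent")

  # all analytes within limits
  r <- classify_record(make_record())
  expect_identical(outcome_codes(r), "iLX-NORMAL")
  expect_identical(r$outcomes[[1]]$category, "advisory")
  expect_identical(r$record_referral, "none")

  # mild isolated ALP
  r <- classify_record(make_record(alp = 150))
  expect_identical(outcome_codes(r), "iL21")
})

test_that("full classification agrees with an independent oracle on a branch grid", {
  fibcats <- c("no_significant_fibrosis", "significant_fibrosis",
               "indeterminate_unresolved")
  aets <- list(character(0), "a1at")
  for (alcohol in c(FALSE, TRUE)) for (metabolic in c(FALSE, TRUE)) {
    for (fibcat in fibcats) for (aet in aets) {
      rec <- make_record(alt = 80, alcohol_over_14 = alcohol,
                         metabolic_syndrome = metabolic)
      rec[names(fib_recipe(fibcat))] <- fib_recipe(fibcat)
      if ("a1at" %in% aet) rec$a1at <- 0.8
      got <- outcome_codes(classify_record(rec))
      want <- classification_oracle(aet, alcohol, metabolic, fibcat,
                                    alt = 80, pattern = "alt")
      expect_setequal(got, want)
    }
  }

  # one case per remaining branch
  specials <- list(
    list(rec = make_record(alt = 80, ggt = 120), want =
           classification_oracle(pattern = c("alt", "ggt"))),
    list(rec = make_record(alt = 80, ggt = 120, alp = 150), want =
           classification_oracle(pattern = c("alt", "ggt", "alp"))),
    list(rec = make_record(ggt = 120), want =
           classification_oracle(pattern = "ggt", alt = 20)),
    list(rec = make_record(alt = 260), want =
           classification_oracle(alt = 260, pattern = "alt")),
    list(rec = make_record(alp = 210, platelets = 450, age = 55), want =
           classification_oracle(pattern = "alp", alt = 20, malig = TRUE)),
    list(rec = make_record(alt = 80, transferrin_saturation = 60), want =
           classification_oracle("iron")),
    list(rec = make_record(alt = 80, hbv_positive = TRUE), want =
           classification_oracle("hbv")),
    list(rec = make_record(alt = 80, hcv_positive = TRUE), want =
           classification_oracle("hcv")),
    list(rec = make_record(alt = 80, autoantibody_positive = TRUE), want =
           classification_oracle("auto")),
    list(rec = make_record(alt = 80, age = 40, crp = 2,
                           caeruloplasmin = 0.12), want =
           classification_oracle("wilson")),
    list(rec = c(make_record(alt = 80, age = 60, ast = 46, platelets = 165,
                             ha = 600, piiinp = 40, timp1 = 900)), want =
           classification_oracle(fibcat = "significant_fibrosis",
                                 urgent = TRUE)))
  for (sp in specials) {
    got <- outcome_codes(classify_record(sp$rec))
    expect_setequal(got, sp$want)
  }
})

test_that("significant fibrosis never leaves the record without referral", {
  fib_sig <- fib_recipe("significant_fibrosis")
  for (alcohol in c(FALSE, TRUE)) for (metabolic in c(FALSE, TRUE)) {
    for (a1at in c(1.5, 0.8)) {
      rec <- make_record(alt = 80, alcohol_over_14 = alcohol,
                         metabolic_syndrome = metabolic, a1at = a1at)
      rec[names(fib_sig)] <- fib_sig
      r <- classify_record(rec)
      expect_identical(r$final_fibrosis_category, "significant_fibrosis")
      expect_true(r$record_referral %in% c("routine", "urgent"),
                  info = sprintf("alc=%s met=%s a1at=%g", alcohol,
                                 metabolic, a1at))
    }
  }
  # aetiological outcome with phenotype-dependent referral alone would not
  # carry a referral: the fail-safe fibrosis outcome must appear
  rec <- make_record(alt = 80, a1at = 0.8)
  rec[names(fib_sig)] <- fib_sig
  r <- classify_record(rec)
  expect_true("iLX-FIB-SIG" %in% outcome_codes(r))
  expect_identical(r$record_referral, "routine")
})

test_that("steatotic liver disease nomenclature is current, with a legacy switch", {
  rec <- make_record(alt = 80, alcohol_over_14 = TRUE,
                     metabolic_syndrome = TRUE)
  r <- classify_record(rec)
  expect_identical(outcome_codes(r), "iLX-METALD-NF")
  expect_match(r$outcomes[[1]]$description, "MetALD")
  expect_no_match(r$outcomes[[1]]$description, "NAFLD")

  leg <- classify_record(rec, legacy_nomenclature = TRUE)
  expect_match(leg$outcomes[[1]]$description, "NAFLD")
  expect_no_match(leg$outcomes[[1]]$description, "MetALD")
})

test_that("identical records yield byte-identical outcomes", {
  rec <- make_record(alt = 80, a1at = 0.8, alcohol_over_14 = TRUE,
                     age = 60, ast = 46, platelets = 165,
                     ha = 150, piiinp = 15, timp1 = 300)
  r1 <- classify_record(rec)
  r2 <- classify_record(rec)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})

test_that("auto-comments carry the management advice and urgency", {
  r <- classify_record(make_record(alp = 150))
  expect_match(r$outcomes[[1]]$comment, "epeat ALP and GGT")
  expect_match(r$outcomes[[1]]$comment, "three months")

  r <- classify_record(make_record(alt = 80, age = 60, ast = 46,
                                   platelets = 165, ha = 600, piiinp = 40,
                                   timp1 = 900))
  urgent <- Filter(function(o) o$code == "iLX-ELF-URGENT", r$outcomes)[[1]]
  expect_match(urgent$comment, "^URGENT")
  expect_match(urgent$comment, "Urgent referral")

  r <- classify_record(make_record(alp = 210, platelets = 450, age = 55))
  alert <- Filter(function(o) o$code == "iLX-MALIGNANCY", r$outcomes)[[1]]
  expect_match(alert$comment, "malignancy")
  expect_match(alert$comment, "further tests")

  # alert outcomes come first in the emitted ordering
  expect_identical(r$outcomes[[1]]$code, "iLX-MALIGNANCY")

  # a template placeholder with no value renders an explicit marker
  entry <- list(comment_template = "Value is {nonexistent_field}.",
                referral_policy = "none", description = "x")
  expect_match(render_comment(entry, list()), "\\[unavailable\\]")
})
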