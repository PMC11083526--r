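#' Profile distribution parameters for the synthetic generator
#'
#' Loads the per-profile analyte distributions (truncated normals), flag
#' probabilities and expected outcome family from the parameters file
#' shipped with the package. Profile overrides are merged over the `base`
#' section, so each profile entry is complete.
#'
#' @param path Parameters YAML; defaults to the shipped file.
#' @return Named list of profile specs, each with `analytes`, `flags`,
#'   `p_male`, `expected_code`, `omit`.
#' @export
profile_params <- function(path = system.file("extdata", "profile_params.yaml",
                                              package = "ilftr")) {
  raw <- yaml::read_yaml(path)
  base <- raw$base
  lapply(raw$profiles, function(p) {
    analytes <- base$analytes
    analytes[names(p$analytes)] <- p$analytes
    flags <- base$flags
    flags[names(p$flags)] <- p$flags
    list(analytes = analytes, flags = flags,
         p_male = if (is.null(p$p_male)) base$p_male else p$p_male,
         expected_code = p$expected_code,
         omit = if (is.null(p$omit)) character(0) else unlist(p$omit))
  })
}

#' Default cohort mixture
#'
#' Eight-profile case mix used by the generator when no prevalences are
#' supplied: a majority of within-limits and common steatotic/alcohol
#' profiles with smaller aetiological fractions.
#'
#' @return Named numeric vector of prevalences summing to 1.
#' @export
default_mixture <- function() {
  c(normal = 0.25, ald = 0.15, masld = 0.15, gilbert = 0.10,
    viral_c = 0.05, iron = 0.10, a1at = 0.10, malignancy_alert = 0.10)
}

#' Specify a synthetic cohort
#'
#' @param n Number of records.
#' @param seed Integer seed; the same `(n, seed, prevalences)` always
#'   produces the byte-identical cohort.
#' @param prevalences Named numeric vector of profile prevalences; must
#'   name known profiles and sum to 1 (tolerance 1e-9).
#' @param params Profile parameters, see [profile_params()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n, seed, prevalences = default_mixture(),
                        params = profile_params()) {
  if (!is.numeric(n) || n < 0) stop("n must be a non-negative count", call. = FALSE)
  unknown <- setdiff(names(prevalences), names(params))
  if (length(unknown)) {
    stop("unknown profile(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(prevalences) - 1) > 1e-9) {
    stop("profile prevalences must sum to 1", call. = FALSE)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 prevalences = prevalences, params = params),
            class = "cohort_spec")
}

# inverse-CDF sampling from a normal truncated to [lo, hi]
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(p, mean, sd), lo), hi)
}

#' Generate a deterministic synthetic cohort
#'
#' Draws `n` patient records from the profile mixture in `spec`. Every
#' analyte comes from the profile's truncated normal; truncation bounds are
#' chosen so each profile fires its intended pathway branch essentially
#' always, which is what makes label-recovery testing possible. Direct
#' bilirubin is derived as `conjugated_fraction * total`, so the
#' direct-never-exceeds-total invariant holds by construction. The hidden
#' true-profile labels are returned as a sidecar data frame (and written to
#' a separate file by [write_cohort()]) so the classification path never
#' sees them.
#'
#' @param spec A [cohort_spec()].
#' @return List with `records` (list of schema records) and `labels`
#'   (data frame: `patient_id`, `profile`, `expected_code`).
#' @examples
#' coh <- generate_cohort(cohort_spec(10, seed = 7))
#' coh$labels$profile
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  set.seed(spec$seed)
  labels <- sample(names(spec$prevalences), n, replace = TRUE,
                   prob = spec$prevalences)
  ids <- sprintf("s%05d", seq_len(n))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    p <- spec$params[[labels[i]]]
    rec <- list(patient_id = ids[i])
    draws <- lapply(p$analytes, function(a)
      rtrunc_norm(1L, a$mean, a$sd, a$min, a$max))
    rec$age <- floor(draws$age)
    rec$sex <- if (stats::runif(1) < p$p_male) "male" else "female"
    rec$bmi <- round(draws$bmi, 1)
    for (f in names(p$flags)) rec[[f]] <- stats::runif(1) < p$flags[[f]]
    for (a in c("alt", "alp", "ggt", "bilirubin_total", "albumin", "ast",
                "platelets", "transferrin_saturation", "crp", "ha", "timp1")) {
      rec[[a]] <- round(draws[[a]], 1)
    }
    for (a in c("a1at", "caeruloplasmin", "haptoglobin", "piiinp")) {
      rec[[a]] <- round(draws[[a]], 2)
    }
    rec$direct_bilirubin <- round(draws$conjugated_fraction * rec$bilirubin_total, 1)
    for (a in p$omit) rec[a] <- list(NA_real_)
    records[[i]] <- rec
  }
  list(records = records,
       labels = data.frame(
         patient_id = ids, profile = labels,
         expected_code = vapply(labels, function(l)
           spec$params[[l]]$expected_code, ""),
         stringsAsFactors = FALSE, row.names = NULL))
}

#' Write a synthetic cohort plus its hidden-label sidecar
#'
#' Records go to `<stem>.csv` (or `.json`); the true-profile labels go to
#' `<stem>_labels.csv`, kept separate so pipeline code cannot peek.
#'
#' @param cohort Output of [generate_cohort()].
#' @param stem Output path stem.
#' @param format `"csv"` or `"json"`.
#' @return Named character vector of the two paths written, invisibly.
#' @export
write_cohort <- function(cohort, stem, format = "csv") {
  rec_path <- paste0(stem, ".", format)
  write_records(cohort$records, rec_path, format)
  lab_path <- paste0(stem, "_labels.csv")
  utils::write.csv(cohort$labels, lab_path, row.names = FALSE)
  invisible(c(records = rec_path, labels = lab_path))
}

#' Deterministic fixture with exact cascade-tier marginals
#'
#' Emits exactly `counts[["full"]]` records engineered to cascade to the
#' full aetiology screen, `counts[["limited"]]` to the limited bilirubin
#' tier and `counts[["none"]]` within limits, so that cohort-level tier
#' percentages can be reproduced exactly. Optionally, the first
#' `n_referral` of the full-cascade records are engineered to carry an
#' indeterminate FIB-4 resolved to significant fibrosis by a reflexed ELF
#' at/above the referral threshold, so that a chosen number of records
#' acquires a referral recommendation through the pathway itself.
#'
#' The fixture is deterministic (no randomness): each tier uses one fixed
#' template record.
#'
#' @param counts Named list/vector with `full`, `limited`, `none`.
#' @param n_referral Number of full-cascade records carrying referral;
#'   must not exceed `counts[["full"]]`.
#' @return List of schema records.
#' @examples
#' recs <- fixture_marginals(c(full = 1, limited = 1, none = 1))
#' vapply(recs, function(r) classify_record(r)$tier, "")
#' @export
fixture_marginals <- function(counts, n_referral = 0) {
  counts <- as.list(counts)
  for (k in c("full", "limited", "none")) {
    if (is.null(counts[[k]])) counts[k] <- list(0L)
    if (counts[[k]] < 0) stop("counts must be non-negative", call. = FALSE)
  }
  if (n_referral > counts$full) {
    stop("n_referral cannot exceed the full-cascade count", call. = FALSE)
  }
  base <- list(
    sex = "male", bmi = 27, alcohol_over_14 = FALSE, metabolic_syndrome = FALSE,
    alp = 100, ggt = 30, albumin = 44,
    transferrin_saturation = 30, a1at = 1.5,
    hbv_positive = FALSE, hcv_positive = FALSE, autoantibody_positive = FALSE)
  # abnormal ALT, negative screen, FIB-4 ruled out -> no referral
  full_plain <- c(base, list(age = 50, alt = 80, bilirubin_total = 10,
                             ast = 30, platelets = 300))
  # indeterminate FIB-4, reflex ELF above the referral threshold
  full_referral <- c(base, list(age = 60, alt = 80, bilirubin_total = 10,
                                ast = 46, platelets = 165,
                                ha = 150, piiinp = 15, timp1 = 300))
  limited <- c(base, list(age = 50, alt = 20, bilirubin_total = 40,
                          direct_bilirubin = 6, haptoglobin = 1.2))
  none <- c(base, list(age = 50, alt = 20, bilirubin_total = 10))

  templates <- c(rep(list(full_referral), n_referral),
                 rep(list(full_plain), counts$full - n_referral),
                 rep(list(limited), counts$limited),
                 rep(list(none), counts$none))
  mapply(function(rec, i) {
    rec$patient_id <- sprintf("f%05d", i)
    rec
  }, templates, seq_along(templates), SIMPLIFY = FALSE)
}
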