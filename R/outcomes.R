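#' Malignancy alert rule
#'
#' The combination of an elevated alkaline phosphatase (> 130 U/L) and
#' thrombocytosis (platelets > 400 x 10^9/L) in a patient over 40 carries a
#' positive predictive value for undiagnosed malignancy well above the
#' usual investigation threshold, so it raises a dedicated alert outcome.
#' All three comparisons are strict.
#'
#' @param age Years.
#' @param alp U/L.
#' @param platelets 10^9/L; `NA` (not measured) never alerts.
#' @param thresholds Thresholds list.
#' @return Logical.
#' @examples
#' malignancy_alert(55, 180, 450) # TRUE
#' malignancy_alert(40, 180, 450) # FALSE ("over 40" is strict)
#' @export
malignancy_alert <- function(age, alp, platelets, thresholds = ilft_thresholds()) {
  th <- thresholds
  if (!has_value(age) || !has_value(alp) || !has_value(platelets)) return(FALSE)
  age > th$malignancy_age && alp > th$malignancy_alp &&
    platelets > th$malignancy_platelets
}

# emission precedence: alerts first, then urgent, aetiological,
# presumed-lifestyle, descriptive/advisory
outcome_rank <- function(outcome, lifestyle) {
  if (outcome$category == "alert") 0L
  else if (outcome$referral == "urgent") 1L
  else if (outcome$category == "aetiological" && !lifestyle) 2L
  else if (lifestyle) 3L
  else 4L
}

lifestyle_codes <- c("iL04", "iL05", "iL16", "iL17", "iLX-METALD-F", "iLX-METALD-NF")

#' Map a fully staged record to its coded outcomes
#'
#' The terminal step of the pathway: combines the cascade plan, aetiology
#' findings and fibrosis assessment into one or more coded outcomes with
#' referral advice. A single request can generate several outcomes.
#'
#' Non-cascade tiers yield their single outcome (normal result, ALP
#' advisory, or the bilirubin subtype from the limited cascade). Full
#' cascades assemble outcomes by precedence:
#'
#' 1. every positive aetiology finding emits its aetiological outcome;
#' 2. lifestyle flags emit a presumed steatotic-liver-disease outcome —
#'    alcohol and metabolic syndrome together map to MetALD, alcohol alone
#'    to ALD, metabolic syndrome alone to MASLD, each split by the fibrosis
#'    category (these are emitted even alongside a specific aetiology);
#' 3. with neither flag and no positive finding, a descriptive outcome is
#'    keyed to the abnormal-analyte pattern (ALT only below 250 U/L; ALT +
#'    GGT; ALT + ALP + GGT; otherwise an explicit fallback descriptive
#'    outcome — never a silent drop);
#' 4. ALT at or above 250 U/L adds the urgent marked-ALT outcome;
#' 5. the malignancy alert appends its alert outcome;
#' 6. unresolved indeterminate fibrosis adds a referral-for-assessment
#'    outcome, an ELF score at/above the urgency threshold adds the urgent
#'    prognosis outcome, and (fail-safe) a significant-fibrosis category
#'    that would otherwise leave the record without any referral-carrying
#'    outcome appends one.
#'
#' The record-level referral is the maximum severity over emitted outcomes
#' (none < phenotype_dependent < routine < urgent).
#'
#' @param context Validated record (demographics and flags).
#' @param panel Validated record (first-line analytes); usually the same
#'   list as `context`.
#' @param plan [evaluate_first_line()] result.
#' @param findings [interpret_screen()] result (may be `NULL` for
#'   non-cascade tiers).
#' @param fibrosis [assess_fibrosis()] result (may be `NULL` for
#'   non-cascade tiers).
#' @param registry Outcome registry, see [load_registry()].
#' @param thresholds Thresholds list.
#' @param legacy_nomenclature If `TRUE`, rewrite steatotic liver disease
#'   terms in descriptions/comments back to the pre-2023 names (MASLD ->
#'   NAFLD, MetALD -> "NAFLD and ALD") for regression comparison.
#' @return List with `outcomes` (list of outcome lists: `code`,
#'   `description`, `category`, `referral`, `comment`) and
#'   `record_referral`.
#' @export
classify <- function(context, panel, plan, findings = NULL, fibrosis = NULL,
                     registry = load_registry(),
                     thresholds = ilft_thresholds(),
                     legacy_nomenclature = FALSE) {
  th <- thresholds
  codes <- character(0)

  if (plan$tier == "none") {
    codes <- "iLX-NORMAL"
  } else if (plan$tier == "alp_advisory") {
    codes <- "iL21"
  } else if (plan$tier == "limited_bilirubin") {
    pattern <- gilbert_check(panel$bilirubin_total, panel$direct_bilirubin,
                             panel$haptoglobin, th)
    codes <- switch(pattern,
                    gilbert_likely = "iL06",
                    conjugated_pattern = "iLX-BILI-CONJ",
                    haemolysis_suspected = "iLX-HAEMOLYSIS",
                    not_applicable = "iLX-BILI-UNRES")
  } else {
    fib_sig <- !is.null(fibrosis) &&
      fibrosis$final_category == "significant_fibrosis"

    aet_map <- c(iron_overload = "iLX-IRON", a1at_deficiency = "iL01",
                 hepatitis_b = "iLX-VIRAL-B", hepatitis_c = "iLX-VIRAL-C",
                 autoimmune = "iLX-AUTOIMMUNE", wilson_possible = "iLX-WILSON")
    positive <- names(aet_map)[vapply(names(aet_map), function(a) {
      !is.null(findings[[a]]) && findings[[a]]$status == "positive"
    }, logical(1))]
    codes <- c(codes, unname(aet_map[positive]))

    alcohol <- isTRUE(context$alcohol_over_14)
    metabolic <- isTRUE(context$metabolic_syndrome)
    if (alcohol && metabolic) {
      codes <- c(codes, if (fib_sig) "iLX-METALD-F" else "iLX-METALD-NF")
    } else if (alcohol) {
      codes <- c(codes, if (fib_sig) "iL04" else "iL05")
    } else if (metabolic) {
      codes <- c(codes, if (fib_sig) "iL16" else "iL17")
    } else if (!length(positive)) {
      # pure descriptive branch: negative screen, no lifestyle flags
      pat <- sort(plan$abnormal_analytes)
      marked <- has_value(panel$alt) && panel$alt >= th$alt_marked
      desc <- if (fib_sig) "iLX-DESC-F"
      else if (identical(pat, "alt") && !marked) "iL15"
      else if (identical(pat, c("alt", "ggt"))) "iL28"
      else if (identical(pat, c("alp", "alt", "ggt"))) "iL02"
      else if (identical(pat, "alt") && marked) NULL  # marked-ALT outcome covers it
      else "iLX-DESC"
      codes <- c(codes, desc)
    }

    if (has_value(panel$alt) && panel$alt >= th$alt_marked) {
      codes <- c(codes, "iLX-ALT-MARKED")
    }
    if (malignancy_alert(context$age, panel$alp, panel$platelets, th)) {
      codes <- c(codes, "iLX-MALIGNANCY")
    }
    if (!is.null(fibrosis)) {
      if (fibrosis$final_category == "indeterminate_unresolved") {
        codes <- c(codes, "iLX-FIB-INDET")
      }
      if (isTRUE(fibrosis$urgent_prognosis)) codes <- c(codes, "iLX-ELF-URGENT")
    }
    if (!length(codes)) codes <- "iLX-DESC"  # fail-safe: never silent
    # fail-safe: significant fibrosis must carry a referral
    pols <- vapply(codes, function(cd) registry_entry(registry, cd)$referral_policy,
                   character(1))
    if (fib_sig && !any(pols %in% c("routine", "urgent"))) {
      codes <- c(codes, "iLX-FIB-SIG")
    }
  }

  values <- render_values(context, panel, plan, fibrosis)
  outcomes <- lapply(codes, function(cd) {
    e <- registry_entry(registry, cd)
    if (legacy_nomenclature) {
      e$description <- legacy_names(e$description)
      e$comment_template <- legacy_names(e$comment_template)
    }
    list(code = e$code,
         description = e$description,
         category = e$category,
         referral = e$referral_policy,
         comment = render_comment(e, values))
  })
  rank <- vapply(outcomes, function(o)
    outcome_rank(o, o$code %in% lifestyle_codes), integer(1))
  outcomes <- outcomes[order(rank, vapply(outcomes, `[[`, "", "code"))]
  list(outcomes = outcomes,
       record_referral = max_referral(vapply(outcomes, `[[`, "", "referral")))
}

legacy_names <- function(x) {
  x <- gsub("MetALD", "combined NAFLD and ALD", x, fixed = TRUE)
  gsub("MASLD", "NAFLD", x, fixed = TRUE)
}

render_values <- function(context, panel, plan, fibrosis) {
  v <- c(as.list(context), as.list(panel))
  v <- v[!duplicated(names(v))]
  if (!is.null(fibrosis)) {
    v$fib4 <- round3(fibrosis$fib4)
    v$nfs <- round3(fibrosis$nfs)
    v$elf <- round3(fibrosis$elf)
  }
  if (!is.null(plan)) {
    v$abnormal_pattern <- paste(toupper(sub("bilirubin_total", "bilirubin",
                                            plan$abnormal_analytes)),
                                collapse = " + ")
  }
  v
}

round3 <- function(x) if (has_value(x)) round(x, 3) else NA_real_

#' Render the auto-comment for an outcome
#'
#' Deterministic text from the outcome's comment template with `{field}`
#' placeholders interpolated from the record and derived values. Urgent
#' outcomes lead with an urgency statement; every comment ends with a
#' referral advice line. A placeholder with no corresponding value renders
#' as `[unavailable]` rather than failing.
#'
#' @param entry Registry row (list) with `comment_template`,
#'   `referral_policy`, `description`.
#' @param values Named list of interpolation values.
#' @return Character scalar.
#' @export
render_comment <- function(entry, values) {
  tmpl <- entry$comment_template
  body <- interpolate(tmpl, values)
  advice <- switch(entry$referral_policy,
    none = "No liver clinic referral is advised.",
    routine = "Consider routine referral to the liver clinic.",
    urgent = "Urgent referral to secondary care hepatology is advised.",
    phenotype_dependent = "Liver clinic referral advice depends on the phenotype result.")
  if (entry$referral_policy == "urgent") {
    paste0("URGENT: ", entry$description, ". ", body, " ", advice)
  } else {
    paste0(body, " ", advice)
  }
}

interpolate <- function(tmpl, values) {
  m <- gregexpr("\\{[a-z0-9_]+\\}", tmpl)[[1]]
  if (m[1] == -1) return(tmpl)
  keys <- unique(substring(regmatches(tmpl, gregexpr("\\{[a-z0-9_]+\\}", tmpl))[[1]], 2))
  keys <- sub("\\}$", "", keys)
  for (k in keys) {
    v <- values[[k]]
    rep <- if (has_value(v)) as.character(v) else "[unavailable]"
    tmpl <- gsub(paste0("{", k, "}"), rep, tmpl, fixed = TRUE)
  }
  tmpl
}
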