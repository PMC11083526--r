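#' Percentage rounded half-away-from-zero to one decimal
#'
#' The reporting convention used throughout the cohort summaries: `100 *
#' numerator / denominator`, rounded to one decimal place with halves
#' rounded away from zero (so 23.55 prints as 23.6). Base R's `round()`
#' rounds half to even, which is the wrong convention for these reports.
#'
#' @param numerator Non-negative count.
#' @param denominator Positive count; a zero denominator returns
#'   `NA_real_` (an explicit undefined marker) rather than an error.
#' @return Numeric percentage with one decimal, or `NA_real_`.
#' @examples
#' percent(8096, 11043) # 73.3
#' percent(2331, 9879)  # 23.6
#' @export
percent <- function(numerator, denominator) {
  if (!is.numeric(numerator) || !is.numeric(denominator) ||
      numerator < 0 || denominator < 0) {
    stop("percent() needs non-negative counts", call. = FALSE)
  }
  if (denominator == 0) return(NA_real_)
  x <- 100 * numerator / denominator
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Summarise a classified cohort
#'
#' Deterministic cohort-level report: request counts by cascade tier (with
#' percentages on the number of requests), outcome counts by code and by
#' category, and referral proportions. Per-code percentages are given
#' against two denominators, matching the reporting convention for outcome
#' tables: the number of outcomes generated and the number of requests
#' (a single request can generate several outcomes, so these differ). The
#' outcome table is sorted by descending count with a stable
#' alphabetical code tie-break; the summary is invariant to input order.
#'
#' @param results List of classified-record lists from [classify_record()].
#' @return A `cohort_summary` list: `n_requests`, `tiers` (data frame:
#'   tier, n, pct), `n_outcomes`, `outcome_table` (data frame: code,
#'   description, n, pct_of_outcomes, pct_of_requests, referral),
#'   `categories` (data frame: category, n, pct_of_outcomes),
#'   `n_referral`, `pct_referral`, `pct_no_referral`, `fibrosis_bands`
#'   (data frame over final fibrosis categories of full cascades).
#' @export
summarize_cohort <- function(results) {
  n_req <- length(results)
  tiers_all <- c("none", "alp_advisory", "limited_bilirubin", "full")
  tier_vec <- vapply(results, `[[`, "", "tier")
  tier_n <- vapply(tiers_all, function(t) sum(tier_vec == t), integer(1))
  tiers <- data.frame(tier = tiers_all, n = unname(tier_n),
                      pct = vapply(tier_n, percent, 0, denominator = n_req),
                      stringsAsFactors = FALSE)

  out_rows <- list()
  for (res in results) for (o in res$outcomes) {
    out_rows[[length(out_rows) + 1L]] <-
      c(code = o$code, description = o$description, category = o$category,
        referral = o$referral)
  }
  n_out <- length(out_rows)
  if (n_out) {
    om <- do.call(rbind, out_rows)
    codes <- om[, "code"]
    tab <- table(codes)
    ord <- order(-as.integer(tab), names(tab))
    code_sorted <- names(tab)[ord]
    first_idx <- match(code_sorted, codes)
    outcome_table <- data.frame(
      code = code_sorted,
      description = om[first_idx, "description"],
      n = as.integer(tab)[ord],
      pct_of_outcomes = vapply(as.integer(tab)[ord], percent, 0,
                               denominator = n_out),
      pct_of_requests = vapply(as.integer(tab)[ord], percent, 0,
                               denominator = n_req),
      referral = om[first_idx, "referral"],
      stringsAsFactors = FALSE, row.names = NULL)
    cat_vec <- om[, "category"]
  } else {
    outcome_table <- data.frame(code = character(0), description = character(0),
                                n = integer(0), pct_of_outcomes = numeric(0),
                                pct_of_requests = numeric(0),
                                referral = character(0))
    cat_vec <- character(0)
  }
  cats_all <- c("aetiological", "descriptive", "advisory", "alert")
  cat_n <- vapply(cats_all, function(x) sum(cat_vec == x), integer(1))
  categories <- data.frame(
    category = cats_all, n = unname(cat_n),
    pct_of_outcomes = vapply(cat_n, percent, 0, denominator = n_out),
    stringsAsFactors = FALSE)

  referral_vec <- vapply(results, `[[`, "", "record_referral")
  n_ref <- sum(referral_vec %in% c("routine", "urgent", "phenotype_dependent"))

  fib_all <- c("no_significant_fibrosis", "indeterminate_resolved_low",
               "significant_fibrosis", "indeterminate_unresolved")
  fib_vec <- vapply(results, function(r) or_na(r$final_fibrosis_category), "")
  fib_n <- vapply(fib_all, function(x) sum(fib_vec == x, na.rm = TRUE), integer(1))
  fibrosis_bands <- data.frame(category = fib_all, n = unname(fib_n),
                               stringsAsFactors = FALSE)

  structure(list(
    n_requests = n_req, tiers = tiers,
    n_outcomes = n_out, outcome_table = outcome_table,
    categories = categories,
    n_referral = n_ref,
    pct_referral = percent(n_ref, n_req),
    pct_no_referral = percent(n_req - n_ref, n_req),
    fibrosis_bands = fibrosis_bands
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d requests, %d outcomes\n", x$n_requests, x$n_outcomes))
  cat("\nCascade tiers:\n")
  print(x$tiers, row.names = FALSE)
  cat("\nOutcomes by code:\n")
  print(x$outcome_table, row.names = FALSE)
  cat("\nOutcome categories:\n")
  print(x$categories, row.names = FALSE)
  cat(sprintf("\nReferral advised: %d (%.1f%%); no referral: %.1f%%\n",
              x$n_referral, x$pct_referral, x$pct_no_referral))
  invisible(x)
}
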