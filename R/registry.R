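#' Load the coded outcome registry
#'
#' The registry is a tab-delimited text file mapping each outcome code to
#' its category, referral policy, description and comment template. Codes
#' of the form `iLxx` are the published pathway codes; only a subset of the
#' 33 production outcomes is public, so the remainder are reconstructed
#' here under an `iLX-*` namespace that cannot be mistaken for official
#' codes. The file is data, not code: sites can edit descriptions (for
#' example to rename disease categories) without touching the engine.
#'
#' @param path Registry file; defaults to the registry shipped with the
#'   package.
#' @return Data frame with columns `code`, `category`, `referral_policy`,
#'   `description`, `comment_template`; codes are unique.
#' @export
load_registry <- function(path = system.file("extdata", "outcome_registry.tsv",
                                             package = "ilftr")) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  needed <- c("code", "category", "referral_policy", "description",
              "comment_template")
  if (!all(needed %in% names(reg))) {
    stop("registry file must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(reg$code)) {
    stop("registry codes must be unique", call. = FALSE)
  }
  bad <- setdiff(reg$referral_policy,
                 c("none", "routine", "urgent", "phenotype_dependent"))
  if (length(bad)) stop("unknown referral policy: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(reg$category, c("aetiological", "descriptive", "advisory", "alert"))
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  reg
}

registry_entry <- function(registry, code) {
  i <- match(code, registry$code)
  if (is.na(i)) stop("outcome code not in registry: ", code, call. = FALSE)
  as.list(registry[i, , drop = FALSE])
}

# referral severity ordering used for the record-level maximum
referral_rank <- c(none = 0L, phenotype_dependent = 1L, routine = 2L, urgent = 3L)

#' @rdname load_registry
#' @details `max_referral()` returns the most severe of a set of referral
#'   policies under the ordering none < phenotype_dependent < routine <
#'   urgent; it defines the record-level referral when several outcomes are
#'   emitted.
#' @param policies Character vector of referral policies.
#' @export
max_referral <- function(policies) {
  if (!length(policies)) return("none")
  names(which.max(referral_rank[policies]))
}
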