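# Independent nested-conditional oracle for the outcome set of a full
# cascade, written straight from the rule precedence (not via classify()).
# Arguments describe which branches are active; the referral policies are
# restated here independently for the fail-safe branch.
classification_oracle <- function(aet = character(0),
                                  alcohol = FALSE, metabolic = FALSE,
                                  fibcat = "low", urgent = FALSE,
                                  alt = 80, pattern = "alt",
                                  malig = FALSE) {
  aet_map <- c(a1at = "iL01", iron = "iLX-IRON", hbv = "iLX-VIRAL-B",
               hcv = "iLX-VIRAL-C", auto = "iLX-AUTOIMMUNE",
               wilson = "iLX-WILSON")
  sig <- fibcat == "significant_fibrosis"
  codes <- unname(aet_map[aet])
  if (alcohol && metabolic) {
    codes <- c(codes, if (sig) "iLX-METALD-F" else "iLX-METALD-NF")
  } else if (alcohol) {
    codes <- c(codes, if (sig) "iL04" else "iL05")
  } else if (metabolic) {
    codes <- c(codes, if (sig) "iL16" else "iL17")
  } else if (!length(aet)) {
    pattern <- sort(pattern)
    codes <- c(codes,
               if (sig) "iLX-DESC-F"
               else if (identical(pattern, "alt") && alt < 250) "iL15"
               else if (identical(pattern, c("alt", "ggt"))) "iL28"
               else if (identical(pattern, c("alp", "alt", "ggt"))) "iL02"
               else if (identical(pattern, "alt") && alt >= 250) NULL
               else "iLX-DESC")
  }
  if (alt >= 250) codes <- c(codes, "iLX-ALT-MARKED")
  if (malig) codes <- c(codes, "iLX-MALIGNANCY")
  if (fibcat == "indeterminate_unresolved") codes <- c(codes, "iLX-FIB-INDET")
  if (urgent) codes <- c(codes, "iLX-ELF-URGENT")
  if (!length(codes)) codes <- "iLX-DESC"
  referral <- c(iL01 = "phenotype_dependent", `iLX-IRON` = "routine",
                `iLX-VIRAL-B` = "routine", `iLX-VIRAL-C` = "routine",
                `iLX-AUTOIMMUNE` = "routine", `iLX-WILSON` = "routine",
                `iLX-METALD-F` = "routine", `iLX-METALD-NF` = "none",
                iL04 = "routine", iL05 = "none", iL16 = "routine",
                iL17 = "none", iL15 = "none", iL28 = "none", iL02 = "none",
                `iLX-DESC` = "none", `iLX-DESC-F` = "routine",
                `iLX-ALT-MARKED` = "urgent", `iLX-MALIGNANCY` = "routine",
                `iLX-FIB-INDET` = "routine", `iLX-ELF-URGENT` = "urgent",
                `iLX-FIB-SIG` = "routine")
  if (sig && !any(referral[codes] %in% c("routine", "urgent"))) {
    codes <- c(codes, "iLX-FIB-SIG")
  }
  codes
}

# Record recipes producing each fibrosis category on a full cascade
# (ALT 80 keeps the cascade open; FIB-4 is set by age/AST/platelets).
fib_recipe <- function(fibcat, urgent = FALSE) {
  base <- switch(fibcat,
    no_significant_fibrosis = list(age = 50, ast = 25, platelets = 300),
    significant_fibrosis = list(age = 60, ast = 46, platelets = 165,
                                ha = 150, piiinp = 15, timp1 = 300),
    indeterminate_resolved_low = list(age = 60, ast = 46, platelets = 165,
                                      ha = 30, piiinp = 6, timp1 = 80),
    indeterminate_unresolved = list(age = 60, ast = 46, platelets = 165))
  if (urgent) {
    base$ha <- 600; base$piiinp <- 40; base$timp1 <- 900
  }
  base
}
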