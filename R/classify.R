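.diagnosis_levels <- c("F0-2", "Biopsy", "F34", "F4")

#' Agile3+/4 four-group classification
#'
#' Crosses the advanced-fibrosis intervals of Agile3+ with the cirrhosis
#' rule-in threshold of Agile4: (i) Agile3+ < 0.451; (ii) 0.451 <= Agile3+
#' < 0.679; (iii) Agile3+ >= 0.679 with Agile4 <= 0.474; (iv) Agile3+ >=
#' 0.679 with Agile4 > 0.474. Boundary conventions are literal: 0.679 falls
#' in group 3+ territory and Agile4 = 0.474 stays in group 3.
#'
#' @param agile3p,agile4 scores in `[0, 1]` (vectorized). `agile4` may be NA
#'   for subjects with Agile3+ < 0.679, where it is not consulted.
#' @param thresholds from [default_thresholds()].
#' @return integer group 1..4.
#' @examples
#' agile_classify(0.30, 0.05)      # 1
#' agile_classify(0.70, 0.50)      # 4
#' agile_classify(0.679, 0.474)    # 3 (boundary: Agile4 <= 0.474 inclusive)
#' @export
agile_classify <- function(agile3p, agile4, thresholds = default_thresholds()) {
  check_unit(agile3p = agile3p)
  high <- !is.na(agile3p) & agile3p >= thresholds$agile3p_high
  if (any(high & is.na(agile4))) {
    stopf("agile4 required when agile3p >= %.3f", thresholds$agile3p_high)
  }
  check_unit(agile4 = agile4[!is.na(agile4)])
  ifelse(agile3p < thresholds$agile3p_low, 1L,
         ifelse(agile3p < thresholds$agile3p_high, 2L,
                ifelse(agile4 <= thresholds$agile4_high, 3L, 4L)))
}

#' FibroMeterV3G/CirrhoMeterV3G four-group classification
#'
#' (i) FMV3G < 0.31; (ii) 0.31 <= FMV3G <= 0.76; (iii) FMV3G > 0.76 with
#' CMV3G <= 0.40; (iv) FMV3G > 0.76 with CMV3G > 0.40.
#'
#' @param fmv3g,cmv3g scores in `[0, 1]` (vectorized). `cmv3g` may be NA for
#'   subjects with FMV3G <= 0.76.
#' @param thresholds from [default_thresholds()].
#' @return integer group 1..4.
#' @examples
#' fmcm_classify(0.20, 0.02)   # 1
#' fmcm_classify(0.91, 0.40)   # 3 (CMV3G <= 0.40 inclusive)
#' fmcm_classify(0.80, 0.41)   # 4
#' @export
fmcm_classify <- function(fmv3g, cmv3g, thresholds = default_thresholds()) {
  check_unit(fmv3g = fmv3g)
  high <- !is.na(fmv3g) & fmv3g > thresholds$fm_high
  if (any(high & is.na(cmv3g))) {
    stopf("cmv3g required when fmv3g > %.2f", thresholds$fm_high)
  }
  check_unit(cmv3g = cmv3g[!is.na(cmv3g)])
  ifelse(fmv3g < thresholds$fm_low, 1L,
         ifelse(fmv3g <= thresholds$fm_high, 2L,
                ifelse(cmv3g <= thresholds$cm_high, 3L, 4L)))
}

check_unit <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (anyNA(x)) stopf("%s contains missing values", nm)
    if (length(x) && (any(x < 0) || any(x > 1))) {
      stopf("%s must lie in [0, 1]", nm)
    }
  }
  invisible(TRUE)
}

#' Default combination map of the two classifications
#'
#' The sequential algorithm crosses the Agile3+/4 group (2-4; group 1
#' short-circuits to F0-2 before blood testing) with the FM/CM group (1-4).
#' The exact 16-cell crossing of the source study is shown only graphically,
#' so the default map encodes agreement logic: final F4 only when both
#' classifications are in their rule-in group 4; final F34 when at least one
#' axis is at F34 level or above, the other is not rule-out, and the double
#' rule-in cell is excluded; F0-2 when the blood tests rule out (group 1)
#' against a merely grey Agile result (group 2); every remaining discordant
#' or doubly grey cell requires biopsy. The map is data: ship your own 12-row
#' table to override it.
#'
#' @return a tibble with columns `agile_group` (2..4), `fmcm_group` (1..4),
#'   `diagnosis` (one of `"F0-2", "Biopsy", "F34", "F4"`).
#' @export
default_combination_map <- function() {
  tibble::tribble(
    ~agile_group, ~fmcm_group, ~diagnosis,
    2L, 1L, "F0-2",
    2L, 2L, "Biopsy",
    2L, 3L, "F34",
    2L, 4L, "F34",
    3L, 1L, "Biopsy",
    3L, 2L, "F34",
    3L, 3L, "F34",
    3L, 4L, "F34",
    4L, 1L, "Biopsy",
    4L, 2L, "F34",
    4L, 3L, "F34",
    4L, 4L, "F4"
  )
}

check_combination_map <- function(map) {
  need <- c("agile_group", "fmcm_group", "diagnosis")
  if (!all(need %in% names(map))) {
    stopf("combination map needs columns %s", paste(need, collapse = ", "))
  }
  cells <- expand.grid(agile_group = 2:4, fmcm_group = 1:4)
  key <- paste(map$agile_group, map$fmcm_group)
  if (anyDuplicated(key)) stopf("combination map has duplicated cells")
  missing <- setdiff(paste(cells$agile_group, cells$fmcm_group), key)
  if (length(missing)) {
    stopf("combination map misses cell(s): %s", paste(missing, collapse = "; "))
  }
  if (!all(map$diagnosis %in% .diagnosis_levels)) {
    stopf("combination map diagnoses must be in {%s}",
          paste(.diagnosis_levels, collapse = ", "))
  }
  invisible(map)
}

#' Sequential study algorithm: VCTE-based scores first, blood tests second
#'
#' Stage one applies the Agile3+/4 classification; patients with Agile3+
#' below the rule-out threshold (group 1) are diagnosed F0-2 with no blood
#' testing. All others require the specialized blood tests: the FM/CM group
#' is crossed with the Agile group through the combination map, yielding one
#' of the four diagnoses F0-2, Biopsy, F34 or F4.
#'
#' @param cohort data frame with columns `agile3p`, `agile4`, and — for every
#'   subject whose Agile group is 2 or higher — `fmv3g`, `cmv3g`.
#' @param map a combination map (default [default_combination_map()]).
#' @param thresholds from [default_thresholds()].
#' @return a tibble of class `classification_result`: `agile_group`,
#'   `fmcm_group` (NA when blood testing was skipped), `final_diagnosis`
#'   (factor F0-2 < Biopsy < F34 < F4), `tests_used`, `rationale` (cell id).
#' @export
study_algorithm <- function(cohort, map = default_combination_map(),
                            thresholds = default_thresholds()) {
  check_combination_map(map)
  if (!all(c("agile3p", "agile4") %in% names(cohort))) {
    stopf("cohort must contain agile3p and agile4")
  }
  n <- nrow(cohort)
  ag <- agile_classify(cohort$agile3p, cohort$agile4, thresholds)
  need_blood <- ag >= 2L

  fg <- rep(NA_integer_, n)
  if (any(need_blood)) {
    fm <- cohort[["fmv3g"]]; cm <- cohort[["cmv3g"]]
    if (is.null(fm) || is.null(cm) || anyNA(fm[need_blood])) {
      stopf("fmv3g/cmv3g required for %d subject(s) with Agile group >= 2",
            sum(need_blood))
    }
    # cmv3g itself is only consulted when fmv3g > fm_high; fmcm_classify
    # enforces its presence there
    fg[need_blood] <- fmcm_classify(fm[need_blood], cm[need_blood], thresholds)
  }

  diag <- rep("F0-2", n)
  lookup <- setNames(map$diagnosis, paste(map$agile_group, map$fmcm_group))
  diag[need_blood] <- lookup[paste(ag[need_blood], fg[need_blood])]

  out <- tibble::tibble(
    agile_group = ag,
    fmcm_group = fg,
    final_diagnosis = factor(diag, levels = .diagnosis_levels),
    tests_used = ifelse(need_blood, "Agile3+/Agile4 > FMV3G/CMV3G",
                        "Agile3+/Agile4"),
    rationale = ifelse(need_blood, paste0("A", ag, "xB", fg), "A1")
  )
  class(out) <- c("classification_result", class(out))
  out
}

#' EASL-style three-tier comparator pathway
#'
#' The guideline triage used as comparator: tier 1 rules out with a simple
#' blood test (FIB4), tier 2 with liver stiffness, tier 3 rules in advanced
#' fibrosis when stiffness and a specialized blood test concord; everything
#' else stays in the grey zone (biopsy). Thresholds are configuration, with
#' guideline defaults FIB4 1.3, stiffness 8 and 12 kPa, FibroMeterV3G 0.76.
#'
#' @param cohort data frame with `fib4`, `vcte_kpa` and `fmv3g`.
#' @param thresholds list with `fib4_low`, `vcte_low`, `vcte_high`,
#'   `blood_high`.
#' @return tibble with `easl_diagnosis` (factor `"F0-2"`, `"Biopsy"`,
#'   `"F34"`) and `tier_used` (1..3).
#' @export
easl_pathway <- function(cohort,
                         thresholds = list(fib4_low = 1.3, vcte_low = 8,
                                           vcte_high = 12, blood_high = 0.76)) {
  need <- c("fib4", "vcte_kpa", "fmv3g")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stopf("easl_pathway needs column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyNA(cohort$fib4)) stopf("fib4 missing for some subjects")
  tier1 <- cohort$fib4 < thresholds$fib4_low
  rest <- !tier1
  if (any(rest) && anyNA(cohort$vcte_kpa[rest])) {
    stopf("vcte_kpa missing for subjects beyond tier 1")
  }
  tier2 <- rest & cohort$vcte_kpa < thresholds$vcte_low
  tier3 <- rest & !tier2
  if (any(tier3) && anyNA(cohort$fmv3g[tier3])) {
    stopf("fmv3g missing for subjects reaching tier 3")
  }
  rule_in <- tier3 & cohort$vcte_kpa >= thresholds$vcte_high &
    cohort$fmv3g > thresholds$blood_high

  diag <- ifelse(tier1 | tier2, "F0-2", ifelse(rule_in, "F34", "Biopsy"))
  tibble::tibble(
    easl_diagnosis = factor(diag, levels = c("F0-2", "Biopsy", "F34")),
    tier_used = ifelse(tier1, 1L, ifelse(tier2, 2L, 3L))
  )
}

#' Map final diagnoses to cirrhosis decision zones
#'
#' F0-2 and Biopsy/grey-zone results rule cirrhosis out for triage purposes,
#' F34 is undetermined, and F4 rules cirrhosis in.
#'
#' @param diagnosis factor/character vector of final diagnoses (`"F0-2"`,
#'   `"Biopsy"`, `"F34"`, `"F4"`).
#' @return factor with levels `"rule-out"`, `"undetermined"`, `"rule-in"`.
#' @export
cirrhosis_zones <- function(diagnosis) {
  d <- as.character(diagnosis)
  bad <- setdiff(unique(d), .diagnosis_levels)
  if (length(bad)) stopf("unknown diagnosis value(s): %s",
                         paste(bad, collapse = ", "))
  zone <- ifelse(d %in% c("F0-2", "Biopsy"), "rule-out",
                 ifelse(d == "F34", "undetermined", "rule-in"))
  factor(zone, levels = c("rule-out", "undetermined", "rule-in"))
}
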