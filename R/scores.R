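#' FIB-4 index
#'
#' `FIB4 = (age * AST) / (platelets * sqrt(ALT))` with age in years, AST and
#' ALT in IU/L and platelets in G/L (10^9/L).
#'
#' @param age years.
#' @param ast,alt IU/L.
#' @param platelets G/L.
#' @return the FIB-4 value (vectorized).
#' @examples
#' compute_fib4(60, 40, 36, 200)  # 2.0
#' @export
compute_fib4 <- function(age, ast, alt, platelets) {
  check_positive(age = age, ast = ast, alt = alt, platelets = platelets)
  (age * ast) / (platelets * sqrt(alt))
}

#' NAFLD fibrosis score
#'
#' `NFS = -1.675 + 0.037*age + 0.094*BMI + 1.13*[IFG or diabetes]
#'  + 0.99*AST/ALT - 0.013*platelets - 0.66*albumin` with age in years, BMI in
#' kg/m^2, platelets in G/L and albumin in g/dL. Albumin is passed in g/L
#' (the unit used throughout this package) and converted internally.
#'
#' @param age years.
#' @param bmi kg/m^2.
#' @param t2dm_or_ifg logical: impaired fasting glycaemia or diabetes.
#' @param ast,alt IU/L.
#' @param platelets G/L.
#' @param albumin_gL g/L (divided by 10 to the formula's g/dL).
#' @return the NFS value (vectorized).
#' @export
compute_nfs <- function(age, bmi, t2dm_or_ifg, ast, alt, platelets, albumin_gL) {
  check_positive(age = age, bmi = bmi, ast = ast, alt = alt,
                 platelets = platelets, albumin_gL = albumin_gL)
  if (anyNA(t2dm_or_ifg)) stopf("missing field: t2dm_or_ifg")
  -1.675 + 0.037 * age + 0.094 * bmi + 1.13 * as.numeric(t2dm_or_ifg) +
    0.99 * (ast / alt) - 0.013 * platelets - 0.66 * (albumin_gL / 10)
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (length(x) == 0L || anyNA(x)) stopf("missing field: %s", nm)
    if (!is.numeric(x) || any(x <= 0)) stopf("%s must be positive", nm)
  }
  invisible(TRUE)
}

#' Decision thresholds of the two classifications
#'
#' Fixed defaults: Agile3+ rule-out/rule-in 0.451 / 0.679, Agile4 rule-in
#' 0.474; FibroMeterV3G 0.31 / 0.76, CirrhoMeterV3G rule-in 0.40. The
#' boundary conventions are honoured literally: group boundaries use
#' ">= 0.679", "> 0.474", "> 0.76" and "> 0.40". Rule-out/rule-in cutoffs for
#' FIB4, NFS and VCTE have no published defaults here and must be supplied
#' when needed (e.g. by [easl_pathway()]).
#'
#' @param ... named overrides of the defaults.
#' @return a named list of cutoffs.
#' @export
default_thresholds <- function(...) {
  th <- list(agile3p_low = 0.451, agile3p_high = 0.679, agile4_high = 0.474,
             fm_low = 0.31, fm_high = 0.76, cm_high = 0.40)
  over <- list(...)
  bad <- setdiff(names(over), names(th))
  if (length(bad)) stopf("unknown threshold(s): %s", paste(bad, collapse = ", "))
  th <- modifyList(th, over)
  if (th$agile3p_low >= th$agile3p_high) stopf("agile3p_low must be < agile3p_high")
  if (th$fm_low >= th$fm_high) stopf("fm_low must be < fm_high")
  th
}

#' Assemble the non-invasive score panel for one patient record
#'
#' Collects the seven test results from a record (a one-row data frame or
#' named list). Scores already present are taken as supplied; under policy
#' `"compute_where_possible"` FIB4 and NFS are computed from raw labs when
#' absent. The patented scores (FibroMeterV3G, CirrhoMeterV3G) and the Agile
#' scores are externally computed tests and are never derived from labs here:
#' if absent they are reported missing. Nothing is silently imputed.
#'
#' @param record one-row data frame or named list with any of the score
#'   columns (`fib4`, `nfs`, `fmv3g`, `cmv3g`, `vcte_kpa`, `agile3p`,
#'   `agile4`) and/or raw labs (`age`, `bmi`, `t2dm`, `ast`, `alt`,
#'   `platelets`, `albumin`).
#' @param policy `"require_precomputed"` or `"compute_where_possible"`.
#' @return a list of class `score_panel`: the seven scores (NA when missing)
#'   plus a `provenance` character vector (`"supplied"`, `"computed"`, or
#'   `"missing: <reason>"` per test).
#' @export
assemble_panel <- function(record,
                           policy = c("require_precomputed",
                                      "compute_where_possible")) {
  policy <- match.arg(policy)
  rec <- as.list(record)
  get1 <- function(nm) {
    v <- rec[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v)) NA_real_ else as.numeric(v)
  }
  score_cols <- c(fib4 = "fib4", nfs = "nfs", fmv3g = "fmv3g", cmv3g = "cmv3g",
                  vcte = "vcte_kpa", agile3p = "agile3p", agile4 = "agile4")
  panel <- lapply(score_cols, get1)
  prov <- ifelse(is.na(unlist(panel)), "missing: not supplied", "supplied")
  names(prov) <- names(score_cols)

  if (policy == "compute_where_possible") {
    need <- function(nms) nms[vapply(nms, function(n) is.na(get1(n)), logical(1))]
    if (is.na(panel$fib4)) {
      miss <- need(c("age", "ast", "alt", "platelets"))
      if (length(miss) == 0L) {
        panel$fib4 <- compute_fib4(get1("age"), get1("ast"), get1("alt"),
                                   get1("platelets"))
        prov["fib4"] <- "computed"
      } else {
        prov["fib4"] <- paste0("missing: labs absent (",
                               paste(miss, collapse = ", "), ")")
      }
    }
    if (is.na(panel$nfs)) {
      miss <- need(c("age", "bmi", "ast", "alt", "platelets", "albumin"))
      t2dm <- rec[["t2dm"]]
      if (is.null(t2dm) || is.na(t2dm)) miss <- c(miss, "t2dm")
      if (length(miss) == 0L) {
        panel$nfs <- compute_nfs(get1("age"), get1("bmi"), isTRUE(as.logical(t2dm)),
                                 get1("ast"), get1("alt"), get1("platelets"),
                                 get1("albumin"))
        prov["nfs"] <- "computed"
      } else {
        prov["nfs"] <- paste0("missing: labs absent (",
                              paste(miss, collapse = ", "), ")")
      }
    }
    for (t in c("fmv3g", "cmv3g", "agile3p", "agile4", "vcte")) {
      if (is.na(panel[[t]])) {
        prov[t] <- "missing: externally computed test not supplied"
      }
    }
  }

  for (t in .fib_unit_tests) {
    if (!is.na(panel[[t]]) && (panel[[t]] < 0 || panel[[t]] > 1)) {
      stopf("%s must lie in [0, 1]", t)
    }
  }
  if (!is.na(panel$vcte) && (panel$vcte < 1.5 || panel$vcte > 75)) {
    stopf("vcte_kpa must lie in [1.5, 75]")
  }

  structure(c(panel, list(provenance = prov)), class = "score_panel")
}

#' @export
print.score_panel <- function(x, ...) {
  cat("<score_panel>\n")
  for (t in names(x$provenance)) {
    cat(sprintf("  %-8s %-10s (%s)\n", t,
                ifelse(is.na(x[[t]]), "NA", format(x[[t]], digits = 4)),
                x$provenance[t]))
  }
  invisible(x)
}
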