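#' Classify therapy response from clinical fields
#'
#' A patient is a nonresponder when they still had seizures under adequate
#' medication, or became seizure-free only after an additional drug was
#' added to the initial one. A patient whose drug was merely substituted
#' because of adverse effects (flagged via `aed_substituted`) remains a
#' responder. The group label is always derived by this rule, never
#' hand-set in pipeline runs.
#'
#' @param records A data.frame of patient records with columns
#'   `seizure_free` (logical or "Y"/"N") and `aeds_added` (drug name, or
#'   "N"/""/NA for none); optional `aed_substituted` (logical). A single
#'   record may be given as a named list.
#' @return Factor with levels `responder`, `nonresponder` (length = number
#'   of records).
#' @examples
#' classify_response(data.frame(seizure_free = "Y", aeds_added = "N"))
#' @export
classify_response <- function(records) {
  if (!is.data.frame(records)) records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (field in c("seizure_free", "aeds_added")) {
    if (is.null(records[[field]]) || anyNA(records[[field]]) && field == "seizure_free")
      stop_config("classify_response: missing required field '%s'", field)
  }
  free <- as_yesno(records$seizure_free, "seizure_free")
  added <- !(is.na(records$aeds_added) | records$aeds_added %in% c("N", "", "none", "None"))
  substituted <- if (is.null(records$aed_substituted)) rep(FALSE, nrow(records))
                 else as_yesno(records$aed_substituted, "aed_substituted")
  nonresp <- (!free) | (added & !substituted)
  factor(ifelse(nonresp, "nonresponder", "responder"),
         levels = c("responder", "nonresponder"))
}

as_yesno <- function(x, field) {
  if (is.logical(x)) return(x)
  up <- toupper(as.character(x))
  if (!all(up %in% c("Y", "N", "TRUE", "FALSE")))
    stop_config("field '%s' must be logical or Y/N", field)
  up %in% c("Y", "TRUE")
}

#' Read the clinical cohort table
#'
#' Reads a TSV of per-patient clinical characteristics (the packaged
#' fixture transcribes the study cohort: 24 children, columns patient,
#' gender, age, onset age, seizure duration, follow-up, initial AED, AEDs
#' added, seizure-free flag, and the reported group used for
#' cross-checking the classification rule).
#'
#' @param path TSV path; defaults to the packaged cohort table.
#' @return A data.frame with a derived `group` column (from
#'   [classify_response()]).
#' @export
read_patient_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cae_cohort_table.tsv", package = "ictalmeg",
                        mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient", "gender", "age", "onset_age", "seizure_duration_s",
            "follow_up_months", "initial_aed", "aeds_added", "seizure_free")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_config("patient table %s lacks column(s): %s", path,
                paste(miss, collapse = ", "))
  if (any(df$onset_age > df$age))
    stop_config("onset_age exceeds age for patient(s) %s",
                paste(df$patient[df$onset_age > df$age], collapse = ", "))
  df$group <- classify_response(df)
  df
}

#' Read the per-band localization count table
#'
#' Long-format TSV with columns `region`, `band`, `nonresponders`,
#' `responders` giving, for each frequency band, how many patients of each
#' group had their predominant source in each region. The packaged fixture
#' transcribes the study's count table verbatim (in some bands the column
#' sums exceed the group sizes because several regions could be credited
#' to one patient; the fixture is used as printed).
#'
#' @param path TSV path; defaults to the packaged table.
#' @return A data.frame.
#' @export
read_localization_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cae_localization_counts.tsv",
                        package = "ictalmeg", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("region", "band", "nonresponders", "responders")
  if (!all(need %in% names(df)))
    stop_config("localization table %s lacks required columns", path)
  if (any(df$nonresponders < 0 | df$responders < 0))
    stop_config("localization counts must be nonnegative")
  df
}

#' Build a 2x2 region-by-group contingency table
#'
#' Rows are the groups (nonresponder, responder), columns count patients
#' whose predominant source was inside vs outside the region:
#' `a` = nonresponders in the region, `b` = nonresponders elsewhere,
#' `c`/`d` likewise for responders.
#'
#' `build_contingency()` works from per-patient labels;
#' `contingency_from_counts()` from tabulated counts and group sizes (the
#' route used with the printed count table).
#'
#' @param group Factor/character per patient (`responder`/`nonresponder`).
#' @param observed_region Character per patient: predominant region label
#'   for the band under test (NA excluded with a warning).
#' @param region The region label being tested.
#' @param band Optional band name recorded with the table.
#' @return A 2x2 integer matrix of class `contingency_table` with
#'   attributes `band` and `region`.
#' @export
build_contingency <- function(group, observed_region, region, band = NULL) {
  group <- as.character(group)
  if (!all(group %in% c("responder", "nonresponder")))
    stop_config("group labels must be responder/nonresponder")
  if (length(group) != length(observed_region))
    stop_config("group and observed_region lengths differ")
  drop <- is.na(observed_region)
  if (any(drop)) {
    warning(sprintf("dropping %d patient(s) without a predominant region", sum(drop)))
    group <- group[!drop]; observed_region <- observed_region[!drop]
  }
  if (!all(c("responder", "nonresponder") %in% group))
    stop_config("both groups must be present to build a contingency table")
  a <- sum(group == "nonresponder" & observed_region == region)
  n_n <- sum(group == "nonresponder")
  c_ <- sum(group == "responder" & observed_region == region)
  n_r <- sum(group == "responder")
  contingency_from_counts(a, n_n, c_, n_r, region = region, band = band)
}

#' @rdname build_contingency
#' @param n_region_nonresp,n_nonresp Nonresponders in the region / total.
#' @param n_region_resp,n_resp Responders in the region / total.
#' @export
contingency_from_counts <- function(n_region_nonresp, n_nonresp,
                                    n_region_resp, n_resp,
                                    region = NULL, band = NULL) {
  counts <- c(n_region_nonresp, n_nonresp, n_region_resp, n_resp)
  if (any(counts < 0) || n_region_nonresp > n_nonresp || n_region_resp > n_resp)
    stop_config("invalid contingency counts")
  m <- matrix(as.integer(c(n_region_nonresp, n_nonresp - n_region_nonresp,
                           n_region_resp, n_resp - n_region_resp)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(group = c("nonresponder", "responder"),
                              region = c("in_region", "elsewhere")))
  structure(m, class = c("contingency_table", "matrix"),
            band = band, region = region)
}

#' Two-sided Fisher exact test of a 2x2 table
#'
#' The two-sided p value sums the hypergeometric probabilities of all
#' margin-fixed tables whose probability does not exceed that of the
#' observed table (with a relative slack of 1e-7 for floating-point ties),
#' i.e. the classical exact test as implemented by [stats::fisher.test()].
#'
#' @param table A [contingency_from_counts()] result or any 2x2 count
#'   matrix.
#' @return The two-sided p value.
#' @export
fisher_exact <- function(table) {
  m <- unclass(table)
  if (!is.matrix(m) || !all(dim(m) == 2L)) stop_config("a 2x2 table is required")
  if (all(m == 0)) stop_config("all-zero table: the test is undefined")
  if (all(rowSums(m) == 0) || all(colSums(m) == 0))
    stop_config("degenerate margins: the test is undefined")
  stats::fisher.test(m)$p.value
}

#' Bonferroni gate across frequency bands
#'
#' Flags p values significant at `alpha / n_tests`; with the study's six
#' bands and alpha 0.05 the threshold is 0.05/6 = 0.00833... (printed as
#' 0.0083).
#'
#' @param p_values Numeric (possibly named) vector of p values.
#' @param n_tests Number of tests corrected for (default 6 bands).
#' @param alpha Family-wise level (default 0.05).
#' @return List with `threshold` and logical `significant` (same names as
#'   `p_values`).
#' @export
bonferroni_gate <- function(p_values, n_tests = 6L, alpha = 0.05) {
  if (!is_number(n_tests) || n_tests < 1) stop_config("n_tests must be >= 1")
  threshold <- alpha / n_tests
  list(threshold = threshold, significant = p_values < threshold)
}

#' Clinical cohort summary with between-group t tests
#'
#' Mean and (n-1) standard deviation of each clinical covariate overall
#' and per response group, with equal-variance two-sample two-tailed
#' Student t tests between groups. Groups with fewer than two patients
#' skip the t test with a warning.
#'
#' @param records A patient data.frame (see [read_patient_table()]); the
#'   `group` column is derived via [classify_response()] when absent.
#' @param covariates Columns to summarize.
#' @return Object of class `clinical_summary`: a data.frame with one row
#'   per covariate (`mean`, `sd`, per-group means/sds, `t`, `df`, `p`).
#' @export
clinical_summary <- function(records,
                             covariates = c("age", "onset_age",
                                            "seizure_duration_s",
                                            "follow_up_months")) {
  if (is.null(records$group)) records$group <- classify_response(records)
  g <- as.character(records$group)
  rows <- lapply(covariates, function(cv) {
    x <- records[[cv]]
    if (is.null(x)) stop_config("covariate '%s' not found", cv)
    xr <- x[g == "responder"]; xn <- x[g == "nonresponder"]
    tt <- if (length(xr) >= 2L && length(xn) >= 2L) {
      ht <- t.test(xr, xn, var.equal = TRUE)
      c(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
    } else {
      warning(sprintf("covariate '%s': a group has fewer than 2 patients; t test skipped", cv))
      c(t = NA_real_, df = NA_real_, p = NA_real_)
    }
    data.frame(covariate = cv, n = length(x), mean = mean(x), sd = sd(x),
               mean_responder = mean(xr), sd_responder = sd(xr),
               mean_nonresponder = mean(xn), sd_nonresponder = sd(xn),
               t = tt[["t"]], df = tt[["df"]], p = tt[["p"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("clinical_summary", "data.frame"))
}

#' @export
print.clinical_summary <- function(x, digits = 2, ...) {
  cat("Clinical summary (mean +/- SD; equal-variance two-tailed t tests)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-20s %.2f +/- %.2f  (R: %.2f +/- %.2f, N: %.2f +/- %.2f)  t=%.2f p=%.3f\n",
                x$covariate[i], x$mean[i], x$sd[i],
                x$mean_responder[i], x$sd_responder[i],
                x$mean_nonresponder[i], x$sd_nonresponder[i], x$t[i], x$p[i]))
  }
  invisible(x)
}
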