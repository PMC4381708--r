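#' Signed per-patient fold change
#'
#' Ratio of tumor to adjacent-normal signal with the signed convention used
#' throughout the package: ratios of at least 1 are reported as-is, ratios
#' below 1 as the negative reciprocal, so the magnitude is always >= 1 and the
#' sign carries the direction (positive = higher in tumor). A ratio of exactly
#' 1 is `+1`.
#'
#' @param tumor,normal positive signal intensities (vectorized).
#' @return signed fold change(s) with `|fc| >= 1`.
#' @examples
#' patient_fold_change(200, 100)  #  2
#' patient_fold_change(100, 200)  # -2
#' @export
patient_fold_change <- function(tumor, normal) {
  if (any(!is.finite(tumor)) || any(!is.finite(normal)) ||
      any(tumor <= 0) || any(normal <= 0))
    stop("signals must be positive to form a fold change")
  r <- tumor / normal
  ifelse(r >= 1, r, -1 / r)
}

#' Natural log of a signed fold change
#'
#' Maps the signed convention onto an additive scale: `ln(fc)` for positive
#' fold changes, `ln(1/|fc|) = -ln(|fc|)` for negative ones, so a fold change
#' of `-2` becomes `-ln 2` and `+1` becomes `0`.
#'
#' @param fc signed fold change(s), `|fc| >= 1` (or any nonzero ratio).
#' @return log fold change(s).
#' @export
ln_fold <- function(fc) {
  if (any(!is.finite(fc)) || any(fc == 0))
    stop("fold change must be finite and nonzero")
  sign(fc) * log(abs(fc))
}

#' Detection-call filter for a paired gene row
#'
#' A patient contributes to a gene's average only if it has usable data: the
#' pair is excluded when **both** its tumor and normal calls are Absent. If
#' that rule excludes every patient, the gene is still summarized from all
#' pairs but flagged `all_absent` so downstream reliability is set to `FALSE`.
#' A `strict` mode excluding a pair when *either* call is Absent is available
#' but off by default. Tables without calls include everyone.
#'
#' @param tumor_calls,normal_calls character vectors of per-patient calls
#'   (`P`/`M`/`A`), or `NULL` when the data carry no calls.
#' @param strict exclude a pair if either call is Absent.
#' @return list with `included` (logical vector) and `all_absent` (flag).
#' @export
call_filter <- function(tumor_calls, normal_calls, strict = FALSE) {
  if (is.null(tumor_calls) || is.null(normal_calls)) {
    n <- max(length(tumor_calls), length(normal_calls))
    return(list(included = rep(TRUE, n), all_absent = FALSE))
  }
  stopifnot(length(tumor_calls) == length(normal_calls))
  excluded <- if (strict) tumor_calls == "A" | normal_calls == "A"
              else            tumor_calls == "A" & normal_calls == "A"
  if (all(excluded))
    list(included = rep(TRUE, length(excluded)), all_absent = TRUE)
  else
    list(included = !excluded, all_absent = FALSE)
}

#' Sign-aware average of signed fold changes
#'
#' If every fold change is positive the plain arithmetic mean is returned.
#' As soon as one value is negative the row is averaged on the log scale:
#' negative values are converted to their positive reciprocals, the mean of
#' the `ln` values is exponentiated, and a sub-unity result is re-expressed as
#' a negative reciprocal so the output keeps the signed convention.
#'
#' @param fcs non-empty numeric vector of signed fold changes.
#' @return the average signed fold change.
#' @examples
#' aggregate_fold_change(c(2, 4))        # 3 (arithmetic branch)
#' aggregate_fold_change(c(-2, -8))      # -4 (geometric branch)
#' @export
aggregate_fold_change <- function(fcs) {
  if (length(fcs) == 0) stop("cannot average an empty fold-change vector")
  if (any(!is.finite(fcs)) || any(fcs == 0))
    stop("fold changes must be finite and nonzero")
  if (all(fcs > 0)) return(mean(fcs))
  m <- exp(mean(log(ifelse(fcs < 0, 1 / abs(fcs), fcs))))
  if (m < 1) -1 / m else m
}

#' One-sample t-test on log fold changes
#'
#' Two-tailed one-sample t-test of the [ln_fold()] values against mean zero:
#' `t = mean / (sd / sqrt(n))` on `n - 1` degrees of freedom. Degenerate
#' inputs do not error: with fewer than two values or zero variance the
#' p-value is `NA` and the reason is flagged.
#'
#' @param fcs signed fold changes for the included patients.
#' @return list with `p_value`, `t`, `df`, `n` and `flag`
#'   (`"ok"`, `"n_too_small"` or `"zero_variance"`).
#' @export
t_test_ln_fc <- function(fcs) {
  lf <- ln_fold(fcs)
  n <- length(lf)
  if (n < 2)
    return(list(p_value = NA_real_, t = NA_real_, df = NA_real_, n = n,
                flag = "n_too_small"))
  if (stats::sd(lf) == 0)
    return(list(p_value = NA_real_, t = NA_real_, df = n - 1, n = n,
                flag = "zero_variance"))
  ht <- stats::t.test(lf, mu = 0)
  list(p_value = ht$p.value, t = unname(ht$statistic),
       df = unname(ht$parameter), n = n, flag = "ok")
}

#' Summarize one gene from its per-patient fold changes
#'
#' Combines [aggregate_fold_change()] and [t_test_ln_fc()] and classifies the
#' gene by the strict two-fold rule: `over` if the average exceeds 2, `under`
#' if it is below -2, otherwise `unchanged` (an average of exactly 2 is
#' unchanged). Significance is `p < alpha`, with no multiple-testing
#' correction. A gene summarized from an all-Absent row keeps its numbers but
#' is flagged `reliable = FALSE`.
#'
#' @param gene gene symbol.
#' @param fcs signed fold changes of the included patients.
#' @param all_absent was the row re-included because every pair was Absent?
#' @param fc_threshold magnitude a gene must exceed to be called DE.
#' @param alpha significance level.
#' @return one-row data frame: `gene`, `avg_fc`, `n_used`, `p_value`, `t`,
#'   `df`, `reliable`, `de_class`, `significant`, `flag`.
#' @export
summarize_gene <- function(gene, fcs, all_absent = FALSE,
                           fc_threshold = 2, alpha = 0.05) {
  avg <- aggregate_fold_change(fcs)
  tt <- t_test_ln_fc(fcs)
  de <- if (avg > fc_threshold) "over"
        else if (avg < -fc_threshold) "under"
        else "unchanged"
  data.frame(gene = gene, avg_fc = avg, n_used = length(fcs),
             p_value = tt$p_value, t = tt$t, df = tt$df,
             reliable = !all_absent, de_class = de,
             significant = !is.na(tt$p_value) && tt$p_value < alpha,
             flag = tt$flag, stringsAsFactors = FALSE)
}
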