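#' Fit paired tumor/normal differential expression
#'
#' The central fitting function of the package. For every gene (row of a
#' gene-level expression table) and every patient of the pairing it forms the
#' signed tumor/normal fold change ([patient_fold_change()]), drops patient
#' pairs whose tumor *and* normal detection calls are Absent
#' ([call_filter()]), averages the remaining fold changes with the sign-aware
#' rule ([aggregate_fold_change()]), tests the log fold changes against zero
#' with a two-tailed one-sample t-test ([t_test_ln_fc()]) and classifies each
#' gene as over-expressed, under-expressed or unchanged by the strict
#' `|avg FC| > fc_threshold` rule. No multiple-testing correction is applied
#' to the significance column; a Benjamini-Hochberg FDR is reported alongside
#' for reference but never drives the classification.
#'
#' @param table gene-level [expression_table()] (e.g. from
#'   [collapse_to_genes()]); all signals must be strictly positive.
#' @param pairing a [sample_pairing()] whose samples exist in `table`.
#' @param strict_calls exclude a pair when either call is Absent (default
#'   `FALSE`: both must be Absent).
#' @param fc_threshold fold-change magnitude for the DE call (default 2).
#' @param alpha significance level (default 0.05).
#' @return An object of class `warburg_de`; see Details.
#' @details The returned object is a list with components
#' \describe{
#'   \item{fc}{genes x patients matrix of signed fold changes (all pairs,
#'     including excluded ones).}
#'   \item{included}{logical matrix of the same shape; `FALSE` marks pairs
#'     excluded by the Absent/Absent rule.}
#'   \item{summary}{per-gene data frame: `avg_fc`, `n_used`, `p_value`, `t`,
#'     `df`, `fdr`, `reliable`, `de_class`, `significant`, `flag`.}
#'   \item{pairing, options}{inputs as supplied.}
#' }
#' @seealso [warburg_de_fc()] to enter the pipeline at the fold-change stage,
#'   and the methods [summary.warburg_de()], [coef.warburg_de()],
#'   [plot.warburg_de()], [residuals.warburg_de()], [simulate.warburg_de()].
#' @export
warburg_de <- function(table, pairing, strict_calls = FALSE,
                       fc_threshold = 2, alpha = 0.05) {
  stopifnot(inherits(table, "expr_table"))
  validate_pairing(pairing, table)
  if (nrow(pairing) == 0) stop("pairing contains no patients")
  if (any(table$signal <= 0))
    stop("gene-level signals must be strictly positive to form fold changes")
  genes <- table$probe_ids
  pats <- pairing$patient
  tum <- table$signal[, pairing$tumor, drop = FALSE]
  nor <- table$signal[, pairing$normal, drop = FALSE]
  fc <- matrix(patient_fold_change(tum, nor), nrow = length(genes),
               dimnames = list(genes, pats))
  included <- matrix(TRUE, length(genes), length(pats),
                     dimnames = list(genes, pats))
  all_absent <- setNames(rep(FALSE, length(genes)), genes)
  if (has_calls(table)) {
    tc <- table$calls[, pairing$tumor, drop = FALSE]
    nc <- table$calls[, pairing$normal, drop = FALSE]
    for (g in genes) {
      cf <- call_filter(tc[g, ], nc[g, ], strict = strict_calls)
      included[g, ] <- cf$included
      all_absent[g] <- cf$all_absent
    }
  }
  sm <- do.call(rbind, lapply(genes, function(g)
    summarize_gene(g, fc[g, included[g, ]], all_absent = all_absent[g],
                   fc_threshold = fc_threshold, alpha = alpha)))
  sm$fdr <- stats::p.adjust(sm$p_value, method = "BH")
  rownames(sm) <- NULL
  structure(list(fc = fc, included = included, summary = sm, pairing = pairing,
                 options = list(strict_calls = strict_calls,
                                fc_threshold = fc_threshold, alpha = alpha)),
            class = "warburg_de")
}

#' Fit from a precomputed fold-change matrix
#'
#' Entry point for data whose verifiable numbers start at the per-patient
#' fold-change stage (published tables print signed fold changes, not raw
#' intensities). `NA` entries mark patient pairs without a ratio (the
#' "A/A" sentinel of the published tables); `exclude` removes further
#' patient values per footnote-style instructions.
#'
#' @param fc genes x patients numeric matrix of signed fold changes, `NA`
#'   for pairs excluded at source.
#' @param exclude optional named list: gene -> character vector of patient
#'   columns to drop in addition to the `NA`s.
#' @param all_absent character vector of genes whose rows were computed from
#'   all-Absent calls (flagged unreliable).
#' @param fc_threshold,alpha as in [warburg_de()].
#' @return A `warburg_de` object (its `fc` matrix keeps the `NA`s).
#' @export
warburg_de_fc <- function(fc, exclude = list(), all_absent = character(),
                          fc_threshold = 2, alpha = 0.05) {
  stopifnot(is.matrix(fc), !is.null(rownames(fc)), !is.null(colnames(fc)))
  genes <- rownames(fc)
  included <- !is.na(fc)
  for (g in names(exclude))
    included[g, exclude[[g]]] <- FALSE
  sm <- do.call(rbind, lapply(genes, function(g) {
    v <- fc[g, included[g, ]]
    summarize_gene(g, v, all_absent = g %in% all_absent,
                   fc_threshold = fc_threshold, alpha = alpha)
  }))
  sm$fdr <- stats::p.adjust(sm$p_value, method = "BH")
  rownames(sm) <- NULL
  structure(list(fc = fc, included = included, summary = sm, pairing = NULL,
                 options = list(strict_calls = FALSE,
                                fc_threshold = fc_threshold, alpha = alpha)),
            class = "warburg_de")
}

#' @export
print.warburg_de <- function(x, ...) {
  sm <- x$summary
  cat(sprintf("Paired tumor/normal differential expression: %d genes, %d patients\n",
              nrow(sm), ncol(x$fc)))
  cat(sprintf("DE rule |avg FC| > %g, alpha = %g (uncorrected)\n",
              x$options$fc_threshold, x$options$alpha))
  tab <- table(factor(sm$de_class, levels = c("over", "under", "unchanged")))
  cat(sprintf("  over-expressed: %d   under-expressed: %d   unchanged: %d\n",
              tab["over"], tab["under"], tab["unchanged"]))
  if (any(!sm$reliable))
    cat(sprintf("  %d gene(s) flagged unreliable (all calls Absent)\n",
                sum(!sm$reliable)))
  invisible(x)
}

#' Summarize a fitted differential-expression object
#'
#' @param object a `warburg_de` fit.
#' @param ... unused.
#' @return the per-gene summary data frame, ordered by descending
#'   fold-change magnitude, with class `summary.warburg_de` for printing.
#' @export
summary.warburg_de <- function(object, ...) {
  sm <- object$summary
  sm <- sm[order(-abs(sm$avg_fc)), ]
  rownames(sm) <- NULL
  class(sm) <- c("summary.warburg_de", "data.frame")
  sm
}

#' @export
print.summary.warburg_de <- function(x, ...) {
  df <- as.data.frame(x)
  df$avg_fc <- round(df$avg_fc, 2)
  df$p_value <- signif(df$p_value, 3)
  df$fdr <- signif(df$fdr, 3)
  print(df[, c("gene", "avg_fc", "n_used", "p_value", "fdr",
               "reliable", "de_class", "significant")], row.names = FALSE)
  invisible(x)
}

#' Average fold changes of a fit
#'
#' @param object a `warburg_de` fit.
#' @param ... unused.
#' @return named vector of average signed fold changes.
#' @export
coef.warburg_de <- function(object, ...) {
  setNames(object$summary$avg_fc, object$summary$gene)
}

#' Per-patient residual log fold changes
#'
#' Residuals on the log scale: each included patient's `ln` fold change minus
#' the gene's mean `ln` fold change. Excluded pairs are `NA`.
#'
#' @param object a `warburg_de` fit.
#' @param ... unused.
#' @return genes x patients matrix of residuals.
#' @export
residuals.warburg_de <- function(object, ...) {
  lf <- matrix(NA_real_, nrow(object$fc), ncol(object$fc),
               dimnames = dimnames(object$fc))
  ok <- object$included & !is.na(object$fc)
  lf[ok] <- ln_fold(object$fc[ok])
  sweep(lf, 1, rowMeans(lf, na.rm = TRUE))
}

#' Volcano plot of a fit
#'
#' Log2 average fold change against -log10 p, with the DE threshold and the
#' significance level drawn as reference lines.
#'
#' @param x a `warburg_de` fit.
#' @param ... further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.warburg_de <- function(x, ...) {
  sm <- x$summary
  lfc <- sign(sm$avg_fc) * log2(abs(sm$avg_fc))
  lp <- -log10(sm$p_value)
  col <- ifelse(sm$de_class == "over", "firebrick",
         ifelse(sm$de_class == "under", "steelblue", "grey40"))
  graphics::plot(lfc, lp, pch = 19, col = col,
                 xlab = "log2 average fold change (signed)",
                 ylab = "-log10 p", ...)
  graphics::abline(v = c(-1, 1) * log2(x$options$fc_threshold), lty = 2)
  graphics::abline(h = -log10(x$options$alpha), lty = 3)
  invisible(x)
}

#' Simulate fold-change matrices from a fit
#'
#' Parametric resampling: for each gene the included patients' log fold
#' changes define a normal distribution (their mean and standard deviation);
#' new per-patient signed fold changes are drawn from it, keeping the
#' exclusion pattern of the fit.
#'
#' @param object a `warburg_de` fit.
#' @param nsim number of simulated matrices.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of `nsim` fold-change matrices shaped like `object$fc`.
#' @export
simulate.warburg_de <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lf <- matrix(NA_real_, nrow(object$fc), ncol(object$fc),
               dimnames = dimnames(object$fc))
  ok <- object$included & !is.na(object$fc)
  lf[ok] <- ln_fold(object$fc[ok])
  mu <- rowMeans(lf, na.rm = TRUE)
  sdv <- apply(lf, 1, stats::sd, na.rm = TRUE)
  sdv[is.na(sdv)] <- 0
  lapply(seq_len(nsim), function(i) {
    sim <- lf
    for (g in seq_len(nrow(lf))) {
      idx <- which(ok[g, ])
      draw <- stats::rnorm(length(idx), mu[g], sdv[g])
      sim[g, idx] <- ifelse(draw >= 0, exp(draw), -exp(-draw))
    }
    sim
  })
}

#' Write per-gene results in the published-table shape
#'
#' One row per gene: per-patient signed fold changes (excluded pairs printed
#' as the `A/A` sentinel), average fold change, patients used, p-value,
#' reliability and DE class.
#'
#' @param object a `warburg_de` fit.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(object, path) {
  stopifnot(inherits(object, "warburg_de"))
  fcch <- matrix(sprintf("%.2f", object$fc), nrow = nrow(object$fc),
                 dimnames = dimnames(object$fc))
  fcch[!object$included | is.na(object$fc)] <- "A/A"
  sm <- object$summary
  out <- data.frame(gene = sm$gene, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(fcch[sm$gene, , drop = FALSE]))
  out$avg_fc <- sprintf("%.2f", sm$avg_fc)
  out$n_used <- sm$n_used
  out$p_value <- sprintf("%.2E", sm$p_value)
  out$reliable <- sm$reliable
  out$de_class <- sm$de_class
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
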