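#' Score a probe set for representative-probe selection
#'
#' Computes the quantities the selection criteria rank on: the fraction of
#' samples with a Present call (a probe set is `reliable` when at least half
#' of all samples call it Present), the suffix rank (`_at` designs rank above
#' `_s_at`, which rank above `_x_at`; anything else last) and the mean signal
#' intensity across all samples.
#'
#' @param probe_id probe-set identifier, must exist in `table`.
#' @param table an [expression_table()].
#' @param count_marginal should Marginal calls count toward the Present
#'   fraction? Default `FALSE`: only literal `P` calls count.
#' @return list with elements `probe_id`, `reliable` (`NA` when the table has
#'   no calls), `present_fraction`, `suffix_class`, `suffix_rank`
#'   (`AT` = 0 ... `OTHER` = 3) and `mean_intensity`.
#' @export
score_probe <- function(probe_id, table, count_marginal = FALSE) {
  stopifnot(inherits(table, "expr_table"))
  if (!probe_id %in% table$probe_ids)
    stop("probe set not in table: ", probe_id)
  ok_codes <- if (count_marginal) c("P", "M") else "P"
  if (has_calls(table)) {
    frac <- mean(table$calls[probe_id, ] %in% ok_codes)
    reliable <- frac >= 0.5
  } else {
    frac <- NA_real_
    reliable <- NA
  }
  cls <- probe_suffix_class(probe_id)
  list(probe_id = probe_id,
       reliable = reliable,
       present_fraction = frac,
       suffix_class = as.character(cls),
       suffix_rank = as.integer(cls) - 1L,
       mean_intensity = mean(table$signal[probe_id, ]))
}

#' Select the representative probe set for a gene
#'
#' When several probe sets interrogate one gene a single representative is
#' chosen. In `mode = "calls"` candidates are ranked lexicographically:
#' reliable before unreliable (at least 50\% Present calls), then by suffix
#' (`_at` before `_s_at` before `_x_at` before anything else), then by higher
#' mean intensity across all samples. In `mode = "intensity_only"` (for
#' tables shipped without detection calls) only the mean intensity is
#' maximized. Any remaining tie is broken deterministically by the smallest
#' probe identifier, so the choice is invariant to candidate order.
#'
#' @param candidates character vector of candidate probe-set identifiers.
#' @param table an [expression_table()].
#' @param mode `"calls"` or `"intensity_only"`. A call-free table forces
#'   `"intensity_only"`.
#' @param count_marginal passed to [score_probe()].
#' @return the selected probe identifier (length-1 character).
#' @export
select_representative <- function(candidates, table,
                                  mode = c("calls", "intensity_only"),
                                  count_marginal = FALSE) {
  mode <- match.arg(mode)
  if (length(candidates) == 0) stop("empty candidate probe set")
  if (length(candidates) == 1) return(candidates)
  if (mode == "calls" && !has_calls(table)) mode <- "intensity_only"
  scores <- lapply(candidates, score_probe, table = table,
                   count_marginal = count_marginal)
  mean_int <- vapply(scores, `[[`, numeric(1), "mean_intensity")
  if (mode == "calls") {
    rel <- vapply(scores, `[[`, logical(1), "reliable")
    rank <- vapply(scores, `[[`, integer(1), "suffix_rank")
    ord <- order(!rel, rank, -mean_int, candidates, method = "radix")
  } else {
    ord <- order(-mean_int, candidates, method = "radix")
  }
  candidates[ord[1]]
}

#' Collapse a probe-level table to one row per gene
#'
#' For every requested gene the representative probe set is selected with
#' [select_representative()] and its signal (and call) row becomes the gene
#' row. Genes with no annotated probe in the table are reported as unmapped,
#' never an error.
#'
#' @param table probe-level [expression_table()].
#' @param annotation data frame from [read_annotation()].
#' @param genes genes to collapse; default all genes in the annotation.
#' @param mode,count_marginal passed to [select_representative()].
#' @return list with elements `table` (gene-level `expr_table`), `report`
#'   (data frame: gene, chosen probe, reliability, suffix class, mean
#'   intensity, rejected candidates) and `unmapped` (character vector).
#' @export
collapse_to_genes <- function(table, annotation, genes = NULL,
                              mode = c("calls", "intensity_only"),
                              count_marginal = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "expr_table"))
  ann <- annotation[annotation$probe_id %in% table$probe_ids, , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(annotation$gene_symbol))
  by_gene <- split(ann$probe_id, ann$gene_symbol)
  unmapped <- setdiff(genes, names(by_gene))
  mapped <- setdiff(genes, unmapped)
  rows <- lapply(mapped, function(g) {
    chosen <- select_representative(by_gene[[g]], table, mode = mode,
                                    count_marginal = count_marginal)
    sc <- score_probe(chosen, table, count_marginal = count_marginal)
    data.frame(gene = g, probe_id = chosen,
               reliable = sc$reliable,
               suffix_class = sc$suffix_class,
               mean_intensity = sc$mean_intensity,
               n_candidates = length(by_gene[[g]]),
               rejected = paste(setdiff(by_gene[[g]], chosen), collapse = ","),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  if (is.null(report))
    report <- data.frame(gene = character(), probe_id = character(),
                         reliable = logical(), suffix_class = character(),
                         mean_intensity = numeric(), n_candidates = integer(),
                         rejected = character(), stringsAsFactors = FALSE)
  sig <- table$signal[report$probe_id, , drop = FALSE]
  rownames(sig) <- report$gene
  calls <- NULL
  if (has_calls(table)) {
    calls <- table$calls[report$probe_id, , drop = FALSE]
    rownames(calls) <- report$gene
  }
  gene_table <- if (nrow(sig)) expression_table(sig, calls) else NULL
  list(table = gene_table, report = report, unmapped = unmapped)
}

#' Write a probe-selection report
#'
#' @param report the `report` element of [collapse_to_genes()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
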