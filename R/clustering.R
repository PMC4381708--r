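#' Euclidean distances between samples
#'
#' Pairwise Euclidean distances between the sample columns of a gene-level
#' expression table, the input to hierarchical sample QC. Intensities are
#' clustered raw by default; a log2 pre-transform is available.
#'
#' @param table gene-level [expression_table()] with no missing values.
#' @param log2_transform apply `log2(x + 1)` before computing distances.
#' @return a [stats::dist] object over the samples.
#' @export
sample_distances <- function(table, log2_transform = FALSE) {
  stopifnot(inherits(table, "expr_table"))
  if (length(table$sample_ids) < 2) stop("need at least two samples")
  m <- t(table$signal)
  if (anyNA(m)) {
    idx <- which(is.na(table$signal), arr.ind = TRUE)[1, ]
    stop(sprintf("missing intensity for gene '%s', sample '%s'",
                 rownames(table$signal)[idx[1]], colnames(table$signal)[idx[2]]))
  }
  if (log2_transform) m <- log2(m + 1)
  stats::dist(m, method = "euclidean")
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering in which the distance between two clusters is the
#' unweighted mean over all cross-pair distances. Average linkage admits no
#' inversions, so merge heights are non-decreasing; this is asserted on every
#' run.
#'
#' @param d a [stats::dist] object (e.g. from [sample_distances()]).
#' @return an object of class `linkage_tree`: list with the underlying
#'   [stats::hclust] fit, a `merges` data frame (children, height, new size)
#'   and the sample `labels`.
#' @export
average_linkage <- function(d) {
  if (!inherits(d, "dist")) stop("`d` must be a dist object")
  n <- attr(d, "Size")
  if (is.null(n) || n < 2) stop("need at least two samples to cluster")
  hc <- stats::hclust(d, method = "average")
  if (any(diff(hc$height) < -1e-8))
    stop("internal error: average-linkage merge heights decreased")
  sizes <- integer(n - 1)
  csize <- function(i) if (i < 0) 1L else sizes[i]
  for (k in seq_len(n - 1))
    sizes[k] <- csize(hc$merge[k, 1]) + csize(hc$merge[k, 2])
  merges <- data.frame(a = hc$merge[, 1], b = hc$merge[, 2],
                       height = hc$height, size = sizes)
  structure(list(hclust = hc, merges = merges, labels = hc$labels),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("Average-linkage tree over %d samples (%d merges, max height %.4g)\n",
              length(x$labels), nrow(x$merges), max(x$merges$height)))
  invisible(x)
}

#' Newick serialization of a linkage tree
#'
#' @param tree a [average_linkage()] result.
#' @return single Newick string (with branch lengths).
#' @export
linkage_newick <- function(tree) {
  stopifnot(inherits(tree, "linkage_tree"))
  ape::write.tree(ape::as.phylo(tree$hclust))
}

#' Tumor/normal concordance of a two-cluster cut
#'
#' Operationalizes the visual dendrogram check used for sample QC: the tree is
#' cut into two clusters, the cluster holding the majority of tumor samples is
#' taken as the tumor group, and a patient is flagged *discordant* when its
#' tumor sample falls in the normal group or vice versa (the behaviour seen
#' when one patient's tissues track the opposite tissue of every other
#' patient). Discordant patients are recommended for exclusion. If the cut is
#' degenerate (all merge heights equal, e.g. identical samples) every sample
#' is reported indeterminate.
#'
#' @param tree a [average_linkage()] result over all tumor + normal samples.
#' @param pairing a [sample_pairing()].
#' @return list with `assignment` (data frame: sample, patient, tissue,
#'   cluster, expected cluster), `discordant` (patient labels) and
#'   `degenerate` flag.
#' @export
two_group_concordance <- function(tree, pairing) {
  stopifnot(inherits(tree, "linkage_tree"), inherits(pairing, "sample_pairing"))
  samples <- c(pairing$tumor, pairing$normal)
  if (!all(samples %in% tree$labels))
    stop("tree does not cover all paired samples")
  degenerate <- diff(range(tree$merges$height)) < 1e-12
  cl <- stats::cutree(tree$hclust, k = 2)
  tissue <- c(rep("tumor", nrow(pairing)), rep("normal", nrow(pairing)))
  patient <- rep(pairing$patient, 2)
  cluster <- unname(cl[samples])
  tumor_cluster <- as.integer(names(which.max(table(cluster[tissue == "tumor"]))))
  expected <- ifelse(tissue == "tumor", tumor_cluster,
                     if (tumor_cluster == 1L) 2L else 1L)
  assignment <- data.frame(sample = samples, patient = patient, tissue = tissue,
                           cluster = cluster, expected = expected,
                           concordant = cluster == expected,
                           stringsAsFactors = FALSE)
  if (degenerate) {
    assignment$concordant <- NA
    return(list(assignment = assignment, discordant = character(),
                degenerate = TRUE))
  }
  discordant <- sort(unique(assignment$patient[!assignment$concordant]))
  list(assignment = assignment, discordant = discordant, degenerate = FALSE)
}

#' Write clustering QC artefacts
#'
#' Writes the distance matrix, the merge table and the Newick dendrogram.
#'
#' @param d a [stats::dist] object.
#' @param tree the matching [average_linkage()] tree.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_clustering <- function(d, tree, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- as.matrix(d)
  p1 <- file.path(dir, "distance_matrix.tsv")
  utils::write.table(data.frame(sample = rownames(dm), dm, check.names = FALSE),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "merges.tsv")
  utils::write.table(tree$merges, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(dir, "dendrogram.nwk")
  writeLines(linkage_newick(tree), p3)
  invisible(c(p1, p2, p3))
}
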