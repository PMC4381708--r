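#' Pathway tag vocabulary of the extended Warburg network
#' @return character vector of the allowed pathway tags.
#' @export
pathway_tags <- function() c("glycolysis", "gluconeogenesis", "ppp", "tca",
                             "serine_glycine", "fructose", "glutaminolysis",
                             "fatty_acid_synthesis", "pkm_splicing",
                             "transporters", "pyruvate_metabolism")

#' Load the curated metabolic network
#'
#' The network covers glycolysis, gluconeogenesis, the pentose phosphate
#' pathway, the TCA cycle, serine/glycine synthesis, fructose utilization,
#' PKM alternative-splicing regulators, glutamine utilization and the initial
#' steps of fatty acid synthesis. It ships as two tab-delimited files: a node
#' table (`id`, `kind` gene|metabolite, `label`, `pathways` pipe-separated
#' tags) and an edge table (`source`, `target`, `relation` in
#' catalysis|conversion|transport|regulation|splicing_regulation). The
#' packaged default is a curated reconstruction of the published pathway
#' composition.
#'
#' @param nodes_path,edges_path paths to node and edge tables; defaults are
#'   the packaged network.
#' @return object of class `pathway_network`: list with data frames `nodes`
#'   and `edges`.
#' @export
load_network <- function(nodes_path = system.file("extdata",
                                                  "warburg_network_nodes.tsv",
                                                  package = "warburgDE"),
                         edges_path = system.file("extdata",
                                                  "warburg_network_edges.tsv",
                                                  package = "warburgDE")) {
  nodes <- utils::read.delim(nodes_path, colClasses = "character")
  edges <- utils::read.delim(edges_path, colClasses = "character")
  stopifnot(all(c("id", "kind", "label", "pathways") %in% names(nodes)),
            all(c("source", "target", "relation") %in% names(edges)))
  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (!all(nodes$kind %in% c("gene", "metabolite")))
    stop("node kind must be 'gene' or 'metabolite'")
  tags <- strsplit(nodes$pathways, "|", fixed = TRUE)
  bad_tags <- setdiff(unique(unlist(tags)), pathway_tags())
  if (length(bad_tags))
    stop("unknown pathway tag(s): ", paste(bad_tags, collapse = ", "))
  untagged <- nodes$id[nodes$kind == "gene" & !nzchar(nodes$pathways)]
  if (length(untagged))
    warning("gene node(s) without a pathway tag: ",
            paste(untagged, collapse = ", "))
  dangling <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(dangling))
    stop("edge endpoint(s) not in node table: ",
         paste(dangling, collapse = ", "))
  rel_ok <- c("catalysis", "conversion", "transport", "regulation",
              "splicing_regulation")
  if (!all(edges$relation %in% rel_ok))
    stop("unknown edge relation(s): ",
         paste(setdiff(edges$relation, rel_ok), collapse = ", "))
  structure(list(nodes = nodes, edges = edges), class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("Extended Warburg network: %d nodes (%d genes, %d metabolites), %d edges\n",
              nrow(x$nodes), sum(x$nodes$kind == "gene"),
              sum(x$nodes$kind == "metabolite"), nrow(x$edges)))
  invisible(x)
}

#' Gene symbols of a network
#' @param network a [load_network()] result.
#' @return character vector of gene-node identifiers (HGNC symbols).
#' @export
network_genes <- function(network) {
  network$nodes$id[network$nodes$kind == "gene"]
}

#' Overlay per-gene summaries onto the network
#'
#' Attaches differential-expression summaries to the network's gene nodes by
#' exact HGNC symbol match. The topology is never modified; network genes
#' without a summary are reported as unmapped, summaries for genes outside
#' the network as unused.
#'
#' @param network a [load_network()] result.
#' @param summaries per-gene data frame with at least `gene`, `avg_fc`,
#'   `n_used`, `p_value`, `reliable`, `de_class` (e.g. `fit$summary` of a
#'   [warburg_de()] fit).
#' @return object of class `overlay_result`: list with `network`,
#'   `gene_attributes` (data frame restricted and aligned to network genes),
#'   `unmapped_genes` and `unused_summaries`.
#' @export
overlay <- function(network, summaries) {
  stopifnot(inherits(network, "pathway_network"),
            is.data.frame(summaries), "gene" %in% names(summaries))
  genes <- network_genes(network)
  hit <- summaries$gene %in% genes
  attrs <- summaries[hit, , drop = FALSE]
  rownames(attrs) <- NULL
  structure(list(network = network,
                 gene_attributes = attrs,
                 unmapped_genes = setdiff(genes, summaries$gene),
                 unused_summaries = summaries$gene[!hit]),
            class = "overlay_result")
}

#' @export
print.overlay_result <- function(x, ...) {
  cat(sprintf("Network overlay: %d/%d gene nodes annotated (%d unmapped, %d unused summaries)\n",
              nrow(x$gene_attributes), length(network_genes(x$network)),
              length(x$unmapped_genes), length(x$unused_summaries)))
  invisible(x)
}

#' Per-pathway report in the published-table shape
#'
#' Partitions the annotated genes of one pathway into over-expressed,
#' under-expressed and unchanged sections (by `de_class`), each ordered by
#' descending fold-change magnitude with alphabetical tie-break.
#'
#' @param result an [overlay()] result.
#' @param pathway_tag one of [pathway_tags()].
#' @return data frame: the gene summaries plus a `section` column, ordered
#'   over / under / unchanged.
#' @export
pathway_report <- function(result, pathway_tag) {
  stopifnot(inherits(result, "overlay_result"))
  if (!pathway_tag %in% pathway_tags())
    stop("unknown pathway tag: ", pathway_tag)
  nodes <- result$network$nodes
  tags <- strsplit(nodes$pathways, "|", fixed = TRUE)
  in_path <- nodes$id[nodes$kind == "gene" &
                      vapply(tags, function(t) pathway_tag %in% t, logical(1))]
  rep <- result$gene_attributes[result$gene_attributes$gene %in% in_path, ,
                                drop = FALSE]
  rep$section <- rep$de_class
  ord <- order(match(rep$section, c("over", "under", "unchanged")),
               -abs(rep$avg_fc), rep$gene, method = "radix")
  rep <- rep[ord, , drop = FALSE]
  rownames(rep) <- NULL
  rep
}

#' Build an igraph representation of an overlay
#'
#' Node attributes: `kind`, `label`, `pathways`, plus `avg_fc`, `p_value`,
#' `de_class`, `reliable`, `n_used` on annotated gene nodes. Edge attribute:
#' `relation`.
#'
#' @param result an [overlay()] result (or a bare network via
#'   `overlay(network, empty_summaries)`).
#' @return an [igraph::graph] object.
#' @export
overlay_igraph <- function(result) {
  stopifnot(inherits(result, "overlay_result"))
  nodes <- result$network$nodes
  at <- result$gene_attributes
  idx <- match(nodes$id, at$gene)
  vdf <- data.frame(name = nodes$id, kind = nodes$kind, label = nodes$label,
                    pathways = nodes$pathways,
                    avg_fc = at$avg_fc[idx],
                    p_value = at$p_value[idx],
                    de_class = ifelse(is.na(idx), NA_character_,
                                      at$de_class[idx]),
                    reliable = at$reliable[idx],
                    n_used = at$n_used[idx],
                    stringsAsFactors = FALSE)
  edf <- result$network$edges
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

#' Export Cytoscape-compatible files
#'
#' Writes a SIF edge file (`source<TAB>relation<TAB>target` per line), a
#' node-attribute TSV (avg FC, p, DE class, reliability, n used) and a
#' GraphML file with the same attributes. Output is deterministic: identical
#' inputs yield byte-identical files.
#'
#' @param result an [overlay()] result.
#' @param out_dir output directory (created if needed).
#' @return invisibly, named character vector of the files written.
#' @export
export_cytoscape <- function(result, out_dir) {
  stopifnot(inherits(result, "overlay_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  e <- result$network$edges
  sif <- file.path(out_dir, "network.sif")
  writeLines(paste(e$source, e$relation, e$target, sep = "\t"), sif)
  nodes <- result$network$nodes
  at <- result$gene_attributes
  idx <- match(nodes$id, at$gene)
  attr_df <- data.frame(id = nodes$id, kind = nodes$kind,
                        avg_fc = ifelse(is.na(idx), "",
                                        sprintf("%.4f", at$avg_fc[idx])),
                        p_value = ifelse(is.na(idx), "",
                                         sprintf("%.4E", at$p_value[idx])),
                        de_class = ifelse(is.na(idx), "", at$de_class[idx]),
                        reliable = ifelse(is.na(idx), "", at$reliable[idx]),
                        n_used = ifelse(is.na(idx), "", at$n_used[idx]),
                        stringsAsFactors = FALSE)
  attrs <- file.path(out_dir, "node_attributes.tsv")
  utils::write.table(attr_df, attrs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gml <- file.path(out_dir, "network.graphml")
  igraph::write_graph(overlay_igraph(result), gml, format = "graphml")
  invisible(c(sif = sif, attributes = attrs, graphml = gml))
}
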