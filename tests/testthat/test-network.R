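# Summaries built from the published-table fixture, using the printed
# averages and p-values as-is.
fixture_summaries <- function(rows = NULL) {
  d <- golden_fixture()
  if (!is.null(rows)) d <- d[d$table %in% rows, ]
  d <- d[!duplicated(d$gene), ]
  data.frame(gene = d$gene, avg_fc = d$avg_fc, n_used = 9L,
             p_value = d$p_value, reliable = !d$all_absent,
             de_class = ifelse(d$avg_fc > 2, "over",
                        ifelse(d$avg_fc < -2, "under", "unchanged")),
             significant = d$p_value < 0.05, stringsAsFactors = FALSE)
}

test_that("the packaged network contains every published-table gene", {
  net <- load_network()
  expect_s3_class(net, "pathway_network")
  genes <- network_genes(net)
  expect_true(all(golden_fixture()$gene %in% genes))
  # and the wider curated inventory
  expect_true(all(c("ENO1", "ENO3", "TKT", "TKTL1", "TKTL2", "G6PD",
                    "HNRNPA1", "HNRNPA2B1", "PTBP1", "PTBP2", "VHL",
                    "SLC16A1", "SLC16A3", "FBP2", "PDHX", "DLAT") %in% genes))
  # all 18 TCA-cycle genes are tagged
  tca <- genes[vapply(strsplit(net$nodes$pathways[net$nodes$kind == "gene"],
                               "|", fixed = TRUE),
                      function(t) "tca" %in% t, logical(1))]
  expect_length(tca, 18)
})

test_that("network validation catches structural problems", {
  nodes <- withr::local_tempfile(fileext = ".tsv")
  edges <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tkind\tlabel\tpathways",
               "GENE1\tgene\tg\tglycolysis",
               "met1\tmetabolite\tm\tglycolysis"), nodes)
  writeLines(c("source\ttarget\trelation",
               "GENE1\tmissing\tcatalysis"), edges)
  expect_error(load_network(nodes, edges), "not in node table")

  writeLines(c("source\ttarget\trelation",
               "GENE1\tmet1\tcatalysis"), edges)
  expect_silent(load_network(nodes, edges))

  writeLines(c("id\tkind\tlabel\tpathways",
               "GENE1\tgene\tg\t",
               "met1\tmetabolite\tm\tglycolysis"), nodes)
  expect_warning(load_network(nodes, edges), "without a pathway tag")

  writeLines(c("id\tkind\tlabel\tpathways",
               "GENE1\tgene\tg\tnot_a_pathway",
               "met1\tmetabolite\tm\tglycolysis"), nodes)
  expect_error(load_network(nodes, edges), "unknown pathway tag")
})

test_that("overlay attaches by exact symbol and reports both leftovers", {
  net <- load_network()
  sm <- fixture_summaries()
  sm <- rbind(sm, data.frame(gene = "NOTAGENE", avg_fc = 5, n_used = 9L,
                             p_value = 0.01, reliable = TRUE,
                             de_class = "over", significant = TRUE))
  ov <- overlay(net, sm)
  expect_s3_class(ov, "overlay_result")
  expect_equal(ov$unused_summaries, "NOTAGENE")
  expect_true(all(golden_fixture()$gene %in% ov$gene_attributes$gene))
  expect_true("SLC25A1" %in% ov$unmapped_genes == FALSE)  # not a network node
  expect_true(all(ov$unmapped_genes %in% network_genes(net)))
  # overlay never mutates topology
  expect_identical(ov$network$nodes, net$nodes)
  expect_identical(ov$network$edges, net$edges)
})

test_that("the glycolysis report reproduces the published section order", {
  ov <- overlay(load_network(), fixture_summaries("T1"))
  rep <- pathway_report(ov, "glycolysis")
  expect_equal(rep$gene[rep$section == "over"],
               c("ENO2", "HK2", "PFKP", "SLC2A3", "ALDOC", "PKM", "PFKFB4",
                 "SLC2A1", "HK1", "ALDOA", "PGAM1"))
  expect_equal(rep$gene[rep$section == "under"],
               c("ALDOB", "PKLR", "PFKFB2", "VHL"))
  expect_error(pathway_report(ov, "nope"), "unknown pathway tag")
})

test_that("report sections partition the pathway genes by DE class", {
  ov <- overlay(load_network(), fixture_summaries())
  for (tag in c("glycolysis", "tca", "gluconeogenesis")) {
    rep <- pathway_report(ov, tag)
    expect_equal(rep$section, rep$de_class)
    expect_equal(anyDuplicated(rep$gene), 0L)
  }
  # a pathway with no DE genes has empty over/under sections
  sm <- fixture_summaries()
  sm$avg_fc <- 1.1
  sm$de_class <- "unchanged"
  rep0 <- pathway_report(overlay(load_network(), sm), "glycolysis")
  expect_equal(sum(rep0$section != "unchanged"), 0L)
})

test_that("ties in fold-change magnitude order alphabetically", {
  sm <- data.frame(gene = c("HK2", "ENO2", "PFKP"),
                   avg_fc = c(5, 5, 5), n_used = 9L, p_value = 0.001,
                   reliable = TRUE, de_class = "over", significant = TRUE)
  rep <- pathway_report(overlay(load_network(), sm), "glycolysis")
  expect_equal(rep$gene, c("ENO2", "HK2", "PFKP"))
})

test_that("Cytoscape export is complete, deterministic and round-trips", {
  net <- load_network()
  ov <- overlay(net, fixture_summaries())
  dir <- withr::local_tempdir()
  paths <- export_cytoscape(ov, dir)
  sif <- readLines(paths["sif"])
  expect_length(sif, nrow(net$edges))
  expect_match(sif[1], "^\\S+\t\\S+\t\\S+$")
  attrs <- utils::read.delim(paths["attributes"])
  expect_equal(nrow(attrs), nrow(net$nodes))

  first <- lapply(paths, readLines)
  export_cytoscape(ov, dir)
  expect_identical(lapply(paths, readLines), first)

  g <- igraph::read_graph(paths["graphml"], format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(igraph::V(g)$name, net$nodes$id)
  back_fc <- setNames(igraph::V(g)$avg_fc, igraph::V(g)$name)
  sm <- fixture_summaries()
  expect_equal(unname(back_fc[sm$gene]), round(sm$avg_fc, 7), tolerance = 1e-6)
  ed <- igraph::as_data_frame(g, what = "edges")
  expect_setequal(paste(ed$from, ed$to, ed$relation),
                  paste(net$edges$source, net$edges$target, net$edges$relation))
})

test_that("a toy three-node network exports a two-line SIF", {
  nodes <- withr::local_tempfile(fileext = ".tsv")
  edges <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tkind\tlabel\tpathways",
               "A\tgene\ta\tglycolysis",
               "B\tgene\tb\tglycolysis",
               "m\tmetabolite\tmm\tglycolysis"), nodes)
  writeLines(c("source\ttarget\trelation",
               "A\tm\tcatalysis", "B\tm\tcatalysis"), edges)
  net <- load_network(nodes, edges)
  ov <- overlay(net, data.frame(gene = "A", avg_fc = 3, n_used = 5L,
                                p_value = 0.01, reliable = TRUE,
                                de_class = "over", significant = TRUE))
  dir <- withr::local_tempdir()
  paths <- export_cytoscape(ov, dir)
  expect_length(readLines(paths["sif"]), 2)
  expect_equal(nrow(utils::read.delim(paths["attributes"])), 3)
})
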