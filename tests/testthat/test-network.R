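site <- function(mirna, chrom, start, end)
  data.frame(mirna = mirna, chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)

test_that("seed-overlap collapse follows the half-open interval rule", {
  # overlapping single sites collapse to the lexically smaller miRNA
  r <- collapse_seed_overlaps("g", rbind(site("mB", "g", 100, 107),
                                         site("mA", "g", 103, 110)))
  expect_equal(r$kept, "mA")
  expect_equal(r$collapsed_groups, list(c("mA", "mB")))
  # touching half-open intervals do not overlap
  r2 <- collapse_seed_overlaps("g", rbind(site("mA", "g", 100, 107),
                                          site("mB", "g", 107, 114)))
  expect_setequal(r2$kept, c("mA", "mB"))
  expect_length(r2$collapsed_groups, 0)
  # two mutually overlapping + one disjoint -> 2 kept
  r3 <- collapse_seed_overlaps("g", rbind(site("mA", "g", 100, 107),
                                          site("mB", "g", 104, 111),
                                          site("mC", "g", 300, 307)))
  expect_setequal(r3$kept, c("mA", "mC"))
  # a regulator with an extra independent site is never collapsed away
  r4 <- collapse_seed_overlaps("g", rbind(site("mA", "g", 100, 107),
                                          site("mB", "g", 104, 111),
                                          site("mB", "g", 300, 307)))
  expect_setequal(r4$kept, c("mA", "mB"))
  expect_length(r4$collapsed_groups, 0)
})

calls_fixture <- function(mirnas, cts) {
  structure(data.frame(transcript = mirnas, platform = "mirna",
                       direction = "up", k = 1L,
                       specific_cell_types = cts, fold_change = 8,
                       p = 1e-5, p_adj = 1e-4, mean_expr = "10",
                       stringsAsFactors = FALSE),
            class = c("specificity_calls", "data.frame"))
}

preds_fixture <- function(pairs) {
  slot <- stats::ave(seq_len(nrow(pairs)), pairs$gene, FUN = seq_along)
  prediction_table(data.frame(
    mirna_family = pairs$mirna, gene = pairs$gene, chrom = pairs$gene,
    start = 100L + 50L * (slot - 1L), end = 107L + 50L * (slot - 1L),
    sources = "targetscan;mirdb", stringsAsFactors = FALSE))
}

test_that("network keeps multiply-targeted genes of specific miRNAs", {
  hub_regs <- paste0("m", 1:5)
  pairs <- rbind(
    data.frame(mirna = hub_regs, gene = "hub", r = -0.8),
    data.frame(mirna = "m1", gene = "solo", r = -0.7),
    data.frame(mirna = c("m1", "m6"), gene = "pair2", r = -0.6))
  calls <- calls_fixture(paste0("m", 1:5), "Neutrophils")
  net <- build_network(pairs, calls, preds_fixture(pairs), min_degree = 2)
  # m6 carries no specificity call -> pair2 drops to degree 1 and is gone;
  # solo is below min_degree; the planted hub keeps its 5 regulators
  hubs <- rank_hubs(net)
  expect_equal(hubs$gene[1], "hub")
  expect_equal(hubs$degree[1], 5L)
  expect_equal(nrow(net$edges), 5L)
  expect_setequal(net$edges$mirna, hub_regs)
  expect_true(all(net$nodes$kind[net$nodes$id == "hub"] == "gene"))
  expect_equal(net$nodes$lineage[net$nodes$id == "m1"], "myeloid")
  # single pair input -> empty network
  empty <- build_network(pairs[6, ], calls, preds_fixture(pairs),
                         min_degree = 2)
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(nrow(rank_hubs(empty)), 0L)
})

test_that("seed-similar regulators are merged before the degree filter", {
  pairs <- data.frame(mirna = c("mA", "mB", "mC"), gene = "g",
                      r = c(-0.8, -0.7, -0.9))
  preds <- prediction_table(data.frame(
    mirna_family = c("mA", "mB", "mC"), gene = "g", chrom = "g",
    start = c(100L, 103L, 300L), end = c(107L, 110L, 307L),
    sources = "targetscan;mirdb", stringsAsFactors = FALSE))
  calls <- calls_fixture(c("mA", "mB", "mC"), "T")
  net <- build_network(pairs, calls, preds, min_degree = 2)
  # mA/mB collapse to mA; with mC the gene keeps degree 2
  expect_setequal(net$edges$mirna, c("mA", "mC"))
  expect_equal(net$collapse_report$g, list(c("mA", "mB")))
  # with min_degree 3 the collapsed gene no longer qualifies
  net3 <- build_network(pairs, calls, preds, min_degree = 3)
  expect_equal(nrow(net3$edges), 0L)
})

test_that("network is bipartite and simple and exports round-trip", {
  pairs <- rbind(
    data.frame(mirna = c("m1", "m2"), gene = "gX", r = -0.8),
    data.frame(mirna = c("m1", "m2"), gene = "gY", r = -0.6),
    data.frame(mirna = c("m1", "m2"), gene = "gY", r = -0.6))  # duplicate
  calls <- calls_fixture(c("m1", "m2"), c("T", "B"))
  net <- build_network(pairs, calls, preds_fixture(unique(pairs)),
                       min_degree = 2)
  expect_equal(nrow(net$edges), 4L)  # duplicate edge removed
  expect_true(all(net$edges$mirna %in%
                    net$nodes$id[net$nodes$kind == "mirna"]))
  expect_true(all(net$edges$gene %in%
                    net$nodes$id[net$nodes$kind == "gene"]))
  g <- as_igraph(net)
  expect_true(igraph::is_bipartite(
    igraph::make_bipartite_graph(
      igraph::V(g)$kind == "gene",
      as.vector(t(igraph::as_edgelist(g, names = FALSE))))))

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  back <- import_network_edges(sif, "sif")
  expect_equal(back, net$edges[order(net$edges$mirna, net$edges$gene),
                               c("mirna", "gene")],
               ignore_attr = TRUE)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back2 <- import_network_edges(gml, "graphml")
  expect_equal(back2, back, ignore_attr = TRUE)
  # empty network -> empty SIF body
  empty <- build_network(pairs[0, ], calls, preds_fixture(unique(pairs)))
  export_network(empty, sif, "sif")
  expect_equal(length(readLines(sif)), 0L)
})

test_that("lineage-coherent couplings separate into lineage components", {
  # two myeloid miRNAs share targets, two lymphoid miRNAs share targets:
  # the graph's connected components split by lineage
  pairs <- rbind(
    data.frame(mirna = c("mMy1", "mMy2"), gene = "gM1", r = -0.8),
    data.frame(mirna = c("mMy1", "mMy2"), gene = "gM2", r = -0.8),
    data.frame(mirna = c("mLy1", "mLy2"), gene = "gL1", r = -0.8))
  calls <- calls_fixture(c("mMy1", "mMy2", "mLy1", "mLy2"),
                         c("Neutrophils", "Monocytes", "T", "B"))
  net <- build_network(pairs, calls, preds_fixture(pairs), min_degree = 2)
  g <- igraph::as_undirected(as_igraph(net))
  comp <- igraph::components(g)
  memb <- split(names(comp$membership), comp$membership)
  lin_of <- function(ids) {
    lin <- net$nodes$lineage[match(ids, net$nodes$id)]
    unique(lin[!is.na(lin) & lin != ""])
  }
  expect_equal(comp$no, 2L)
  expect_true(all(lengths(lapply(memb, lin_of)) == 1L))
})
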