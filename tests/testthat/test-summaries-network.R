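# Ranking, per-feature summaries, coverage and the network export.

mk_table <- function(mirna, mrna, cor, fdr, dat_sum = 1L) {
  n <- length(mirna)
  data.frame(mirna_id = mirna, mrna_id = mrna,
             cor = rep_len(cor, n), fdr = rep_len(fdr, n),
             dat_sum = rep_len(dat_sum, n), stringsAsFactors = FALSE)
}

test_that("ranking uses fdr, then cor, then lexicographic tie-breaks", {
  tab <- mk_table(c("miR-b", "miR-a"), c("G1", "G1"), c(-0.5, -0.5),
                  c(0.01, 0.01))
  expect_identical(rank_interactions(tab)$mirna_id, c("miR-a", "miR-b"))

  sorted <- mk_table(c("miR-a", "miR-b"), c("G1", "G2"), c(-0.9, -0.5),
                     c(0.01, 0.02))
  expect_identical(rank_interactions(sorted)$mirna_id, sorted$mirna_id)

  set.seed(41)
  rnd <- mk_table(sprintf("miR-%d", sample(1:9, 50, TRUE)),
                  sprintf("G%d", sample(1:9, 50, TRUE)),
                  round(-runif(50), 1), round(runif(50, 0, 0.1), 2))
  got <- rank_interactions(rnd)
  # independent sort: successive stable passes from the last key to the first
  ord <- seq_len(50)
  ord <- ord[order(rnd$mrna_id[ord])]
  ord <- ord[order(rnd$mirna_id[ord])]
  ord <- ord[order(rnd$cor[ord])]
  ord <- ord[order(rnd$fdr[ord])]
  expect_identical(got$mirna_id, rnd$mirna_id[ord])
  expect_identical(got$cor, rnd$cor[ord])
})

test_that("targets are counted once per distinct mRNA", {
  expect_identical(nrow(targets_per_mirna(mk_table(character(0), character(0),
                                                   numeric(0), numeric(0)))), 0L)
  tab <- mk_table(c("miR-a", "miR-a", "miR-a", "miR-b"),
                  c("G1", "G1", "G2", "G1"), -0.5, 0.01)
  tp <- targets_per_mirna(tab)
  expect_identical(tp$mirna_id, c("miR-a", "miR-b"))
  expect_identical(tp$n_targets, c(2L, 1L))

  set.seed(43)
  rnd <- mk_table(sprintf("miR-%d", sample(1:5, 60, TRUE)),
                  sprintf("G%d", sample(1:20, 60, TRUE)), -0.5, 0.01)
  tp2 <- targets_per_mirna(rnd)
  for (i in seq_len(nrow(tp2))) {
    expect_identical(tp2$n_targets[i],
                     length(unique(rnd$mrna_id[rnd$mirna_id == tp2$mirna_id[i]])))
  }
})

test_that("coverage accumulates set unions in rank order", {
  uni <- sprintf("G%d", 1:10)
  full <- mk_table(rep("miR-a", 10), uni, -0.5, 0.01)
  cov <- cumulative_coverage(full, uni)
  expect_equal(cov$cum_fraction[1], 1.0)

  disj <- mk_table(rep(c("miR-a", "miR-b"), c(3, 2)),
                   c("G1", "G2", "G3", "G4", "G5"), -0.5, 0.01)
  cd <- cumulative_coverage(disj, uni)
  expect_identical(cd$cum_mrnas, c(3L, 5L))

  set.seed(47)
  rnd <- unique(mk_table(sprintf("miR-%d", sample(1:8, 80, TRUE)),
                         sample(uni, 80, TRUE), -0.5, 0.01))
  cr <- cumulative_coverage(rnd, uni)
  seen <- character(0)
  for (i in seq_len(nrow(cr))) {  # brute-force replay
    seen <- union(seen, rnd$mrna_id[rnd$mirna_id == cr$mirna_id[i]])
    expect_identical(cr$cum_mrnas[i], length(seen))
  }
  expect_true(all(diff(cr$cum_fraction) >= 0))
  # terminal fraction ties out against the histogram zero bin
  h <- mirnas_per_mrna_histogram(rnd, uni)
  expect_equal(cr$cum_fraction[nrow(cr)], 1 - h[["0"]] / length(uni))

  expect_error(cumulative_coverage(mk_table("miR-a", "NOT_THERE", -0.5, 0.01),
                                   uni), "outside")
})

test_that("regulator histogram bins every universe member exactly once", {
  uni <- sprintf("G%d", 1:12)
  h0 <- mirnas_per_mrna_histogram(mk_table(character(0), character(0),
                                           numeric(0), numeric(0)), uni)
  expect_identical(unname(h0[["0"]]), 12L)
  expect_identical(sum(h0), 12L)

  six <- mk_table(sprintf("miR-%d", 1:6), rep("G1", 6), -0.5, 0.01)
  h6 <- mirnas_per_mrna_histogram(six, uni)
  expect_identical(unname(h6[[">5"]]), 1L)

  set.seed(53)
  rnd <- unique(mk_table(sprintf("miR-%d", sample(1:9, 100, TRUE)),
                         sample(uni, 100, TRUE), -0.5, 0.01))
  hr <- mirnas_per_mrna_histogram(rnd, uni)
  expect_identical(sum(hr), length(uni))
  oracle_bins <- vapply(uni, function(g) {  # direct per-mRNA degree count
    d <- length(unique(rnd$mirna_id[rnd$mrna_id == g]))
    if (d > 5) ">5" else as.character(d)
  }, "")
  expect_identical(unname(hr),
                   as.integer(table(factor(oracle_bins, levels = names(hr)))))
})

test_that("the exported network is bipartite, attribute-complete, re-parseable", {
  ds <- tiny_dataset(59)
  res <- run_recovery(ds)
  int <- res$interactions
  g <- build_network(int, res$de_mirna, res$de_mrna)
  expect_identical(igraph::ecount(g), as.numeric(nrow(int)))
  expect_identical(igraph::vcount(g),
                   as.numeric(length(unique(int$mirna_id)) +
                                length(unique(int$mrna_id))))
  # bipartite: every edge goes miRNA -> mRNA
  el <- igraph::as_data_frame(g, "edges")
  kind <- setNames(igraph::V(g)$kind, igraph::V(g)$name)
  expect_true(all(kind[el$from] == "miRNA"))
  expect_true(all(kind[el$to] == "mRNA"))
  # miRNA out-degree equals its distinct-target count
  tp <- targets_per_mirna(int)
  deg <- igraph::degree(g, mode = "out")
  expect_identical(unname(deg[tp$mirna_id]), as.numeric(tp$n_targets))

  dir <- withr::local_tempdir()
  gml <- file.path(dir, "net.graphml")
  export_network(g, gml, file.path(dir, "edges.tsv"))
  back <- igraph::read_graph(gml, format = "graphml")
  expect_identical(igraph::vcount(back), igraph::vcount(g))
  expect_identical(igraph::ecount(back), igraph::ecount(g))
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  expect_equal(sort(igraph::E(back)$cor), sort(igraph::E(g)$cor),
               tolerance = 1e-12)
  expect_true(all(c("kind", "signed_fc", "direction") %in%
                    igraph::vertex_attr_names(back)))

  # empty table still exports valid GraphML
  g0 <- build_network(int[0, ], res$de_mirna, res$de_mrna)
  f0 <- file.path(dir, "empty.graphml")
  export_network(g0, f0)
  b0 <- igraph::read_graph(f0, format = "graphml")
  expect_identical(igraph::vcount(b0), 0)
  expect_identical(igraph::ecount(b0), 0)
})
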