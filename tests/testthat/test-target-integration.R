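# Database annotation, interaction filtering, Venn regions, reduction.

three_dbs <- function(pairs_list) {
  lapply(names(pairs_list), function(nm)
    suppressMessages(target_db(nm, pairs_list[[nm]]$mirna,
                               pairs_list[[nm]]$gene)))
}

test_that("a pair present in all databases gets dat_sum 3", {
  tab <- data.frame(mirna_id = "miR-21", mrna_id = "PDCD4",
                    cor = -0.93, p = 1e-4, fdr = 0.010)
  dbs <- three_dbs(list(
    TargetScan = list(mirna = "hsa-miR-21", gene = "PDCD4"),
    miRSVR = list(mirna = "miR-21", gene = "pdcd4"),
    miRDB = list(mirna = "miR-21", gene = "PDCD4")))
  ann <- suppressMessages(annotate_predictions(tab, dbs))
  expect_identical(unname(unlist(ann[1, c("TargetScan", "miRSVR", "miRDB")])),
                   c(1L, 1L, 1L))
  expect_identical(ann$dat_sum, 3L)

  none <- suppressMessages(annotate_predictions(
    data.frame(mirna_id = "miR-99", mrna_id = "NOPE",
               cor = -0.5, p = 0.01, fdr = 0.02), dbs))
  expect_identical(none$dat_sum, 0L)
  expect_error(annotate_predictions(tab, list()), "at least one")
})

test_that("annotation flags equal an independent set-lookup pass", {
  set.seed(91)
  mir <- sprintf("miR-%d", 1:20)
  gene <- sprintf("G%03d", 1:30)
  tab <- data.frame(mirna_id = sample(mir, 100, TRUE),
                    mrna_id = sample(gene, 100, TRUE),
                    cor = -runif(100), p = runif(100), fdr = runif(100))
  dbs <- lapply(c("d1", "d2", "d3"), function(nm) {
    suppressMessages(target_db(nm, sample(mir, 60, TRUE), sample(gene, 60, TRUE)))
  })
  ann <- annotate_predictions(tab, dbs)
  for (d in dbs) {
    member <- logical(100)
    for (i in 1:100) {
      member[i] <- any(d$pairs$mirna_id == tab$mirna_id[i] &
                         d$pairs$gene_id == tab$mrna_id[i])
    }
    expect_identical(ann[[d$name]], as.integer(member))
  }
  expect_identical(ann$dat_sum, as.integer(ann$d1 + ann$d2 + ann$d3))
})

test_that("interaction filtering applies the full truth table strictly", {
  th <- 0.05
  tab <- data.frame(
    mirna_id = sprintf("miR-%d", 1:8), mrna_id = sprintf("G%d", 1:8),
    cor = c(-0.9, 0.9, -0.9, -0.9, 0.9, -0.9, 0.9, -0.9),
    p = rep(0.01, 8),
    fdr = c(0.01, 0.01, 0.05, 0.01, 0.2, 0.049, 0.01, 0.01),
    d1 = c(1L, 1L, 1L, 0L, 1L, 1L, 0L, 0L),
    d2 = c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L))
  tab$dat_sum <- tab$d1 + tab$d2
  attr(tab, "db_names") <- c("d1", "d2")
  kept <- filter_interactions(tab, th, 1L)
  oracle <- character(0)
  for (i in 1:8) {
    if (tab$cor[i] < 0 && tab$fdr[i] < th && tab$dat_sum[i] >= 1)
      oracle <- c(oracle, tab$mirna_id[i])
  }
  expect_identical(kept$mirna_id, oracle)   # excludes cor>0, fdr==th, dat_sum 0
  expect_error(filter_interactions(tab, th, 3L), "exceeds")
  expect_error(filter_interactions(unclass(tab)[1:7], th), "annotate")
})

test_that("min_dbs filtering is monotonically nested", {
  ds <- tiny_dataset(37)
  res <- run_recovery(ds)
  ann <- annotate_predictions(res$pairs, ds$dbs)
  prev <- NULL
  for (k in 3:1) {
    cur <- filter_interactions(ann, 0.05, k)
    if (!is.null(prev)) {
      expect_true(all(key_of(prev$mirna_id, prev$mrna_id) %in%
                        key_of(cur$mirna_id, cur$mrna_id)))
    }
    prev <- cur
  }
})

test_that("Venn regions handle identical, disjoint and random databases", {
  same <- three_dbs(list(a = list(mirna = c("miR-1", "miR-2"), gene = c("A", "B")),
                         b = list(mirna = c("miR-1", "miR-2"), gene = c("A", "B")),
                         c = list(mirna = c("miR-1", "miR-2"), gene = c("A", "B"))))
  vr <- venn_regions(same)
  expect_identical(unname(vr["a&b&c"]), 2L)
  expect_identical(sum(vr), 2L)

  disj <- three_dbs(list(a = list(mirna = "miR-1", gene = "A"),
                         b = list(mirna = "miR-2", gene = "B"),
                         c = list(mirna = "miR-3", gene = "C")))
  vd <- venn_regions(disj)
  expect_identical(unname(vd[c("a", "b", "c")]), rep(1L, 3))
  expect_identical(sum(vd), 3L)

  expect_identical(sum(venn_regions(disj, universe = character(0))), 0L)

  set.seed(77)
  rnd <- lapply(c("x", "y", "z"), function(nm)
    suppressMessages(target_db(nm, sprintf("miR-%d", sample(1:15, 40, TRUE)),
                               sprintf("G%d", sample(1:15, 40, TRUE)))))
  vv <- venn_regions(rnd)
  keys <- unique(unlist(lapply(rnd, `[[`, "key")))
  # brute-force enumeration of membership patterns
  for (region in names(vv)) {
    inset <- strsplit(region, "&", fixed = TRUE)[[1]]
    cnt <- 0L
    for (k in keys) {
      memb <- vapply(rnd, function(d) k %in% d$key, NA)
      if (identical(sort(db_names <- c("x", "y", "z")[memb]), sort(inset)))
        cnt <- cnt + 1L
    }
    expect_identical(unname(vv[region]), cnt)
  }
  # inclusion-exclusion: |x| counted from regions equals the db size on keys
  sx <- sum(vv[grepl("(^|&)x(&|$)", names(vv))])
  expect_identical(sx, length(rnd[[1]]$key))
})

test_that("reduction percentages follow (orig - kept) / orig", {
  genes <- sprintf("G%04d", 1:900)
  mk_pairs <- function(mir, n) data.frame(mirna = mir, gene = genes[1:n])
  db <- suppressMessages(target_db("u", c(rep("miR-374b", 866), rep("miR-148a", 595)),
                                   c(genes[1:866], genes[1:595])))
  inter <- data.frame(
    mirna_id = c(rep("miR-374b", 381), rep("miR-148a", 363)),
    mrna_id = c(genes[1:381], genes[1:363]))
  rep1 <- reduction_report(inter, list(db),
                           de_mirnas = c("miR-374b", "miR-148a", "miR-0"),
                           de_mrnas = genes)
  r374 <- rep1[rep1$mirna_id == "miR-374b", ]
  r148 <- rep1[rep1$mirna_id == "miR-148a", ]
  expect_identical(c(r374$kept, r374$orig, r374$reduction_pct), c(381, 866, 56))
  expect_identical(c(r148$kept, r148$orig, r148$reduction_pct), c(363, 595, 39))
  # no raw predictions -> flagged, excluded from the average
  r0 <- rep1[rep1$mirna_id == "miR-0", ]
  expect_true(is.na(r0$reduction_pct))
  expect_equal(attr(rep1, "mean_reduction_pct"), mean(c(56, 39)))
  # kept == orig -> 0 %
  rep2 <- reduction_report(data.frame(mirna_id = rep("miR-374b", 866),
                                      mrna_id = genes[1:866]),
                           list(db), "miR-374b", genes)
  expect_identical(rep2$reduction_pct, 0)
})
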