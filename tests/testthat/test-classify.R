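# small hand-built annotation: one two-isoform gene on +, one gene on -,
# an adjacent same-strand partner for gene A
toy_annotation <- function() {
  bind_rows(
    mk_tx("gA.t1", "c1", "+", c(1000L, 1400L, 1800L), c(1200L, 1600L, 2000L),
          gene_id = "gA"),
    mk_tx("gA.t2", "c1", "+", c(1000L, 1800L), c(1200L, 2000L), gene_id = "gA"),
    mk_tx("gB.t1", "c1", "+", c(5000L, 5400L), c(5200L, 5600L), gene_id = "gB"),
    mk_tx("gC.t1", "c1", "-", c(9000L, 9400L), c(9200L, 9600L), gene_id = "gC")
  )
}

test_that("the classification ladder resolves the hand-built cases", {
  idx <- annotation_index(toy_annotation())
  cases <- list(
    list(mk_tx("full", "c1", "+", c(1050L, 1400L, 1800L), c(1200L, 1600L, 1950L)), "c"),
    list(mk_tx("partial", "c1", "+", c(1450L, 1800L), c(1600L, 1990L)), "g"),
    list(mk_tx("novel_iso", "c1", "+", c(1000L, 1400L, 1811L), c(1200L, 1600L, 2000L)), "b"),
    list(mk_tx("exonic", "c1", "+", 1050L, 1150L), "d"),
    list(mk_tx("intronic_read", "c1", "+", 1250L, 1350L), "e"),
    list(mk_tx("anti", "c1", "-", 1050L, 1150L), "f"),
    list(mk_tx("novel_locus", "c1", "+", c(20000L, 20500L), c(20200L, 20700L)), "a"),
    list(mk_tx("merged", "c1", "+",
               c(1000L, 1400L, 1800L, 5000L, 5400L),
               c(1200L, 1600L, 2000L, 5200L, 5600L)), "h")
  )
  for (cs in cases) {
    res <- classify_isoforms(cs[[1]], idx)
    expect_equal(res$group, cs[[2]], label = cs[[1]]$transcript_id)
  }
  # intronic subtype in the other direction: annotated gene inside read intron
  spanning <- mk_tx("span", "c1", "+", c(8000L, 9900L), c(8200L, 10100L))
  res <- classify_isoforms(spanning, idx)
  expect_equal(res$group, "e")
  expect_equal(res$subtype, "annotation_inside_read")
})

test_that("planted categories are recovered exactly and label order is stable", {
  sim <- std_fixture()
  cats <- sim$reads$truth$categories
  tx <- sim$reads$reads %>% filter(.data$transcript_id %in% cats$transcript_id)
  res <- classify_isoforms(tx, sim$index)
  m <- inner_join(cats, res, by = "transcript_id", suffix = c(".true", ".pred"))
  expect_gte(min(table(m$group.true)), 25)
  expect_equal(m$group.pred, m$group.true)
  expect_equal(m$subtype.pred[!is.na(m$subtype.true)],
               m$subtype.true[!is.na(m$subtype.true)])

  # permutation invariance of annotation record order
  perm <- sim$ann$annotation[sample(nrow(sim$ann$annotation)), ]
  res2 <- classify_isoforms(tx, annotation_index(perm))
  expect_equal(res2$group[match(res$transcript_id, res2$transcript_id)], res$group)

  # partition: one category per isoform; no b-labelled isoform has a full
  # chain match (the ladder must let c win)
  expect_equal(anyDuplicated(res$transcript_id), 0L)
  chains <- tx_chain(tx)
  ann_chains <- tx_chain(sim$ann$annotation)
  b_ids <- res$transcript_id[res$group == "b"]
  expect_false(any(chains[match(b_ids, tx$transcript_id)] %in% ann_chains))
})

test_that("split-gene candidates are confirmed by merged reads", {
  sim <- std_fixture()
  cats <- sim$reads$truth$categories
  tx <- sim$reads$reads %>% filter(.data$transcript_id %in% cats$transcript_id)
  res <- classify_isoforms(tx, sim$index)
  sc <- sim$reads$truth$split_candidates
  verdicts <- confirm_split_genes(res, tx, sim$index,
                                  sc %>% select("candidate_id", "gene_ids"))
  expect_equal(verdicts$verdict, sc$expect)
  expect_error(
    confirm_split_genes(res, tx, sim$index,
                        tibble(candidate_id = "x", gene_ids = list(c("nope", "gX")))),
    "unknown gene")
})

test_that("partially_correct fires when the annotation spans the merged genes", {
  # gene D's transcript crosses into gene E's territory and matches a
  # sub-chain of the merged read
  ann <- bind_rows(
    mk_tx("gD.t1", "c1", "+", c(100L, 400L), c(200L, 500L), gene_id = "gD"),
    mk_tx("gD.t2", "c1", "+", c(100L, 400L, 900L), c(200L, 500L, 1000L),
          gene_id = "gD"),
    mk_tx("gE.t1", "c1", "+", c(900L, 1200L), c(1000L, 1300L), gene_id = "gE")
  )
  idx <- annotation_index(ann)
  merged <- mk_tx("merged", "c1", "+", c(100L, 400L, 900L, 1200L),
                  c(200L, 500L, 1000L, 1300L))
  res <- classify_isoforms(merged, idx)
  expect_equal(res$group, "h")
  v <- confirm_split_genes(res, merged, idx,
                           tibble(candidate_id = "s1", gene_ids = list(c("gD", "gE"))))
  expect_equal(v$verdict, "partially_correct")
})

test_that("TE screening applies all three thresholds jointly", {
  tx <- bind_rows(mk_tx("t1", "c1", "+", 0L, 100L),
                  mk_tx("t2", "c1", "+", 200L, 300L),
                  mk_tx("t3", "c1", "+", 400L, 500L))
  hits <- tibble(
    query_id = c("t1", "t2", "t2"),
    subject_db = "TE", subject_id = c("a", "b", "c"),
    e_value = c(1e-12, 1e-12, 1e-20),
    coverage = c(0.90, 0.50, 0.84),
    identity = c(0.95, 0.95, 0.99),
    subject_class = c("Gypsy", "Copia", NA))
  res <- screen_te(tx, hits)
  expect_equal(res$te$transcript_id, "t1")
  expect_equal(res$te$superfamily, "Gypsy")
  expect_setequal(res$non_te$transcript_id, c("t2", "t3"))
  expect_equal(res$tally$n_isoforms[res$tally$superfamily == "Gypsy"], 1L)
  # planted fixture TEs are flagged, near-miss hits are not
  sim <- std_fixture()
  sres <- screen_te(sim$reads$reads, sim$reads$te_hits)
  expect_setequal(sres$te$transcript_id, sim$reads$truth$te$transcript_id)
})

test_that("isoforms_per_gene matches a direct recount and groups novel loci", {
  sim <- std_fixture()
  cats <- sim$reads$truth$categories
  tx <- sim$reads$reads %>% filter(.data$transcript_id %in% cats$transcript_id)
  res <- classify_isoforms(tx, sim$index)
  ipg <- isoforms_per_gene(res, tx)
  n_assigned <- sum(res$group %in% c("b", "c", "g"))
  known <- ipg$per_gene %>% filter(!.data$novel)
  expect_equal(sum(known$n_isoforms), n_assigned)
  expect_equal(ipg$summary$mean_isoforms, mean(ipg$per_gene$n_isoforms))
  expect_equal(ipg$summary$genes_with_ge2, sum(ipg$per_gene$n_isoforms >= 2))
  # the 25 planted novel-locus reads occupy 25 disjoint intergenic loci
  expect_equal(sum(ipg$per_gene$novel), 25L)
})

test_that("density track counts midpoints in trailing 1-Mb windows", {
  tr <- density_track(tibble(chrom = "c1", pos = 0), c(c1 = 2e6))
  expect_equal(sum(tr$count), 50L)
  expect_equal(tr$window_pos[tr$count == 1], seq(0, 980000, by = 20000))

  empty <- density_track(tibble(chrom = character(), pos = numeric()), c(c1 = 1e6))
  expect_true(all(empty$count == 0))
  expect_equal(nrow(density_track(tibble(chrom = "c1", pos = 1), c(c1 = 0))), 0L)

  set.seed(1)
  feats <- tibble(chrom = "c1", pos = runif(1000, 0, 1e7))
  tr <- density_track(feats, c(c1 = 1e7))
  interior <- tr$count[tr$window_pos >= 1e6 & tr$window_pos <= 9e6]
  expect_true(all(abs(interior - 100) < 3 * sqrt(100) + 10))
  expect_equal(mean(interior), 100, tolerance = 0.1)
})
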