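# tiny dependency-free connected components for the test oracle
igraph_free_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

test_that("quality filter applies inclusive coverage/identity thresholds", {
  tx <- bind_rows(
    mk_tx("ok_boundary", "c1", "+", c(0L, 200L), c(100L, 300L),
          coverage = 0.85, identity = 0.90),
    mk_tx("low_cov", "c1", "+", c(0L, 200L), c(100L, 300L),
          coverage = 0.84, identity = 0.95),
    mk_tx("low_ident", "c1", "+", c(0L, 200L), c(100L, 300L),
          coverage = 0.95, identity = 0.89)
  )
  res <- filter_alignments(tx)
  expect_equal(res$kept$transcript_id, "ok_boundary")
  expect_equal(res$discarded$reason[res$discarded$transcript_id == "low_cov"],
               "low_coverage")
  expect_equal(res$discarded$reason[res$discarded$transcript_id == "low_ident"],
               "low_identity")
  empty <- filter_alignments(tx[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$discarded), 0L)
})

test_that("collapse keys ignore terminal boundaries but not chains or strand", {
  a <- mk_tx("a", "c1", "+", c(0L, 200L), c(100L, 300L))
  b <- mk_tx("b", "c1", "+", c(30L, 200L), c(100L, 330L))  # 5' and 3' wobble
  c_ <- mk_tx("c", "c1", "-", c(0L, 200L), c(100L, 300L))
  d <- mk_tx("d", "c1", "+", c(0L, 201L), c(100L, 300L))   # 1 bp intron shift
  expect_equal(collapse_key(a), collapse_key(b))
  expect_false(collapse_key(a) == collapse_key(c_))
  expect_false(collapse_key(a) == collapse_key(d))
  # with 3' collapsing off the differing 3' end separates a and b
  p3 <- collapse_params(collapse_3prime = FALSE)
  expect_false(collapse_key(a, p3) == collapse_key(b, p3))
  expect_error(collapse_key(mk_tx("m", "c1", "+", 0L, 50L)), "multi-exon")
})

test_that("collapse merges 5'-degraded duplicates, keeps the longest, and is stable", {
  parent <- mk_tx("p1", "c1", "+", c(0L, 200L, 400L), c(100L, 300L, 520L))
  degraded <- mk_tx("p2", "c1", "+", c(40L, 200L, 400L), c(100L, 300L, 520L))
  other <- mk_tx("q", "c1", "+", c(0L, 250L), c(120L, 380L))
  tx <- bind_rows(parent, degraded, other)
  cl <- collapse_isoforms(tx)
  expect_equal(nrow(cl$isoforms), 2L)
  expect_true("p1" %in% cl$isoforms$transcript_id)  # longest member retained
  expect_setequal(cl$member_map$transcript_id[cl$member_map$isoform_id == "p1"],
                  c("p1", "p2"))

  # equal-length duplicates: lexicographically smallest id wins
  dup <- bind_rows(mk_tx("b", "c1", "+", c(0L, 200L), c(100L, 300L)),
                   mk_tx("a", "c1", "+", c(0L, 200L), c(100L, 300L)))
  expect_equal(collapse_isoforms(dup)$isoforms$transcript_id, "a")

  # mono-exon merge at >= 50% reciprocal overlap of the shorter
  mono <- bind_rows(mk_tx("m1", "c1", "+", 0L, 100L),
                    mk_tx("m2", "c1", "+", 40L, 160L),   # 60% of shorter
                    mk_tx("m3", "c1", "+", 500L, 600L),
                    mk_tx("m4", "c1", "-", 0L, 100L))    # strand differs
  clm <- collapse_isoforms(mono)
  expect_equal(nrow(clm$isoforms), 3L)
  expect_true("m2" %in% clm$isoforms$transcript_id)  # longest representative

  # idempotence and order independence
  again <- collapse_isoforms(cl$isoforms)
  expect_equal(sort(again$isoforms$transcript_id), sort(cl$isoforms$transcript_id))
  shuf <- collapse_isoforms(tx[c(3, 1, 2), ])
  expect_equal(sort(shuf$isoforms$transcript_id), sort(cl$isoforms$transcript_id))
})

test_that("collapse partitions the fixture into the planted distinct chains", {
  sim <- std_fixture()
  flt <- filter_alignments(sim$reads$reads)
  expect_setequal(flt$discarded$transcript_id,
                  sim$reads$truth$qc_decoys$transcript_id)
  cl <- collapse_isoforms(flt$kept, discarded = flt$discarded)

  # brute-force oracle: group by (chrom,strand,chain) for multi-exon and by
  # pairwise reciprocal-overlap components for mono-exon
  kept <- flt$kept
  multi <- kept[n_exons(kept) >= 2, ]
  mono <- kept[n_exons(kept) < 2, ]
  oracle_groups <- length(unique(tx_chain(multi)))
  if (nrow(mono)) {
    xt <- tx_extent(mono)
    adj <- outer(seq_len(nrow(xt)), seq_len(nrow(xt)), Vectorize(function(i, j) {
      if (xt$chrom[i] != xt$chrom[j] || xt$strand[i] != xt$strand[j]) return(FALSE)
      ov <- min(xt$end[i], xt$end[j]) - max(xt$start[i], xt$start[j])
      ov > 0 && ov >= 0.5 * min(xt$end[i] - xt$start[i], xt$end[j] - xt$start[j])
    }))
    g <- igraph_free_components(adj)
    oracle_groups <- oracle_groups + length(unique(g))
  }
  expect_equal(nrow(cl$isoforms), oracle_groups)

  # conservation: every input id appears exactly once across members/discards
  all_ids <- c(cl$member_map$transcript_id, cl$discarded$transcript_id)
  expect_setequal(all_ids, sim$reads$reads$transcript_id)
  expect_equal(anyDuplicated(all_ids), 0L)

  # every degraded duplicate collapses onto its parent's isoform
  deg <- sim$reads$truth$degraded
  mm <- cl$member_map
  iso_of <- setNames(mm$isoform_id, mm$transcript_id)
  expect_equal(unname(iso_of[deg$transcript_id]), unname(iso_of[deg$parent_id]))

  # no two retained multi-exon isoforms share a chain
  ret <- cl$isoforms[n_exons(cl$isoforms) >= 2, ]
  expect_equal(anyDuplicated(tx_chain(ret)), 0L)
})

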