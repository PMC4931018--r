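mk_aln <- function(qid, L, q0, q1, chrom, strand, s, e, identity = 0.99) {
  tibble(query_id = qid, read_length = as.integer(L), q_start = as.integer(q0),
         q_end = as.integer(q1), chrom = chrom, strand = strand,
         exon_starts = list(as.integer(s)), exon_ends = list(as.integer(e)),
         identity = identity)
}

test_that("locus clustering merges within 100 kb on one chromosome only", {
  a <- bind_rows(
    mk_aln("q", 1000, 0, 300, "c1", "+", 1000L, 1300L),
    mk_aln("q", 1000, 300, 600, "c1", "+", 31000L, 31300L),   # 30 kb away
    mk_aln("q", 1000, 600, 800, "c1", "+", 200000L, 200200L), # 169 kb away
    mk_aln("q", 1000, 800, 1000, "c2", "+", 1000L, 1200L))
  loci <- cluster_loci(a)
  expect_equal(nrow(loci), 3L)
  merged <- loci[loci$start == 1000 & loci$chrom == "c1", ]
  expect_equal(merged$end, 31300L)
  expect_equal(nrow(merged$q_intervals[[1]]), 2L)
  # idempotent and order independent
  loci2 <- cluster_loci(a[c(3, 1, 4, 2), ])
  expect_equal(sort(loci2$start), sort(loci$start))
})

test_that("the four criteria reproduce the worked arithmetic example", {
  a <- bind_rows(
    mk_aln("q", 1000, 0, 600, "c1", "+", c(1000L, 1300L), c(1200L, 1700L)),
    mk_aln("q", 1000, 595, 1000, "c2", "+", 5000L, 5405L))
  res <- evaluate_fusions(cluster_loci(a))
  expect_true(res$passes)
  expect_equal(res$combined_coverage, 1.0)
  expect_equal(res$min_locus_frac, 0.405)
  expect_equal(res$classification, "inter_chromosomal")
  # per-locus 8% fails criterion (b) only
  b <- bind_rows(
    mk_aln("q2", 1000, 0, 80, "c1", "+", 1000L, 1080L),
    mk_aln("q2", 1000, 80, 1000, "c2", "+", 5000L, 5920L))
  resb <- evaluate_fusions(cluster_loci(b))
  expect_false(resb$passes)
  expect_false(resb$per_locus_min_fraction)
  expect_true(resb$multi_locus && resb$combined_coverage_ok && resb$min_separation_ok)
  # 95% union fails criterion (c) only
  cc <- bind_rows(
    mk_aln("q3", 1000, 0, 500, "c1", "+", 1000L, 1500L),
    mk_aln("q3", 1000, 550, 1000, "c2", "+", 5000L, 5450L))
  resc <- evaluate_fusions(cluster_loci(cc))
  expect_false(resc$passes)
  expect_false(resc$combined_coverage_ok)
  expect_equal(resc$combined_coverage, 0.95)
  # 50 kb separation fails criterion (d) only
  d <- bind_rows(
    mk_aln("q4", 1000, 0, 500, "c1", "+", 1000L, 1500L),
    mk_aln("q4", 1000, 500, 1000, "c1", "+", 151500L, 152000L))
  resd <- evaluate_fusions(cluster_loci(d), min_separation = 2e5)
  expect_false(resd$passes)
  expect_false(resd$min_separation_ok)
  expect_error(evaluate_fusions(cluster_loci(mk_aln("z", 0, 0, 0, "c1", "+", 1L, 2L))),
               "read length")
})

test_that("fixture verdicts equal an independent brute-force oracle", {
  sim <- std_fixture()
  loci <- cluster_loci(sim$fus$alignments)
  res <- evaluate_fusions(loci)
  # brute force: re-apply the four rules from the raw locus table
  oracle <- vapply(split(loci, loci$query_id), function(l) {
    L <- l$read_length[1]
    iv <- do.call(rbind, l$q_intervals)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    cov <- 0; hi <- -Inf
    for (r in seq_len(nrow(iv))) {
      cov <- cov + max(0, iv[r, 2] - max(iv[r, 1], hi)); hi <- max(hi, iv[r, 2])
    }
    fr <- vapply(l$q_intervals, function(m) sum(m[, 2] - m[, 1]) / L, 1.0)
    sep <- TRUE
    if (nrow(l) > 1) {
      for (i in 1:(nrow(l) - 1)) for (j in (i + 1):nrow(l)) {
        if (l$chrom[i] == l$chrom[j] &&
              max(l$start[i], l$start[j]) - min(l$end[i], l$end[j]) < 1e5)
          sep <- FALSE
      }
    }
    nrow(l) >= 2 && all(fr >= 0.10) && cov / L >= 0.99 && sep
  }, TRUE)
  expect_equal(res$passes, unname(oracle[res$query_id]))
  # precision and recall of 1 against planted truth
  tr <- inner_join(res, sim$fus$truth, by = "query_id",
                   suffix = c(".pred", ".true"))
  expect_equal(tr$passes.pred, tr$passes.true)
  # each decoy fails exactly its planted criterion
  dec <- tr %>% filter(startsWith(.data$class, "decoy_"), !is.na(.data$violated))
  for (i in seq_len(nrow(dec))) {
    crit <- c("multi_locus", "per_locus_min_fraction", "combined_coverage_ok",
              "min_separation_ok")
    vals <- unlist(dec[i, crit])
    expect_false(vals[[dec$violated[i]]])
    expect_true(all(vals[setdiff(crit, dec$violated[i])]))
  }
  # inter/intra classification recount
  pass <- tr %>% filter(.data$passes.pred)
  expect_equal(pass$classification == "inter_chromosomal", pass$inter_chromosomal)
})

test_that("breakpoint concordance separates splice-site fusions from shifted decoys", {
  sim <- std_fixture()
  loci <- cluster_loci(sim$fus$alignments)
  res <- breakpoint_concordance(evaluate_fusions(loci), loci,
                                tx_junctions(sim$ann$annotation))
  tr <- inner_join(res, sim$fus$truth, by = "query_id")
  pass <- tr %>% filter(.data$passes.x)
  expect_equal(pass$breakpoint_concordant, pass$concordant)
  expect_true(all(is.na(tr$breakpoint_concordant[!tr$passes.x])))
})

test_that("short-read validation needs a unique record spanning two loci", {
  a <- bind_rows(
    mk_aln("q", 1000, 0, 500, "c1", "+", 1000L, 1500L),
    mk_aln("q", 1000, 500, 1000, "c2", "+", 5000L, 5500L))
  loci <- cluster_loci(a)
  fus <- evaluate_fusions(loci)
  base <- tibble(pair_id = "p", type = "pair", chrom1 = "c1", start1 = 1100L,
                 end1 = 1200L, chrom2 = "c2", start2 = 5100L, end2 = 5200L,
                 unique = TRUE)
  expect_true(validate_with_short_reads(fus, loci, base)$supported)
  within <- base %>% mutate(chrom2 = "c1", start2 = 1300L, end2 = 1400L)
  expect_false(validate_with_short_reads(fus, loci, within)$supported)
  multi <- base %>% mutate(unique = FALSE)
  expect_false(validate_with_short_reads(fus, loci, multi)$supported)
  span <- base %>% mutate(type = "spanning")
  v <- validate_with_short_reads(fus, loci, span)
  expect_true(v$supported)
  expect_equal(v$n_spanning_reads, 1L)
  # fixture: planted validation labels recovered
  sim <- std_fixture()
  l2 <- cluster_loci(sim$fus$alignments)
  f2 <- validate_with_short_reads(evaluate_fusions(l2), l2, sim$fus$pairs)
  tr <- inner_join(f2, sim$fus$truth, by = "query_id") %>%
    filter(.data$class == "true")
  expect_equal(tr$supported, tr$validated)
})
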