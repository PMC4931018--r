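test_that("read_genome loads, uppercases, and rejects malformed FASTA", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c2", "NN"), fa)
  g <- read_genome(fa)
  expect_equal(setNames(Biostrings::width(g), names(g)), c(c1 = 4L, c2 = 2L))

  writeLines(c(">c1", "acgt"), fa)
  expect_equal(as.character(read_genome(fa)[[1]]), "ACGT")

  writeLines(c(">c1", "ACGT", ">c1", "GG"), fa)
  expect_error(read_genome(fa), "duplicate")
  writeLines(character(), fa)
  expect_error(read_genome(fa), "empty|read")
})

test_that("GFF3/GTF/BED12 transcript models convert coordinates correctly", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tx\ttranscript\t101\t400\t.\t+\t.\tID=t1;identity=0.95;coverage=0.9",
    "c1\tx\texon\t101\t200\t.\t+\t.\tParent=t1",
    "c1\tx\texon\t301\t400\t.\t+\t.\tParent=t1"
  ), gff)
  tx <- read_transcript_models(gff)
  expect_equal(tx$exon_starts[[1]], c(100L, 300L))
  expect_equal(tx$exon_ends[[1]], c(200L, 400L))
  expect_equal(tx$identity, 0.95)
  expect_equal(tx$coverage, 0.9)

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("c1\t50\t150\tm1\t0\t-\t50\t150\t0\t1\t100,\t0,", bed)
  mono <- read_transcript_models(bed, "bed12")
  expect_equal(n_exons(mono), 1L)
  expect_equal(nrow(tx_junctions(mono)), 0L)
  expect_equal(mono$strand, "-")
})

test_that("mixed-chromosome exon groups are dropped with a warning", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tx\texon\t1\t100\t.\t+\t.\tParent=t1",
    "c2\tx\texon\t201\t300\t.\t+\t.\tParent=t1",
    "c1\tx\texon\t1\t100\t.\t+\t.\tParent=t2"
  ), gff)
  expect_warning(tx <- read_transcript_models(gff), "fusion")
  expect_equal(tx$transcript_id, "t2")
})

test_that("tx_junctions maps exon gaps to introns and tiles the extent", {
  t1 <- mk_tx("t", "c1", "+", c(0L, 200L), c(100L, 300L))
  expect_equal(tx_junctions(t1)[, c("intron_start", "intron_end")],
               tibble(intron_start = 100L, intron_end = 200L))
  expect_equal(nrow(tx_junctions(mk_tx("m", "c1", "+", 0L, 50L))), 0L)
  t3 <- mk_tx("t3", "c1", "-", c(0L, 20L, 40L), c(10L, 30L, 50L))
  j <- tx_junctions(t3)
  expect_equal(j$intron_start, c(10L, 30L))
  expect_equal(j$intron_end, c(20L, 40L))

  # exons + introns tile [first start, last end) with no gaps or overlaps
  for (i in 1:10) {
    tx <- random_tx(paste0("r", i))
    ex <- tx_exons(tx); jn <- tx_junctions(tx)
    spans <- rbind(cbind(ex$start, ex$end),
                   cbind(jn$intron_start, jn$intron_end))
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    expect_equal(spans[1, 1], tx$exon_starts[[1]][1])
    expect_true(all(spans[-1, 1] == spans[-nrow(spans), 2]))
  }
})

test_that("junction evidence dialects convert to 0-based half-open introns", {
  sj <- withr::local_tempfile(fileext = ".tab")
  writeLines(c("c1\t101\t200\t1\t1\t1\t5\t0\t20",
               "c1\t500\t600\t0\t0\t0\t2\t1\t15"), sj)
  ev <- read_junction_evidence(sj, "star_sj_tab", tissue = "root")
  expect_equal(ev$intron_start, c(100L, 499L))
  expect_equal(ev$intron_end, c(200L, 600L))
  expect_equal(ev$read_count, c(5L, 2L))
  expect_equal(ev$strand, c("+", NA))
  expect_equal(ev$tissue, c("root", "root"))
  writeLines("c1\tnot\ta\tnumber", sj)
  expect_error(read_junction_evidence(sj, "star_sj_tab"), "line 1")

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("c1\t0\t200\tj1\t4\t+\t0\t200\t0\t2\t50,50\t0,150", bed)
  ev2 <- read_junction_evidence(bed, "bed12_junctions")
  expect_equal(ev2$intron_start, 50L)
  expect_equal(ev2$intron_end, 150L)
})

test_that("methylation tables are validated on read", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "c1\t10\t+\tCG\t3\t1"), tsv)
  m <- read_methylation(tsv)
  expect_equal(site_level(m$count_c, m$count_t), 0.75)
  writeLines(character(), tsv)
  expect_equal(nrow(read_methylation(tsv)), 0L)
  writeLines("c1\t10\t+\tCHX\t3\t1", tsv)
  expect_error(read_methylation(tsv), "context")
  writeLines("c1\t10\t+\tCG\t-3\t1", tsv)
  expect_error(read_methylation(tsv), "negative")
  writeLines(c("c1\t10\t+\tCG\t3\t1", "c1\t10\t+\tCHH\t1\t1"), tsv)
  expect_error(read_methylation(tsv), "duplicate")
})

test_that("transcript model writing round-trips exactly in both formats", {
  set.seed(7)
  tx <- bind_rows(lapply(1:3, function(i) random_tx(paste0("t", i))))
  tx$tissues <- list(c("root", "pollen"), "ear", character())
  for (fmt in c("gff3", "bed12")) {
    path <- withr::local_tempfile(fileext = if (fmt == "gff3") ".gff3" else ".bed")
    write_transcript_models(tx, path, fmt)
    back <- read_transcript_models(path)
    back <- back[match(tx$transcript_id, back$transcript_id), ]
    expect_equal(back$exon_starts, tx$exon_starts)
    expect_equal(back$exon_ends, tx$exon_ends)
    expect_equal(back$strand, tx$strand)
    # byte-stability after one normalization pass
    path2 <- withr::local_tempfile()
    write_transcript_models(back, path2, fmt)
    if (fmt == "bed12") expect_identical(readLines(path), readLines(path2))
  }
  # GFF3 carries quality and tissue attributes through
  path <- withr::local_tempfile(fileext = ".gff3")
  tx$coverage <- c(0.9, 1, 0.87)
  write_transcript_models(tx, path, "gff3")
  back <- read_transcript_models(path)
  back <- back[match(tx$transcript_id, back$transcript_id), ]
  expect_equal(back$coverage, tx$coverage)
  expect_equal(back$tissues[[1]], c("root", "pollen"))
  path2 <- withr::local_tempfile()
  write_transcript_models(back, path2, "gff3")
  expect_identical(readLines(path), readLines(path2))
})

test_that("multilocus alignment and homology tables round-trip", {
  aln <- tibble(
    query_id = "q1", read_length = 1000L, q_start = 0L, q_end = 600L,
    chrom = "c1", strand = "+", exon_starts = list(c(10L, 200L)),
    exon_ends = list(c(100L, 400L)), identity = 0.99)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_multilocus_alignments(aln, p)
  back <- read_multilocus_alignments(p)
  expect_equal(back$exon_starts, aln$exon_starts)
  expect_equal(back$read_length, 1000L)

  hits <- tibble(query_id = "t1", subject_db = "TE", subject_id = "x",
                 e_value = 1e-12, coverage = 0.9, identity = 0.95,
                 subject_class = "Gypsy")
  write_homology_hits(hits, p)
  expect_equal(read_homology_hits(p)$e_value, 1e-12)
  writeLines("t1\tTE\tx\t1e-12\t1.4\t0.95\tGypsy", p)
  expect_error(read_homology_hits(p), "0, 1")
})
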