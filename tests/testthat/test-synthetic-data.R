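small_cfg <- function(seed = 13) {
  sim_config(seed = seed, n_genes = 24, chromosome_length = 300000L,
             category_counts = c(a = 4, b = 4, c = 4, d = 4, e = 4, f = 4,
                                 g = 4, h = 4),
             n_as_events = 10, n_degraded = 3, n_qc_decoys = 4,
             n_fusions_true = 6, n_fusions_decoy = 8,
             n_fusions_concordance_decoy = 2,
             n_lncrnas = c(intergenic = 4, antisense = 2, sense = 2, intronic = 1),
             n_lncrna_decoys = c(short = 2, coding = 2, homology = 2, known = 2),
             n_te = 2, read_depth = 5L)
}

test_that("identical configurations give byte-identical datasets", {
  s1 <- simulate_dataset(small_cfg())
  s2 <- simulate_dataset(small_cfg())
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$methylation, s2$methylation)
  expect_identical(s1$truth, s2$truth)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(s1, d1); write_dataset(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # different seed changes the data
  s3 <- simulate_dataset(small_cfg(seed = 14))
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
})

test_that("simulated genome base composition is uniform", {
  cfg <- sim_config(seed = 4, n_chromosomes = 1, chromosome_length = 100000L)
  g <- simulate_genome(cfg)
  freq <- Biostrings::letterFrequency(g[[1]], c("A", "C", "G", "T"))
  p <- freq / 100000
  expect_true(all(abs(p - 0.25) < 3 * sqrt(0.25 * 0.75 / 100000)))
  expect_equal(length(simulate_genome(sim_config(n_chromosomes = 3))), 3L)
  expect_error(sim_config(chromosome_length = 5000), "10 kb")
})

test_that("annotation respects the isoform-count configuration", {
  cfg1 <- sim_config(seed = 6, n_genes = 15,
                     isoform_count_weights = c(`1` = 1, `2-10` = 0, `>=20` = 0))
  ann1 <- simulate_annotation(cfg1, simulate_genome(cfg1))
  expect_true(all(ann1$gene_info$n_isoforms[!ann1$gene_info$small] == 1L))
  # overcrowding is rejected with a clear error
  cfg_full <- sim_config(seed = 6, chromosome_length = 10000L, n_genes = 50)
  expect_error(simulate_annotation(cfg_full, simulate_genome(cfg_full)),
               "too short")
})

test_that("ground truth covers every emitted read exactly once", {
  sim <- simulate_dataset(small_cfg())
  tr <- sim$truth
  ids <- c(tr$categories$transcript_id, tr$degraded$transcript_id,
           tr$qc_decoys$transcript_id, tr$te$transcript_id,
           tr$as_events$isoform_1, tr$as_events$isoform_2)
  expect_setequal(ids, sim$reads$transcript_id)
  expect_equal(anyDuplicated(ids), 0L)
  expect_setequal(sim$truth$lncrna$transcript_id,
                  sim$lncrna$lncrnas$transcript_id)
  expect_setequal(sim$truth$fusion$query_id,
                  unique(sim$fusion$alignments$query_id))
})

test_that("junction evidence honours the planted extremes", {
  cfg1 <- small_cfg()
  cfg1$junction_support_fraction <- 1
  ann <- simulate_annotation(cfg1, simulate_genome(cfg1))
  reads <- simulate_isoform_reads(cfg1, ann)
  ev1 <- simulate_junction_evidence(cfg1, reads$reads)
  expect_true(all(ev1$evidence$read_count >= 1))
  expect_equal(nrow(ev1$evidence), nrow(ev1$truth))
  cfg0 <- small_cfg()
  cfg0$junction_support_fraction <- 0
  ev0 <- simulate_junction_evidence(cfg0, reads$reads)
  expect_equal(nrow(ev0$evidence), 0L)
})

test_that("written fixtures read back to the in-memory objects", {
  sim <- simulate_dataset(small_cfg())
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_identical(as.character(g), as.character(sim$genome))
  ann <- read_transcript_models(file.path(dir, "annotation.gff3"))
  ann <- ann[match(sim$annotation$transcript_id, ann$transcript_id), ]
  expect_equal(ann$exon_starts, sim$annotation$exon_starts)
  expect_equal(ann$gene_id, sim$annotation$gene_id)
  reads <- read_transcript_models(file.path(dir, "reads.gff3"))
  reads <- reads[match(sim$reads$transcript_id, reads$transcript_id), ]
  expect_equal(reads$tissues, sim$reads$tissues)
  expect_equal(reads$coverage, sim$reads$coverage)
  ev_file <- list.files(dir, pattern = "^evidence_root", full.names = TRUE)
  ev <- read_junction_evidence(ev_file, "star_sj_tab", tissue = "root")
  orig <- sim$evidence %>% filter(.data$tissue == "root")
  expect_equal(nrow(ev), nrow(orig))
  expect_setequal(paste(ev$chrom, ev$intron_start, ev$intron_end, ev$read_count),
                  paste(orig$chrom, orig$intron_start, orig$intron_end,
                        orig$read_count))
  meth <- read_methylation(file.path(dir, "methylation.tsv"))
  expect_equal(nrow(meth), nrow(sim$methylation))
})
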