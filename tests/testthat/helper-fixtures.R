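suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# one shared synthetic study fixture per test run (no methylation table:
# methylation tests build their own smaller, junction-dense fixture)
.fixture_env <- new.env()

std_fixture <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- sim_config(seed = 42)
    genome0 <- simulate_genome(cfg)
    ann <- simulate_annotation(cfg, genome0)
    lnc <- simulate_lncrnas(cfg, ann)
    reads <- simulate_isoform_reads(cfg, ann)
    fus <- simulate_fusions(cfg, ann)
    ev <- simulate_junction_evidence(cfg, reads$reads)
    .fixture_env$sim <- list(
      cfg = cfg, genome = lnc$genome, ann = ann, lnc = lnc, reads = reads,
      fus = fus, ev = ev, index = annotation_index(ann$annotation)
    )
  }
  .fixture_env$sim
}

# minimal transcript constructor for hand fixtures
mk_tx <- function(id, chrom, strand, starts, ends, ...) {
  tx_tbl(transcript_id = id, chrom = chrom, strand = strand,
         exon_starts = starts, exon_ends = ends, ...)
}

# random multi-exon transcript on a virtual chromosome of length len
random_tx <- function(id, len = 10000L, n_ex = sample(3:6, 1),
                      chrom = "c1", strand = sample(c("+", "-"), 1)) {
  pos <- sort(sample(seq(10L, len - 10L), 2L * n_ex))
  mk_tx(id, chrom, strand, pos[seq(1, 2 * n_ex, 2)], pos[seq(2, 2 * n_ex, 2)])
}

# mirror a transcript through position L (strand flip): coordinates reverse
mirror_tx <- function(tx, L) {
  tx %>% mutate(
    strand = ifelse(.data$strand == "+", "-", "+"),
    new_starts = purrr::map(.data$exon_ends, ~ rev(L - .x)),
    exon_ends = purrr::map(.data$exon_starts, ~ rev(L - .x)),
    exon_starts = .data$new_starts
  ) %>% select(-"new_starts")
}

# random single-difference perturbation of a transcript (guards keep the
# exon chain valid; an inapplicable op returns the transcript unchanged)
perturb_tx <- function(t1, shift = 3L) {
  s <- t1$exon_starts[[1]]; e <- t1$exon_ends[[1]]; m <- length(s)
  op <- sample(c("a3", "a5", "drop", "merge"), 1)
  j <- sample(m - 1, 1)
  if (op == "a3" && e[j + 1] - s[j + 1] > shift + 1) s[j + 1] <- s[j + 1] + shift
  if (op == "a5" && e[j] - s[j] > shift + 1) e[j] <- e[j] - shift
  if (op == "drop" && m >= 3) { k <- sample(2:(m - 1), 1); s <- s[-k]; e <- e[-k] }
  if (op == "merge") { e <- e[-j]; s <- s[-(j + 1)] }
  mk_tx("perturbed", t1$chrom, t1$strand, s, e)
}

# independent six-frame ORF oracle: translate every frame and regex-scan for
# M...* runs (a different algorithm from the package's codon walk)
oracle_orf <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  for (st in c("+", "-")) {
    s <- if (st == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    for (f in 0:2) {
      sub <- substr(s, f + 1, n - ((n - f) %% 3))
      if (nchar(sub) < 6) next
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(sub), no.init.codon = TRUE, if.fuzzy.codon = "X")))
      m <- gregexpr("M[^*]*\\*", aa)[[1]]
      if (m[1] == -1) next
      best <- max(best, attr(m, "match.length") - 1L)
    }
  }
  best
}

# a small written study fixture shared by the pipeline and acceptance tests
pipeline_fixture <- function() {
  if (is.null(.fixture_env$pipe)) {
    cfg <- sim_config(seed = 21, n_genes = 24, chromosome_length = 300000L,
                      category_counts = c(a = 4, b = 4, c = 4, d = 4, e = 4,
                                          f = 4, g = 4, h = 4),
                      n_as_events = 8, n_degraded = 3, n_qc_decoys = 4,
                      n_fusions_true = 6, n_fusions_decoy = 8,
                      n_fusions_concordance_decoy = 2,
                      n_lncrnas = c(intergenic = 4, antisense = 2, sense = 2,
                                    intronic = 1),
                      n_lncrna_decoys = c(short = 2, coding = 2, homology = 2,
                                          known = 2),
                      n_te = 2, read_depth = 5L)
    dir <- file.path(tempdir(), "isoscope_pipe_fixture")
    write_dataset(simulate_dataset(cfg), dir)
    .fixture_env$pipe <- dir
  }
  .fixture_env$pipe
}

fixture_config <- function(dir, outdir, ...) {
  ev_files <- list.files(dir, pattern = "^evidence_", full.names = TRUE)
  names(ev_files) <- sub("^evidence_(.*)[.]sj[.]tab$", "\\1", basename(ev_files))
  pipeline_config(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gff3"),
    reads = file.path(dir, "reads.gff3"),
    evidence = ev_files,
    fusion_alignments = file.path(dir, "fusion_alignments.tsv"),
    fusion_pairs = file.path(dir, "fusion_pairs.tsv"),
    lncrna_reads = file.path(dir, "lncrna.gff3"),
    homology_hits = file.path(dir, "homology_hits.tsv"),
    split_candidates = file.path(dir, "split_candidates.tsv"),
    outdir = outdir, seed = 5, ...)
}
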