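# independent six-frame ORF check used by the generator when engineering
# non-coding sequences (translate + regex; distinct from the codon-scan in
# longest_orf())
gen_orf_scan <- function(seq) {
  n <- nchar(seq)
  out <- list()
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
      for (k in seq_along(m)) {
        codons <- attr(m, "match.length")[k] - 1L
        out[[length(out) + 1]] <- tibble(
          strand = st, frame = f,
          nt_start = f + 3L * (m[k] - 1L),  # 0-based, on the scanned strand
          codons = codons)
      }
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(strand = character(), frame = integer(), nt_start = integer(),
           codons = integer())
}

# transcript position (0-based, 5'->3') to genomic position map
tx_pos_map <- function(strand, s, e) {
  g <- unlist(purrr::map2(s, e, ~ seq(.x, .y - 1L)))
  if (strand == "-") rev(g) else g
}

# write bases given in transcript orientation into the genome view
write_tx_bases <- function(env, chrom, strand, gmap, tpos0, bases) {
  gpos <- gmap[tpos0 + 1L]
  if (strand == "-") bases <- unname(complement_base[bases])
  set_bases(env, chrom, gpos, bases)
}

# destroy any ORF longer than max_codons by injecting in-frame stops,
# avoiding protected genomic positions (splice motifs)
ensure_noncoding <- function(env, chrom, strand, s, e, protected, max_codons = 100L) {
  gmap <- tx_pos_map(strand, s, e)
  n <- length(gmap)
  for (iter in 1:20) {
    chars <- get_bases(env, chrom, gmap)  # gmap is 5'->3', descending on '-'
    if (strand == "-") chars <- unname(complement_base[chars])
    seq <- paste(chars, collapse = "")
    orfs <- gen_orf_scan(seq)
    long <- orfs[orfs$codons > max_codons, , drop = FALSE]
    if (!nrow(orfs) || !nrow(long)) return(invisible(env))
    o <- long[which.max(long$codons), ]
    injected <- FALSE
    for (c_off in c(floor(o$codons / 2) + (0:5), 1:5)) {
      if (c_off >= o$codons) next
      p_on <- o$nt_start + 3L * c_off  # codon start on the scanned strand
      if (o$strand == "+") {
        tpos <- p_on + 0:2; bases <- c("T", "A", "A")
      } else {
        tpos <- (n - 1L - (p_on + 2L)) + 0:2; bases <- c("T", "T", "A")
      }
      if (any(tpos < 0 | tpos >= n)) next
      gpos <- gmap[tpos + 1L]
      if (any(gpos %in% protected)) next
      write_tx_bases(env, chrom, strand, gmap, tpos, bases)
      injected <- TRUE
      break
    }
    if (!injected) abort("could not engineer a non-coding sequence (protected positions)")
  }
  abort("failed to remove long ORFs after 20 injections")
}

#' Simulate lncRNAs of the four positional classes plus cascade decoys
#'
#' Plants true lncRNAs (length >= 200 bp, longest ORF <= 100 codons,
#' engineered by stop-codon injection) in intergenic space, antisense and
#' sense over gene exons, and inside long introns; and one decoy family per
#' cascade stage: too-short (150 bp), coding (planted 121-codon ORF),
#' protein-homology (hit to a grass proteome) and known-lncRNA (high-identity
#' hit) decoys. Edits the shared genome view so sequences extracted from the
#' returned genome reproduce the engineering.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()] (its genome view is updated
#'   in place).
#' @return List with `lncrnas` (transcript tibble), `sequences` (named
#'   character), `hits` (homology tibble), `genome` (updated `DNAStringSet`),
#'   `truth` (tibble `transcript_id`, `class`, `decoy`, `is_true`).
#' @export
simulate_lncrnas <- function(cfg, ann) {
  set.seed(cfg$seed + 6L)
  env <- ann$genome_env
  protected <- ann$motif_positions
  prot_of <- function(chrom) protected$pos[protected$chrom == chrom]
  gi <- ann$gene_info %>% filter(!.data$small)
  rows <- list(); truth <- list(); hits <- list()
  add_lnc <- function(id, chrom, strand, s, e, class, decoy = NA_character_) {
    rows[[length(rows) + 1]] <<- tibble(
      transcript_id = id, gene_id = NA_character_, chrom = chrom, strand = strand,
      exon_starts = list(as.integer(s)), exon_ends = list(as.integer(e)),
      coverage = 1, identity = 1, tissues = list(character()))
    truth[[length(truth) + 1]] <<- tibble(
      transcript_id = id, class = class, decoy = decoy, is_true = is.na(decoy))
  }
  make_noncoding <- function(chrom, strand, s, e) {
    ensure_noncoding(env, chrom, strand, s, e, prot_of(chrom))
  }

  # intergenic (≈40% two-exon), from the free tail space
  for (i in seq_len(cfg$n_lncrnas[["intergenic"]])) {
    id <- sprintf("lnc_ig_%03d", i)
    strand <- sample(c("+", "-"), 1)
    if (i %% 5 %in% c(1, 2)) {
      iv <- alloc_interval(ann$alloc, 420L)
      s <- c(iv$start, iv$start + 270L); e <- c(iv$start + 150L, iv$start + 420L)
    } else {
      iv <- alloc_interval(ann$alloc, sample(350:600, 1))
      s <- iv$start; e <- iv$end
    }
    make_noncoding(iv$chrom, strand, s, e)
    add_lnc(id, iv$chrom, strand, s, e, "intergenic")
  }
  # antisense / sense: overlap an internal exon and run into the intron
  gene_overlap_lnc <- function(i, same_strand, k) {
    g <- gi[((i * 3L) %% nrow(gi)) + 1L, ]
    p <- list(s = g$primary_starts[[1]], e = g$primary_ends[[1]])
    start <- p$e[k] - 60L
    strand <- if (same_strand) g$strand else if (g$strand == "+") "-" else "+"
    list(chrom = g$chrom, strand = strand, s = start, e = start + 260L)
  }
  for (i in seq_len(cfg$n_lncrnas[["antisense"]])) {
    l <- gene_overlap_lnc(i, FALSE, k = 2L)
    id <- sprintf("lnc_as_%03d", i)
    make_noncoding(l$chrom, l$strand, l$s, l$e)
    add_lnc(id, l$chrom, l$strand, l$s, l$e, "antisense")
  }
  for (i in seq_len(cfg$n_lncrnas[["sense"]])) {
    l <- gene_overlap_lnc(i + 50L, TRUE, k = 3L)
    id <- sprintf("lnc_se_%03d", i)
    make_noncoding(l$chrom, l$strand, l$s, l$e)
    add_lnc(id, l$chrom, l$strand, l$s, l$e, "sense")
  }
  # intronic: inside the long intron of genes taken from the list tail
  gi_rev <- gi %>% arrange(dplyr::desc(.data$gene_id))
  gcur <- 0L
  for (i in seq_len(cfg$n_lncrnas[["intronic"]])) {
    iv <- NULL
    while (is.null(iv) && gcur < nrow(gi_rev)) {
      gcur <- gcur + 1L
      g <- gi_rev[gcur, ]
      iv <- stable_intron_of(g, ann$annotation, min_len = 320L)
    }
    if (is.null(iv))
      abort("no uncovered intron long enough for an intronic lncRNA")
    a <- iv$start + 30L
    width <- min(280L, iv$len - 60L)
    id <- sprintf("lnc_in_%03d", i)
    strand <- sample(c("+", "-"), 1)
    make_noncoding(g$chrom, strand, a, a + width)
    add_lnc(id, g$chrom, strand, a, a + width, "intronic")
  }
  # decoys: each fails exactly one cascade stage
  for (i in seq_len(cfg$n_lncrna_decoys[["short"]])) {
    iv <- alloc_interval(ann$alloc, 150L)
    make_noncoding(iv$chrom, "+", iv$start, iv$end)
    add_lnc(sprintf("lnc_short_%03d", i), iv$chrom, "+", iv$start, iv$end,
            "intergenic", "short")
  }
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste, collapse = "")
  non_stop <- setdiff(all_codons, stop_codons)
  for (i in seq_len(cfg$n_lncrna_decoys[["coding"]])) {
    iv <- alloc_interval(ann$alloc, 500L)
    id <- sprintf("lnc_cds_%03d", i)
    orf <- paste0("ATG", paste(sample(non_stop, 120, replace = TRUE), collapse = ""), "TAA")
    gmap <- tx_pos_map("+", iv$start, iv$end)
    write_tx_bases(env, iv$chrom, "+", gmap, 10L + seq_len(nchar(orf)) - 1L,
                   strsplit(orf, "")[[1]])
    add_lnc(id, iv$chrom, "+", iv$start, iv$end, "intergenic", "coding")
  }
  for (i in seq_len(cfg$n_lncrna_decoys[["homology"]])) {
    iv <- alloc_interval(ann$alloc, 400L)
    id <- sprintf("lnc_hom_%03d", i)
    make_noncoding(iv$chrom, "+", iv$start, iv$end)
    add_lnc(id, iv$chrom, "+", iv$start, iv$end, "intergenic", "homology")
    hits[[length(hits) + 1]] <- tibble(
      query_id = id, subject_db = "sorghum", subject_id = sprintf("Sb_%03d", i),
      e_value = 1e-20, coverage = 0.9, identity = 0.8, subject_class = NA_character_)
  }
  for (i in seq_len(cfg$n_lncrna_decoys[["known"]])) {
    iv <- alloc_interval(ann$alloc, 400L)
    id <- sprintf("lnc_known_%03d", i)
    make_noncoding(iv$chrom, "+", iv$start, iv$end)
    add_lnc(id, iv$chrom, "+", iv$start, iv$end, "intergenic", "known")
    hits[[length(hits) + 1]] <- tibble(
      query_id = id, subject_db = "known_lncRNA", subject_id = sprintf("KL_%03d", i),
      e_value = 1e-30, coverage = 0.9, identity = 0.95, subject_class = NA_character_)
  }
  # a harmless borderline hit that must not eliminate its (true) candidate
  if (length(rows)) {
    hits[[length(hits) + 1]] <- tibble(
      query_id = rows[[1]]$transcript_id, subject_db = "sorghum",
      subject_id = "Sb_weak", e_value = 1e-4, coverage = 0.3, identity = 0.4,
      subject_class = NA_character_)
  }
  lnc <- bind_rows(rows)
  lnc$seq_length <- exonic_length(lnc)
  lnc$tissues <- rand_tissues(nrow(lnc), cfg$tissue_labels)
  validate_tx(lnc)
  genome <- genome_from_env(env)
  list(lncrnas = lnc, sequences = transcript_sequences(lnc, genome),
       hits = bind_rows(hits), genome = genome, truth = bind_rows(truth))
}

#' Simulate a complete study fixture
#'
#' Runs every generator in a fixed order with stage-specific streams derived
#' from the master seed, returning a fully consistent dataset: genome (with
#' splice motifs and engineered lncRNA sequences written in), annotation,
#' reads, fusion alignments and validation pairs, junction evidence,
#' methylation calls (planted from the annotation's junctions) and all
#' ground-truth tables. Identical configurations yield byte-identical
#' outputs.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `iso_sim_dataset`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  genome0 <- simulate_genome(cfg)
  ann <- simulate_annotation(cfg, genome0)
  lnc <- simulate_lncrnas(cfg, ann)
  genome <- lnc$genome
  reads <- simulate_isoform_reads(cfg, ann)
  fus <- simulate_fusions(cfg, ann)
  ev <- simulate_junction_evidence(cfg, reads$reads)
  meth <- simulate_methylation(cfg, genome, ann$annotation)
  structure(list(
    config = cfg,
    genome = genome,
    annotation = ann$annotation,
    gene_info = ann$gene_info,
    reads = reads$reads,
    lncrna = lnc,
    fusion = fus,
    evidence = ev$evidence,
    methylation = meth,
    hits = bind_rows(lnc$hits, reads$te_hits),
    truth = c(reads$truth,
              list(lncrna = lnc$truth, fusion = fus$truth,
                   junction_support = ev$truth))
  ), class = "iso_sim_dataset")
}

#' @export
print.iso_sim_dataset <- function(x, ...) {
  cat("<iso_sim_dataset> ", length(x$genome), " chromosomes, ",
      nrow(x$annotation), " annotated transcripts, ", nrow(x$reads),
      " reads, ", nrow(x$lncrna$lncrnas), " lncRNA candidates, ",
      length(unique(x$fusion$alignments$query_id)), " fusion queries\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to files
#'
#' Emits the fixture in the standard formats consumed by [run_pipeline()]:
#' `genome.fa`, `annotation.gff3`, `reads.gff3`, `lncrna.gff3`,
#' `fusion_alignments.tsv`, `fusion_pairs.tsv`, one STAR-style
#' `evidence_<tissue>.sj.tab` per tissue, `methylation.tsv`,
#' `homology_hits.tsv`, `split_candidates.tsv` and `truth.json`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_genome(sim$genome, fp("genome.fa"))
  write_transcript_models(sim$annotation, fp("annotation.gff3"), "gff3")
  write_transcript_models(sim$reads, fp("reads.gff3"), "gff3")
  write_transcript_models(sim$lncrna$lncrnas, fp("lncrna.gff3"), "gff3")
  write_multilocus_alignments(sim$fusion$alignments, fp("fusion_alignments.tsv"))
  readr::write_tsv(sim$fusion$pairs, fp("fusion_pairs.tsv"), progress = FALSE)
  for (t in unique(sim$evidence$tissue)) {
    ev <- sim$evidence %>% filter(.data$tissue == t)
    lines <- sprintf("%s\t%d\t%d\t%d\t0\t0\t%d\t0\t20",
                     ev$chrom, ev$intron_start + 1L, ev$intron_end,
                     ifelse(is.na(ev$strand), 0L, ifelse(ev$strand == "+", 1L, 2L)),
                     ev$read_count)
    writeLines(lines, fp(paste0("evidence_", t, ".sj.tab")))
  }
  write_methylation(sim$methylation, fp("methylation.tsv"))
  write_homology_hits(sim$hits, fp("homology_hits.tsv"))
  sc <- sim$truth$split_candidates %>%
    mutate(gene_ids = vapply(.data$gene_ids, paste, "", collapse = ","))
  readr::write_tsv(sc, fp("split_candidates.tsv"), progress = FALSE)
  truth <- sim$truth
  truth$split_candidates <- sc
  jsonlite::write_json(truth, fp("truth.json"), dataframe = "rows", na = "null")
  invisible(dir)
}
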