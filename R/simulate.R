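#' Simulation configuration
#'
#' Parameters of the synthetic study fixture. Defaults emulate the structure
#' of a multi-tissue long-read isoform survey at desk scale: a small
#' multi-chromosome genome, an annotation with multi-isoform genes, long-read
#' transcripts planted into each of the eight structural categories and the
#' five alternative-splicing modes, multi-locus fusion alignments satisfying
#' or violating each detection criterion, lncRNAs of the four positional
#' classes, short-read junction evidence with a controllable support
#' fraction, and per-cytosine methylation with planted donor/acceptor
#' context profiles. The same seed always yields byte-identical outputs.
#'
#' @param seed Integer master seed; every stage derives its stream from it.
#' @param n_chromosomes,chromosome_length Genome shape (>= 10 kb per
#'   chromosome).
#' @param n_genes Protein-coding-like genes (4-7 exons each); a few extra
#'   short mono-exon genes are added to host intron-containment plantings.
#' @param isoform_count_weights Probabilities over the strata
#'   `1`, `2-10`, `>=20` isoforms per gene.
#' @param gc_ag_fraction Fraction of donor sites written as GC (vs GT).
#' @param category_counts Named counts of planted reads per structural
#'   category `a`-`h`.
#' @param n_degraded 5'-degraded duplicates of planted full-match reads.
#' @param n_qc_decoys Low-quality decoys (coverage or identity below the
#'   85%/90% thresholds).
#' @param as_mode_mix Probabilities over the five AS modes for planted event
#'   pairs.
#' @param n_as_events Number of planted AS isoform pairs.
#' @param n_fusions_true,n_fusions_decoy,n_fusions_concordance_decoy Fusion
#'   plantings: true fusions satisfy all four criteria with breakpoints at
#'   annotated splice sites; criterion decoys each violate exactly one
#'   criterion; concordance decoys pass all four but have breakpoints shifted
#'   into an exon.
#' @param junction_support_fraction Bernoulli probability that a read
#'   junction receives short-read evidence in a tissue.
#' @param read_depth Methylation read depth per cytosine (0 = no table).
#' @param methylation_background,methylation_donor,methylation_acceptor Named
#'   per-context levels (CG/CHG/CHH); donor/acceptor levels apply to the
#'   50-bp intron side of the respective splice-site window.
#' @param n_lncrnas Named counts per positional class
#'   (intergenic/antisense/sense/intronic).
#' @param n_lncrna_decoys Named counts per decoy class
#'   (short/coding/homology/known), each failing exactly one cascade stage.
#' @param n_te Planted TE transcripts (screened out by homology hits).
#' @param tissue_labels Tissue names.
#' @return A validated list of class `iso_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chromosome_length = 600000L,
                       n_genes = 60L,
                       isoform_count_weights = c(`1` = 0.44, `2-10` = 0.46, `>=20` = 0.10),
                       gc_ag_fraction = 0,
                       category_counts = c(a = 25, b = 25, c = 25, d = 25,
                                           e = 25, f = 25, g = 25, h = 25),
                       n_degraded = 12L,
                       n_qc_decoys = 10L,
                       as_mode_mix = c(IR = 0.40, ES = 0.078, A3 = 0.19,
                                       A5 = 0.18, MXE = 0.152),
                       n_as_events = 40L,
                       n_fusions_true = 24L,
                       n_fusions_decoy = 36L,
                       n_fusions_concordance_decoy = 6L,
                       junction_support_fraction = 0.9,
                       read_depth = 20L,
                       methylation_background = c(CG = 0.2, CHG = 0.2, CHH = 0.2),
                       methylation_donor = c(CG = 0.5, CHG = 0.2, CHH = 0.2),
                       methylation_acceptor = c(CG = 0.2, CHG = 0.6, CHH = 0.2),
                       n_lncrnas = c(intergenic = 12, antisense = 5,
                                     sense = 4, intronic = 2),
                       n_lncrna_decoys = c(short = 5, coding = 5,
                                           homology = 5, known = 5),
                       n_te = 6L,
                       tissue_labels = c("root", "pollen", "embryo",
                                         "endosperm", "ear", "tassel")) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              n_genes = as.integer(n_genes),
              isoform_count_weights = isoform_count_weights,
              gc_ag_fraction = gc_ag_fraction,
              category_counts = category_counts,
              n_degraded = as.integer(n_degraded),
              n_qc_decoys = as.integer(n_qc_decoys),
              as_mode_mix = as_mode_mix, n_as_events = as.integer(n_as_events),
              n_fusions_true = as.integer(n_fusions_true),
              n_fusions_decoy = as.integer(n_fusions_decoy),
              n_fusions_concordance_decoy = as.integer(n_fusions_concordance_decoy),
              junction_support_fraction = junction_support_fraction,
              read_depth = as.integer(read_depth),
              methylation_background = methylation_background,
              methylation_donor = methylation_donor,
              methylation_acceptor = methylation_acceptor,
              n_lncrnas = n_lncrnas, n_lncrna_decoys = n_lncrna_decoys,
              n_te = as.integer(n_te),
              tissue_labels = tissue_labels)
  if (cfg$chromosome_length < 10000)
    abort("chromosome_length must be at least 10 kb to place features")
  if (abs(sum(cfg$isoform_count_weights) - 1) > 1e-8)
    abort("isoform_count_weights must sum to 1")
  if (abs(sum(cfg$as_mode_mix) - 1) > 1e-8) abort("as_mode_mix must sum to 1")
  if (any(unlist(cfg[c("category_counts", "n_lncrnas", "n_lncrna_decoys")]) < 0))
    abort("planted counts must be non-negative")
  if (cfg$junction_support_fraction < 0 || cfg$junction_support_fraction > 1)
    abort("junction_support_fraction must lie in [0, 1]")
  structure(cfg, class = "iso_sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Simulate a genome
#'
#' I.i.d. uniform bases from the seeded generator; deterministic per seed.
#'
#' @param cfg A [sim_config()].
#' @return A `DNAStringSet` with `n_chromosomes` entries.
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  seqs <- vapply(seq_len(cfg$n_chromosomes), function(i) rand_dna(cfg$chromosome_length), "")
  Biostrings::DNAStringSet(setNames(seqs, paste0("chr", seq_len(cfg$n_chromosomes))))
}

complement_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# mutable per-chromosome character-vector view of a genome, for planted edits
genome_env <- function(genome) {
  e <- new.env(parent = emptyenv())
  e$chars <- lapply(as.character(genome), function(s) strsplit(s, "")[[1]])
  names(e$chars) <- names(genome)
  e
}

genome_from_env <- function(e) {
  Biostrings::DNAStringSet(vapply(e$chars, paste, "", collapse = ""))
}

set_bases <- function(e, chrom, pos0, bases) {
  e$chars[[chrom]][pos0 + 1L] <- bases
  invisible(e)
}

get_bases <- function(e, chrom, pos0) e$chars[[chrom]][pos0 + 1L]

# write the canonical splice motif bases of one intron into the genome view
write_motif <- function(env, chrom, strand, intron_start, intron_end, gc = FALSE) {
  if (strand == "+") {
    set_bases(env, chrom, intron_start + 0:1, if (gc) c("G", "C") else c("G", "T"))
    set_bases(env, chrom, intron_end - 2:1, c("A", "G"))
  } else {
    set_bases(env, chrom, intron_end - 2:1, if (gc) c("G", "C") else c("A", "C"))
    set_bases(env, chrom, intron_start + 0:1, c("C", "T"))
  }
  invisible(env)
}

#' Simulate a reference annotation (and write splice motifs into the genome)
#'
#' Places non-overlapping genes with 2-kb flanks, each with 4-7 exons
#' (>= 110 bp) and introns >= 120 bp (one long intron >= 360 bp per gene),
#' draws the isoform count of each gene from the configured strata and builds
#' extra isoforms by exon-skipping and intron-retention edits of the primary
#' isoform (so all annotated junctions reuse motif-bearing splice sites).
#' Canonical GT..AG motifs (GC..AG for a `gc_ag_fraction` of donors) are
#' written into the genome at every annotated intron boundary. A handful of
#' short mono-exon genes are appended to host intron-containment plantings.
#'
#' @param cfg A [sim_config()].
#' @param genome Output of [simulate_genome()].
#' @return List with `annotation` (transcript tibble), `genome` (edited
#'   `DNAStringSet`), `gene_info` (per-gene geometry and isoform counts),
#'   `alloc` (internal allocator for intergenic plantings),
#'   `motif_positions` (protected genomic positions).
#' @export
simulate_annotation <- function(cfg, genome) {
  set.seed(cfg$seed + 1L)
  chroms <- names(genome)
  lens <- setNames(Biostrings::width(genome), chroms)
  env <- genome_env(genome)
  cursors <- setNames(rep(2000L, length(chroms)), chroms)

  n_small <- max(ceiling(unname(cfg$category_counts["e"]) / 2), 2L)
  gene_rows <- list(); ann_rows <- list()
  motif_pos <- list()
  strata_names <- names(cfg$isoform_count_weights)

  place_gene <- function(gi, small = FALSE, n_ex = NULL) {
    chrom <- chroms[((gi - 1L) %% length(chroms)) + 1L]
    if (small) {
      width <- sample(100:140, 1)
      ex_lens <- width; in_lens <- integer()
    } else {
      if (is.null(n_ex)) n_ex <- sample(4:7, 1)
      ex_lens <- sample(110:240, n_ex, replace = TRUE)
      in_lens <- sample(120:300, n_ex - 1, replace = TRUE)
      in_lens[sample(n_ex - 1, 1)] <- sample(360:450, 1)
    }
    span <- sum(ex_lens) + sum(in_lens)
    start <- cursors[[chrom]]
    if (start + span + 2000L > lens[[chrom]])
      abort(paste0("cannot place gene ", gi, " on ", chrom,
                   ": chromosome too short for the requested gene count"))
    cursors[[chrom]] <<- start + span + 3500L + sample(0:1500, 1)
    s <- integer(length(ex_lens)); e <- integer(length(ex_lens))
    p <- start
    for (k in seq_along(ex_lens)) {
      s[k] <- p; e[k] <- p + ex_lens[k]
      p <- e[k] + if (k < length(ex_lens)) in_lens[k] else 0L
    }
    list(chrom = chrom, strand = sample(c("+", "-"), 1), s = s, e = e)
  }

  gid <- function(i) sprintf("g%03d", i)
  total_genes <- cfg$n_genes + n_small
  for (gi in seq_len(total_genes)) {
    small <- gi > cfg$n_genes
    stratum <- if (small) "1" else sample(strata_names, 1, prob = cfg$isoform_count_weights)
    # high-isoform genes need enough exons to host 20+ distinct edit sets
    g <- place_gene(gi, small,
                    n_ex = if (!small && stratum == ">=20") sample(6:7, 1) else NULL)
    m <- length(g$s)
    if (small) {
      n_iso <- 1L
      iso_exons <- list(list(s = g$s, e = g$e))
    } else {
      n_iso <- switch(stratum, `1` = 1L, `2-10` = sample(2:10, 1),
                      `>=20` = sample(20:26, 1))
      # candidate edits: S = skipped internal exons, M = retained introns
      ops <- list()
      for (k in seq(2, m - 1)) ops[[length(ops) + 1]] <- list(S = k, M = integer())
      for (j in seq_len(m - 1)) ops[[length(ops) + 1]] <- list(S = integer(), M = j)
      singles <- ops
      combine_ops <- function(idx) {
        S <- sort(unique(unlist(purrr::map(singles[idx], "S"))))
        M <- sort(unique(unlist(purrr::map(singles[idx], "M"))))
        if (any(M %in% c(S - 1L, S))) return(NULL)  # retained intron must keep both exons
        if (length(S) + length(M) < length(idx)) return(NULL)
        list(S = S, M = M)
      }
      if (n_iso > length(singles) + 1) {
        for (p in utils::combn(length(singles), 2, simplify = FALSE)) {
          op <- combine_ops(p)
          if (!is.null(op)) ops[[length(ops) + 1]] <- op
        }
      }
      if (n_iso > length(ops) + 1 && length(singles) >= 3) {
        for (p in utils::combn(length(singles), 3, simplify = FALSE)) {
          op <- combine_ops(p)
          if (!is.null(op)) ops[[length(ops) + 1]] <- op
          if (length(ops) >= n_iso + 10) break
        }
      }
      take <- min(n_iso - 1L, length(ops))
      picked <- if (take > 0) ops[sample(length(ops), take)] else list()
      iso_exons <- c(list(list(s = g$s, e = g$e)),
                     purrr::map(picked, function(op) apply_edit(g$s, g$e, op$S, op$M)))
      # defensive chain dedup
      sig <- vapply(iso_exons, function(x) chain_string(x$s, x$e), "")
      iso_exons <- iso_exons[!duplicated(sig)]
      n_iso <- length(iso_exons)
    }
    gene_rows[[gi]] <- tibble(
      gene_id = gid(gi), chrom = g$chrom, strand = g$strand,
      start = g$s[1], end = g$e[m], n_exons = m,
      n_isoforms = n_iso, stratum = stratum, small = small,
      primary_starts = list(g$s), primary_ends = list(g$e)
    )
    for (k in seq_along(iso_exons)) {
      ann_rows[[length(ann_rows) + 1]] <- tibble(
        transcript_id = sprintf("%s.t%d", gid(gi), k), gene_id = gid(gi),
        chrom = g$chrom, strand = g$strand,
        exon_starts = list(iso_exons[[k]]$s), exon_ends = list(iso_exons[[k]]$e),
        coverage = 1, identity = 1, tissues = list(character())
      )
    }
  }
  annotation <- bind_rows(ann_rows)
  annotation$seq_length <- exonic_length(annotation)
  gene_info <- bind_rows(gene_rows)

  # motifs for every unique annotated junction; GC decided per donor site
  junc <- tx_junctions(annotation) %>%
    distinct(.data$chrom, .data$strand, .data$intron_start, .data$intron_end)
  donor_coord <- ifelse(junc$strand == "+", junc$intron_start, junc$intron_end)
  donor_key <- paste(junc$chrom, junc$strand, donor_coord)
  uk <- unique(donor_key)
  gc_of <- setNames(runif(length(uk)) < cfg$gc_ag_fraction, uk)
  for (i in seq_len(nrow(junc))) {
    write_motif(env, junc$chrom[i], junc$strand[i],
                junc$intron_start[i], junc$intron_end[i], gc = gc_of[[donor_key[i]]])
  }
  mp <- bind_rows(
    tibble(chrom = junc$chrom, pos = junc$intron_start),
    tibble(chrom = junc$chrom, pos = junc$intron_start + 1L),
    tibble(chrom = junc$chrom, pos = junc$intron_end - 2L),
    tibble(chrom = junc$chrom, pos = junc$intron_end - 1L)
  )

  alloc <- new.env(parent = emptyenv())
  alloc$cursors <- cursors
  alloc$lens <- lens
  alloc$i <- 0L
  list(annotation = annotation, genome = genome_from_env(env),
       genome_env = env, gene_info = gene_info, alloc = alloc,
       motif_positions = mp)
}

# apply an exon-skip / intron-retention edit set to a primary exon chain
apply_edit <- function(s, e, S, M) {
  keep <- setdiff(seq_along(s), S)
  out_s <- integer(); out_e <- integer()
  cur_s <- s[keep[1]]; cur_e <- e[keep[1]]
  if (length(keep) > 1) {
    for (idx in seq(2, length(keep))) {
      t <- keep[idx]; prev <- keep[idx - 1]
      if (t == prev + 1L && prev %in% M) {
        cur_e <- e[t]  # retained intron: merge across the boundary
      } else {
        out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e)
        cur_s <- s[t]; cur_e <- e[t]
      }
    }
  }
  list(s = c(out_s, cur_s), e = c(out_e, cur_e))
}

# allocate an intergenic interval from the free tail space, round-robin
alloc_interval <- function(alloc, width, chrom = NULL, margin = 500L) {
  chroms <- names(alloc$cursors)
  tries <- if (is.null(chrom)) {
    alloc$i <- alloc$i + 1L
    chroms[(seq_along(chroms) + alloc$i - 2L) %% length(chroms) + 1L]
  } else chrom
  for (ch in tries) {
    start <- alloc$cursors[[ch]] + margin
    if (start + width + margin <= alloc$lens[[ch]] - 500L) {
      alloc$cursors[[ch]] <- start + width
      return(list(chrom = ch, start = start, end = start + width))
    }
  }
  abort("no intergenic space left for allocation")
}

rand_tissues <- function(n, labels) {
  purrr::map(seq_len(n), ~ sort(sample(labels, sample(1:3, 1))))
}

# first intron of a gene's primary isoform that is >= min_len long and not
# covered by any exon of any annotated isoform of the gene (intron-retention
# variants cover introns with exons, so containment plantings must avoid them)
stable_intron_of <- function(g, annotation, min_len) {
  s <- g$primary_starts[[1]]; e <- g$primary_ends[[1]]
  if (length(s) < 2) return(NULL)
  ex <- tx_exons(annotation[annotation$gene_id == g$gene_id, ])
  for (j in seq_len(length(s) - 1)) {
    a <- e[j]; b <- s[j + 1]
    if (b - a < min_len) next
    if (any(ex$start < b & ex$end > a)) next
    return(list(start = a, end = b, len = b - a))
  }
  NULL
}
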