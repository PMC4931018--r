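#' Simulate long-read transcript models with planted structural categories
#'
#' Emits reads constructed to satisfy exactly one structural category each
#' under the classification ladder (see [classify_isoforms()]), plus
#' 5'-degraded duplicates of full-match reads (identical junctions, shorter
#' first exon), low-quality decoys below the coverage/identity thresholds,
#' planted alternative-splicing isoform pairs for each of the five modes, and
#' a few transposable-element reads with matching homology hits.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return List with `reads` (transcript tibble), `te_hits` (homology tibble)
#'   and `truth` (list of tibbles: `categories`, `degraded`, `qc_decoys`,
#'   `as_events`, `te`, `split_candidates`, `read_gene`).
#' @export
simulate_isoform_reads <- function(cfg, ann) {
  set.seed(cfg$seed + 2L)
  gi <- ann$gene_info %>% filter(!.data$small)
  small_genes <- ann$gene_info %>% filter(.data$small)
  n_norm <- nrow(gi)
  ann_chains <- tx_chain(ann$annotation)
  rows <- list(); cat_truth <- list()

  add_read <- function(id, gene_id, chrom, strand, s, e, coverage = 1, identity = 1) {
    rows[[length(rows) + 1]] <<- tibble(
      transcript_id = id, gene_id = gene_id, chrom = chrom, strand = strand,
      exon_starts = list(as.integer(s)), exon_ends = list(as.integer(e)),
      coverage = coverage, identity = identity, tissues = list(character())
    )
  }
  add_cat <- function(id, grp, gene_id = NA_character_, subtype = NA_character_) {
    cat_truth[[length(cat_truth) + 1]] <<- tibble(
      transcript_id = id, group = grp, gene_id = gene_id, subtype = subtype)
  }
  primary <- function(g) list(s = g$primary_starts[[1]], e = g$primary_ends[[1]])
  cyc <- function(i, n) ((i - 1L) %% n) + 1L
  stable_intron <- function(g, annotation, min_len) stable_intron_of(g, annotation, min_len)
  cc <- cfg$category_counts

  # a: novel intergenic loci (two-exon)
  for (i in seq_len(cc[["a"]])) {
    iv <- alloc_interval(ann$alloc, 500L)
    id <- sprintf("read_a_%03d", i)
    add_read(id, NA, iv$chrom, sample(c("+", "-"), 1),
             c(iv$start, iv$start + 350L), c(iv$start + 150L, iv$start + 500L))
    add_cat(id, "a")
  }
  # b: novel isoform — one internal acceptor shifted 13 bp into the exon
  for (i in seq_len(cc[["b"]])) {
    g <- gi[cyc(i, n_norm), ]; p <- primary(g)
    j <- 2L  # shift the boundary of exon j+1
    s <- p$s; e <- p$e; s[j + 1] <- s[j + 1] + 13L
    id <- sprintf("read_b_%03d", i)
    add_read(id, g$gene_id, g$chrom, g$strand, s, e)
    add_cat(id, "b", g$gene_id)
  }
  # c: identical chain to an annotated isoform
  iso_pool <- ann$annotation %>% filter(n_exons(ann$annotation) >= 2)
  pick <- sample(nrow(iso_pool), min(cc[["c"]], nrow(iso_pool)))
  c_parents <- character()
  for (i in seq_along(pick)) {
    t <- iso_pool[pick[i], ]
    id <- sprintf("read_c_%03d", i)
    add_read(id, t$gene_id, t$chrom, t$strand, t$exon_starts[[1]], t$exon_ends[[1]])
    add_cat(id, "c", t$gene_id)
    c_parents <- c(c_parents, id)
  }
  # d: mono-exon read inside exon 2, same strand
  for (i in seq_len(cc[["d"]])) {
    g <- gi[cyc(i, n_norm), ]; p <- primary(g)
    a <- p$s[2] + 15L
    id <- sprintf("read_d_%03d", i)
    add_read(id, g$gene_id, g$chrom, g$strand, a, a + 80L)
    add_cat(id, "d", g$gene_id)
  }
  # e (read inside annotated intron): mono-exon read in an intron that no
  # isoform of the gene (e.g. an intron-retention variant) covers with an exon
  n_e_read <- ceiling(cc[["e"]] / 2)
  gene_cursor <- 0L
  for (i in seq_len(n_e_read)) {
    placed <- FALSE
    for (try in seq_len(n_norm)) {
      gene_cursor <- gene_cursor + 1L
      g <- gi[cyc(gene_cursor, n_norm), ]; p <- primary(g)
      iv <- stable_intron(g, ann$annotation, min_len = 260L)
      if (is.null(iv)) next
      a <- iv$start + 80L
      id <- sprintf("read_ei_%03d", i)
      add_read(id, g$gene_id, g$chrom, g$strand, a, a + min(100L, iv$len - 160L))
      add_cat(id, "e", g$gene_id, "read_inside_annotation")
      placed <- TRUE
      break
    }
    if (!placed) abort("no uncovered intron available for an intron-contained read")
  }
  # e (annotation inside read intron): read spanning a short mono-exon gene
  n_e_anno <- cc[["e"]] - n_e_read
  for (i in seq_len(n_e_anno)) {
    g <- small_genes[cyc(i, nrow(small_genes)), ]
    id <- sprintf("read_ea_%03d", i)
    add_read(id, g$gene_id, g$chrom, g$strand,
             c(g$start - 400L, g$end + 250L), c(g$start - 250L, g$end + 400L))
    add_cat(id, "e", g$gene_id, "annotation_inside_read")
  }
  # f: mono-exon read inside exon 3, opposite strand
  for (i in seq_len(cc[["f"]])) {
    g <- gi[cyc(i, n_norm), ]; p <- primary(g)
    a <- p$s[3] + 15L
    id <- sprintf("read_f_%03d", i)
    add_read(id, g$gene_id, g$chrom, if (g$strand == "+") "-" else "+", a, a + 80L)
    add_cat(id, "f", g$gene_id)
  }
  # g: contiguous proper sub-chain (5'-truncated), guarded against chance
  # collisions with an annotated variant chain
  g_cursor <- 0L
  for (i in seq_len(cc[["g"]])) {
    placed <- FALSE
    for (try in seq_len(n_norm)) {
      g_cursor <- g_cursor + 1L
      g <- gi[cyc(g_cursor, n_norm), ]; p <- primary(g); m <- length(p$s)
      wins <- list()
      for (w in seq(m - 1L, 2L)) for (i0 in seq_len(m - w + 1L)) {
        wins[[length(wins) + 1]] <- c(i0, i0 + w - 1L)
      }
      for (win in wins) {
        i0 <- win[1]; i1 <- win[2]
        s <- p$s[i0:i1]; e <- p$e[i0:i1]
        if (g$strand == "+") s[1] <- s[1] + 15L else e[length(e)] <- e[length(e)] - 15L
        cand <- paste(g$chrom, g$strand, chain_string(s, e), sep = "|")
        if (cand %in% ann_chains) next
        id <- sprintf("read_g_%03d", i)
        add_read(id, g$gene_id, g$chrom, g$strand, s, e)
        add_cat(id, "g", g$gene_id)
        placed <- TRUE
        break
      }
      if (placed) break
    }
    if (!placed) abort("could not construct any partial-match read")
  }
  # h: read covering two adjacent same-strand genes with both junction sets
  gi_sorted <- gi %>% arrange(.data$chrom, .data$start)
  pair_idx <- which(gi_sorted$chrom[-nrow(gi_sorted)] == gi_sorted$chrom[-1] &
                      gi_sorted$strand[-nrow(gi_sorted)] == gi_sorted$strand[-1])
  if (!length(pair_idx) && cc[["h"]] > 0)
    abort("no adjacent same-strand gene pair available for multi-gene reads")
  used_pairs <- list()
  for (i in seq_len(cc[["h"]])) {
    k <- pair_idx[cyc(i, length(pair_idx))]
    g1 <- gi_sorted[k, ]; g2 <- gi_sorted[k + 1, ]
    p1 <- primary(g1); p2 <- primary(g2)
    s <- c(p1$s, p2$s); e <- c(p1$e, p2$e)
    off <- 7L * ((i - 1L) %/% length(pair_idx))  # distinguish reuses at the 5' end
    if (g1$strand == "+") s[1] <- s[1] + off else e[length(e)] <- e[length(e)] - off
    id <- sprintf("read_h_%03d", i)
    add_read(id, g1$gene_id, g1$chrom, g1$strand, s, e)
    add_cat(id, "h", g1$gene_id)
    used_pairs[[paste(g1$gene_id, g2$gene_id)]] <- c(g1$gene_id, g2$gene_id)
  }
  unused <- setdiff(pair_idx, pair_idx[vapply(seq_len(min(cc[["h"]], length(pair_idx))), cyc,
                                              1L, n = length(pair_idx))])
  no_read_pairs <- purrr::map(utils::head(unused, 3), function(k) {
    c(gi_sorted$gene_id[k], gi_sorted$gene_id[k + 1])
  })
  split_candidates <- tibble(
    candidate_id = sprintf("split_%03d", seq_len(length(used_pairs) + length(no_read_pairs))),
    gene_ids = c(unname(used_pairs), no_read_pairs),
    expect = c(rep("confirmed", length(used_pairs)), rep("no_read", length(no_read_pairs)))
  )

  reads <- bind_rows(rows)
  categories <- bind_rows(cat_truth)

  # 5'-degraded duplicates of full-match reads
  degraded <- list()
  for (i in seq_len(min(cfg$n_degraded, length(c_parents)))) {
    parent <- reads[reads$transcript_id == c_parents[i], ]
    s <- parent$exon_starts[[1]]; e <- parent$exon_ends[[1]]
    off <- sample(10:40, 1)
    if (parent$strand == "+") s[1] <- s[1] + off else e[length(e)] <- e[length(e)] - off
    id <- sprintf("read_deg_%03d", i)
    reads <- bind_rows(reads, parent %>%
                         mutate(transcript_id = id,
                                exon_starts = list(as.integer(s)),
                                exon_ends = list(as.integer(e))))
    degraded[[i]] <- tibble(transcript_id = id, parent_id = c_parents[i])
  }
  # low-quality decoys
  qc <- list()
  for (i in seq_len(cfg$n_qc_decoys)) {
    t <- iso_pool[sample(nrow(iso_pool), 1), ]
    low_cov <- i %% 2 == 0
    id <- sprintf("read_lowq_%03d", i)
    reads <- bind_rows(reads, tibble(
      transcript_id = id, gene_id = t$gene_id, chrom = t$chrom, strand = t$strand,
      exon_starts = t$exon_starts, exon_ends = t$exon_ends,
      coverage = if (low_cov) 0.80 else 1, identity = if (low_cov) 1 else 0.80,
      tissues = list(character())
    ))
    qc[[i]] <- tibble(transcript_id = id,
                      reason = if (low_cov) "low_coverage" else "low_identity")
  }
  # planted alternative-splicing pairs
  modes <- sample(names(cfg$as_mode_mix), cfg$n_as_events, replace = TRUE,
                  prob = cfg$as_mode_mix)
  as_truth <- list()
  for (i in seq_along(modes)) {
    mode <- modes[i]
    g <- gi[cyc(i + 5L, n_norm), ]
    p <- primary(g); m <- length(p$s)
    iso2 <- switch(mode,
      IR = apply_edit(p$s, p$e, integer(), sample(m - 1, 1)),
      ES = apply_edit(p$s, p$e, sample(2:(m - 1), 1), integer()),
      A3 = {
        j <- sample(m - 1, 1); s <- p$s; e <- p$e
        if (g$strand == "+") s[j + 1] <- s[j + 1] + 12L else e[j] <- e[j] - 12L
        list(s = s, e = e)
      },
      A5 = {
        j <- sample(m - 1, 1); s <- p$s; e <- p$e
        if (g$strand == "+") e[j] <- e[j] - 12L else s[j + 1] <- s[j + 1] + 12L
        list(s = s, e = e)
      },
      MXE = {
        k <- if (m >= 5) sample(2:(m - 2), 1) else 2L
        list(pair = TRUE, k = k)
      })
    id1 <- sprintf("read_as_%03d_1", i); id2 <- sprintf("read_as_%03d_2", i)
    if (mode == "MXE") {
      k <- iso2$k
      e1 <- apply_edit(p$s, p$e, k + 1L, integer())
      e2 <- apply_edit(p$s, p$e, k, integer())
      add_read2 <- function(id, x) {
        reads <<- bind_rows(reads, tibble(
          transcript_id = id, gene_id = g$gene_id, chrom = g$chrom,
          strand = g$strand, exon_starts = list(as.integer(x$s)),
          exon_ends = list(as.integer(x$e)),
          coverage = 1, identity = 1, tissues = list(character())))
      }
      add_read2(id1, e1); add_read2(id2, e2)
    } else {
      reads <- bind_rows(reads, tibble(
        transcript_id = id1, gene_id = g$gene_id, chrom = g$chrom,
        strand = g$strand, exon_starts = list(as.integer(p$s)),
        exon_ends = list(as.integer(p$e)),
        coverage = 1, identity = 1, tissues = list(character())))
      reads <- bind_rows(reads, tibble(
        transcript_id = id2, gene_id = g$gene_id, chrom = g$chrom,
        strand = g$strand, exon_starts = list(as.integer(iso2$s)),
        exon_ends = list(as.integer(iso2$e)),
        coverage = 1, identity = 1, tissues = list(character())))
    }
    as_truth[[i]] <- tibble(event_id = sprintf("as_%03d", i), gene_id = g$gene_id,
                            mode = mode, isoform_1 = id1, isoform_2 = id2)
  }
  # transposable-element reads plus hits passing the screen thresholds
  te_rows <- list(); te_hits <- list()
  te_classes <- c("Gypsy", "Copia", "TIR", "LINE", "unknown")
  for (i in seq_len(cfg$n_te)) {
    iv <- alloc_interval(ann$alloc, 300L)
    id <- sprintf("read_te_%03d", i)
    reads <- bind_rows(reads, tibble(
      transcript_id = id, gene_id = NA_character_, chrom = iv$chrom,
      strand = "+", exon_starts = list(iv$start), exon_ends = list(iv$end),
      coverage = 1, identity = 1, tissues = list(character())))
    te_rows[[i]] <- tibble(transcript_id = id,
                           superfamily = te_classes[cyc(i, length(te_classes))])
    te_hits[[i]] <- tibble(query_id = id, subject_db = "TE",
                           subject_id = sprintf("TE%03d", i),
                           e_value = 1e-12, coverage = 0.92, identity = 0.95,
                           subject_class = te_classes[cyc(i, length(te_classes))])
  }
  # near-miss TE hits that must NOT flag their reads
  if (length(c_parents) >= 2) {
    te_hits[[length(te_hits) + 1]] <- tibble(
      query_id = c_parents[1:2], subject_db = "TE",
      subject_id = c("TEx1", "TEx2"),
      e_value = c(1e-12, 1e-5), coverage = c(0.50, 0.95),
      identity = c(0.95, 0.95), subject_class = "Gypsy")
  }

  reads$tissues <- rand_tissues(nrow(reads), cfg$tissue_labels)
  reads$seq_length <- exonic_length(reads)
  validate_tx(reads)
  read_gene <- reads %>% select("transcript_id", "gene_id")
  list(
    reads = reads,
    te_hits = bind_rows(te_hits),
    truth = list(
      categories = categories,
      degraded = bind_rows(degraded),
      qc_decoys = bind_rows(qc),
      as_events = bind_rows(as_truth),
      te = bind_rows(te_rows),
      split_candidates = split_candidates,
      read_gene = read_gene
    )
  )
}

#' Simulate multi-locus fusion alignments with planted criterion outcomes
#'
#' True fusions join the transcript-5' half of one gene to the transcript-3'
#' half of another (different chromosomes, or the same chromosome far apart),
#' with breakpoints placed exactly at annotated splice sites, full combined
#' read coverage and balanced per-locus fractions. Each decoy violates
#' exactly one criterion: a single-locus alignment, a locus at 8% of the
#' read, 95% combined coverage, or two loci under 100 kb apart. Concordance
#' decoys pass all four criteria but their breakpoint is shifted 7 bp into an
#' exon. Paired-end validation evidence is emitted for a subset of true
#' fusions.
#'
#' @param cfg A [sim_config()].
#' @param ann Output of [simulate_annotation()].
#' @return List with `alignments` (multi-locus tibble), `pairs` (validation
#'   evidence) and `truth`.
#' @export
simulate_fusions <- function(cfg, ann) {
  set.seed(cfg$seed + 3L)
  gi <- ann$gene_info %>% filter(!.data$small)
  aln <- list(); pairs <- list(); truth <- list()
  tx5_part <- function(g, trim = 0L) {
    s <- g$primary_starts[[1]]; e <- g$primary_ends[[1]]; m <- length(s)
    k <- max(1L, floor(m / 2))
    if (g$strand == "+") {
      idx <- 1:k; e2 <- e[idx]; e2[k] <- e2[k] - trim
      list(s = s[idx], e = e2)
    } else {
      idx <- (m - k + 1):m; s2 <- s[idx]; s2[1] <- s2[1] + trim
      list(s = s2, e = e[idx])
    }
  }
  tx3_part <- function(g) {
    s <- g$primary_starts[[1]]; e <- g$primary_ends[[1]]; m <- length(s)
    k <- max(1L, floor(m / 2))
    if (g$strand == "+") list(s = s[(m - k + 1):m], e = e[(m - k + 1):m])
    else list(s = s[1:k], e = e[1:k])
  }
  add_locus <- function(qid, L, q0, q1, g, part, identity = 0.99) {
    aln[[length(aln) + 1]] <<- tibble(
      query_id = qid, read_length = as.integer(L),
      q_start = as.integer(q0), q_end = as.integer(q1),
      chrom = g$chrom, strand = g$strand,
      exon_starts = list(as.integer(part$s)), exon_ends = list(as.integer(part$e)),
      identity = identity)
  }
  add_pair <- function(pid, type, c1, a1, b1, c2, a2, b2, unique) {
    pairs[[length(pairs) + 1]] <<- tibble(
      pair_id = pid, type = type, chrom1 = c1, start1 = as.integer(a1),
      end1 = as.integer(b1), chrom2 = c2, start2 = as.integer(a2),
      end2 = as.integer(b2), unique = unique)
  }
  plen <- function(p) sum(p$e - p$s)
  pick_pair <- function(i, cross = TRUE) {
    if (cross) {
      ga <- gi[((i - 1L) %% nrow(gi)) + 1L, ]
      others <- gi %>% filter(.data$chrom != ga$chrom)
      gb <- others[((i * 7L) %% nrow(others)) + 1L, ]
    } else {
      cand <- gi %>% group_by(.data$chrom) %>%
        filter(n() >= 2) %>% arrange(.data$start) %>%
        summarise(ga = first(.data$gene_id), gb = dplyr::last(.data$gene_id),
                  gap = dplyr::last(.data$start) - first(.data$end), .groups = "drop") %>%
        filter(.data$gap >= 110000)
      if (!nrow(cand)) return(NULL)
      r <- cand[((i - 1L) %% nrow(cand)) + 1L, ]
      ga <- gi[gi$gene_id == r$ga, ]; gb <- gi[gi$gene_id == r$gb, ]
    }
    list(ga = ga, gb = gb)
  }

  for (i in seq_len(cfg$n_fusions_true)) {
    cross <- i %% 3 != 0
    pr <- pick_pair(i, cross)
    if (is.null(pr)) pr <- pick_pair(i, TRUE)
    pa <- tx5_part(pr$ga); pb <- tx3_part(pr$gb)
    qa <- plen(pa); qb <- plen(pb); L <- qa + qb
    qid <- sprintf("fusT_%03d", i)
    add_locus(qid, L, 0, qa, pr$ga, pa)
    add_locus(qid, L, qa, L, pr$gb, pb)
    validated <- i %% 4 != 0
    if (validated) {
      for (r in 1:2) {
        add_pair(sprintf("%s_p%d", qid, r), "pair",
                 pr$ga$chrom, pa$s[1] + 10, pa$s[1] + 110,
                 pr$gb$chrom, pb$s[1] + 10, pb$s[1] + 110, TRUE)
      }
      add_pair(sprintf("%s_sp", qid), "spanning",
               pr$ga$chrom, pa$s[1] + 10, pa$s[1] + 110,
               pr$gb$chrom, pb$s[1] + 10, pb$s[1] + 110, TRUE)
    } else {
      add_pair(sprintf("%s_mm", qid), "pair",
               pr$ga$chrom, pa$s[1] + 10, pa$s[1] + 110,
               pr$gb$chrom, pb$s[1] + 10, pb$s[1] + 110, FALSE)
    }
    truth[[length(truth) + 1]] <- tibble(
      query_id = qid, class = "true", passes = TRUE, violated = NA_character_,
      concordant = TRUE, validated = NA,
      inter_chromosomal = pr$ga$chrom != pr$gb$chrom)
  }

  n_per <- ceiling(cfg$n_fusions_decoy / 4)
  decoy_classes <- rep(c("single_locus", "locus_fraction", "combined_coverage",
                         "separation"), each = n_per)[seq_len(cfg$n_fusions_decoy)]
  for (i in seq_along(decoy_classes)) {
    cls <- decoy_classes[i]
    qid <- sprintf("fusD_%03d", i)
    if (cls == "single_locus") {
      g <- gi[((i - 1L) %% nrow(gi)) + 1L, ]
      p <- list(s = g$primary_starts[[1]], e = g$primary_ends[[1]])
      add_locus(qid, plen(p), 0, plen(p), g, p)
      vio <- "multi_locus"
    } else if (cls == "locus_fraction") {
      pr <- pick_pair(i + 31L, TRUE)
      pb <- tx3_part(pr$gb); qb <- plen(pb)
      a <- max(20L, round(0.08 / 0.92 * qb))
      s1 <- pr$ga$primary_starts[[1]][1]
      pa <- list(s = s1, e = s1 + a)
      L <- a + qb
      add_locus(qid, L, 0, a, pr$ga, pa)
      add_locus(qid, L, a, L, pr$gb, pb)
      vio <- "per_locus_min_fraction"
    } else if (cls == "combined_coverage") {
      pr <- pick_pair(i + 57L, TRUE)
      pa <- tx5_part(pr$ga); pb <- tx3_part(pr$gb)
      qa <- plen(pa); qb <- plen(pb)
      L <- round((qa + qb) / 0.95)
      add_locus(qid, L, 0, qa, pr$ga, pa)
      add_locus(qid, L, L - qb, L, pr$gb, pb)
      vio <- "combined_coverage_ok"
    } else {
      # nearby loci must not be mergeable, so use an opposite-strand neighbour
      near <- gi %>% arrange(.data$chrom, .data$start)
      ks <- which(near$chrom[-nrow(near)] == near$chrom[-1] &
                    near$strand[-nrow(near)] != near$strand[-1])
      if (!length(ks)) abort("no opposite-strand adjacent gene pair for a separation decoy")
      k <- ks[((i - 1L) %% length(ks)) + 1L]
      ga <- near[k, ]; gb <- near[k + 1, ]
      pa <- tx5_part(ga); pb <- tx3_part(gb)
      qa <- plen(pa); qb <- plen(pb); L <- qa + qb
      add_locus(qid, L, 0, qa, ga, pa)
      add_locus(qid, L, qa, L, gb, pb)
      vio <- "min_separation_ok"
    }
    truth[[length(truth) + 1]] <- tibble(
      query_id = qid, class = paste0("decoy_", cls), passes = FALSE,
      violated = vio, concordant = NA, validated = NA,
      inter_chromosomal = NA)
  }

  for (i in seq_len(cfg$n_fusions_concordance_decoy)) {
    pr <- pick_pair(i + 83L, TRUE)
    pa <- tx5_part(pr$ga, trim = 7L); pb <- tx3_part(pr$gb)
    qa <- plen(pa); qb <- plen(pb); L <- qa + qb
    qid <- sprintf("fusX_%03d", i)
    add_locus(qid, L, 0, qa, pr$ga, pa)
    add_locus(qid, L, qa, L, pr$gb, pb)
    truth[[length(truth) + 1]] <- tibble(
      query_id = qid, class = "decoy_breakpoint", passes = TRUE,
      violated = NA_character_, concordant = FALSE, validated = NA,
      inter_chromosomal = pr$ga$chrom != pr$gb$chrom)
  }

  alignments <- bind_rows(aln)
  pairs <- bind_rows(pairs)
  truth <- bind_rows(truth)
  # ground-truth validation by direct interval arithmetic: fusions sharing a
  # gene pair legitimately validate each other, so the label is computed from
  # the emitted evidence, not from intent
  for (r in which(truth$class == "true")) {
    l <- alignments[alignments$query_id == truth$query_id[r], ]
    ext <- tibble(chrom = l$chrom,
                  start = purrr::map_int(l$exon_starts, ~ .x[1]),
                  end = purrr::map_int(l$exon_ends, ~ .x[length(.x)]))
    in_locus <- function(ch, a, b) which(ext$chrom == ch & ext$start < b & ext$end > a)
    ok <- FALSE
    for (p in seq_len(nrow(pairs))) {
      if (!isTRUE(pairs$unique[p])) next
      h1 <- in_locus(pairs$chrom1[p], pairs$start1[p], pairs$end1[p])
      h2 <- in_locus(pairs$chrom2[p], pairs$start2[p], pairs$end2[p])
      if (length(h1) && length(h2) && length(setdiff(h2, h1))) { ok <- TRUE; break }
    }
    truth$validated[r] <- ok
  }
  list(alignments = alignments, pairs = pairs, truth = truth)
}

#' Simulate short-read junction evidence with a planted support fraction
#'
#' Each distinct (tissue, junction) pair among the reads' junctions receives
#' evidence with probability `junction_support_fraction`; supported junctions
#' get `1 + Poisson(5)` reads, unsupported junctions are absent from the
#' evidence.
#'
#' @param cfg A [sim_config()].
#' @param tx Transcript tibble whose junctions are to be covered.
#' @return List with `evidence` (junction-evidence tibble) and `truth`
#'   (all tissue-junctions with a `supported` flag).
#' @export
simulate_junction_evidence <- function(cfg, tx) {
  set.seed(cfg$seed + 4L)
  j <- tx_junctions(tx) %>%
    left_join(tx %>% select("transcript_id", "tissues"), by = "transcript_id") %>%
    tidyr::unnest("tissues") %>%
    rename(tissue = "tissues") %>%
    distinct(.data$tissue, .data$chrom, .data$strand,
             .data$intron_start, .data$intron_end) %>%
    arrange(.data$tissue, .data$chrom, .data$intron_start, .data$intron_end)
  j$supported <- runif(nrow(j)) < cfg$junction_support_fraction
  j$read_count <- ifelse(j$supported, 1L + rpois(nrow(j), 5), 0L)
  evidence <- j %>%
    filter(.data$supported) %>%
    select("chrom", "strand", "intron_start", "intron_end", "read_count", "tissue")
  list(evidence = evidence, truth = j)
}

#' Simulate per-cytosine methylation with planted splice-site profiles
#'
#' Every genomic cytosine on both strands receives its context from the
#' genome sequence and a true methylation level: the configured background
#' per context, overridden on the 50-bp intron side of donor and acceptor
#' windows of the supplied transcripts' junctions by the donor/acceptor
#' profiles. Counts are Binomial(`read_depth`, level) per site.
#'
#' @param cfg A [sim_config()].
#' @param genome The (motif-edited) genome.
#' @param tx Transcripts whose junctions define the planted windows.
#' @param flank Window half-width (default 50, matching [stack_junctions()]).
#' @return A methylation tibble (see [read_methylation()]); empty when
#'   `read_depth` is 0.
#' @export
simulate_methylation <- function(cfg, genome, tx, flank = 50L) {
  set.seed(cfg$seed + 5L)
  empty <- tibble(chrom = character(), pos = integer(), strand = character(),
                  context = character(), count_c = integer(), count_t = integer())
  if (cfg$read_depth <= 0) return(empty)
  sites <- purrr::imap(as.list(as.character(genome)), function(s, chr) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    ip <- which(ch == "C"); ip <- ip[ip <= n - 2]
    im <- which(ch == "G"); im <- im[im >= 3]
    ctx_p <- ifelse(ch[ip + 1] == "G", "CG", ifelse(ch[ip + 2] == "G", "CHG", "CHH"))
    ctx_m <- ifelse(ch[im - 1] == "C", "CG", ifelse(ch[im - 2] == "C", "CHG", "CHH"))
    bind_rows(
      tibble(chrom = chr, pos = ip - 1L, strand = "+", context = ctx_p),
      tibble(chrom = chr, pos = im - 1L, strand = "-", context = ctx_m)
    )
  }) %>% bind_rows() %>% arrange(.data$chrom, .data$pos, .data$strand)

  level <- unname(cfg$methylation_background[sites$context])
  j <- tx_junctions(tx) %>%
    distinct(.data$chrom, .data$strand, .data$intron_start, .data$intron_end)
  if (nrow(j)) {
    donor_win <- tibble(
      chrom = j$chrom,
      start = ifelse(j$strand == "+", j$intron_start, j$intron_end - flank),
      end = ifelse(j$strand == "+", j$intron_start + flank, j$intron_end)
    )
    acceptor_win <- tibble(
      chrom = j$chrom,
      start = ifelse(j$strand == "+", j$intron_end - flank, j$intron_start),
      end = ifelse(j$strand == "+", j$intron_end, j$intron_start + flank)
    )
    site_gr <- GenomicRanges::GRanges(sites$chrom,
                                      IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
    assign_win <- function(win, prof) {
      gr <- GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$start + 1L, win$end))
      hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(site_gr, gr)))
      level[hit] <<- unname(prof[sites$context[hit]])
    }
    assign_win(donor_win, cfg$methylation_donor)
    assign_win(acceptor_win, cfg$methylation_acceptor)
  }
  count_c <- rbinom(nrow(sites), cfg$read_depth, level)
  sites$count_c <- count_c
  sites$count_t <- cfg$read_depth - count_c
  sites
}
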