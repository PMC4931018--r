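#' Merge a query's alignment segments into loci
#'
#' Same-chromosome, same-strand alignment segments of one query whose
#' genomic extents lie closer than `merge_gap` are merged into a single
#' locus (query spans kept as an interval set, exons pooled). After merging,
#' any two loci of a query are either on different chromosomes or at least
#' `merge_gap` apart (or on opposite strands, which are never merged). The
#' operation is idempotent and independent of input order.
#'
#' @param aln Multi-locus alignment tibble (see
#'   [read_multilocus_alignments()]); may contain several queries.
#' @param merge_gap Genomic gap below which segments merge, in bases
#'   (default 100 kb).
#' @return A locus tibble: `query_id`, `locus_id`, `chrom`, `strand`,
#'   `start`, `end` (genomic extent), `q_intervals` (list of 2-column
#'   matrices of 0-based half-open read intervals), `exon_starts`,
#'   `exon_ends`, `identity` (max over segments), `read_length`.
#' @export
cluster_loci <- function(aln, merge_gap = 1e5) {
  out <- purrr::map(split(aln, aln$query_id), function(a) {
    a <- a %>%
      mutate(g_start = purrr::map_int(.data$exon_starts, ~ .x[1]),
             g_end = purrr::map_int(.data$exon_ends, ~ .x[length(.x)])) %>%
      arrange(.data$chrom, .data$strand, .data$g_start, .data$g_end, .data$q_start)
    grp <- integer(nrow(a)); cur <- 0L; hi <- -Inf; last_key <- ""
    for (i in seq_len(nrow(a))) {
      key <- paste(a$chrom[i], a$strand[i])
      if (key != last_key || a$g_start[i] - hi >= merge_gap) {
        cur <- cur + 1L; hi <- a$g_end[i]; last_key <- key
      } else hi <- max(hi, a$g_end[i])
      grp[i] <- cur
    }
    a$grp <- grp
    a %>%
      group_by(.data$grp) %>%
      summarise(
        query_id = first(.data$query_id),
        chrom = first(.data$chrom), strand = first(.data$strand),
        start = min(.data$g_start), end = max(.data$g_end),
        q_intervals = list(cbind(.data$q_start, .data$q_end)),
        exon_starts = list(sort(unlist(.data$exon_starts))),
        exon_ends = list(sort(unlist(.data$exon_ends))),
        identity = max(.data$identity),
        read_length = first(.data$read_length),
        .groups = "drop"
      ) %>%
      arrange(.data$chrom, .data$start) %>%
      mutate(locus_id = paste0(.data$query_id, ":L", row_number())) %>%
      select(-"grp")
  })
  bind_rows(out)
}

interval_union_length <- function(mat) {
  if (!nrow(mat)) return(0L)
  o <- order(mat[, 1], mat[, 2])
  s <- mat[o, 1]; e <- mat[o, 2]
  tot <- 0L; lo <- s[1]; hi <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > hi) { tot <- tot + (hi - lo); lo <- s[i]; hi <- e[i] }
    else hi <- max(hi, e[i])
  }
  tot + (hi - lo)
}

#' Evaluate fusion-transcript criteria
#'
#' Applies the four fusion criteria to each query's merged loci:
#' (a) the read maps to two or more loci; (b) every locus covers at least
#' `min_locus_fraction` of the read; (c) the union of the loci's read spans
#' covers at least `min_combined_coverage` of the read (overlaps counted
#' once); (d) every pair of loci is on different chromosomes or at least
#' `min_separation` apart (extent gap, closest edges). A candidate passes iff
#' all four hold; passing candidates are classed inter- or intra-chromosomal.
#'
#' @param loci Output of [cluster_loci()].
#' @param min_locus_fraction,min_combined_coverage Fractions of the read
#'   length (defaults 0.10 and 0.99).
#' @param min_separation Minimum locus separation in bases (default 100 kb).
#' @return Tibble per query: criterion booleans `multi_locus`,
#'   `per_locus_min_fraction`, `combined_coverage_ok`, `min_separation_ok`,
#'   measured `min_locus_frac` and `combined_coverage`, `passes`,
#'   `classification` (`inter_chromosomal`/`intra_chromosomal`, `NA` for
#'   non-passing), `n_loci`.
#' @export
evaluate_fusions <- function(loci, min_locus_fraction = 0.10,
                             min_combined_coverage = 0.99,
                             min_separation = 1e5) {
  out <- purrr::map(split(loci, loci$query_id), function(l) {
    L <- l$read_length[1]
    if (is.na(L) || L <= 0) abort(paste0("zero read length for query ", l$query_id[1]))
    frac <- vapply(l$q_intervals, interval_union_length, 1L) / L
    comb <- interval_union_length(do.call(rbind, l$q_intervals)) / L
    sep_ok <- TRUE
    if (nrow(l) >= 2) {
      for (i in seq_len(nrow(l) - 1)) for (j in seq(i + 1, nrow(l))) {
        if (l$chrom[i] == l$chrom[j]) {
          gap <- max(l$start[i], l$start[j]) - min(l$end[i], l$end[j])
          if (gap < min_separation) sep_ok <- FALSE
        }
      }
    }
    crit <- c(
      multi_locus = nrow(l) >= 2,
      per_locus_min_fraction = all(frac >= min_locus_fraction),
      combined_coverage_ok = comb >= min_combined_coverage,
      min_separation_ok = sep_ok
    )
    passes <- all(crit)
    tibble(
      query_id = l$query_id[1],
      n_loci = nrow(l),
      multi_locus = crit[["multi_locus"]],
      per_locus_min_fraction = crit[["per_locus_min_fraction"]],
      combined_coverage_ok = crit[["combined_coverage_ok"]],
      min_separation_ok = crit[["min_separation_ok"]],
      min_locus_frac = min(frac),
      combined_coverage = comb,
      passes = passes,
      classification = if (!passes) NA_character_
        else if (length(unique(l$chrom)) > 1) "inter_chromosomal"
        else "intra_chromosomal"
    )
  })
  bind_rows(out) %>% arrange(.data$query_id)
}

#' Breakpoint splice-site concordance
#'
#' For each passing candidate the loci are ordered along the read; at every
#' internal breakpoint the genomic boundary of each flanking locus adjacent
#' to the breakpoint is compared with known splice sites: an exon-end edge
#' must coincide with a known intron start (donor side in genomic
#' coordinates) and an exon-start edge with a known intron end. A candidate
#' is concordant iff every breakpoint-adjacent boundary matches exactly.
#'
#' @param fusions Output of [evaluate_fusions()].
#' @param loci Output of [cluster_loci()].
#' @param known_junctions Tibble with `chrom`, `intron_start`, `intron_end`
#'   (e.g. `tx_junctions()` of the non-fused isoform set or annotation).
#' @return `fusions` with added `breakpoint_concordant` (logical; `NA` for
#'   non-passing candidates) and `breakpoint_detail` (list of per-boundary
#'   tibbles).
#' @export
breakpoint_concordance <- function(fusions, loci, known_junctions) {
  donor_sites <- paste(known_junctions$chrom, known_junctions$intron_start)
  acceptor_sites <- paste(known_junctions$chrom, known_junctions$intron_end)
  res <- purrr::map(seq_len(nrow(fusions)), function(i) {
    if (!fusions$passes[i]) {
      return(list(concordant = NA, detail = tibble()))
    }
    l <- loci[loci$query_id == fusions$query_id[i], ]
    q_lo <- vapply(l$q_intervals, function(m) min(m[, 1]), 1L)
    l <- l[order(q_lo), ]
    k <- nrow(l)
    rows <- list()
    for (b in seq_len(k - 1)) {
      # query-end side of locus b and query-start side of locus b+1
      up <- l[b, ]; down <- l[b + 1, ]
      up_edge <- if (up$strand == "+") {
        list(coord = max(up$exon_ends[[1]]), type = "exon_end")
      } else list(coord = min(up$exon_starts[[1]]), type = "exon_start")
      down_edge <- if (down$strand == "+") {
        list(coord = min(down$exon_starts[[1]]), type = "exon_start")
      } else list(coord = max(down$exon_ends[[1]]), type = "exon_end")
      for (e in list(c(up$chrom, up_edge$coord, up_edge$type),
                     c(down$chrom, down_edge$coord, down_edge$type))) {
        key <- paste(e[1], e[2])
        ok <- if (e[3] == "exon_end") key %in% donor_sites else key %in% acceptor_sites
        rows[[length(rows) + 1]] <- tibble(
          breakpoint = b, chrom = e[1], coord = as.integer(e[2]),
          edge = e[3], matches_splice_site = ok
        )
      }
    }
    detail <- bind_rows(rows)
    list(concordant = all(detail$matches_splice_site), detail = detail)
  })
  fusions$breakpoint_concordant <- purrr::map_lgl(res, ~ as.logical(.x$concordant))
  fusions$breakpoint_detail <- purrr::map(res, "detail")
  fusions
}

#' Validate fusion candidates with short-read evidence
#'
#' A candidate is supported when at least one uniquely-mapping evidence
#' record places its two segments in two *different* loci of the candidate:
#' discordant read pairs (`type = "pair"`) and split junction-spanning reads
#' (`type = "spanning"`) both qualify; non-unique records never do.
#'
#' @param fusions Output of [evaluate_fusions()] (optionally after
#'   [breakpoint_concordance()]).
#' @param loci Output of [cluster_loci()].
#' @param pairs Evidence tibble: `pair_id`, `type` (`pair`/`spanning`),
#'   `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2` (0-based
#'   half-open), `unique` (logical).
#' @return `fusions` with `n_discordant_pairs`, `n_spanning_reads`,
#'   `supported` columns added.
#' @export
validate_with_short_reads <- function(fusions, loci, pairs) {
  hit_locus <- function(chrom, start, end, l) {
    which(l$chrom == chrom & l$start < end & l$end > start)
  }
  res <- purrr::map(seq_len(nrow(fusions)), function(i) {
    l <- loci[loci$query_id == fusions$query_id[i], ]
    np <- 0L; ns <- 0L
    if (nrow(pairs)) {
      for (r in seq_len(nrow(pairs))) {
        if (!isTRUE(pairs$unique[r])) next
        h1 <- hit_locus(pairs$chrom1[r], pairs$start1[r], pairs$end1[r], l)
        h2 <- hit_locus(pairs$chrom2[r], pairs$start2[r], pairs$end2[r], l)
        if (length(h1) && length(h2) && length(setdiff(h2, h1)) > 0) {
          if (pairs$type[r] == "spanning") ns <- ns + 1L else np <- np + 1L
        }
      }
    }
    tibble(n_discordant_pairs = np, n_spanning_reads = ns,
           supported = (np + ns) > 0)
  })
  bind_cols(fusions, bind_rows(res))
}
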