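#' Per-site methylation level
#'
#' The methylation level of a cytosine is `C / (C + T)` over bisulfite read
#' counts; sites with zero total count are undefined (`NA`) and are excluded
#' from any pooling.
#'
#' @param count_c,count_t Non-negative integer vectors.
#' @return Numeric vector of levels in `[0, 1]`, `NA` where `C + T = 0`.
#' @export
site_level <- function(count_c, count_t) {
  if (any(count_c < 0 | count_t < 0, na.rm = TRUE))
    abort("negative methylation counts")
  tot <- count_c + count_t
  ifelse(tot > 0, count_c / tot, NA_real_)
}

# relative-position -> genomic-position map for one site class.
# rel in -flank..-1 (transcript-5' side of the boundary) and 1..flank
# (transcript-3' side); donor boundary sits at the intron 5' end,
# acceptor at the intron 3' end, both in transcript orientation.
junction_window_positions <- function(junctions, site_class, flank) {
  rel <- c(-(flank:1), 1:flank)
  n <- nrow(junctions)
  rep_rel <- rep(rel, times = n)
  idx <- rep(seq_len(n), each = length(rel))
  strand <- junctions$strand[idx]
  is_ex <- rep_rel < 0  # exonic side for donor, intronic side for acceptor
  if (site_class == "donor") {
    anchor_plus <- junctions$intron_start[idx]
    anchor_minus <- junctions$intron_end[idx]
    pos <- ifelse(strand == "+",
                  ifelse(is_ex, anchor_plus + rep_rel, anchor_plus + rep_rel - 1L),
                  ifelse(is_ex, anchor_minus - rep_rel - 1L, anchor_minus - rep_rel))
  } else {
    anchor_plus <- junctions$intron_end[idx]
    anchor_minus <- junctions$intron_start[idx]
    pos <- ifelse(strand == "+",
                  ifelse(is_ex, anchor_plus + rep_rel, anchor_plus + rep_rel - 1L),
                  ifelse(is_ex, anchor_minus - rep_rel - 1L, anchor_minus - rep_rel))
  }
  tibble(
    chrom = junctions$chrom[idx],
    jstrand = strand,
    position = rep_rel,
    pos = as.integer(pos),
    site_class = site_class
  )
}

#' Stacked methylation profiles at splice donor and acceptor sites
#'
#' Stacks deduplicated junctions in transcript orientation (`-` strand
#' junctions coordinate-mirrored) and pools per-cytosine counts at each
#' relative position: for donors, positions -50..-1 are exonic and +1..+50
#' intronic; for acceptors, -50..-1 intronic and +1..+50 exonic. Pooling is
#' count-weighted (`sum C / sum (C+T)`), per context (CG/CHG/CHH) and per
#' cytosine strand relative to the transcript (`sense`, `antisense`), plus a
#' `combined` track whose counts are exactly the sense + antisense sums.
#'
#' @param junctions Tibble `chrom`, `strand`, `intron_start`, `intron_end`
#'   (strand required; duplicates removed before stacking).
#' @param meth Methylation tibble (see [read_methylation()]).
#' @param flank Window half-width in bases (default 50).
#' @param min_depth Minimum `C + T` for a site to contribute (default 1).
#' @param chrom_lengths Optional named vector; junctions whose windows extend
#'   past a chromosome end are skipped with a warning.
#' @return An object of class `iso_junction_profile`: tibble `site_class`,
#'   `position` (-flank..-1, 1..flank), `context`, `strand_rel`
#'   (sense/antisense/combined), `sum_c`, `sum_ct`, `level`.
#' @export
stack_junctions <- function(junctions, meth, flank = 50, min_depth = 1,
                            chrom_lengths = NULL) {
  j <- junctions %>%
    distinct(.data$chrom, .data$strand, .data$intron_start, .data$intron_end)
  if (any(is.na(j$strand))) abort("junction strand must be known for stacking")
  if (!is.null(chrom_lengths)) {
    lo <- pmin(j$intron_start - flank, j$intron_start)
    hi <- pmax(j$intron_end + flank, j$intron_end)
    bad <- lo < 0 | hi > chrom_lengths[j$chrom]
    if (any(bad)) {
      warn(paste0(sum(bad), " junction(s) with windows past chromosome ends skipped"))
      j <- j[!bad, , drop = FALSE]
    }
  }
  win <- bind_rows(
    junction_window_positions(j, "donor", flank),
    junction_window_positions(j, "acceptor", flank)
  )
  m <- meth %>% filter(.data$count_c + .data$count_t >= min_depth)
  hits <- win %>%
    inner_join(m, by = c("chrom", "pos"), relationship = "many-to-many") %>%
    mutate(strand_rel = if_else(.data$strand == .data$jstrand, "sense", "antisense"))
  prof <- hits %>%
    group_by(.data$site_class, .data$position, .data$context, .data$strand_rel) %>%
    summarise(sum_c = sum(.data$count_c),
              sum_ct = sum(.data$count_c + .data$count_t), .groups = "drop")
  combined <- prof %>%
    group_by(.data$site_class, .data$position, .data$context) %>%
    summarise(sum_c = sum(.data$sum_c), sum_ct = sum(.data$sum_ct),
              .groups = "drop") %>%
    mutate(strand_rel = "combined")
  out <- bind_rows(prof, combined) %>%
    tidyr::complete(
      site_class = c("donor", "acceptor"),
      position = c(-(flank:1), 1:flank),
      context = methylation_contexts,
      strand_rel = c("sense", "antisense", "combined"),
      fill = list(sum_c = 0L, sum_ct = 0L)
    ) %>%
    mutate(level = ifelse(.data$sum_ct > 0, .data$sum_c / .data$sum_ct, NA_real_)) %>%
    arrange(.data$site_class, .data$context, .data$strand_rel, .data$position)
  structure(out, class = c("iso_junction_profile", class(out)))
}

#' Splice-site profiles stratified by isoforms per gene
#'
#' Routes each gene's junctions into the isoform-count stratum of its gene
#' (`1`, `2-10`, `>=20`) and computes one stacked profile per stratum.
#' Genes with 11-19 isoforms belong to no stratum and are reported in
#' `excluded_genes`.
#'
#' @param gene_counts Tibble `gene_id`, `n_isoforms`.
#' @param junctions Tibble `gene_id`, `chrom`, `strand`, `intron_start`,
#'   `intron_end` (all junctions of the genes' isoforms).
#' @param meth Methylation tibble.
#' @param ... Passed on to [stack_junctions()].
#' @return List with `profiles` (tibble with a `stratum` column prepended to
#'   the profile rows) and `excluded_genes` (character).
#' @export
stratify_by_isoform_count <- function(gene_counts, junctions, meth, ...) {
  gc <- gene_counts %>%
    mutate(stratum = case_when(
      .data$n_isoforms == 1 ~ "1",
      .data$n_isoforms >= 2 & .data$n_isoforms <= 10 ~ "2-10",
      .data$n_isoforms >= 20 ~ ">=20",
      TRUE ~ NA_character_
    ))
  excluded <- gc$gene_id[is.na(gc$stratum)]
  if (length(excluded))
    message(length(excluded), " gene(s) with 11-19 isoforms excluded from strata")
  j <- junctions %>%
    inner_join(gc %>% filter(!is.na(.data$stratum)) %>% select("gene_id", "stratum"),
               by = "gene_id")
  profiles <- purrr::map(split(j, j$stratum), function(jj) {
    p <- stack_junctions(jj, meth, ...)
    p$stratum <- jj$stratum[1]
    as_tibble(p)
  }) %>% bind_rows()
  list(profiles = profiles, excluded_genes = excluded)
}

#' Binned metagene methylation profile (TSS / body / TTS)
#'
#' Maps each transcript's upstream flank, body and downstream flank to
#' `bins` equal bins in transcript orientation (fractional bin edges; bodies
#' shorter than `bins` bases are assigned proportionally, not skipped) and
#' pools per-cytosine counts into bins across all transcripts of each group;
#' the level per bin and context is pooled `C / (C + T)`.
#'
#' @param tx Transcript tibble (extents are used; splicing is ignored).
#' @param meth Methylation tibble.
#' @param groups Optional tibble `transcript_id`, `group` (e.g. lncRNA vs
#'   non-lncRNA); defaults to a single group `all`.
#' @param upstream,downstream Flank sizes in bases (default 1 kb each).
#' @param bins Bins per region (default 100).
#' @return Tibble `group`, `region` (`upstream`/`body`/`downstream`), `bin`
#'   (1-based), `context`, `sum_c`, `sum_ct`, `level` — `3 * bins` bins per
#'   group and context.
#' @export
metagene_profile <- function(tx, meth, groups = NULL, upstream = 1000,
                             downstream = 1000, bins = 100) {
  xt <- tx_extent(tx)
  if (is.null(groups)) groups <- tibble(transcript_id = xt$transcript_id, group = "all")
  xt <- xt %>% inner_join(groups, by = "transcript_id")
  win_gr <- GenomicRanges::GRanges(
    xt$chrom,
    IRanges::IRanges(pmax(xt$start - upstream, 0) + 1L, xt$end + downstream)
  )
  m_gr <- GenomicRanges::GRanges(meth$chrom, IRanges::IRanges(meth$pos + 1L, meth$pos + 1L))
  ov <- GenomicRanges::findOverlaps(m_gr, win_gr)
  if (!length(ov)) {
    empty <- tidyr::expand_grid(group = unique(xt$group),
                                region = c("upstream", "body", "downstream"),
                                bin = seq_len(bins), context = methylation_contexts) %>%
      mutate(sum_c = 0L, sum_ct = 0L, level = NA_real_)
    return(empty)
  }
  d <- tibble(
    mi = S4Vectors::queryHits(ov),
    ti = S4Vectors::subjectHits(ov)
  )
  pos <- meth$pos[d$mi]
  start <- xt$start[d$ti]; end <- xt$end[d$ti]; strand <- xt$strand[d$ti]
  len <- end - start
  # transcript-oriented offset within each region
  up <- ifelse(strand == "+", pos < start, pos >= end)
  down <- ifelse(strand == "+", pos >= end, pos < start)
  body <- !up & !down
  off <- numeric(length(pos))
  off[up] <- ifelse(strand[up] == "+",
                    pos[up] - (start[up] - upstream),
                    end[up] + downstream - 1 - pos[up])
  off[body] <- ifelse(strand[body] == "+", pos[body] - start[body],
                      end[body] - 1 - pos[body])
  off[down] <- ifelse(strand[down] == "+", pos[down] - end[down],
                      start[down] - 1 - pos[down])
  reg_len <- numeric(length(pos))
  reg_len[up] <- upstream
  reg_len[body] <- len[body]
  reg_len[down] <- downstream
  keep <- off >= 0 & off < reg_len
  d <- tibble(
    group = xt$group[d$ti][keep],
    region = c("upstream", "body", "downstream")[1L + body[keep] + 2L * down[keep]],
    bin = pmin(bins, 1L + floor(off[keep] * bins / reg_len[keep])),
    context = meth$context[d$mi][keep],
    count_c = meth$count_c[d$mi][keep],
    count_t = meth$count_t[d$mi][keep]
  )
  d %>%
    group_by(.data$group, .data$region, .data$bin, .data$context) %>%
    summarise(sum_c = sum(.data$count_c),
              sum_ct = sum(.data$count_c + .data$count_t), .groups = "drop") %>%
    tidyr::complete(group = unique(xt$group),
                    region = c("upstream", "body", "downstream"),
                    bin = seq_len(bins), context = methylation_contexts,
                    fill = list(sum_c = 0L, sum_ct = 0L)) %>%
    mutate(level = ifelse(.data$sum_ct > 0, .data$sum_c / .data$sum_ct, NA_real_),
           region = factor(.data$region, levels = c("upstream", "body", "downstream"))) %>%
    arrange(.data$group, .data$context, .data$region, .data$bin)
}
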