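#' Pairwise alternative-splicing events between two isoforms
#'
#' Compares the intron chains of two overlapping isoforms of one gene and
#' classifies every localized difference into one of the five classical
#' modes, or `OTHER` when the difference matches no template:
#' \describe{
#'   \item{IR}{intron retention: an intron of one isoform fully contained in
#'     an exon of the other.}
#'   \item{ES}{exon skipping: an internal exon of one isoform absent from the
#'     other, outer flanking splice sites shared.}
#'   \item{A5 / A3}{alternative donor / acceptor: two junctions share one
#'     boundary and differ at the other; which mode applies is resolved by
#'     strand (the donor is the transcript-5' intron boundary).}
#'   \item{MXE}{mutually exclusive exons: two disjoint internal exons, each
#'     present in exactly one isoform, outer flanking sites shared.}
#' }
#' Differing junctions are grouped into clusters by genomic overlap and each
#' cluster yields exactly one event. Junctions extending beyond the shared
#' extent of the two isoforms (terminal-exon differences) are not events.
#'
#' @param t1,t2 One-row transcript tibbles on the same chromosome and strand.
#' @return A tibble of events: `mode`, `isoform_1`, `isoform_2`, `chrom`,
#'   `strand`, `start`, `end` (cluster span), `detail` (mode-specific
#'   coordinates). Zero rows when the chains are identical.
#' @export
pairwise_events <- function(t1, t2) {
  stopifnot(nrow(t1) == 1, nrow(t2) == 1)
  if (t1$chrom != t2$chrom || t1$strand != t2$strand)
    abort("pairwise_events requires the same chromosome and strand")
  strand <- t1$strand
  j1 <- tx_junctions(t1)
  j2 <- tx_junctions(t2)
  key1 <- paste(j1$intron_start, j1$intron_end)
  key2 <- paste(j2$intron_start, j2$intron_end)
  d1 <- j1[!key1 %in% key2, , drop = FALSE]
  d2 <- j2[!key2 %in% key1, , drop = FALSE]
  if (!nrow(d1) && !nrow(d2)) return(empty_events())

  shared_lo <- max(t1$exon_starts[[1]][1], t2$exon_starts[[1]][1])
  shared_hi <- min(tail(t1$exon_ends[[1]], 1), tail(t2$exon_ends[[1]], 1))
  keep <- function(d) d[d$intron_start >= shared_lo & d$intron_end <= shared_hi, , drop = FALSE]
  d1 <- keep(d1); d2 <- keep(d2)
  if (!nrow(d1) && !nrow(d2)) return(empty_events())

  allj <- bind_rows(
    d1 %>% mutate(side = 1L),
    d2 %>% mutate(side = 2L)
  ) %>% arrange(.data$intron_start, .data$intron_end)
  # single-linkage clustering by genomic overlap
  cl <- integer(nrow(allj)); cur <- 0L; hi <- -Inf
  for (i in seq_len(nrow(allj))) {
    if (allj$intron_start[i] >= hi) { cur <- cur + 1L; hi <- allj$intron_end[i] }
    else hi <- max(hi, allj$intron_end[i])
    cl[i] <- cur
  }
  allj$cluster <- cl

  in_exon <- function(t, a, b) {
    any(t$exon_starts[[1]] <= a & t$exon_ends[[1]] >= b)
  }
  events <- purrr::map(split(allj, allj$cluster), function(g) {
    g1 <- g[g$side == 1L, ]; g2 <- g[g$side == 2L, ]
    span <- c(min(g$intron_start), max(g$intron_end))
    mode <- "OTHER"; detail <- paste0("introns:", paste(g$intron_start, g$intron_end, sep = "-", collapse = ","))
    if (nrow(g1) == 0 || nrow(g2) == 0) {
      solo <- if (nrow(g1)) g1 else g2
      other <- if (nrow(g1)) t2 else t1
      if (nrow(solo) == 1 && in_exon(other, solo$intron_start, solo$intron_end)) {
        mode <- "IR"
        detail <- paste0("retained:", solo$intron_start, "-", solo$intron_end)
      }
    } else if (nrow(g1) == 1 && nrow(g2) == 1) {
      a <- g1; b <- g2
      same_start <- a$intron_start == b$intron_start
      same_end <- a$intron_end == b$intron_end
      if (xor(same_start, same_end)) {
        # the differing boundary is the donor on the strand-5' side
        donor_differs <- if (strand == "+") !same_start else !same_end
        mode <- if (donor_differs) "A5" else "A3"
        detail <- paste0("sites:", min(a$intron_start, b$intron_start), "/",
                         max(a$intron_start, b$intron_start), "-",
                         min(a$intron_end, b$intron_end), "/",
                         max(a$intron_end, b$intron_end))
      }
    } else if ((nrow(g1) == 2 && nrow(g2) == 1) || (nrow(g1) == 1 && nrow(g2) == 2)) {
      two <- if (nrow(g1) == 2) g1 else g2
      one <- if (nrow(g1) == 2) g2 else g1
      two <- two %>% arrange(.data$intron_start)
      if (one$intron_start == two$intron_start[1] &&
            one$intron_end == two$intron_end[2] &&
            two$intron_end[1] < two$intron_start[2]) {
        mode <- "ES"
        detail <- paste0("skipped:", two$intron_end[1], "-", two$intron_start[2])
      }
    } else if (nrow(g1) == 2 && nrow(g2) == 2) {
      g1 <- g1 %>% arrange(.data$intron_start)
      g2 <- g2 %>% arrange(.data$intron_start)
      e1 <- c(g1$intron_end[1], g1$intron_start[2])
      e2 <- c(g2$intron_end[1], g2$intron_start[2])
      outer_shared <- g1$intron_start[1] == g2$intron_start[1] &&
        g1$intron_end[2] == g2$intron_end[2]
      valid_exons <- e1[1] < e1[2] && e2[1] < e2[2]
      disjoint <- valid_exons && (e1[2] <= e2[1] || e2[2] <= e1[1])
      if (outer_shared && disjoint) {
        mode <- "MXE"
        lo <- if (e1[1] < e2[1]) e1 else e2
        hi2 <- if (e1[1] < e2[1]) e2 else e1
        detail <- paste0("exons:", lo[1], "-", lo[2], "|", hi2[1], "-", hi2[2])
      }
    }
    tibble(
      mode = mode,
      isoform_1 = t1$transcript_id, isoform_2 = t2$transcript_id,
      chrom = t1$chrom, strand = strand,
      start = span[1], end = span[2], detail = detail
    )
  })
  bind_rows(events)
}

empty_events <- function() {
  tibble(mode = character(), isoform_1 = character(), isoform_2 = character(),
         chrom = character(), strand = character(),
         start = integer(), end = integer(), detail = character())
}

as_modes <- c("IR", "ES", "A3", "A5", "MXE")

#' Alternative-splicing events of a gene (or a whole isoform set)
#'
#' Evaluates all unordered isoform pairs within each gene, deduplicates
#' events by `(mode, chrom, strand, detail)`, and tabulates mode frequencies.
#' `OTHER` events are reported in `events` but excluded from the five-mode
#' frequency table.
#'
#' @param tx A transcript tibble with a `gene_id` column (isoforms grouped by
#'   gene); rows with `NA` gene_id are ignored.
#' @return List with `events` (deduplicated event tibble with `gene_id`) and
#'   `mode_freq` (tibble `mode`, `n`, `freq` over the five modes).
#' @export
gene_events <- function(tx) {
  gx <- tx %>% filter(!is.na(.data$gene_id))
  ev <- purrr::map(split(seq_len(nrow(gx)), gx$gene_id), function(idx) {
    if (length(idx) < 2) return(NULL)
    pairs <- utils::combn(idx, 2, simplify = FALSE)
    out <- purrr::map(pairs, function(p) {
      t1 <- gx[p[1], , drop = FALSE]; t2 <- gx[p[2], , drop = FALSE]
      if (t1$chrom != t2$chrom || t1$strand != t2$strand) return(NULL)
      pairwise_events(t1, t2)
    })
    res <- bind_rows(out)
    if (nrow(res)) res$gene_id <- gx$gene_id[idx[1]]
    res
  }) %>% bind_rows()
  if (!nrow(ev)) {
    return(list(events = dplyr::mutate(empty_events(), gene_id = character()),
                mode_freq = tibble(mode = as_modes, n = 0L, freq = NA_real_)))
  }
  ev <- ev %>% distinct(.data$mode, .data$chrom, .data$strand, .data$detail,
                        .keep_all = TRUE)
  five <- ev %>% filter(.data$mode %in% as_modes)
  freq <- tibble(mode = as_modes) %>%
    left_join(five %>% count(.data$mode), by = "mode") %>%
    mutate(n = if_else(is.na(.data$n), 0L, .data$n),
           freq = if (sum(.data$n) > 0) .data$n / sum(.data$n) else NA_real_)
  list(events = ev, mode_freq = freq)
}

#' Tissue-specific isoform sets and the tissue overlap matrix
#'
#' An isoform is exclusive to a tissue when its tissue set is exactly that
#' one tissue. The overlap matrix counts, for each tissue pair, the isoforms
#' observed in both tissues (diagonal: isoforms observed in the tissue).
#'
#' @param tx A transcript tibble; every row must have a non-empty `tissues`
#'   set.
#' @return List with `exclusive` (tibble `tissue`, `n_isoforms`,
#'   `n_exclusive`, `prop_exclusive`, `transcript_ids` list) and `overlap`
#'   (named integer matrix).
#' @export
tissue_specific_sets <- function(tx) {
  sizes <- purrr::map_int(tx$tissues, length)
  if (any(sizes == 0))
    abort(paste0("isoform(s) with empty tissue set: ",
                 paste(tx$transcript_id[sizes == 0], collapse = ", ")))
  long <- tibble(transcript_id = rep(tx$transcript_id, sizes),
                 tissue = unlist(tx$tissues)) %>% distinct()
  tissues <- sort(unique(long$tissue))
  excl_ids <- tx$transcript_id[sizes == 1]
  excl_tissue <- vapply(tx$tissues[sizes == 1], `[[`, "", 1)
  exclusive <- tibble(tissue = tissues) %>%
    left_join(long %>% count(.data$tissue, name = "n_isoforms"), by = "tissue") %>%
    mutate(
      transcript_ids = purrr::map(.data$tissue, ~ sort(excl_ids[excl_tissue == .x])),
      n_exclusive = purrr::map_int(.data$transcript_ids, length),
      prop_exclusive = .data$n_exclusive / .data$n_isoforms
    )
  overlap <- matrix(0L, length(tissues), length(tissues),
                    dimnames = list(tissues, tissues))
  by_tissue <- split(long$transcript_id, long$tissue)
  for (a in tissues) for (b in tissues) {
    overlap[a, b] <- length(intersect(by_tissue[[a]], by_tissue[[b]]))
  }
  list(exclusive = exclusive, overlap = overlap)
}
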