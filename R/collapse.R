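#' Collapse parameters
#'
#' Defaults mirror the standard long-read collapse settings: alignments are
#' kept when coverage >= 85% and identity >= 90%, and transcripts differing
#' only at their 5' start within the first exon are treated as redundant
#' (only the longest version is retained). The 3' outer boundary is likewise
#' ignored by default (polyA-priming artifacts); set `collapse_3prime = FALSE`
#' to make it part of the identity key. Mono-exon transcripts, which have no
#' intron chain, are merged by reciprocal overlap of at least
#' `monoexon_merge_overlap` of the shorter transcript.
#'
#' @param min_coverage,min_identity Quality thresholds in `[0, 1]`.
#' @param ignore_5prime Ignore the 5' outer boundary when keying chains.
#' @param collapse_3prime Also ignore the 3' outer boundary (default `TRUE`).
#' @param monoexon_merge_overlap Reciprocal-overlap fraction for mono-exon
#'   merging, in `[0, 1]`.
#' @return A named list of parameters.
#' @export
collapse_params <- function(min_coverage = 0.85, min_identity = 0.90,
                            ignore_5prime = TRUE, collapse_3prime = TRUE,
                            monoexon_merge_overlap = 0.5) {
  stopifnot(
    min_coverage >= 0, min_coverage <= 1,
    min_identity >= 0, min_identity <= 1,
    monoexon_merge_overlap >= 0, monoexon_merge_overlap <= 1
  )
  list(min_coverage = min_coverage, min_identity = min_identity,
       ignore_5prime = ignore_5prime, collapse_3prime = collapse_3prime,
       monoexon_merge_overlap = monoexon_merge_overlap)
}

#' Filter alignments on coverage and identity
#'
#' An alignment is kept iff `coverage >= min_coverage` and
#' `identity >= min_identity` (both thresholds inclusive).
#'
#' @param tx A transcript tibble.
#' @param params See [collapse_params()].
#' @return A list with `kept` (transcript tibble) and `discarded` (tibble of
#'   `transcript_id`, `reason` in `{low_coverage, low_identity}`; an alignment
#'   failing both is reported as `low_coverage`).
#' @export
filter_alignments <- function(tx, params = collapse_params()) {
  low_cov <- tx$coverage < params$min_coverage
  low_ident <- tx$identity < params$min_identity
  discarded <- tibble(
    transcript_id = tx$transcript_id[low_cov | low_ident],
    reason = if_else(low_cov[low_cov | low_ident], "low_coverage", "low_identity")
  )
  list(kept = tx[!(low_cov | low_ident), , drop = FALSE], discarded = discarded)
}

#' Collapse identity key of a multi-exon transcript
#'
#' The key is `(chrom, strand, ordered intron chain)`. With the default
#' parameters both terminal outer boundaries are excluded, so transcripts
#' differing only by 5' degradation (or 3' end wobble) within their terminal
#' exons share a key. With `collapse_3prime = FALSE` the transcript-3' outer
#' boundary is appended to the key.
#'
#' @param tx A transcript tibble (all rows must be multi-exon).
#' @param params See [collapse_params()].
#' @return Character vector of keys, one per row.
#' @export
collapse_key <- function(tx, params = collapse_params()) {
  if (any(n_exons(tx) < 2))
    abort("collapse_key is defined for multi-exon transcripts only")
  key <- tx_chain(tx)
  if (!params$collapse_3prime) {
    end3 <- ifelse(
      tx$strand == "+",
      purrr::map_int(tx$exon_ends, ~ .x[length(.x)]),
      purrr::map_int(tx$exon_starts, ~ .x[1])
    )
    key <- paste0(key, "|3p:", end3)
  }
  if (!params$ignore_5prime) {
    start5 <- ifelse(
      tx$strand == "+",
      purrr::map_int(tx$exon_starts, ~ .x[1]),
      purrr::map_int(tx$exon_ends, ~ .x[length(.x)])
    )
    key <- paste0(key, "|5p:", start5)
  }
  key
}

# single-linkage grouping of mono-exon transcripts by reciprocal overlap
monoexon_groups <- function(tx, min_frac) {
  xt <- tx_extent(tx)
  n <- nrow(xt)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (xt$chrom[i] != xt$chrom[j] || xt$strand[i] != xt$strand[j]) next
      ov <- min(xt$end[i], xt$end[j]) - max(xt$start[i], xt$start[j])
      shorter <- min(xt$end[i] - xt$start[i], xt$end[j] - xt$start[j])
      if (ov >= min_frac * shorter && ov > 0) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Collapse redundant transcript models into unique isoforms
#'
#' Multi-exon transcripts are grouped by [collapse_key()] (identical intron
#' chain, 5'/3' outer boundaries ignored by default); mono-exon transcripts
#' are merged by single-linkage reciprocal overlap. Each group is represented
#' by its longest member (sum of exon lengths), ties broken by the
#' lexicographically smallest id. The operation is idempotent and independent
#' of input order. Inputs are assumed already quality-filtered (see
#' [filter_alignments()]); pass `discarded` to carry the filter report into
#' the result's bookkeeping.
#'
#' @param tx A transcript tibble.
#' @param params See [collapse_params()].
#' @param discarded Optional discard tibble from [filter_alignments()].
#' @return An object of class `iso_collapse`: list with `isoforms` (transcript
#'   tibble of representatives, tissue labels unioned over members),
#'   `member_map` (tibble `isoform_id`, `transcript_id`), and `discarded`.
#' @export
collapse_isoforms <- function(tx, params = collapse_params(),
                              discarded = tibble(transcript_id = character(),
                                                 reason = character())) {
  multi <- tx[n_exons(tx) >= 2, , drop = FALSE]
  mono <- tx[n_exons(tx) < 2, , drop = FALSE]
  key_multi <- if (nrow(multi)) collapse_key(multi, params) else character()
  key_mono <- if (nrow(mono)) {
    # order-stable group labels: sort mono rows before union-find, then name
    # each group after its sorted member ids
    mono <- mono %>% arrange(.data$transcript_id)
    grp <- monoexon_groups(mono, params$monoexon_merge_overlap)
    sig <- vapply(split(mono$transcript_id, grp),
                  function(ids) paste(sort(ids), collapse = ","), "")
    paste0("mono|", sig[as.character(grp)])
  } else character()
  tx_all <- bind_rows(multi, mono)
  tx_all$.key <- c(key_multi, key_mono)
  tx_all$.len <- exonic_length(tx_all)
  reps <- tx_all %>%
    arrange(.data$.key, dplyr::desc(.data$.len), .data$transcript_id) %>%
    group_by(.data$.key) %>%
    slice(1) %>%
    ungroup()
  member_map <- tx_all %>%
    select("transcript_id", ".key") %>%
    left_join(reps %>% select(".key", isoform_id = "transcript_id"), by = ".key") %>%
    select("isoform_id", "transcript_id") %>%
    arrange(.data$isoform_id, .data$transcript_id)
  tissue_union <- tx_all %>%
    group_by(.data$.key) %>%
    summarise(tissues = list(sort(unique(unlist(.data$tissues)))), .groups = "drop")
  reps <- reps %>%
    select(-"tissues") %>%
    left_join(tissue_union, by = ".key") %>%
    select(-".key", -".len")
  structure(
    list(isoforms = reps, member_map = member_map, discarded = discarded),
    class = "iso_collapse"
  )
}

#' @export
print.iso_collapse <- function(x, ...) {
  cat("<iso_collapse> ", nrow(x$isoforms), " unique isoforms from ",
      nrow(x$member_map), " transcripts (", nrow(x$discarded),
      " discarded by quality filters)\n", sep = "")
  invisible(x)
}

#' @describeIn collapse_isoforms `tidy()` returns the member map with per-group
#'   sizes.
#' @param x An `iso_collapse` object.
#' @param ... Unused.
#' @export
tidy.iso_collapse <- function(x, ...) {
  x$member_map %>%
    group_by(.data$isoform_id) %>%
    mutate(n_members = n()) %>%
    ungroup()
}

#' @describeIn collapse_isoforms `glance()` returns one-row summary counts.
#' @export
glance.iso_collapse <- function(x, ...) {
  tibble(
    n_input = nrow(x$member_map) + nrow(x$discarded),
    n_collapsed = nrow(x$member_map),
    n_unique = nrow(x$isoforms),
    n_discarded = nrow(x$discarded)
  )
}
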