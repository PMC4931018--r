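#' Transcript model tables
#'
#' Throughout the package an aligned long-read transcript model (or a
#' reference transcript) is one row of a *transcript table*: a tibble with one
#' row per transcript and list-columns holding the ordered exon blocks.
#' All genomic coordinates are 0-based half-open; GFF3/GTF/BED inputs are
#' converted at the boundary.
#'
#' Columns:
#' \describe{
#'   \item{transcript_id}{character, unique.}
#'   \item{gene_id}{character; `NA` for unassigned reads.}
#'   \item{chrom, strand}{character; strand one of `"+"`, `"-"`.}
#'   \item{exon_starts, exon_ends}{list of integer vectors, ascending,
#'     non-overlapping, equal length; `exon_ends[i] > exon_starts[i]`,
#'     consecutive exons separated by at least 1 base (an intron).}
#'   \item{coverage, identity}{alignment quality fractions in `[0, 1]`.}
#'   \item{tissues}{list of character vectors (may be empty).}
#'   \item{seq_length}{integer; the read length in bases (soft clips allowed,
#'     so it may exceed the exonic span); defaults to the exonic sum.}
#' }
#'
#' @param transcript_id,gene_id,chrom,strand,exon_starts,exon_ends,coverage,identity,tissues,seq_length
#'   Column values, recycled per tibble rules. `exon_starts`/`exon_ends` may
#'   be bare integer vectors for a single transcript or lists of vectors.
#' @return A validated transcript tibble.
#' @export
tx_tbl <- function(transcript_id, chrom, strand, exon_starts, exon_ends,
                   gene_id = NA_character_, coverage = 1, identity = 1,
                   tissues = list(character()), seq_length = NA_integer_) {
  if (!is.list(exon_starts)) exon_starts <- list(as.integer(exon_starts))
  if (!is.list(exon_ends)) exon_ends <- list(as.integer(exon_ends))
  if (!is.list(tissues)) tissues <- list(as.character(tissues))
  tx <- tibble(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    exon_starts = lapply(exon_starts, as.integer),
    exon_ends = lapply(exon_ends, as.integer),
    coverage = as.numeric(coverage),
    identity = as.numeric(identity),
    tissues = tissues,
    seq_length = as.integer(seq_length)
  )
  exonic <- exonic_length(tx)
  tx$seq_length <- ifelse(is.na(tx$seq_length), exonic, tx$seq_length)
  validate_tx(tx)
}

#' Validate a transcript table
#'
#' Checks the structural invariants of a transcript tibble (see [tx_tbl()]):
#' unique ids, valid strands, sorted non-overlapping exons with intron gaps,
#' quality fractions in range.
#'
#' @param tx A transcript tibble.
#' @return `tx`, invisibly unchanged, or an error describing the violation.
#' @export
validate_tx <- function(tx) {
  stopifnot(is.data.frame(tx))
  need <- c("transcript_id", "chrom", "strand", "exon_starts", "exon_ends")
  miss <- setdiff(need, names(tx))
  if (length(miss)) abort(paste("transcript table missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(tx$transcript_id)) abort("duplicate transcript_id in transcript table")
  if (!all(tx$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  ok <- purrr::map2_lgl(tx$exon_starts, tx$exon_ends, function(s, e) {
    length(s) == length(e) && length(s) >= 1 && all(e > s) &&
      (length(s) == 1 || (all(diff(s) > 0) && all(s[-1] - e[-length(e)] >= 1)))
  })
  if (!all(ok)) {
    abort(paste0("invalid exon chain for transcript(s): ",
                 paste(tx$transcript_id[!ok], collapse = ", ")))
  }
  if (!is.null(tx$coverage) && any(tx$coverage < 0 | tx$coverage > 1, na.rm = TRUE))
    abort("coverage must lie in [0, 1]")
  if (!is.null(tx$identity) && any(tx$identity < 0 | tx$identity > 1, na.rm = TRUE))
    abort("identity must lie in [0, 1]")
  invisible(tx)
}

#' Sum of exon lengths per transcript
#' @param tx A transcript tibble.
#' @return Integer vector, one value per row.
#' @export
exonic_length <- function(tx) {
  purrr::map2_int(tx$exon_starts, tx$exon_ends, ~ sum(.y - .x))
}

#' Number of exons per transcript
#' @param tx A transcript tibble.
#' @return Integer vector.
#' @export
n_exons <- function(tx) {
  purrr::map_int(tx$exon_starts, length)
}

#' Exon-level view of a transcript table
#'
#' Unnests the exon list-columns into one row per exon.
#'
#' @param tx A transcript tibble.
#' @return A tibble with columns `transcript_id`, `gene_id` (if present),
#'   `chrom`, `strand`, `start`, `end`, `exon_rank` (1-based, in genomic
#'   coordinate order).
#' @export
tx_exons <- function(tx) {
  keep <- intersect(c("transcript_id", "gene_id", "chrom", "strand"), names(tx))
  out <- tx[keep]
  out$start <- tx$exon_starts
  out$end <- tx$exon_ends
  out <- tidyr::unnest(out, c("start", "end"))
  out %>%
    group_by(.data$transcript_id) %>%
    mutate(exon_rank = row_number()) %>%
    ungroup()
}

#' Splice junctions of transcript models
#'
#' Each gap between consecutive exons is one intron, reported as a junction
#' `(chrom, strand, intron_start, intron_end)` with 0-based half-open intron
#' coordinates. The donor is the transcript-5' intron boundary (`intron_start`
#' on `+`, `intron_end - 1` on `-`); the acceptor is the 3' boundary.
#' Mono-exon transcripts contribute no junctions.
#'
#' @param tx A transcript tibble.
#' @return A tibble `transcript_id`, `chrom`, `strand`, `intron_start`,
#'   `intron_end`, `junction_rank` (genomic order).
#' @export
tx_junctions <- function(tx) {
  rows <- purrr::pmap(
    list(tx$transcript_id, tx$chrom, tx$strand, tx$exon_starts, tx$exon_ends),
    function(id, chrom, strand, s, e) {
      k <- length(s)
      if (k < 2) return(NULL)
      tibble(
        transcript_id = id, chrom = chrom, strand = strand,
        intron_start = e[-k], intron_end = s[-1],
        junction_rank = seq_len(k - 1)
      )
    }
  )
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(transcript_id = character(), chrom = character(),
                  strand = character(), intron_start = integer(),
                  intron_end = integer(), junction_rank = integer())
  }
  out
}

#' Transcript extents
#' @param tx A transcript tibble.
#' @return A tibble `transcript_id`, `chrom`, `strand`, `start`, `end` where
#'   start/end span the whole exon chain.
#' @export
tx_extent <- function(tx) {
  tibble(
    transcript_id = tx$transcript_id,
    chrom = tx$chrom, strand = tx$strand,
    start = purrr::map_int(tx$exon_starts, ~ .x[1]),
    end = purrr::map_int(tx$exon_ends, ~ .x[length(.x)])
  )
}

# Junction chain signature used for collapse/classification identity.
# Terminal outer boundaries are never part of the chain.
chain_string <- function(starts, ends) {
  k <- length(starts)
  if (k < 2) return(NA_character_)
  paste(ends[-k], starts[-1], sep = "-", collapse = ",")
}

#' Intron chain signature per transcript
#'
#' `NA` for mono-exon transcripts; otherwise a canonical string of the ordered
#' intron coordinates prefixed with chrom and strand.
#'
#' @param tx A transcript tibble.
#' @return Character vector.
#' @export
tx_chain <- function(tx) {
  core <- purrr::map2_chr(tx$exon_starts, tx$exon_ends, chain_string)
  ifelse(is.na(core), NA_character_, paste(tx$chrom, tx$strand, core, sep = "|"))
}

# GRanges helpers -------------------------------------------------------------

exons_granges <- function(tx) {
  ex <- tx_exons(tx)
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand
  )
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  if ("gene_id" %in% names(ex)) S4Vectors::mcols(gr)$gene_id <- ex$gene_id
  gr
}

extent_granges <- function(tx) {
  xt <- tx_extent(tx)
  gr <- GenomicRanges::GRanges(
    seqnames = xt$chrom,
    ranges = IRanges::IRanges(start = xt$start + 1L, end = xt$end),
    strand = xt$strand
  )
  S4Vectors::mcols(gr)$transcript_id <- xt$transcript_id
  gr
}
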