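stop_codons <- c("TAA", "TAG", "TGA")

#' Longest open reading frame of a nucleotide sequence
#'
#' Scans all six frames (both strands) for `ATG ... stop` ORFs and reports
#' the longest, counted in translated amino acids: the ATG codon is counted,
#' the stop codon is not, and a stop codon is required (`"ATGAAATAG"` has 2
#' codons). Ties are broken toward the `+` strand, then the lowest frame,
#' then the lowest start. A sequence with no qualifying ORF reports 0 codons.
#'
#' @param sequence A single nucleotide string over `A,C,G,T,N`.
#' @return List with `codons` (integer), and for a found ORF `strand`
#'   (`+`/`-` relative to the input), `frame` (0-2), `start` (0-based
#'   position on the reported strand), `span` (nt length including the stop).
#' @export
longest_orf <- function(sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) abort("sequence contains non-ACGTN characters")
  best <- list(codons = 0L, strand = NA_character_, frame = NA_integer_,
               start = NA_integer_, span = NA_integer_)
  n <- nchar(sequence)
  if (n < 6) return(best)
  strands <- c("+", "-")
  for (st in strands) {
    s <- if (st == "+") sequence else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    for (f in 0:2) {
      starts_nt <- seq(1 + f, n - 2, by = 3)
      cods <- substring(s, starts_nt, starts_nt + 2)
      is_start <- cods == "ATG"
      is_stop <- cods %in% stop_codons
      if (!any(is_start) || !any(is_stop)) next
      stop_idx <- which(is_stop)
      for (a in which(is_start)) {
        nxt <- stop_idx[stop_idx > a]
        if (!length(nxt)) break_val <- NA else break_val <- nxt[1]
        if (is.na(break_val)) next
        codons <- break_val - a
        if (codons > best$codons) {
          best <- list(codons = as.integer(codons), strand = st, frame = f,
                       start = as.integer(starts_nt[a] - 1L),
                       span = as.integer(3L * (codons + 1L)))
        }
      }
    }
  }
  best
}

#' Spliced transcript sequences from a genome
#'
#' Concatenates each transcript's exon sequences in genomic order and
#' reverse-complements the result for `-` strand transcripts, yielding the
#' 5'-to-3' transcript sequence.
#'
#' @param tx A transcript tibble.
#' @param genome A `DNAStringSet`.
#' @return Named character vector of sequences (names = transcript ids).
#' @export
transcript_sequences <- function(tx, genome) {
  seqs <- as.character(genome)
  out <- purrr::pmap_chr(
    list(tx$chrom, tx$strand, tx$exon_starts, tx$exon_ends),
    function(chrom, strand, s, e) {
      parts <- substring(seqs[chrom], s + 1L, e)
      joined <- paste(parts, collapse = "")
      if (strand == "-")
        joined <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(joined)))
      joined
    }
  )
  setNames(out, tx$transcript_id)
}

#' lncRNA filtering cascade
#'
#' Applies the four high-confidence lncRNA filters in order:
#' \enumerate{
#'   \item length >= `min_len` bases;
#'   \item longest ORF <= `max_orf_codons` codons (exactly 100 passes;
#'     "exceeding 100" fails);
#'   \item no protein homology: no hit to a protein database
#'     (`protein_dbs`) with `e_value <= max_e`;
#'   \item novelty: no hit to a known-lncRNA database with
#'     `e_value <= max_e`, `identity >= 0.90` and `coverage >= 0.85`.
#' }
#' Each stage only sees survivors of the previous one, so the attrition table
#' is monotone.
#'
#' @param candidates Tibble with `transcript_id` and `sequence` columns (any
#'   other columns are carried through).
#' @param hits Homology-hit tibble (see [read_homology_hits()]); may be empty.
#' @param min_len,max_orf_codons,max_e Stage thresholds.
#' @param protein_dbs,known_lnc_db Database labels in `hits$subject_db`.
#' @return List with `candidates` (input plus `longest_orf_codons`,
#'   `length_pass`, `orf_pass`, `homology_pass`, `novelty_pass`,
#'   `high_confidence`) and `attrition` (tibble `stage`, `n_in`, `n_out`).
#' @export
filter_lncrna_candidates <- function(candidates, hits = NULL, min_len = 200,
                                     max_orf_codons = 100, max_e = 1e-10,
                                     protein_dbs = c("sorghum", "rice", "brachypodium"),
                                     known_lnc_db = "known_lncRNA") {
  if (is.null(hits)) hits <- tibble(query_id = character(), subject_db = character(),
                                    e_value = numeric(), coverage = numeric(),
                                    identity = numeric())
  out <- candidates
  out$length_pass <- nchar(out$sequence) >= min_len
  out$longest_orf_codons <- NA_integer_
  alive <- out$length_pass
  out$longest_orf_codons[alive] <-
    vapply(out$sequence[alive], function(s) longest_orf(s)$codons, 1L)
  out$orf_pass <- alive & out$longest_orf_codons <= max_orf_codons
  prot_fail <- unique(hits$query_id[
    hits$subject_db %in% protein_dbs & hits$e_value <= max_e])
  out$homology_pass <- out$orf_pass & !out$transcript_id %in% prot_fail
  known_fail <- unique(hits$query_id[
    hits$subject_db == known_lnc_db & hits$e_value <= max_e &
      hits$identity >= 0.90 & hits$coverage >= 0.85])
  out$novelty_pass <- out$homology_pass & !out$transcript_id %in% known_fail
  out$high_confidence <- out$novelty_pass
  attrition <- tibble(
    stage = c("input", "length", "orf", "homology", "novelty"),
    n_out = c(nrow(out), sum(out$length_pass), sum(out$orf_pass),
              sum(out$homology_pass), sum(out$novelty_pass))
  ) %>% mutate(n_in = dplyr::lag(.data$n_out, default = nrow(out))) %>%
    select("stage", "n_in", "n_out")
  list(candidates = out, attrition = attrition)
}

#' Positional class of lncRNAs relative to an annotation
#'
#' Classifies each lncRNA by position relative to annotated genes, with the
#' precedence sense -> antisense -> intronic -> intergenic:
#' `sense` = same-strand exonic overlap; `antisense` = opposite-strand exonic
#' overlap only; `intronic` = fully contained in a single annotated intron
#' (either strand) with no exon overlap; `intergenic` = no overlap with any
#' gene extent. Transcripts overlapping a gene extent without matching any of
#' the first three patterns fall through to `intergenic` with
#' `extent_overlap = TRUE`.
#'
#' @param lnc_tx Transcript tibble of passing lncRNAs.
#' @param index An [annotation_index()] or annotation tibble.
#' @return Tibble `transcript_id`, `positional_class`, `extent_overlap`.
#' @export
classify_lncrna_position <- function(lnc_tx, index) {
  if (!inherits(index, "iso_annotation_index")) index <- annotation_index(index)
  ex_gr <- exons_granges(lnc_tx)
  ov_same <- GenomicRanges::findOverlaps(ex_gr, index$exon_gr, ignore.strand = FALSE)
  ov_any <- GenomicRanges::findOverlaps(ex_gr, index$exon_gr, ignore.strand = TRUE)
  ids <- S4Vectors::mcols(ex_gr)$transcript_id
  same_ids <- unique(ids[S4Vectors::queryHits(ov_same)])
  any_ids <- unique(ids[S4Vectors::queryHits(ov_any)])
  xt <- tx_extent(lnc_tx)
  xt_gr <- GenomicRanges::GRanges(xt$chrom, IRanges::IRanges(xt$start + 1L, xt$end))
  in_intron <- unique(xt$transcript_id[S4Vectors::queryHits(
    GenomicRanges::findOverlaps(xt_gr, index$intron_gr, type = "within",
                                ignore.strand = TRUE))])
  ext_ov <- unique(xt$transcript_id[S4Vectors::queryHits(
    GenomicRanges::findOverlaps(xt_gr, index$extent_gr, ignore.strand = TRUE))])
  tibble(transcript_id = lnc_tx$transcript_id) %>%
    mutate(
      positional_class = case_when(
        .data$transcript_id %in% same_ids ~ "sense",
        .data$transcript_id %in% any_ids ~ "antisense",
        .data$transcript_id %in% in_intron ~ "intronic",
        TRUE ~ "intergenic"
      ),
      extent_overlap = .data$transcript_id %in% ext_ov
    )
}

#' Exon-count summary of a lncRNA set
#'
#' @param lnc_tx Transcript tibble.
#' @param classes Optional tibble `transcript_id`, `positional_class` for
#'   per-class tallies.
#' @return List with `single_exon_fraction` and `tally` (per exon-count bin,
#'   optionally per class). Empty input yields an empty tally and `NA`
#'   fraction.
#' @export
exon_count_summary <- function(lnc_tx, classes = NULL) {
  if (!nrow(lnc_tx)) {
    return(list(single_exon_fraction = NA_real_,
                tally = tibble(n_exons = integer(), n = integer())))
  }
  k <- n_exons(lnc_tx)
  tab <- tibble(transcript_id = lnc_tx$transcript_id,
                n_exons = k,
                single_exon = k == 1)
  if (!is.null(classes)) tab <- left_join(tab, classes, by = "transcript_id")
  tally <- tab %>%
    count(across(dplyr::any_of(c("positional_class", "single_exon"))))
  list(single_exon_fraction = mean(tab$single_exon), tally = tally)
}
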