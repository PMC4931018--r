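#' Score long-read splice junctions against short-read evidence
#'
#' A junction is supported in a tissue iff the evidence contains a record
#' with the identical intron coordinates (`chrom`, `intron_start`,
#' `intron_end`; exact match, no tolerance window) in the same tissue with at
#' least `min_reads` reads. By default junction identity is strand-agnostic
#' (short-read junction strand is often unknown); `strand_mode = "strict"`
#' additionally requires an exact strand match. Junctions are deduplicated
#' within each tissue before scoring, and the headline rate is the
#' macro-average over tissues.
#'
#' @param tx Transcript tibble; each transcript's junctions are scored in
#'   every tissue of its `tissues` set.
#' @param evidence Junction-evidence tibble (see [read_junction_evidence()]).
#' @param min_reads Minimum read count for support (default 1).
#' @param strand_mode `"ignore"` (default) or `"strict"`.
#' @return An object of class `iso_support`: list with `per_tissue` (tibble
#'   `tissue`, `n_junctions`, `n_supported`, `support_rate`), `macro_rate`,
#'   `per_junction` (flags), and `params`.
#' @export
support_junctions <- function(tx, evidence, min_reads = 1, strand_mode = c("ignore", "strict")) {
  strand_mode <- match.arg(strand_mode)
  j <- tx_junctions(tx) %>%
    left_join(tx %>% select("transcript_id", "tissues"), by = "transcript_id") %>%
    tidyr::unnest("tissues") %>%
    rename(tissue = "tissues")
  key_cols <- c("chrom", "intron_start", "intron_end", "tissue")
  if (strand_mode == "strict") key_cols <- c(key_cols, "strand")
  jd <- j %>% distinct(across(dplyr::all_of(c(key_cols, "strand"))))
  missing_tissues <- setdiff(unique(jd$tissue), unique(evidence$tissue))
  if (length(missing_tissues))
    warn(paste0("no junction evidence for tissue(s): ",
                paste(missing_tissues, collapse = ", "),
                "; support computed against empty evidence"))
  ev <- evidence %>%
    group_by(across(dplyr::all_of(intersect(key_cols, names(evidence))))) %>%
    summarise(read_count = sum(.data$read_count), .groups = "drop")
  per_junction <- jd %>%
    left_join(ev, by = intersect(key_cols, names(ev))) %>%
    mutate(supported = !is.na(.data$read_count) & .data$read_count >= min_reads)
  per_tissue <- per_junction %>%
    group_by(.data$tissue) %>%
    summarise(n_junctions = n(), n_supported = sum(.data$supported),
              support_rate = mean(.data$supported), .groups = "drop")
  structure(
    list(per_tissue = per_tissue,
         macro_rate = mean(per_tissue$support_rate),
         per_junction = per_junction,
         params = list(min_reads = min_reads, strand_mode = strand_mode)),
    class = "iso_support"
  )
}

#' @export
print.iso_support <- function(x, ...) {
  cat("<iso_support> macro-average support rate ",
      sprintf("%.1f%%", 100 * x$macro_rate), " over ",
      nrow(x$per_tissue), " tissue(s)\n", sep = "")
  invisible(x)
}

#' @describeIn support_junctions `tidy()` returns the per-tissue table.
#' @param x An `iso_support` object.
#' @param ... Unused.
#' @export
tidy.iso_support <- function(x, ...) x$per_tissue

#' @describeIn support_junctions `glance()` returns a one-row summary.
#' @export
glance.iso_support <- function(x, ...) {
  tibble(n_tissues = nrow(x$per_tissue),
         n_junctions = sum(x$per_tissue$n_junctions),
         macro_rate = x$macro_rate,
         min_reads = x$params$min_reads)
}

splice_motif_classes <- c("GT/AG", "GC/AG", "CT/AC", "CT/GC", "GT/AT", "AT/AC")

#' Splice motif of junctions
#'
#' Returns the dinucleotides at the intron boundaries, read 5' to 3' on the
#' transcript strand (reverse-complemented for `-` junctions), as
#' `"donor/acceptor"` (e.g. `"GT/AG"`). Any ambiguous base (N) in the motif
#' window yields `"other"`.
#'
#' @param genome A `DNAStringSet` (see [read_genome()]).
#' @param junctions Tibble with `chrom`, `strand`, `intron_start`,
#'   `intron_end` (strand must be known).
#' @return Character vector of motifs, one per junction.
#' @export
splice_motif <- function(genome, junctions) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (any(!junctions$chrom %in% names(genome)) ||
        any(junctions$intron_start < 0) ||
        any(junctions$intron_end > lens[junctions$chrom]))
    abort("junction outside chromosome bounds")
  if (any(junctions$intron_end - junctions$intron_start < 2))
    abort("intron shorter than 2 bases has no motif")
  seqs <- as.character(genome)
  first2 <- substr(seqs[junctions$chrom], junctions$intron_start + 1L,
                   junctions$intron_start + 2L)
  last2 <- substr(seqs[junctions$chrom], junctions$intron_end - 1L,
                  junctions$intron_end)
  revcomp <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  plus <- junctions$strand == "+"
  donor <- ifelse(plus, first2, revcomp(last2))
  acceptor <- ifelse(plus, last2, revcomp(first2))
  motif <- paste0(donor, "/", acceptor)
  motif[grepl("[^ACGT/]", motif)] <- "other"
  motif
}

#' Per-tissue splice-motif table
#'
#' Tallies deduplicated junction motifs per tissue over the canonical and
#' known non-canonical classes; motifs outside the six named classes are
#' counted as `other`.
#'
#' @param genome A `DNAStringSet`.
#' @param tx Transcript tibble with tissue labels.
#' @return Tibble `tissue`, `motif`, `n`; per tissue the counts sum to the
#'   junction total.
#' @export
motif_table <- function(genome, tx) {
  j <- tx_junctions(tx) %>%
    left_join(tx %>% select("transcript_id", "tissues"), by = "transcript_id") %>%
    tidyr::unnest("tissues") %>%
    rename(tissue = "tissues") %>%
    distinct(.data$tissue, .data$chrom, .data$strand,
             .data$intron_start, .data$intron_end)
  j$motif <- splice_motif(genome, j)
  j$motif[!j$motif %in% splice_motif_classes] <- "other"
  j %>%
    count(.data$tissue, .data$motif) %>%
    tidyr::complete(tissue = unique(j$tissue),
                    motif = c(splice_motif_classes, "other"),
                    fill = list(n = 0L))
}
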