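#' Build a reusable index over a reference annotation
#'
#' Precomputes the lookup structures used by [classify_isoforms()]: exon and
#' gene-extent interval indexes, per-transcript intron chains, per-gene splice
#' site sets and per-transcript intron ranges.
#'
#' @param annotation A transcript tibble with a non-`NA` `gene_id` column.
#' @return An object of class `iso_annotation_index`.
#' @export
annotation_index <- function(annotation) {
  validate_tx(annotation)
  if (any(is.na(annotation$gene_id)))
    abort("annotation transcripts must all carry a gene_id")
  ann <- annotation %>% arrange(.data$transcript_id)
  ex <- tx_exons(ann)
  exon_gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end),
                                    strand = ex$strand)
  S4Vectors::mcols(exon_gr)$gene_id <- ex$gene_id
  S4Vectors::mcols(exon_gr)$transcript_id <- ex$transcript_id

  extents <- ann %>%
    mutate(start = purrr::map_int(.data$exon_starts, ~ .x[1]),
           end = purrr::map_int(.data$exon_ends, ~ .x[length(.x)])) %>%
    group_by(.data$gene_id) %>%
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              start = min(.data$start), end = max(.data$end), .groups = "drop")
  extent_gr <- GenomicRanges::GRanges(extents$chrom,
                                      IRanges::IRanges(extents$start + 1L, extents$end),
                                      strand = extents$strand)
  S4Vectors::mcols(extent_gr)$gene_id <- extents$gene_id

  junc <- tx_junctions(ann) %>%
    left_join(ann %>% select("transcript_id", "gene_id"), by = "transcript_id")
  intron_gr <- GenomicRanges::GRanges(junc$chrom,
                                      IRanges::IRanges(junc$intron_start + 1L, junc$intron_end),
                                      strand = junc$strand)
  S4Vectors::mcols(intron_gr)$gene_id <- junc$gene_id
  S4Vectors::mcols(intron_gr)$transcript_id <- junc$transcript_id

  sites <- bind_rows(
    junc %>% select("chrom", "strand", "gene_id", coord = "intron_start"),
    junc %>% select("chrom", "strand", "gene_id", coord = "intron_end")
  ) %>% distinct()

  chains <- tibble(
    transcript_id = ann$transcript_id,
    gene_id = ann$gene_id,
    chain = tx_chain(ann),
    chain_core = purrr::map2_chr(ann$exon_starts, ann$exon_ends, chain_string),
    prefix = paste(ann$chrom, ann$strand, sep = "|")
  ) %>% filter(!is.na(.data$chain))

  tx_extent_tbl <- tx_extent(ann) %>%
    left_join(ann %>% select("transcript_id", "gene_id"), by = "transcript_id")

  structure(
    list(annotation = ann, exon_gr = exon_gr, extent_gr = extent_gr,
         extents = extents, intron_gr = intron_gr, junctions = junc,
         sites = sites, chains = chains, tx_extents = tx_extent_tbl),
    class = "iso_annotation_index"
  )
}

category_levels <- c(
  a = "novel_locus", b = "novel_isoform", c = "full_match",
  d = "exonic_no_ss", e = "intronic", f = "antisense",
  g = "partial_match", h = "multi_gene"
)

#' Classify isoforms against a reference annotation
#'
#' Assigns every isoform to exactly one of eight structural categories by a
#' fixed precedence ladder, evaluated top-down:
#' \describe{
#'   \item{h `multi_gene`}{same-strand exon or splice-site sharing with two or
#'     more distinct genes (a merged/"split gene" read).}
#'   \item{c `full_match`}{intron chain identical to a reference transcript.}
#'   \item{g `partial_match`}{intron chain is a contiguous proper sub-chain of
#'     a reference transcript (e.g. a 5'-truncated read).}
#'   \item{b `novel_isoform`}{shares at least one splice site (a single donor
#'     or acceptor coordinate, same strand) with an annotated gene.}
#'   \item{e `intronic`}{read fully inside an annotated intron
#'     (`read_inside_annotation`), or an annotated transcript fully inside one
#'     of the read's introns (`annotation_inside_read`).}
#'   \item{d `exonic_no_ss`}{same-strand exonic overlap without any shared
#'     splice site.}
#'   \item{f `antisense`}{exonic overlap with an annotated locus on the
#'     opposite strand only.}
#'   \item{a `novel_locus`}{everything else (no exonic overlap).}
#' }
#' The ladder puts `multi_gene` above `full_match` so merged genes are not
#' hidden by a chain match to one member, and is deterministic under
#' permutation of annotation records.
#'
#' @param tx A transcript tibble (typically collapsed isoforms).
#' @param index An [annotation_index()], or an annotation tibble.
#' @return A tibble `transcript_id`, `group` (letter a-h), `category`,
#'   `subtype` (intronic direction, else `NA`), `matched_genes` (list),
#'   `matched_transcript` (for `full_match`/`partial_match`),
#'   `shared_splice_sites`, `rationale`.
#' @export
classify_isoforms <- function(tx, index) {
  if (!inherits(index, "iso_annotation_index")) index <- annotation_index(index)
  validate_tx(tx)
  qex <- tx_exons(tx)
  q_exon_gr <- GenomicRanges::GRanges(qex$chrom, IRanges::IRanges(qex$start + 1L, qex$end),
                                      strand = qex$strand)
  S4Vectors::mcols(q_exon_gr)$transcript_id <- qex$transcript_id

  # exonic overlap, strand-aware and strand-blind
  ov_same <- GenomicRanges::findOverlaps(q_exon_gr, index$exon_gr, ignore.strand = FALSE)
  ov_any <- GenomicRanges::findOverlaps(q_exon_gr, index$exon_gr, ignore.strand = TRUE)
  pair_genes <- function(hits) {
    tibble(
      transcript_id = S4Vectors::mcols(q_exon_gr)$transcript_id[S4Vectors::queryHits(hits)],
      gene_id = S4Vectors::mcols(index$exon_gr)$gene_id[S4Vectors::subjectHits(hits)]
    ) %>% distinct()
  }
  same_genes <- pair_genes(ov_same)
  any_genes <- pair_genes(ov_any)
  opp_genes <- anti_join(any_genes, same_genes, by = c("transcript_id", "gene_id"))

  # shared splice sites
  qj <- tx_junctions(tx)
  qsites <- bind_rows(
    qj %>% select("transcript_id", "chrom", "strand", coord = "intron_start"),
    qj %>% select("transcript_id", "chrom", "strand", coord = "intron_end")
  ) %>% distinct()
  shared <- inner_join(qsites, index$sites, by = c("chrom", "strand", "coord"),
                       relationship = "many-to-many") %>%
    distinct(.data$transcript_id, .data$gene_id, .data$coord)
  shared_by_tx <- shared %>%
    group_by(.data$transcript_id) %>%
    summarise(genes = list(sort(unique(.data$gene_id))),
              n_sites = dplyr::n_distinct(.data$coord), .groups = "drop")
  shared_gene_counts <- shared %>%
    count(.data$transcript_id, .data$gene_id, name = "n_shared")

  # chain match / sub-chain
  q_chain <- tx_chain(tx)
  q_core <- purrr::map2_chr(tx$exon_starts, tx$exon_ends, chain_string)
  chain_match <- setNames(rep(NA_character_, nrow(tx)), tx$transcript_id)
  hit <- match(q_chain, index$chains$chain)
  chain_match[!is.na(hit)] <- index$chains$transcript_id[hit[!is.na(hit)]]

  # intronic containment (either strand)
  q_extent_tbl <- tx_extent(tx)
  q_extent_gr <- GenomicRanges::GRanges(q_extent_tbl$chrom,
                                        IRanges::IRanges(q_extent_tbl$start + 1L, q_extent_tbl$end))
  within_intron <- GenomicRanges::findOverlaps(
    q_extent_gr, index$intron_gr, type = "within", ignore.strand = TRUE)
  read_in_intron <- unique(q_extent_tbl$transcript_id[S4Vectors::queryHits(within_intron)])

  q_intron <- qj
  ann_tx_gr <- GenomicRanges::GRanges(index$tx_extents$chrom,
                                      IRanges::IRanges(index$tx_extents$start + 1L,
                                                       index$tx_extents$end))
  anno_in_read <- if (nrow(q_intron)) {
    qi_gr <- GenomicRanges::GRanges(q_intron$chrom,
                                    IRanges::IRanges(q_intron$intron_start + 1L,
                                                     q_intron$intron_end))
    h <- GenomicRanges::findOverlaps(ann_tx_gr, qi_gr, type = "within", ignore.strand = TRUE)
    tibble(
      transcript_id = q_intron$transcript_id[S4Vectors::subjectHits(h)],
      contained_gene = index$tx_extents$gene_id[S4Vectors::queryHits(h)]
    ) %>% distinct()
  } else tibble(transcript_id = character(), contained_gene = character())

  # extent overlap with any gene (for the novel-locus rationale)
  ext_ov <- GenomicRanges::findOverlaps(q_extent_gr, index$extent_gr, ignore.strand = TRUE)
  has_extent_ov <- unique(q_extent_tbl$transcript_id[S4Vectors::queryHits(ext_ov)])

  subchain_match <- function(i) {
    core <- q_core[i]
    if (is.na(core)) return(NA_character_)
    pref <- paste(tx$chrom[i], tx$strand[i], sep = "|")
    cand <- index$chains[index$chains$prefix == pref & index$chains$chain_core != core, ]
    if (!nrow(cand)) return(NA_character_)
    needle <- paste0(",", core, ",")
    hay <- paste0(",", cand$chain_core, ",")
    j <- which(stringr::str_detect(stringr::fixed(hay), stringr::fixed(needle)))
    if (length(j)) sort(cand$transcript_id[j])[1] else NA_character_
  }

  n <- nrow(tx)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    id <- tx$transcript_id[i]
    sg <- same_genes$gene_id[same_genes$transcript_id == id]
    og <- opp_genes$gene_id[opp_genes$transcript_id == id]
    sh <- shared_by_tx[shared_by_tx$transcript_id == id, ]
    sh_genes <- if (nrow(sh)) sh$genes[[1]] else character()
    n_sites <- if (nrow(sh)) sh$n_sites else 0L
    multi_genes <- sort(unique(c(sg, sh_genes)))
    contained <- anno_in_read$contained_gene[anno_in_read$transcript_id == id]

    res <- NULL
    if (length(multi_genes) >= 2) {
      res <- list("h", NA, multi_genes, NA_character_,
                  "same-strand exon/splice-site sharing with multiple genes")
    } else if (!is.na(chain_match[id])) {
      m <- chain_match[id]
      g <- index$chains$gene_id[index$chains$transcript_id == m]
      res <- list("c", NA, g, m, paste0("intron chain identical to ", m))
    } else if (!is.na(sub <- subchain_match(i))) {
      g <- index$chains$gene_id[index$chains$transcript_id == sub]
      res <- list("g", NA, g, sub, paste0("contiguous sub-chain of ", sub))
    } else if (n_sites >= 1) {
      counts <- shared_gene_counts[shared_gene_counts$transcript_id == id, ]
      primary <- counts$gene_id[order(-counts$n_shared, counts$gene_id)][1]
      res <- list("b", NA, primary,
                  NA_character_, paste0("shares ", n_sites, " splice site(s) with ", primary))
    } else if (id %in% read_in_intron && !length(sg) && !length(og)) {
      res <- list("e", "read_inside_annotation", character(), NA_character_,
                  "read contained in an annotated intron")
    } else if (length(contained) && !length(sg) && !length(og)) {
      res <- list("e", "annotation_inside_read", sort(unique(contained)), NA_character_,
                  "annotated transcript contained in a read intron")
    } else if (length(sg)) {
      res <- list("d", NA, sort(unique(sg)), NA_character_,
                  "same-strand exonic overlap without shared splice sites")
    } else if (length(og)) {
      res <- list("f", NA, sort(unique(og)), NA_character_,
                  "opposite-strand exonic overlap only")
    } else {
      note <- if (id %in% has_extent_ov)
        "no exonic overlap (gene-extent overlap only; flagged)" else "no overlap with any gene"
      res <- list("a", NA, character(), NA_character_, note)
    }
    out[[i]] <- tibble(
      transcript_id = id,
      group = res[[1]],
      category = unname(category_levels[res[[1]]]),
      subtype = as.character(res[[2]]),
      matched_genes = list(res[[3]]),
      matched_transcript = res[[4]],
      shared_splice_sites = n_sites,
      rationale = res[[5]]
    )
  }
  bind_rows(out)
}

#' Confirm split-gene candidates with merged reads
#'
#' A split-gene candidate (one true gene mis-annotated as several adjacent
#' genes) is `confirmed` when at least one `multi_gene` read spans all genes
#' of the tuple; `partially_correct` when, in addition, the annotation
#' already predicts part of the merged structure — i.e. it contains a
#' transcript whose chain is a contiguous sub-chain of such a merged read
#' *and* whose extent reaches across two or more of the candidate genes;
#' `no_read` otherwise. (A constituent gene's own chain is always a sub-chain
#' of the merged read, so the multi-gene-extent requirement is what makes the
#' annotation "partially correct" rather than simply split.)
#'
#' @param classified Output of [classify_isoforms()].
#' @param tx The transcript tibble that was classified.
#' @param index Annotation index (or annotation tibble).
#' @param candidates Tibble with columns `candidate_id` and `gene_ids`
#'   (list of character vectors, or a comma-separated string column).
#' @return `candidates` with a `verdict` column and `n_spanning_reads`.
#' @export
confirm_split_genes <- function(classified, tx, index, candidates) {
  if (!inherits(index, "iso_annotation_index")) index <- annotation_index(index)
  if (!is.list(candidates$gene_ids))
    candidates$gene_ids <- strsplit(as.character(candidates$gene_ids), ",")
  known <- unique(index$annotation$gene_id)
  bad <- setdiff(unique(unlist(candidates$gene_ids)), known)
  if (length(bad))
    abort(paste0("unknown gene id(s) in split candidates: ", paste(bad, collapse = ", ")))
  merged <- classified %>% filter(.data$group == "h")
  q_core <- setNames(purrr::map2_chr(tx$exon_starts, tx$exon_ends, chain_string),
                     tx$transcript_id)
  ext <- index$extents
  verdicts <- purrr::map(seq_len(nrow(candidates)), function(i) {
    genes <- candidates$gene_ids[[i]]
    spanning <- merged$transcript_id[
      purrr::map_lgl(merged$matched_genes, ~ all(genes %in% .x))]
    if (!length(spanning)) return(tibble(verdict = "no_read", n_spanning_reads = 0L))
    gene_ext <- ext[ext$gene_id %in% genes, ]
    spans_multi <- function(tx_id) {
      xt <- index$tx_extents[index$tx_extents$transcript_id == tx_id, ]
      sum(gene_ext$chrom == xt$chrom & gene_ext$start < xt$end &
            gene_ext$end > xt$start) >= 2
    }
    cand <- index$chains[index$chains$gene_id %in% genes, ]
    cand <- cand[vapply(cand$transcript_id, spans_multi, TRUE), ]
    partial <- nrow(cand) > 0 && any(purrr::map_lgl(spanning, function(id) {
      hay <- paste0(",", q_core[id], ",")
      any(stringr::str_detect(hay, stringr::fixed(paste0(",", cand$chain_core, ","))))
    }))
    tibble(verdict = if (partial) "partially_correct" else "confirmed",
           n_spanning_reads = length(spanning))
  })
  bind_cols(candidates, bind_rows(verdicts))
}

#' Screen isoforms for transposable elements
#'
#' An isoform is flagged as a TE iff it has a hit with
#' `e_value <= max_e`, `coverage >= min_coverage` and
#' `identity >= min_identity`; flagged isoforms are tallied by TE superfamily
#' (`subject_class`, `unknown` when absent).
#'
#' @param tx A transcript tibble.
#' @param te_hits Homology-hit tibble (see [read_homology_hits()]).
#' @param max_e,min_coverage,min_identity Hit thresholds.
#' @return List with `te` (tibble `transcript_id`, `superfamily`), `non_te`
#'   (transcript tibble), and `tally` (counts per superfamily).
#' @export
screen_te <- function(tx, te_hits, max_e = 1e-10, min_coverage = 0.85,
                      min_identity = 0.90) {
  pass <- te_hits %>%
    filter(.data$e_value <= max_e, .data$coverage >= min_coverage,
           .data$identity >= min_identity,
           .data$query_id %in% tx$transcript_id) %>%
    mutate(superfamily = if_else(is.na(.data$subject_class), "unknown",
                                 .data$subject_class)) %>%
    arrange(.data$query_id, .data$e_value) %>%
    distinct(.data$query_id, .keep_all = TRUE)
  te <- tibble(transcript_id = pass$query_id, superfamily = pass$superfamily)
  list(
    te = te,
    non_te = tx %>% filter(!.data$transcript_id %in% te$transcript_id),
    tally = te %>% count(.data$superfamily, name = "n_isoforms")
  )
}

#' Isoforms per gene
#'
#' Counts isoforms per assigned gene: `full_match`, `partial_match` and
#' `novel_isoform` isoforms count toward their primary matched gene;
#' `novel_locus` isoforms are grouped into novel loci by single-linkage
#' same-strand exon overlap, each locus counting as one gene.
#'
#' @param classified Output of [classify_isoforms()].
#' @param tx The classified transcript tibble.
#' @return List with `per_gene` (tibble `gene_id`, `n_isoforms`, `novel`) and
#'   `summary` (one-row tibble: `mean_isoforms`, `max_isoforms`,
#'   `genes_with_ge2`, `n_genes`).
#' @export
isoforms_per_gene <- function(classified, tx) {
  assigned <- classified %>%
    filter(.data$group %in% c("b", "c", "g")) %>%
    mutate(gene_id = purrr::map_chr(.data$matched_genes,
                                    ~ if (length(.x)) sort(.x)[1] else NA_character_)) %>%
    filter(!is.na(.data$gene_id))
  known <- assigned %>% count(.data$gene_id, name = "n_isoforms") %>% mutate(novel = FALSE)

  novel_tx <- tx %>%
    filter(.data$transcript_id %in%
             classified$transcript_id[classified$group == "a"])
  novel <- if (nrow(novel_tx)) {
    gr <- exons_granges(novel_tx)
    ov <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = FALSE)
    edges <- tibble(
      from = S4Vectors::mcols(gr)$transcript_id[S4Vectors::queryHits(ov)],
      to = S4Vectors::mcols(gr)$transcript_id[S4Vectors::subjectHits(ov)]
    ) %>% distinct()
    ids <- sort(unique(novel_tx$transcript_id))
    parent <- setNames(seq_along(ids), ids)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (r in seq_len(nrow(edges))) {
      a <- find(match(edges$from[r], ids)); b <- find(match(edges$to[r], ids))
      if (a != b) parent[a] <- b
    }
    comp <- vapply(seq_along(ids), find, 1L)
    tibble(transcript_id = ids, comp = comp) %>%
      group_by(.data$comp) %>%
      summarise(gene_id = paste0("novel_locus_", sort(.data$transcript_id)[1]),
                n_isoforms = n(), .groups = "drop") %>%
      select("gene_id", "n_isoforms") %>%
      mutate(novel = TRUE)
  } else tibble(gene_id = character(), n_isoforms = integer(), novel = logical())

  per_gene <- bind_rows(known, novel) %>% arrange(.data$gene_id)
  list(
    per_gene = per_gene,
    summary = tibble(
      n_genes = nrow(per_gene),
      mean_isoforms = if (nrow(per_gene)) mean(per_gene$n_isoforms) else NA_real_,
      max_isoforms = if (nrow(per_gene)) max(per_gene$n_isoforms) else NA_integer_,
      genes_with_ge2 = sum(per_gene$n_isoforms >= 2)
    )
  )
}

#' Sliding-window feature density track
#'
#' Counts feature midpoints in a sliding window (default 1 Mb) anchored at
#' every step (default 20 kb) along each chromosome: the window reported at
#' position `s` covers `(s - window, s]`, so a feature contributes to every
#' window whose anchor lies within `window` bases downstream of it.
#'
#' @param features Tibble with columns `chrom` and `pos` (midpoints, 0-based).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param window,step Window span and anchor spacing, in bases.
#' @return Tibble `chrom`, `window_pos` (anchor), `count`.
#' @export
density_track <- function(features, chrom_lengths, window = 1e6, step = 2e4) {
  purrr::imap(as.list(chrom_lengths), function(len, chr) {
    if (len <= 0) return(NULL)
    anchors <- seq(0, len, by = step)
    p <- features$pos[features$chrom == chr]
    counts <- vapply(anchors, function(s) sum(p > s - window & p <= s), 1L)
    tibble(chrom = chr, window_pos = anchors, count = counts)
  }) %>% bind_rows()
}
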