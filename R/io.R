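#' Read a genome FASTA
#'
#' Loads a genome into a [Biostrings::DNAStringSet], folding lowercase
#' (soft-masked) bases to uppercase. Record names are the first whitespace
#' token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one entry per chromosome.
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  if (length(genome) == 0) abort(paste0("empty FASTA: ", path))
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    abort(paste0("duplicate FASTA header in ", path))
  toupper_dna(genome)
}

toupper_dna <- function(genome) {
  Biostrings::DNAStringSet(toupper(as.character(genome)))
}

#' Write a genome FASTA
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read transcript models from GFF3, GTF or BED12
#'
#' Parses aligned transcript models (or a reference annotation) into a
#' transcript tibble (see [tx_tbl()]). Exon features are grouped by transcript
#' id (GFF3 `Parent`/`ID`, GTF `transcript_id`, BED12 `name`). Alignment
#' `coverage` and `identity` are taken from attributes of the transcript-level
#' feature when present and default to 1. A `tissues` attribute is split on
#' commas. Records whose exons mix chromosomes or strands are dropped with a
#' warning: such multi-locus alignments are fusion candidates and belong in
#' [read_multilocus_alignments()].
#'
#' @param path Input file.
#' @param format One of `"auto"` (by extension), `"gff3"`, `"gtf"`, `"bed12"`.
#' @return A transcript tibble.
#' @export
read_transcript_models <- function(path, format = c("auto", "gff3", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      gff = , gff3 = "gff3", gtf = "gtf", bed = "bed12",
      abort(paste0("cannot guess format of ", path))
    )
  }
  if (format == "bed12") return(read_tx_bed12(path))
  gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3")
  df <- as_tibble(as.data.frame(gr))
  if (format == "gtf") {
    df$tx_id <- df$transcript_id
  } else {
    parent <- vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
    df$tx_id <- ifelse(df$type == "exon", parent, df$ID)
  }
  ex <- df %>% filter(.data$type == "exon")
  if (!nrow(ex)) abort(paste0("no exon features in ", path))
  meta <- df %>% filter(.data$type %in% c("transcript", "mRNA"))
  # rtracklayer parses comma-separated attribute values into CharacterList
  flatten_chr <- function(v) {
    if (is.list(v)) vapply(v, function(x) paste(x, collapse = ","), "")
    else as.character(v)
  }
  meta_of <- function(col) {
    if (nrow(meta) && col %in% names(meta)) {
      setNames(flatten_chr(meta[[col]]), meta$tx_id)
    } else setNames(character(), character())
  }
  cov_map <- meta_of("coverage")
  ident_map <- meta_of("identity")
  tiss_map <- meta_of("tissues")
  gene_map <- if ("gene_id" %in% names(df)) {
    src <- df %>% filter(!is.na(.data$tx_id))
    src$gene_id <- flatten_chr(src$gene_id)
    src <- src %>% filter(!is.na(.data$gene_id), .data$gene_id != "")
    setNames(src$gene_id, src$tx_id)
  } else setNames(character(), character())

  ex <- ex %>% arrange(.data$tx_id, .data$start)
  grp <- split(ex, ex$tx_id)
  rows <- purrr::map(grp, function(g) {
    if (length(unique(g$seqnames)) > 1 || length(unique(g$strand)) > 1) {
      warn(paste0("transcript ", g$tx_id[1],
                  " has exons on multiple chromosomes/strands; dropped ",
                  "(use read_multilocus_alignments for fusion candidates)"))
      return(NULL)
    }
    id <- g$tx_id[1]
    num_or <- function(map, default) {
      v <- suppressWarnings(as.numeric(map[id]))
      if (is.na(v)) default else v
    }
    tiss <- tiss_map[id]
    tibble(
      transcript_id = id,
      gene_id = if (!is.na(gene_map[id])) unname(gene_map[id]) else NA_character_,
      chrom = as.character(g$seqnames[1]),
      strand = as.character(g$strand[1]),
      exon_starts = list(as.integer(g$start - 1L)),
      exon_ends = list(as.integer(g$end)),
      coverage = num_or(cov_map, 1),
      identity = num_or(ident_map, 1),
      tissues = list(if (is.na(tiss)) character() else strsplit(tiss, ",")[[1]])
    )
  })
  tx <- bind_rows(rows)
  tx$seq_length <- exonic_length(tx)
  validate_tx(tx)
  tx
}

read_tx_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  start0 <- GenomicRanges::start(gr) - 1L
  blocks <- if (!is.null(gr$blocks)) gr$blocks else {
    IRanges::IRangesList(lapply(GenomicRanges::width(gr), function(w) IRanges::IRanges(1L, w)))
  }
  rows <- purrr::map(seq_along(gr), function(i) {
    b <- blocks[[i]]
    tibble(
      transcript_id = if (!is.null(gr$name)) gr$name[i] else paste0("tx", i),
      gene_id = NA_character_,
      chrom = as.character(GenomicRanges::seqnames(gr)[i]),
      strand = as.character(GenomicRanges::strand(gr)[i]),
      exon_starts = list(as.integer(start0[i] + IRanges::start(b) - 1L)),
      exon_ends = list(as.integer(start0[i] + IRanges::end(b))),
      coverage = 1, identity = 1, tissues = list(character())
    )
  })
  tx <- bind_rows(rows)
  tx$seq_length <- exonic_length(tx)
  validate_tx(tx)
  tx
}

#' Write transcript models to GFF3 or BED12
#'
#' Serialization is exact: `read_transcript_models(write_transcript_models(x))`
#' reproduces ids, coordinates and strand. GFF3 output carries `coverage`,
#' `identity`, `tissues` and `gene_id` as attributes of the transcript
#' feature; BED12 carries coordinates only.
#'
#' @param tx A transcript tibble.
#' @param path Output path.
#' @param format `"gff3"` or `"bed12"`.
#' @return `path`, invisibly.
#' @export
write_transcript_models <- function(tx, path, format = c("gff3", "bed12")) {
  format <- match.arg(format)
  validate_tx(tx)
  if (format == "gff3") {
    lines <- c("##gff-version 3", purrr::pmap(
      list(tx$transcript_id, tx$gene_id, tx$chrom, tx$strand,
           tx$exon_starts, tx$exon_ends, tx$coverage, tx$identity, tx$tissues),
      function(id, gene, chrom, strand, s, e, cov, ident, tiss) {
        attrs <- sprintf("ID=%s;coverage=%s;identity=%s", id,
                         format(cov, digits = 12), format(ident, digits = 12))
        if (!is.na(gene)) attrs <- paste0(attrs, ";gene_id=", gene)
        if (length(tiss)) attrs <- paste0(attrs, ";tissues=", paste(tiss, collapse = ","))
        c(
          sprintf("%s\tisoscope\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                  chrom, s[1] + 1L, e[length(e)], strand, attrs),
          sprintf("%s\tisoscope\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                  chrom, s + 1L, e, strand, id)
        )
      }
    ))
    writeLines(unlist(lines), path)
  } else {
    lines <- purrr::pmap_chr(
      list(tx$transcript_id, tx$chrom, tx$strand, tx$exon_starts, tx$exon_ends),
      function(id, chrom, strand, s, e) {
        sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
                chrom, s[1], e[length(e)], id, strand, s[1], e[length(e)],
                length(s),
                paste0(paste(e - s, collapse = ","), ","),
                paste0(paste(s - s[1], collapse = ","), ","))
      }
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read short-read splice-junction evidence
#'
#' Two dialects are supported. `star_sj_tab` is the 9-column splice-junction
#' table written by the STAR aligner: 1-based inclusive intron coordinates
#' (converted here to 0-based half-open), strand code 0/1/2 for
#' unknown/`+`/`-`, and column 7 (uniquely-mapping read count) used as
#' `read_count`. `bed12_junctions` is the TopHat-style dialect where each
#' record's two blocks flank exactly one intron.
#'
#' @param path Input file.
#' @param dialect `"star_sj_tab"` or `"bed12_junctions"`.
#' @param tissue Tissue label attached to every record (one file per tissue).
#' @return A tibble `chrom`, `strand` (`NA` when unknown), `intron_start`,
#'   `intron_end`, `read_count`, `tissue`.
#' @export
read_junction_evidence <- function(path, dialect = c("star_sj_tab", "bed12_junctions"),
                                   tissue = NA_character_) {
  dialect <- match.arg(dialect)
  if (dialect == "star_sj_tab") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    rows <- purrr::imap(lines, function(ln, i) {
      f <- strsplit(ln, "[\t ]+")[[1]]
      if (length(f) < 7) abort(sprintf("malformed STAR junction line %d in %s", i, path))
      nums <- suppressWarnings(as.integer(f[c(2, 3, 4, 7)]))
      if (anyNA(nums)) abort(sprintf("malformed STAR junction line %d in %s", i, path))
      tibble(
        chrom = f[1],
        strand = c(NA_character_, "+", "-")[nums[3] + 1L],
        intron_start = nums[1] - 1L,
        intron_end = nums[2],
        read_count = nums[4]
      )
    })
    ev <- bind_rows(rows)
  } else {
    tx <- read_tx_bed12(path)
    if (any(n_exons(tx) != 2))
      abort(paste0("bed12_junctions dialect requires exactly two blocks per record: ", path))
    j <- tx_junctions(tx)
    counts <- tryCatch({
      gr <- rtracklayer::import(path, format = "bed")
      if (!is.null(gr$score)) setNames(as.integer(gr$score), gr$name) else NULL
    }, error = function(e) NULL)
    ev <- tibble(
      chrom = j$chrom, strand = j$strand,
      intron_start = j$intron_start, intron_end = j$intron_end,
      read_count = if (!is.null(counts)) unname(counts[j$transcript_id]) else 1L
    )
    ev$read_count[is.na(ev$read_count)] <- 1L
  }
  if (any(ev$read_count < 0)) abort("negative read_count in junction evidence")
  ev$tissue <- tissue
  ev
}

methylation_contexts <- c("CG", "CHG", "CHH")

#' Read a per-cytosine methylation table
#'
#' Tab-separated columns `chrom`, `pos` (0-based), `strand`, `context`
#' (CG/CHG/CHH), `count_c`, `count_t`; `#` lines are comments; a header line
#' with these names is allowed. The per-site methylation level used downstream
#' is `count_c / (count_c + count_t)`.
#'
#' @param path Input TSV.
#' @return A tibble with the six columns above.
#' @export
read_methylation <- function(path) {
  meth <- readr::read_tsv(
    path, comment = "#",
    col_names = c("chrom", "pos", "strand", "context", "count_c", "count_t"),
    col_types = "cccccc", progress = FALSE
  )
  if (nrow(meth) && meth$chrom[1] == "chrom") meth <- meth[-1, , drop = FALSE]
  meth$pos <- as.integer(meth$pos)
  meth$count_c <- as.integer(meth$count_c)
  meth$count_t <- as.integer(meth$count_t)
  if (!nrow(meth)) return(meth)
  bad <- !meth$context %in% methylation_contexts
  if (any(bad)) abort(paste0("invalid methylation context: ",
                             paste(unique(meth$context[bad]), collapse = ", ")))
  if (any(meth$count_c < 0 | meth$count_t < 0, na.rm = TRUE))
    abort("negative methylation counts")
  if (!all(meth$strand %in% c("+", "-"))) abort("methylation strand must be '+' or '-'")
  if (anyDuplicated(meth[c("chrom", "pos", "strand")]))
    abort("duplicate (chrom, pos, strand) in methylation table")
  meth
}

#' Write a methylation table
#' @param meth A methylation tibble (see [read_methylation()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(meth, path) {
  readr::write_tsv(meth, path, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a tabular homology-hit table
#'
#' Tab-separated columns `query_id`, `subject_db` (e.g. sorghum, rice,
#' brachypodium, TE, known_lncRNA), `subject_id`, `e_value`, `coverage`,
#' `identity`, `subject_class` (optional label such as a TE superfamily).
#'
#' @param path Input TSV ('#' comments allowed).
#' @return A tibble with the seven columns above.
#' @export
read_homology_hits <- function(path) {
  hits <- readr::read_tsv(
    path, comment = "#",
    col_names = c("query_id", "subject_db", "subject_id", "e_value",
                  "coverage", "identity", "subject_class"),
    col_types = "ccccccc", progress = FALSE
  )
  if (nrow(hits) && hits$query_id[1] == "query_id") hits <- hits[-1, , drop = FALSE]
  hits$e_value <- as.numeric(hits$e_value)
  hits$coverage <- as.numeric(hits$coverage)
  hits$identity <- as.numeric(hits$identity)
  if (nrow(hits)) {
    if (any(hits$e_value < 0, na.rm = TRUE)) abort("negative e-value in homology hits")
    if (any(hits$coverage < 0 | hits$coverage > 1 |
              hits$identity < 0 | hits$identity > 1, na.rm = TRUE))
      abort("homology coverage/identity must lie in [0, 1]")
  }
  hits
}

#' Write a homology-hit table
#' @param hits Homology tibble (see [read_homology_hits()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_homology_hits <- function(hits, path) {
  readr::write_tsv(hits, path, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read multi-locus (fusion candidate) alignments
#'
#' One row per locus alignment of a query read: tab-separated columns
#' `query_id`, `read_length`, `q_start`, `q_end` (0-based half-open span on
#' the read), `chrom`, `strand`, `exon_starts`, `exon_ends` (comma-separated
#' 0-based coordinates), `identity`.
#'
#' @param path Input TSV ('#' comments allowed).
#' @return A tibble with list-columns `exon_starts`, `exon_ends`.
#' @export
read_multilocus_alignments <- function(path) {
  aln <- readr::read_tsv(
    path, comment = "#",
    col_names = c("query_id", "read_length", "q_start", "q_end", "chrom",
                  "strand", "exon_starts", "exon_ends", "identity"),
    col_types = "ccccccccc", progress = FALSE
  )
  if (nrow(aln) && aln$query_id[1] == "query_id") aln <- aln[-1, , drop = FALSE]
  aln$read_length <- as.integer(aln$read_length)
  aln$q_start <- as.integer(aln$q_start)
  aln$q_end <- as.integer(aln$q_end)
  aln$identity <- as.numeric(aln$identity)
  split_int <- function(x) lapply(strsplit(x, ","), as.integer)
  aln$exon_starts <- split_int(aln$exon_starts)
  aln$exon_ends <- split_int(aln$exon_ends)
  aln
}

#' Write multi-locus alignments
#' @param aln Multi-locus alignment tibble (see [read_multilocus_alignments()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_multilocus_alignments <- function(aln, path) {
  out <- aln
  out$exon_starts <- vapply(aln$exon_starts, paste, "", collapse = ",")
  out$exon_ends <- vapply(aln$exon_ends, paste, "", collapse = ",")
  readr::write_tsv(out, path, col_names = TRUE, progress = FALSE)
  invisible(path)
}
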