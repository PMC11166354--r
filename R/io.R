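#' Read and write standard sequence and interval formats
#'
#' Thin wrappers over Biostrings and rtracklayer that move between files and
#' the tibble/character conventions used throughout the package: FASTA
#' wrapped at 60 columns, FASTQ Phred+33, GFF3 1-based closed on disk
#' (converted to 0-based half-open in memory), BED/bedGraph 0-based
#' half-open.
#'
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname io
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' @rdname io
#' @export
read_fastq <- function(path) {
  # the parser stashes qualities in a metadata column before pairing them
  # with the sequences and warns when that column is dropped again
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  tibble(read_id = sub("\\s.*$", "", names(x)),
         read = unname(as.character(x)),
         quality = unname(as.character(Biostrings::quality(x))))
}

#' @rdname io
#' @param reads tibble with `read_id`, `read`, `quality` columns.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$read),
    Biostrings::PhredQuality(reads$quality))
  names(x) <- reads$read_id
  # qualities ride along as a metadata column; the writer emits them in the
  # quality line and warns about dropping the column itself
  withCallingHandlers(
    Biostrings::writeQualityScaledXStringSet(x, path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  invisible(path)
}

#' @rdname io
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(seqname = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         strand = chartr("*", ".", as.character(GenomicRanges::strand(gr))),
         type = as.character(gr$type),
         name = if (!is.null(gr$Name)) as.character(gr$Name) else
           as.character(gr$ID %||% NA_character_))
}

#' @rdname io
#' @param features tibble with `start`, `end` (0-based half-open), `strand`,
#'   `type`, `name`.
#' @param seqname sequence name for single-sequence feature tables.
#' @export
write_gff3 <- function(features, path, seqname = "seq1") {
  if (!"seqname" %in% names(features)) features$seqname <- seqname
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqname,
    ranges = IRanges::IRanges(features$start + 1L, features$end),
    strand = chartr(".", "*", features$strand))
  gr$type <- features$type
  gr$Name <- features$name
  gr$source <- "repeatloop"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname io
#' @param intervals tibble with `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @export
write_bed <- function(intervals, path, seqname = "seq1") {
  has <- function(col) col %in% names(intervals)
  gr <- GenomicRanges::GRanges(
    seqnames = if (has("seqname")) intervals$seqname else seqname,
    ranges = IRanges::IRanges(intervals$start + 1L, intervals$end),
    strand = if (has("strand")) chartr(".", "*", intervals$strand) else "*")
  if (has("name")) gr$name <- intervals$name
  if (has("score")) gr$score <- intervals$score
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname io
#' @param track tibble with `start`, `end`, `value`.
#' @export
write_bedgraph <- function(track, path, seqname = "seq1") {
  gr <- GenomicRanges::GRanges(
    seqnames = if ("seqname" %in% names(track)) track$seqname else seqname,
    ranges = IRanges::IRanges(track$start + 1L, track$end))
  gr$score <- track$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname io
#' @details `read_ct_table()` accepts TSV or CSV with columns (case
#'   insensitive) `sample`, `group`, `amplicon`, `replicate`, `ct`.
#' @export
read_ct_table <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  x <- reader(path, show_col_types = FALSE, comment = "#")
  names(x) <- tolower(names(x))
  need <- c("sample", "group", "amplicon", "replicate", "ct")
  if (!all(need %in% names(x))) {
    abort(sprintf("Ct table must have columns: %s", paste(need, collapse = ", ")))
  }
  as_tibble(x[need])
}
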