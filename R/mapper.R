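#' Build an exact-match sequence index
#'
#' Indexes one or more named reference sequences for zero-mismatch substring
#' queries on both strands. Internally a per-read-width dictionary of
#' forward-strand reference windows is built on first use and cached, so
#' classifying many libraries against the same index costs one hash lookup
#' per read. `N` in a read never matches.
#'
#' @param references named character vector (or named `DNAStringSet`) of
#'   reference sequences over `{A,C,G,T,N}`.
#' @return object of class `sequence_index`.
#' @export
build_index <- function(references) {
  if (inherits(references, "DNAStringSet")) {
    references <- setNames(as.character(references), names(references))
  }
  if (is.null(names(references)) || any(!nzchar(names(references)))) {
    abort("references must be named")
  }
  if (anyDuplicated(names(references))) abort("duplicate reference names")
  references <- toupper(references)
  check_dna(references, "reference")
  structure(list(refs = references,
                 lens = setNames(nchar(references), names(references)),
                 cache = new.env(parent = emptyenv())),
            class = "sequence_index")
}

#' @export
print.sequence_index <- function(x, ...) {
  cat(sprintf("<sequence_index> %d reference(s), %s bp total\n",
              length(x$refs), format(sum(x$lens), big.mark = ",")))
  invisible(x)
}

# cached dictionary of all width-w forward-strand reference windows:
# unique window values with total occurrence count and, for single-occurrence
# values, their (ref, 0-based position)
width_lookup <- function(index, w) {
  key <- as.character(w)
  if (!is.null(index$cache[[key]])) return(index$cache[[key]])
  subs <- character(0); refs <- character(0); pos <- integer(0)
  for (nm in names(index$refs)) {
    s <- seq_windows(index$refs[[nm]], w)
    if (!length(s)) next
    subs <- c(subs, s)
    refs <- c(refs, rep(nm, length(s)))
    pos <- c(pos, seq_along(s) - 1L)
  }
  if (!length(subs)) {
    lk <- list(u = character(0), count = integer(0),
               ref = character(0), pos = integer(0))
  } else {
    u <- unique(subs)
    m <- match(subs, u)
    count <- tabulate(m, nbins = length(u))
    first <- which(!duplicated(m))
    ord <- m[first]                        # == seq_along(u)
    lk <- list(u = u, count = count,
               ref = refs[first][order(ord)], pos = pos[first][order(ord)])
  }
  index$cache[[key]] <- lk
  lk
}

lookup_counts <- function(lk, seqs) {
  m <- match(seqs, lk$u)
  list(count = ifelse(is.na(m), 0L, lk$count[m]),
       ref = lk$ref[m], pos = lk$pos[m])
}

#' Classify reads by exact-match placement
#'
#' Counts zero-mismatch occurrences of each read over both strands of all
#' indexed references. Zero occurrences classifies the read `unmapped`,
#' exactly one `unique` (with its placement), two or more `multi` (no
#' placement; a perfect palindrome matching one locus on both strands counts
#' twice and is therefore `multi`). This reproduces the contract of
#' zero-mismatch, suppress-multimapper short-read alignment.
#'
#' @param index a `sequence_index`.
#' @param reads character vector of read sequences (`{A,C,G,T,N}`).
#' @param read_id optional identifiers (default `read_1..n`).
#' @param mode `"unique"` (default; placements only for unique reads) or
#'   `"all"` (every placement reported, one row per hit, for all-reads
#'   profiles).
#' @return tibble with `read_id`, `read`, `status`, `ref_name`, `start`
#'   (0-based), `strand`, `length`. In `"all"` mode multi reads contribute
#'   one row per placement.
#' @export
classify_reads <- function(index, reads, read_id = NULL,
                           mode = c("unique", "all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(index, "sequence_index"))
  if (!length(reads)) {
    return(tibble(read_id = character(), read = character(),
                  status = character(), ref_name = character(),
                  start = integer(), strand = character(), length = integer()))
  }
  reads <- toupper(reads)
  check_dna(reads, "read")
  if (any(nchar(reads) < 1L)) abort("reads must have length >= 1")
  read_id <- read_id %||% paste0("read_", seq_along(reads))

  useq <- unique(reads)
  n_u <- length(useq)
  has_n <- grepl("N", useq, fixed = TRUE)
  status <- rep("unmapped", n_u)
  ref_name <- rep(NA_character_, n_u)
  start0 <- rep(NA_integer_, n_u)
  strand <- rep(NA_character_, n_u)

  by_w <- split(which(!has_n), nchar(useq[!has_n]))
  for (wchr in names(by_w)) {
    ii <- by_w[[wchr]]
    lk <- width_lookup(index, as.integer(wchr))
    fwd <- lookup_counts(lk, useq[ii])
    rcs <- revcomp(useq[ii])
    rev <- lookup_counts(lk, rcs)
    tot <- fwd$count + rev$count
    status[ii] <- ifelse(tot == 0L, "unmapped",
                         ifelse(tot == 1L, "unique", "multi"))
    up <- tot == 1L & fwd$count == 1L
    um <- tot == 1L & rev$count == 1L
    ref_name[ii[up]] <- fwd$ref[up]
    start0[ii[up]] <- fwd$pos[up]
    strand[ii[up]] <- "+"
    ref_name[ii[um]] <- rev$ref[um]
    start0[ii[um]] <- rev$pos[um]
    strand[ii[um]] <- "-"
  }

  idx <- match(reads, useq)
  read_status <- status[idx]
  out <- tibble(read_id = read_id, read = reads, status = read_status,
                ref_name = ref_name[idx], start = start0[idx],
                strand = strand[idx],
                length = ifelse(read_status == "unique", nchar(reads),
                                NA_integer_))
  if (mode == "unique") return(out)

  # all-placements mode: enumerate every hit (including overlapping and
  # both-strand hits) with a direct scan per unique mapped sequence
  hits <- list()
  for (i in which(status != "unmapped")) {
    s <- useq[i]
    rc <- revcomp(s)
    for (nm in names(index$refs)) {
      subj <- Biostrings::DNAString(index$refs[[nm]])
      for (sd in c("+", "-")) {
        pat <- if (sd == "+") s else rc
        m <- Biostrings::matchPattern(pat, subj)
        if (length(m)) {
          hits[[length(hits) + 1L]] <- tibble(
            .uidx = i, ref_name = nm,
            start = Biostrings::start(m) - 1L, strand = sd)
        }
      }
    }
  }
  hits <- bind_rows(hits)
  placed <- tibble(read_id = read_id, read = reads, status = status[idx],
                   .uidx = idx, length = nchar(reads)) |>
    inner_join(hits, by = ".uidx", relationship = "many-to-many") |>
    select("read_id", "read", "status", "ref_name", "start", "strand",
           "length")
  none <- out |> filter(.data$status == "unmapped")
  bind_rows(placed, none) |> arrange(match(.data$read_id, read_id))
}

#' Two-pass genome-then-target filtering
#'
#' Reproduces the published filtering cascade: reads are first classified
#' against a background genome; multi-mappers are discarded; the surviving
#' (genome-unique or genome-unmapped) reads are classified against the target
#' (typically the collapsed haplotype) and only unique target placements are
#' retained.
#'
#' @param reads character vector of read sequences.
#' @param genome_index `sequence_index` of the background genome, or `NULL`
#'   to skip the first pass.
#' @param target_index `sequence_index` of the target reference.
#' @param read_id optional identifiers.
#' @return tibble of unique target alignments (columns as
#'   [classify_reads()]), plus attribute `"filter_counts"`: a tibble of read
#'   fates across the cascade.
#' @export
two_pass_filter <- function(reads, genome_index, target_index, read_id = NULL) {
  read_id <- read_id %||% paste0("read_", seq_along(reads))
  if (!is.null(genome_index)) {
    g <- classify_reads(genome_index, reads, read_id)
    keep <- g$status != "multi"
    n_genome_multi <- sum(!keep)
    reads <- reads[keep]
    read_id <- read_id[keep]
  } else {
    n_genome_multi <- 0L
  }
  t <- classify_reads(target_index, reads, read_id)
  out <- t |> filter(.data$status == "unique")
  counts <- tibble(
    stage = c("genome_multi", "target_multi", "target_unmapped", "retained"),
    n = c(n_genome_multi, sum(t$status == "multi"),
          sum(t$status == "unmapped"), nrow(out)))
  attr(out, "filter_counts") <- counts
  out
}
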