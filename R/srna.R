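#' Construct a small-RNA library object
#'
#' @param reads character vector of processed read sequences.
#' @param name library identifier.
#' @param genotype,tissue labels carried through grouping and testing.
#' @param clean_total reads-per-million denominator (reads surviving
#'   structural-RNA removal); set by [filter_structural()].
#' @return object of class `srna_library`.
#' @export
srna_library <- function(reads, name, genotype = NA_character_,
                         tissue = NA_character_, clean_total = NA_integer_) {
  structure(list(reads = reads, name = name, genotype = genotype,
                 tissue = tissue, clean_total = clean_total),
            class = "srna_library")
}

#' @export
print.srna_library <- function(x, ...) {
  cat(sprintf("<srna_library> %s (%s, %s): %d reads, clean_total %s\n",
              x$name, x$genotype, x$tissue, length(x$reads),
              ifelse(is.na(x$clean_total), "unset", x$clean_total)))
  invisible(x)
}

#' Preprocess raw small-RNA reads
#'
#' 3' adapter removal under the shared k/mink/hdist contract, followed by
#' protocol-specific handling: for the `umi4n` protocol (4 random nt flanking
#' the insert on both sides) reads are deduplicated on the full trimmed
#' sequence first, then 4 nt are removed from each end; for `plain` libraries
#' deduplication is optional. A final length filter keeps 18-30 nt inserts.
#'
#' @param reads character vector of raw read sequences (or tibble with a
#'   `read` column).
#' @param adapter 3' adapter sequence.
#' @param protocol `"umi4n"` or `"plain"`.
#' @param length_range final insert length window (default `c(18, 30)`).
#' @param stage_range trimmed-read length window applied right after adapter
#'   removal (default `c(26, 38)` for `umi4n`, i.e. the insert window plus
#'   the 8 random nt; `length_range` for `plain`).
#' @param dedup deduplicate on full sequence (`plain` protocol only; always
#'   on for `umi4n`).
#' @param trim_k,trim_mink,trim_hdist adapter-trim contract (defaults 18, 11,
#'   1).
#' @param name,genotype,tissue metadata for the returned library.
#' @return an [srna_library()] (with a warning and zero reads if everything
#'   is filtered).
#' @export
preprocess_srna <- function(reads, adapter, protocol = c("umi4n", "plain"),
                            length_range = c(18L, 30L), stage_range = NULL,
                            dedup = TRUE, trim_k = 18L, trim_mink = 11L,
                            trim_hdist = 1L, name = "lib",
                            genotype = NA_character_, tissue = NA_character_) {
  protocol <- match.arg(protocol)
  if (is.data.frame(reads)) reads <- reads$read
  if (!nzchar(adapter)) abort("adapter must be non-empty")
  reads <- toupper(reads)
  stage_range <- stage_range %||%
    if (protocol == "umi4n") c(26L, 38L) else length_range

  tr <- trim_right_adapter(reads, adapter, trim_k, trim_mink, trim_hdist)
  x <- tr$read
  x <- x[nchar(x) >= stage_range[1] & nchar(x) <= stage_range[2]]
  if (protocol == "umi4n") {
    x <- unique(x)
    x <- substr(x, 5L, nchar(x) - 4L)
  } else if (dedup) {
    x <- unique(x)
  }
  x <- x[nchar(x) >= length_range[1] & nchar(x) <= length_range[2]]
  if (!length(x)) warn(sprintf("library %s is empty after preprocessing", name))
  srna_library(x, name = name, genotype = genotype, tissue = tissue)
}

#' Remove structural (rRNA/tRNA) reads
#'
#' Reads with any exact placement on the structural reference are removed;
#' the survivors are "clean" and their count becomes the library's
#' reads-per-million denominator.
#'
#' @param lib an [srna_library()].
#' @param structural either a `sequence_index` or named character vector of
#'   rRNA/tRNA sequences.
#' @return the library with structural reads removed and `clean_total` set.
#' @export
filter_structural <- function(lib, structural) {
  stopifnot(inherits(lib, "srna_library"))
  if (!inherits(structural, "sequence_index")) {
    structural <- build_index(structural)
  }
  if (length(lib$reads)) {
    cls <- classify_reads(structural, lib$reads)
    lib$reads <- lib$reads[cls$status == "unmapped"]
  }
  lib$clean_total <- length(lib$reads)
  lib
}

#' Map a small-RNA library with the two-pass cascade
#'
#' @param lib a clean [srna_library()] (after [filter_structural()]).
#' @param genome_index background genome `sequence_index` (or `NULL`).
#' @param target_index target `sequence_index` (collapsed haplotype).
#' @return tibble of unique target alignments with a `library` column;
#'   attribute `clean_total` carries the rpm denominator.
#' @export
map_srna_library <- function(lib, genome_index, target_index) {
  stopifnot(inherits(lib, "srna_library"))
  if (is.na(lib$clean_total)) {
    abort("library has no clean_total; run filter_structural() first")
  }
  aln <- two_pass_filter(lib$reads, genome_index, target_index)
  aln$library <- lib$name
  attr(aln, "clean_total") <- lib$clean_total
  aln
}

# alignments (one or a list) -> single tibble + named clean totals
gather_alignments <- function(alignments, clean_totals = NULL) {
  if (is.data.frame(alignments)) alignments <- list(alignments)
  ct <- clean_totals %||%
    setNames(vapply(alignments, function(a) attr(a, "clean_total") %||%
                      NA_integer_, numeric(1)),
             vapply(alignments, function(a) a$library[1], character(1)))
  if (any(is.na(ct))) abort("clean totals missing for some libraries")
  list(aln = bind_rows(alignments), clean_totals = ct)
}

#' Call small-RNA clusters on a collapsed reference
#'
#' Cluster islands are the union of uniquely-mapped read intervals across the
#' defining libraries, merged whenever separated by less than `pad` bp, and
#' retained when their summed read count reaches the coverage floor. The
#' floor is recomputed from the defining libraries' clean totals as
#' `ceiling(mincov_rpm * sum(clean_total) / 1e6)` (the published floor of 152
#' reads is 0.5 rpm for its datasets).
#'
#' @param alignments a list of alignment tibbles from [map_srna_library()]
#'   (the defining libraries), or one combined tibble.
#' @param clean_totals named vector of rpm denominators (taken from the
#'   alignment attributes when omitted).
#' @param mincov_rpm coverage floor in rpm (default 0.5).
#' @param pad minimum distance between independent clusters (default 50).
#' @return tibble of class `srna_cluster_set`: `cluster` (dense ids by
#'   coordinate), `start`, `end` (0-based half-open), `n_reads`.
#' @export
call_clusters <- function(alignments, clean_totals = NULL, mincov_rpm = 0.5,
                          pad = 50L) {
  if (pad < 0L) abort("pad must be >= 0")
  g <- gather_alignments(alignments, clean_totals)
  mincov_reads <- ceiling(mincov_rpm * sum(g$clean_totals) / 1e6)
  empty <- tibble(cluster = integer(), start = integer(), end = integer(),
                  n_reads = integer())
  if (!nrow(g$aln)) return(structure(empty, class = c("srna_cluster_set", class(empty)),
                                     mincov_reads = mincov_reads))
  ir <- IRanges::IRanges(start = g$aln$start + 1L, width = g$aln$length)
  merged <- IRanges::reduce(ir, min.gapwidth = pad)
  hits <- IRanges::findOverlaps(ir, merged)
  cnt <- tabulate(S4Vectors::subjectHits(hits), nbins = length(merged))
  out <- tibble(start = IRanges::start(merged) - 1L,
                end = IRanges::end(merged),
                n_reads = as.integer(cnt)) |>
    filter(.data$n_reads >= mincov_reads) |>
    arrange(.data$start) |>
    mutate(cluster = row_number(), .before = 1L)
  structure(out, class = c("srna_cluster_set", class(out)),
            mincov_reads = mincov_reads)
}

# per-cluster, per-library counts (>= 1 bp overlap) and rpm
count_in_clusters <- function(clusters, aln, clean_totals) {
  libs <- names(clean_totals)
  grid <- tidyr::expand_grid(cluster = clusters$cluster, library = libs)
  if (nrow(aln)) {
    ir_read <- IRanges::IRanges(aln$start + 1L, width = aln$length)
    ir_cl <- IRanges::IRanges(clusters$start + 1L, clusters$end)
    hits <- IRanges::findOverlaps(ir_read, ir_cl)
    ov <- tibble(library = aln$library[S4Vectors::queryHits(hits)],
                 cluster = clusters$cluster[S4Vectors::subjectHits(hits)]) |>
      count(.data$cluster, .data$library, name = "count")
  } else {
    ov <- tibble(cluster = integer(), library = character(), count = integer())
  }
  grid |>
    left_join(ov, by = c("cluster", "library")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L),
           clean_total = unname(clean_totals[.data$library]),
           rpm = 1e6 * .data$count / .data$clean_total)
}

#' Quantify clusters and test differential abundance between two groups
#'
#' Computes per-library rpm per cluster, group means, the fold change
#' `mean_B / mean_A`, and a two-sided two-sample t-test on the per-library
#' rpm values (Welch by default). When both groups have zero variance and
#' equal means the p-value is 1 by convention. No multiple-testing correction
#' is applied by default; `p_adjust = "bonferroni"` is available.
#'
#' @param clusters an `srna_cluster_set`.
#' @param group_a,group_b lists of alignment tibbles (from
#'   [map_srna_library()]) for the two groups; group A is the reference of
#'   the fold change.
#' @param test `"welch"` (default) or `"pooled"`.
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return tibble of class `srna_diff`: per-cluster `mean_a`, `mean_b`,
#'   `fold`, `t`, `p` (and `p_adj` when adjusted), with per-library rpm in
#'   attribute `"rpm"`.
#' @export
quantify_and_test <- function(clusters, group_a, group_b,
                              test = c("welch", "pooled"),
                              p_adjust = "none") {
  test <- match.arg(test)
  ga <- gather_alignments(group_a)
  gb <- gather_alignments(group_b)
  qa <- count_in_clusters(clusters, ga$aln, ga$clean_totals) |>
    mutate(group = "A")
  qb <- count_in_clusters(clusters, gb$aln, gb$clean_totals) |>
    mutate(group = "B")
  rpm <- bind_rows(qa, qb)
  res <- rpm |>
    group_by(.data$cluster) |>
    group_modify(function(d, key) {
      a <- d$rpm[d$group == "A"]; b <- d$rpm[d$group == "B"]
      fold <- mean(b) / mean(a)
      if (length(a) < 2L || length(b) < 2L) {
        return(tibble(mean_a = mean(a), mean_b = mean(b), fold = fold,
                      t = NA_real_, p = NA_real_))
      }
      if (sd(a) == 0 && sd(b) == 0) {
        if (mean(a) == mean(b)) {
          return(tibble(mean_a = mean(a), mean_b = mean(b), fold = fold,
                        t = 0, p = 1))
        }
        return(tibble(mean_a = mean(a), mean_b = mean(b), fold = fold,
                      t = Inf * sign(mean(b) - mean(a)), p = 0))
      }
      tt <- t.test(b, a, var.equal = (test == "pooled"))
      tibble(mean_a = mean(a), mean_b = mean(b), fold = fold,
             t = unname(tt$statistic), p = tt$p.value)
    }) |>
    ungroup() |>
    left_join(as_tibble(clusters)[, c("cluster", "start", "end")],
              by = "cluster") |>
    relocate("cluster", "start", "end")
  if (p_adjust != "none") res$p_adj <- stats::p.adjust(res$p, method = p_adjust)
  structure(res, class = c("srna_diff", class(res)), rpm = rpm, test = test)
}

#' 5'-collapsed size/strand profile over a region
#'
#' Collapses uniquely-mapped reads to their strand-aware 5'-most coordinate
#' (plus strand: interval start; minus strand: interval end - 1), keeps those
#' inside the region, and reports mean rpm per half-open bin, strand and read
#' length across libraries.
#'
#' @param alignments list of alignment tibbles from [map_srna_library()] (or
#'   one tibble).
#' @param region `c(start, end)` 0-based half-open region on the reference.
#' @param bin bin width in nt (default 10).
#' @return tibble `bin_start`, `strand`, `length`, `rpm` (mean across
#'   libraries).
#' @export
collapse_5prime_profile <- function(alignments, region, bin = 10L) {
  g <- gather_alignments(alignments)
  libs <- names(g$clean_totals)
  aln <- g$aln |>
    mutate(p5 = ifelse(.data$strand == "+", .data$start,
                       .data$start + .data$length - 1L)) |>
    filter(.data$p5 >= region[1], .data$p5 < region[2]) |>
    mutate(bin_start = region[1] +
             ((.data$p5 - region[1]) %/% bin) * bin)
  aln |>
    count(.data$library, .data$bin_start, .data$strand, .data$length,
          name = "count") |>
    mutate(rpm = 1e6 * .data$count / g$clean_totals[.data$library]) |>
    group_by(.data$bin_start, .data$strand, .data$length) |>
    summarise(rpm = sum(.data$rpm) / length(libs), .groups = "drop")
}

#' Size-class profile of a library
#'
#' Per-length percentages of 18-30 nt reads, over the whole library or over
#' reads whose unique alignments overlap a region by at least 1 bp.
#'
#' @param lib an [srna_library()] (whole-library profile), or an alignment
#'   tibble from [map_srna_library()] when `region` is given.
#' @param region optional `c(start, end)` 0-based half-open region.
#' @param lengths length window (default 18:30).
#' @return tibble of class `size_class_profile`: `length`, `n`, `pct`;
#'   attribute `total` holds the read count (zero rows are kept with `pct`
#'   `NaN`-free; an empty profile is flagged via attribute `empty`).
#' @export
size_class_profile <- function(lib, region = NULL, lengths = 18:30) {
  if (inherits(lib, "srna_library")) {
    lens <- nchar(lib$reads)
  } else {
    aln <- lib
    if (!is.null(region)) {
      aln <- aln |>
        filter(.data$start < region[2], .data$start + .data$length > region[1])
    }
    lens <- aln$length
  }
  lens <- lens[lens %in% lengths]
  total <- length(lens)
  out <- tibble(length = as.integer(lengths),
                n = vapply(lengths, function(L) sum(lens == L), integer(1))) |>
    mutate(pct = if (total > 0) 100 * .data$n / total else 0)
  if (total == 0L) warn("empty region/library: size-class profile undefined")
  structure(out, class = c("size_class_profile", class(out)),
            total = total, empty = total == 0L)
}

#' Normalize a mutant size-class profile by its 21-mer fraction
#'
#' 24-nt RNA loss in RdDM mutants inflates the relative share of other size
#' classes; since 21-mer levels are unaffected by these mutants, scaling the
#' mutant percentages by `pct21(control) / pct21(mutant)` restores
#' comparability. The residual fraction per length is the normalized mutant
#' percentage over the control percentage.
#'
#' @param mutant,control `size_class_profile` objects.
#' @return tibble `length`, `pct_mutant`, `pct_control`, `normalized_pct`,
#'   `residual_fraction`.
#' @export
normalize_by_21mer <- function(mutant, control) {
  p21m <- mutant$pct[mutant$length == 21L]
  p21c <- control$pct[control$length == 21L]
  if (!length(p21m) || !length(p21c) || p21m == 0 || p21c == 0) {
    abort("21-mer percentage is zero or absent: normalization undefined")
  }
  tibble(length = mutant$length,
         pct_mutant = mutant$pct,
         pct_control = control$pct[match(mutant$length, control$length)]) |>
    mutate(normalized_pct = .data$pct_mutant * p21c / p21m,
           residual_fraction = ifelse(.data$pct_control > 0,
                                      .data$normalized_pct / .data$pct_control,
                                      NA_real_))
}
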