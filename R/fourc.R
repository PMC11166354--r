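#' 4C pipeline configuration
#'
#' Bundles the amplicon anatomy and filtering parameters of the 4C read
#' parser. Defaults reproduce the published filtering cascade for 49 bp
#' single-end reads of `P5 - forward primer (bait) - DpnII - interacting
#' sequence - NlaIII - reverse primer - P7` amplicons: an anchor check for
#' the first cutter in primer context, a left trim through the forward
#' primer, an optional right trim of the second cutter plus reverse primer,
#' and a quality filter.
#'
#' @param bait_position 0-based position of the bait fragment midpoint on the
#'   haplotype (used to centre the exclusion window).
#' @param forward_anchor 3' 3 nt of the forward primer plus first-cutter site.
#' @param left_trim_adapter 3' end of the forward primer (trimming through it
#'   leaves the first-cutter site at the fragment 5' end).
#' @param right_trim_adapter second-cutter site plus reverse-primer start.
#' @param first_cutter,second_cutter restriction sites (DpnII `GATC`,
#'   NlaIII `CATG`).
#' @param anchor_k,anchor_min_k,anchor_max_hamming anchor-match contract.
#' @param left_trim_k,left_trim_min_k,left_trim_max_hamming,post_left_max_len
#'   left-trim contract; reads longer than `post_left_max_len` after the trim
#'   (i.e. whose primer was not recognized) are rejected.
#' @param right_trim_k,right_trim_min_k,right_trim_max_hamming right-trim
#'   contract.
#' @param min_fragment_len minimum retained fragment (ensures an interacting
#'   sequence is present).
#' @param quality_floor mean Phred quality floor (also the 3' trim threshold).
#' @param read_length expected read length.
#' @param exclusion_radius bp excluded on either side of the bait.
#' @param bin_size bp per bin for binned displays.
#' @return list of class `fourc_config`.
#' @export
fourc_config <- function(bait_position = 0L,
                         forward_anchor = "CTCGATC",
                         left_trim_adapter = "TACGCCGGCGGAGCTC",
                         right_trim_adapter = "CATGAGCTATGA",
                         first_cutter = "GATC",
                         second_cutter = "CATG",
                         anchor_k = 7L, anchor_min_k = 7L,
                         anchor_max_hamming = 1L,
                         left_trim_k = 16L, left_trim_min_k = 12L,
                         left_trim_max_hamming = 2L,
                         post_left_max_len = 28L,
                         right_trim_k = 12L, right_trim_min_k = 7L,
                         right_trim_max_hamming = 1L,
                         min_fragment_len = 8L,
                         quality_floor = 20L,
                         read_length = 49L,
                         exclusion_radius = 2000L,
                         bin_size = 2000L) {
  cfg <- as.list(environment())
  stopifnot(cfg$anchor_k >= 1L, cfg$left_trim_k >= 1L, cfg$right_trim_k >= 1L)
  check_dna(toupper(c(forward_anchor, left_trim_adapter, right_trim_adapter)),
            "adapter")
  structure(cfg, class = "fourc_config")
}

#' Parse 4C reads by their designed amplicon anatomy
#'
#' Runs the four-stage filtering cascade on raw reads and returns the
#' captured first-cutter-adjacent fragment for proper amplicons, or a single
#' rejection reason per read. The retained fragment starts with the
#' first-cutter site (genomic, so it maps at the captured fragment's
#' position); the second cutter and reverse primer, when present, are
#' removed.
#'
#' @param reads tibble with columns `read_id`, `read` and `quality`
#'   (Phred+33), e.g. from [read_fastq()].
#' @param cfg a [fourc_config()].
#' @return tibble `read_id`, `fragment` (NA when rejected), `reject_reason`
#'   (one of `anchor`, `left_trim`, `min_fragment_len`, `quality`, or NA when
#'   retained).
#' @export
parse_4c_reads <- function(reads, cfg) {
  stopifnot(inherits(cfg, "fourc_config"),
            all(c("read_id", "read", "quality") %in% names(reads)))
  n <- nrow(reads)
  seqs <- toupper(reads$read)
  qual <- reads$quality
  reason <- rep(NA_character_, n)

  # stage 1: first-cutter site in forward-primer context
  ok <- adapter_contains(seqs, cfg$forward_anchor, cfg$anchor_k,
                         cfg$anchor_min_k, cfg$anchor_max_hamming)
  reason[!ok] <- "anchor"

  # stage 2: left trim through the forward primer; unrecognized primers leave
  # the read over the length cap
  act <- which(is.na(reason))
  if (length(act)) {
    lt <- trim_left_adapter(seqs[act], cfg$left_trim_adapter, cfg$left_trim_k,
                            cfg$left_trim_min_k, cfg$left_trim_max_hamming)
    cut <- ifelse(lt$trimmed, lt$cut, 0L)
    seqs[act] <- lt$read
    qual[act] <- substr(qual[act], cut + 1L, nchar(qual[act]) + cut)
    too_long <- nchar(seqs[act]) > cfg$post_left_max_len
    reason[act[too_long]] <- "left_trim"
  }

  # stage 3: right trim of second cutter + reverse primer, if present
  act <- which(is.na(reason))
  if (length(act)) {
    rt <- trim_right_adapter(seqs[act], cfg$right_trim_adapter,
                             cfg$right_trim_k, cfg$right_trim_min_k,
                             cfg$right_trim_max_hamming)
    seqs[act] <- rt$read
    qual[act] <- substr(qual[act], 1L, nchar(rt$read))
    short <- nchar(seqs[act]) < cfg$min_fragment_len
    reason[act[short]] <- "min_fragment_len"
  }

  # stage 4: 3' quality trim then mean-quality and length floor
  act <- which(is.na(reason))
  if (length(act)) {
    qt <- qtrim_right(seqs[act], qual[act], cfg$quality_floor)
    seqs[act] <- qt$read
    bad <- qt$mean_q < cfg$quality_floor | qt$length < cfg$min_fragment_len
    reason[act[bad]] <- "quality"
  }

  tibble(read_id = reads$read_id,
         fragment = ifelse(is.na(reason), seqs, NA_character_),
         reject_reason = reason)
}

#' Rejection report for a parsed 4C library
#'
#' @param parsed output of [parse_4c_reads()].
#' @return tibble of stage-wise read fates; counts sum to the input size.
#' @export
fourc_rejection_report <- function(parsed) {
  parsed |>
    mutate(fate = ifelse(is.na(.data$reject_reason), "retained",
                         .data$reject_reason)) |>
    count(.data$fate, name = "n") |>
    arrange(match(.data$fate, c("anchor", "left_trim", "min_fragment_len",
                                "quality", "retained")))
}

#' Quantify 4C ligation tags near a bait
#'
#' Maps parsed fragments with the two-pass genome/target cascade, collapses
#' unique placements to their strand-aware 5'-most coordinate, removes
#' positions within the bait exclusion window, normalizes counts to reads per
#' million over the retained tags, and assigns competition ranks (ties share
#' the better rank).
#'
#' @param fragments character vector of captured fragments (or the tibble
#'   from [parse_4c_reads()], whose retained rows are used).
#' @param genome_index background `sequence_index` (or `NULL` to skip the
#'   genome pass).
#' @param collapsed_index target `sequence_index` (collapsed haplotype).
#' @param cfg a [fourc_config()].
#' @return tibble of class `fourc_tag_table`: `position` (0-based 5' most
#'   coordinate), `count`, `rpm`, `rank`; attribute `library_size` holds the
#'   retained tag total.
#' @export
quantify_tags <- function(fragments, genome_index, collapsed_index, cfg) {
  stopifnot(inherits(cfg, "fourc_config"))
  if (is.data.frame(fragments)) {
    fragments <- fragments$fragment[!is.na(fragments$fragment)]
  }
  aln <- two_pass_filter(fragments, genome_index, collapsed_index)
  tag_pos <- ifelse(aln$strand == "+", aln$start, aln$start + aln$length - 1L)
  tab <- tibble(position = tag_pos) |>
    count(.data$position, name = "count") |>
    filter(abs(.data$position - cfg$bait_position) > cfg$exclusion_radius)
  if (!nrow(tab)) {
    warn("no 4C tags retained after bait exclusion")
    out <- tibble(position = integer(), count = integer(),
                  rpm = numeric(), rank = integer())
    attr(out, "library_size") <- 0L
    class(out) <- c("fourc_tag_table", class(out))
    return(out)
  }
  lib <- sum(tab$count)
  out <- tab |>
    mutate(rpm = 1e6 * .data$count / lib,
           rank = min_rank(desc(.data$rpm))) |>
    arrange(.data$position)
  attr(out, "library_size") <- lib
  class(out) <- c("fourc_tag_table", class(out))
  out
}

#' Bin a 4C tag table
#'
#' Sums rpm (and counts) of member positions into half-open bins tiled from
#' position 0.
#'
#' @param table a `fourc_tag_table`.
#' @param bin_size bp per bin (>= 1).
#' @return tibble with `bin_start`, `bin_end`, `count`, `rpm`.
#' @export
bin_tags <- function(table, bin_size = 2000L) {
  stopifnot(bin_size >= 1L)
  table |>
    as_tibble() |>
    mutate(bin_start = (.data$position %/% bin_size) * bin_size) |>
    group_by(.data$bin_start) |>
    summarise(count = sum(.data$count), rpm = sum(.data$rpm), .groups = "drop") |>
    mutate(bin_end = .data$bin_start + bin_size, .after = "bin_start")
}
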