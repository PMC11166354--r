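# Shared adapter/anchor matching under the k / mink / hdist contract:
# an adapter matches at a read position if any window of length k (or, at the
# relevant read end, any adapter prefix/suffix of length >= mink) aligns with
# at most hdist mismatches. This is the published semantics of the trimming
# parameters used throughout the 4C and sRNA pipelines; it is implemented
# directly rather than by emulating any particular trimming tool.

# mismatch counts of an equal-width character set against a pattern
mismatch_counts <- function(dss, pattern) {
  if (!length(dss)) return(integer(0))
  m <- as.matrix(dss)
  pat <- strsplit(pattern, "")[[1]]
  rowSums(m != matrix(pat, nrow = nrow(m), ncol = length(pat), byrow = TRUE))
}

# 1-based start positions of full k-window adapter alignments in each read;
# returns list(first = leftmost alignment start or NA, last_end = rightmost
# alignment end or NA)
adapter_hits <- function(reads, adapter, k, mink, hdist,
                         side = c("contain", "left", "right")) {
  side <- match.arg(side)
  dss <- Biostrings::DNAStringSet(reads)
  n <- length(reads)
  w <- Biostrings::width(dss)
  first <- rep(NA_integer_, n)
  last_end <- rep(NA_integer_, n)
  alen <- nchar(adapter)
  stopifnot(k <= alen, mink <= k)
  # full k-length windows of the adapter, anywhere in the read
  for (o in 0:(alen - k)) {
    pat <- substr(adapter, o + 1L, o + k)
    mi <- Biostrings::vmatchPattern(pat, dss, max.mismatch = hdist)
    st <- Biostrings::startIndex(mi)
    hit <- which(lengths(st) > 0L)
    for (i in hit) {
      a_start <- min(st[[i]]) - o           # implied adapter alignment start
      a_end <- max(st[[i]]) - o + alen - 1L
      first[i] <- min(first[i], a_start, na.rm = TRUE)
      last_end[i] <- max(last_end[i], min(a_end, w[i]), na.rm = TRUE)
    }
  }
  # shorter windows only count flush with the relevant read end
  if (mink < k) {
    for (len in mink:(k - 1L)) {
      ok <- which(w >= len)
      if (!length(ok)) next
      if (side == "right") {
        tails <- Biostrings::subseq(dss[ok], start = w[ok] - len + 1L)
        mm <- mismatch_counts(tails, substr(adapter, 1L, len))
        hit <- ok[mm <= hdist]
        first[hit] <- pmin(first[hit], w[hit] - len + 1L, na.rm = TRUE)
      } else if (side == "left") {
        heads <- Biostrings::subseq(dss[ok], start = 1L, width = len)
        mm <- mismatch_counts(heads, substr(adapter, alen - len + 1L, alen))
        hit <- ok[mm <= hdist]
        last_end[hit] <- pmax(last_end[hit], len, na.rm = TRUE)
      } else {
        tails <- Biostrings::subseq(dss[ok], start = w[ok] - len + 1L)
        mm <- mismatch_counts(tails, substr(adapter, 1L, len))
        hit <- ok[mm <= hdist]
        first[hit] <- pmin(first[hit], w[hit] - len + 1L, na.rm = TRUE)
        heads <- Biostrings::subseq(dss[ok], start = 1L, width = len)
        mm <- mismatch_counts(heads, substr(adapter, alen - len + 1L, alen))
        hit <- ok[mm <= hdist]
        last_end[hit] <- pmax(last_end[hit], len, na.rm = TRUE)
      }
    }
  }
  list(first = first, last_end = last_end)
}

# does each read contain the adapter under the contract?
adapter_contains <- function(reads, adapter, k, mink, hdist) {
  h <- adapter_hits(reads, adapter, k, mink, hdist, side = "contain")
  !is.na(h$first) | !is.na(h$last_end)
}

# remove everything up to and including the adapter match (ktrim = l);
# reads without a match are returned unchanged with trimmed = FALSE
trim_left_adapter <- function(reads, adapter, k, mink, hdist) {
  h <- adapter_hits(reads, adapter, k, mink, hdist, side = "left")
  cut <- h$last_end
  trimmed <- !is.na(cut)
  out <- reads
  out[trimmed] <- substr(reads[trimmed], cut[trimmed] + 1L, nchar(reads[trimmed]))
  list(read = out, trimmed = trimmed, cut = cut)
}

# remove the adapter match and everything right of it (ktrim = r)
trim_right_adapter <- function(reads, adapter, k, mink, hdist) {
  h <- adapter_hits(reads, adapter, k, mink, hdist, side = "right")
  cut <- h$first
  trimmed <- !is.na(cut) & cut >= 1L
  out <- reads
  out[trimmed] <- substr(reads[trimmed], 1L, cut[trimmed] - 1L)
  list(read = out, trimmed = trimmed, cut = cut)
}

# Phred+33 quality strings -> integer lists
phred_values <- function(quality) {
  lapply(quality, function(q) as.integer(charToRaw(q)) - 33L)
}

# trim the maximal 3' run of bases below `floor`, then report mean quality
qtrim_right <- function(reads, quality, floor = 20L) {
  qv <- phred_values(quality)
  keep_len <- vapply(qv, function(q) {
    n <- length(q)
    while (n > 0L && q[n] < floor) n <- n - 1L
    n
  }, integer(1))
  read <- substr(reads, 1L, keep_len)
  qual <- substr(quality, 1L, keep_len)
  meanq <- vapply(seq_along(qv), function(i) {
    if (keep_len[i] == 0L) return(0)
    mean(qv[[i]][seq_len(keep_len[i])])
  }, numeric(1))
  list(read = read, quality = qual, mean_q = meanq, length = keep_len)
}
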