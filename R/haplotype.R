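#' Build a haplotype model
#'
#' A haplotype model bundles a reference sequence with feature annotations
#' (TE fragments, bait, unique subregion, ...) and any perfect tandem arrays
#' it contains. All coordinates are 0-based half-open; strands are one of
#' `"+"`, `"-"`, `"."`.
#'
#' @param name single identifier.
#' @param sequence character scalar over `{A,C,G,T,N}`.
#' @param features tibble with columns `start`, `end`, `strand`, `type`,
#'   `name` (0-based half-open), or `NULL`.
#' @param arrays tibble of tandem arrays as returned by
#'   [detect_tandem_arrays()], or `NULL` to detect none.
#' @return an object of class `haplotype_model`.
#' @export
haplotype_model <- function(name, sequence, features = NULL, arrays = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) abort("haplotype sequence must be non-empty")
  check_dna(sequence, "haplotype sequence")
  L <- nchar(sequence)
  if (is.null(features)) {
    features <- tibble(start = integer(), end = integer(),
                       strand = character(), type = character(),
                       name = character())
  }
  features <- as_tibble(features)
  if (nrow(features)) {
    stopifnot(all(features$start >= 0L), all(features$end <= L),
              all(features$start < features$end),
              all(features$strand %in% c("+", "-", ".")))
  }
  if (is.null(arrays)) {
    arrays <- tibble(start = integer(), unit_length = integer(),
                     copy_number = integer(), unit_sequence = character())
  }
  structure(list(name = name, sequence = sequence,
                 features = features,
                 arrays = as_tibble(arrays)),
            class = "haplotype_model")
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat(sprintf("<haplotype_model> %s: %d bp, %d feature(s), %d tandem array(s)\n",
              x$name, nchar(x$sequence), nrow(x$features), nrow(x$arrays)))
  invisible(x)
}

# smallest period of a string that is a divisor of p (Fine-Wilf: with >= 2
# copies the primitive period divides p)
primitive_period <- function(region_raw, p) {
  n <- length(region_raw)
  divs <- seq_len(p)[p %% seq_len(p) == 0L]
  for (d in divs) {
    if (all(region_raw[seq_len(n - d)] == region_raw[(d + 1L):n])) return(d)
  }
  p
}

# maximal run of s[i] == s[i+p] containing 1-based position i0 (in eq space)
run_at <- function(eq, i0) {
  lo <- i0
  while (lo > 1L && eq[lo - 1L]) lo <- lo - 1L
  hi <- i0
  n <- length(eq)
  while (hi < n && eq[hi + 1L]) hi <- hi + 1L
  c(lo, hi)
}

#' Detect maximal perfect tandem arrays
#'
#' Finds every maximal run of identical, directly repeated units with unit
#' length at least `min_unit` and at least `min_copies` copies. Arrays are
#' reported at their primitive (shortest) period and at the leftmost phase;
#' overlap conflicts are resolved in favour of the longer array.
#'
#' Candidate periods are seeded from distances between duplicated k-mers, and
#' each candidate is verified with a vectorized shift comparison, so a 192 kb
#' haplotype screens in seconds.
#'
#' @param sequence character scalar (or `haplotype_model`).
#' @param min_unit minimum unit length in bp (>= 1).
#' @param min_copies minimum copy number (>= 2).
#' @return tibble with `start` (0-based), `unit_length`, `copy_number`,
#'   `unit_sequence`; zero rows when nothing qualifies.
#' @export
detect_tandem_arrays <- function(sequence, min_unit = 2L, min_copies = 2L) {
  if (inherits(sequence, "haplotype_model")) sequence <- sequence$sequence
  sequence <- toupper(as.character(sequence))
  stopifnot(min_unit >= 1L, min_copies >= 2L)
  empty <- tibble(start = integer(), unit_length = integer(),
                  copy_number = integer(), unit_sequence = character())
  L <- nchar(sequence)
  max_p <- L %/% min_copies
  if (L == 0L || max_p < min_unit) return(empty)

  x <- charToRaw(sequence)
  k <- max(1L, min(12L, min_unit))
  if (L < k) return(empty)
  words <- seq_windows(sequence, k)
  grp <- split(seq_along(words), words)
  grp <- grp[lengths(grp) > 1L]
  cand <- integer(0)
  for (pos in grp) {
    # distances between occurrences up to 8 apart in rank; covers seeds
    # occurring several times per unit
    jmax <- min(8L, length(pos) - 1L)
    for (j in seq_len(jmax)) {
      cand <- c(cand, pos[-seq_len(j)] - pos[seq_len(length(pos) - j)])
    }
  }
  cand <- sort(unique(cand[cand >= min_unit & cand <= max_p]))
  if (!length(cand)) return(empty)

  seen <- character(0)
  res <- list()
  for (p in cand) {
    eq <- x[seq_len(L - p)] == x[(p + 1L):L]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= p * (min_copies - 1L))
    for (h in hit) {
      span_start <- starts[h]                  # 1-based
      span_len <- r$lengths[h] + p
      region <- x[span_start:(span_start + span_len - 1L)]
      q <- primitive_period(region, p)
      if (q < min_unit) next
      if (q < p) {
        # re-extend maximality at the primitive period
        eq_q <- x[seq_len(L - q)] == x[(q + 1L):L]
        rr <- run_at(eq_q, span_start)
        span_start <- rr[1L]
        span_len <- rr[2L] - rr[1L] + 1L + q
      }
      copies <- span_len %/% q
      if (copies < min_copies) next
      key <- paste(span_start, q)
      if (key %in% seen) next
      seen <- c(seen, key)
      res[[length(res) + 1L]] <- tibble(
        start = span_start - 1L,
        unit_length = as.integer(q),
        copy_number = as.integer(copies),
        unit_sequence = substr(sequence, span_start, span_start + q - 1L))
    }
  }
  if (!length(res)) return(empty)
  out <- bind_rows(res) |> distinct() |>
    mutate(span = .data$unit_length * .data$copy_number) |>
    arrange(desc(.data$span), .data$start)
  # greedy overlap resolution: keep longer arrays
  keep <- logical(nrow(out))
  occ_s <- integer(0); occ_e <- integer(0)
  for (i in seq_len(nrow(out))) {
    s <- out$start[i]; e <- s + out$span[i]
    if (!any(s < occ_e & e > occ_s)) {
      keep[i] <- TRUE
      occ_s <- c(occ_s, s); occ_e <- c(occ_e, e)
    }
  }
  out[keep, ] |> select(-"span") |> arrange(.data$start)
}

#' Collapse tandem arrays to single units
#'
#' Produces the collapsed reference used for unique mapping: each tandem
#' array is reduced to one unit so a read matching any repeat copy has a
#' single placement. The returned object carries complete coordinate maps
#' between collapsed and full space.
#'
#' @param model a `haplotype_model` whose `arrays` are non-overlapping.
#' @return object of class `collapsed_reference` with elements `sequence`,
#'   `arrays` (with `collapsed_start` added) and `full_length`.
#' @export
collapse_repeats <- function(model) {
  stopifnot(inherits(model, "haplotype_model"))
  arr <- model$arrays |> arrange(.data$start)
  L <- nchar(model$sequence)
  if (nrow(arr) > 1L) {
    ends <- arr$start + arr$unit_length * arr$copy_number
    if (any(arr$start[-1L] < ends[-nrow(arr)])) {
      abort("overlapping tandem arrays: annotation conflict")
    }
  }
  removed <- if (nrow(arr)) (arr$copy_number - 1L) * arr$unit_length else integer(0)
  shift <- c(0L, cumsum(removed))          # removed bp before each segment
  # build collapsed sequence piecewise
  pieces <- character(0)
  cur <- 0L
  c_start <- integer(nrow(arr))
  c_off <- 0L
  for (i in seq_len(nrow(arr))) {
    a <- arr[i, ]
    pieces <- c(pieces, substr(model$sequence, cur + 1L, a$start),
                substr(model$sequence, a$start + 1L, a$start + a$unit_length))
    c_start[i] <- a$start - c_off
    c_off <- c_off + (a$copy_number - 1L) * a$unit_length
    cur <- a$start + a$unit_length * a$copy_number
  }
  pieces <- c(pieces, substr(model$sequence, cur + 1L, L))
  arr$collapsed_start <- c_start
  structure(list(sequence = paste(pieces, collapse = ""),
                 arrays = arr, full_length = L, name = model$name),
            class = "collapsed_reference")
}

#' @export
print.collapsed_reference <- function(x, ...) {
  cat(sprintf("<collapsed_reference> %s: %d bp (full %d bp), %d array(s)\n",
              x$name, nchar(x$sequence), x$full_length, nrow(x$arrays)))
  invisible(x)
}

#' Lift a collapsed-space interval to full-haplotype intervals
#'
#' An interval fully inside a collapsed array unit lifts to one interval per
#' repeat copy; an interval outside any array lifts to exactly one. Intervals
#' straddling an array boundary are refused.
#'
#' @param ref a `collapsed_reference`.
#' @param start,end 0-based half-open interval in collapsed space.
#' @return tibble with `start`, `end` in full-haplotype coordinates and
#'   `copy` (0 outside arrays, 1..copy_number inside).
#' @export
lift_to_full <- function(ref, start, end) {
  stopifnot(inherits(ref, "collapsed_reference"), start >= 0, end > start)
  cl <- nchar(ref$sequence)
  if (end > cl) abort("interval outside collapsed space")
  arr <- ref$arrays
  for (i in seq_len(nrow(arr))) {
    a <- arr[i, ]
    cs <- a$collapsed_start; ce <- cs + a$unit_length
    if (start >= cs && end <= ce) {
      off <- start - cs
      w <- end - start
      return(tibble(
        start = a$start + (seq_len(a$copy_number) - 1L) * a$unit_length + off,
        end = a$start + (seq_len(a$copy_number) - 1L) * a$unit_length + off + w,
        copy = seq_len(a$copy_number)))
    }
    if (start < ce && end > cs && !(start >= cs && end <= ce)) {
      abort("interval straddles a tandem-array boundary")
    }
  }
  # outside all arrays: shift by repeats removed upstream
  shift <- 0L
  for (i in seq_len(nrow(arr))) {
    a <- arr[i, ]
    if (start >= a$collapsed_start + a$unit_length) {
      shift <- shift + (a$copy_number - 1L) * a$unit_length
    }
  }
  tibble(start = start + shift, end = end + shift, copy = 0L)
}

#' Map a full-haplotype position back to collapsed space
#'
#' Positions inside any repeat copy fold onto the corresponding offset of the
#' retained (first) unit.
#'
#' @param ref a `collapsed_reference`.
#' @param pos vector of 0-based full-haplotype positions.
#' @return integer vector of collapsed positions.
#' @export
lift_to_collapsed <- function(ref, pos) {
  stopifnot(inherits(ref, "collapsed_reference"))
  arr <- ref$arrays
  out <- as.integer(pos)
  for (p in seq_along(out)) {
    x <- out[p]
    if (x < 0L || x >= ref$full_length) abort("position outside full space")
    shift <- 0L
    mapped <- NA_integer_
    for (i in seq_len(nrow(arr))) {
      a <- arr[i, ]
      fs <- a$start; fe <- fs + a$unit_length * a$copy_number
      if (x >= fs && x < fe) {
        mapped <- a$collapsed_start + (x - fs) %% a$unit_length
        break
      }
      if (x >= fe) shift <- shift + (a$copy_number - 1L) * a$unit_length
    }
    out[p] <- if (is.na(mapped)) x - shift else mapped
  }
  out
}

#' Repetitive index of sliding windows
#'
#' For every window start in `query`, counts exact occurrences of that window
#' (forward or reverse complement) across a set of background sequences.
#' Windows containing `N` get a count of 0 and are flagged.
#'
#' @param query character scalar.
#' @param background character vector of background sequences (default: the
#'   query itself).
#' @param window window size in bp (default 24, matching a 24-nt sliding
#'   window heat map).
#' @return tibble with `start` (0-based), `window`, `count`, `has_n`.
#' @export
repetitive_index <- function(query, background = query, window = 24L) {
  query <- toupper(as.character(query))
  background <- toupper(as.character(background))
  stopifnot(window >= 1L, window <= nchar(query))
  qw <- seq_windows(query, window)
  bgw <- unlist(lapply(background, seq_windows, w = window), use.names = FALSE)
  u <- unique(bgw)
  btab <- tabulate(match(bgw, u), nbins = length(u))
  cnt <- function(w) {
    m <- match(w, u)
    ifelse(is.na(m), 0L, btab[m])
  }
  rcq <- revcomp(qw)
  val <- cnt(qw) + ifelse(qw == rcq, 0L, cnt(rcq))
  has_n <- grepl("N", qw, fixed = TRUE)
  val[has_n] <- 0L
  tibble(start = seq_along(qw) - 1L, window = window,
         count = as.integer(val), has_n = has_n)
}
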