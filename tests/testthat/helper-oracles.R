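# Independent brute-force oracles. These deliberately share no code with the
# implementation: plain loops and base R only.

# exhaustive period scan for maximal perfect tandem arrays
oracle_detect_arrays <- function(seq, min_unit, min_copies) {
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  found <- list()
  for (p in seq(min_unit, max(min_unit, L %/% min_copies))) {
    if (p * min_copies > L) break
    i <- 1L
    while (i + p <= L) {
      # extend the match run starting at i for period p
      j <- i
      while (j + p <= L && ch[j] == ch[j + p]) j <- j + 1L
      run <- j - i
      if (run >= p * (min_copies - 1L)) {
        span <- run + p
        # primitive period among divisors
        region <- ch[i:(i + span - 1L)]
        q <- p
        for (d in seq_len(p)) {
          if (p %% d == 0L &&
              all(region[seq_len(span - d)] == region[(d + 1L):span])) {
            q <- d; break
          }
        }
        if (q >= min_unit) {
          copies <- span %/% q
          if (copies >= min_copies) {
            found[[length(found) + 1L]] <-
              c(start = i - 1L, unit = q, copies = copies)
          }
        }
        i <- j + 1L
      } else {
        i <- i + max(1L, run + 1L)
      }
    }
  }
  if (!length(found)) {
    return(data.frame(start = integer(), unit = integer(), copies = integer()))
  }
  df <- unique(do.call(rbind, found))
  df <- as.data.frame(df)
  # same leftmost-phase maximality: drop arrays contained in longer ones
  df$span <- df$unit * df$copies
  df <- df[order(-df$span, df$start), ]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(df))) {
      if (j == i || !keep[j]) next
      if (df$start[j] < df$start[i] + df$span[i] &&
          df$start[j] + df$span[j] > df$start[i] &&
          df$span[j] <= df$span[i] && !(j < i && df$span[j] == df$span[i])) {
        keep[j] <- FALSE
      }
    }
  }
  df <- df[keep, c("start", "unit", "copies")]
  df[order(df$start), ]
}

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# naive two-strand sliding scan: status + placements for one read
oracle_scan_read <- function(refs, read) {
  hits <- list()
  rc <- oracle_revcomp(read)
  w <- nchar(read)
  for (nm in names(refs)) {
    ref <- refs[[nm]]
    L <- nchar(ref)
    if (w > L) next
    for (i in seq_len(L - w + 1L)) {
      win <- substr(ref, i, i + w - 1L)
      if (grepl("N", win) || grepl("N", read)) next
      if (win == read) hits[[length(hits) + 1L]] <- c(nm, i - 1L, "+")
      if (win == rc) hits[[length(hits) + 1L]] <- c(nm, i - 1L, "-")
    }
  }
  n <- length(hits)
  status <- if (n == 0L) "unmapped" else if (n == 1L) "unique" else "multi"
  list(status = status, hits = hits)
}

# interval merge (gap < pad) then count threshold
oracle_clusters <- function(starts, lens, pad, mincov) {
  o <- order(starts)
  starts <- starts[o]; ends <- starts + lens[o]
  cs <- starts[1]; ce <- ends[1]; cn <- 1L
  out <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - ce < pad) {
      ce <- max(ce, ends[i]); cn <- cn + 1L
    } else {
      out[[length(out) + 1L]] <- c(cs, ce, cn)
      cs <- starts[i]; ce <- ends[i]; cn <- 1L
    }
  }
  out[[length(out) + 1L]] <- c(cs, ce, cn)
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("start", "end", "n_reads")
  df[df$n_reads >= mincov, , drop = FALSE]
}

# trinucleotide scan for cytosine contexts on the plus strand
oracle_contexts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  out <- character(0)
  pos <- integer(0)
  for (i in seq_len(L)) {
    if (ch[i] != "C") next
    ctx <- if (i + 1L > L) NA_character_
    else if (ch[i + 1L] == "G") "CG"
    else if (i + 2L > L) NA_character_
    else if (ch[i + 1L] %in% c("A", "C", "T") && ch[i + 2L] == "G") "CHG"
    else if (ch[i + 1L] %in% c("A", "C", "T") &&
             ch[i + 2L] %in% c("A", "C", "T")) "CHH"
    else NA_character_
    pos <- c(pos, i - 1L)
    out <- c(out, ctx)
  }
  data.frame(position = pos, context = out)
}

# spreadsheet-style ddCt: plain loops, no package code
oracle_ddct <- function(tab, target, reference, calibrator) {
  samples <- unique(tab$sample)
  dct <- sapply(samples, function(s) {
    ct_t <- mean(tab$ct[tab$sample == s & tab$amplicon == target])
    ct_r <- mean(tab$ct[tab$sample == s & tab$amplicon == reference])
    ct_t - ct_r
  })
  grp <- tab$group[match(samples, tab$sample)]
  cal <- mean(dct[grp == calibrator])
  fold <- 2^-(dct - cal)
  data.frame(sample = samples, group = grp, fold = unname(fold))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
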