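#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap list_rbind
#' @importFrom stats t.test sd setNames
#' @importFrom utils head tail
NULL

# reverse complement for plain character vectors; N maps to N
revcomp <- function(x) {
  out <- character(length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out[!ok] <- x[!ok]
  out
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf("%s contains symbols outside {A,C,G,T,N}", what))
  }
  invisible(x)
}

# all windows of width w starting at 0-based positions 0..L-w
seq_windows <- function(seq, w) {
  L <- nchar(seq)
  if (w > L) return(character(0))
  substring(seq, seq_len(L - w + 1L), seq(w, L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
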