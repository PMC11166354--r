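#' Classify cytosine contexts along a reference interval
#'
#' Every cytosine on the chosen strand is assigned one of the plant contexts
#' from the two bases immediately 3' of it on that strand: `CG` when the
#' next base is G, `CHG` when the next is H (A/C/T) and the second-next is G,
#' `CHH` otherwise. Terminal cytosines whose 3' flank falls outside the
#' reference are reported with context `NA` (ambiguous) and excluded from
#' context totals.
#'
#' @param reference character scalar reference sequence (plus strand).
#' @param start,end 0-based half-open interval (default: whole reference).
#' @param strand `"+"` or `"-"`; positions are always reported in plus-strand
#'   coordinates.
#' @return tibble `position` (0-based), `strand`, `context`.
#' @export
classify_contexts <- function(reference, start = 0L,
                              end = nchar(reference), strand = "+") {
  reference <- toupper(as.character(reference))
  L <- nchar(reference)
  stopifnot(start >= 0L, end <= L, start < end, strand %in% c("+", "-"))
  chars <- strsplit(reference, "")[[1]]
  if (strand == "+") {
    pos <- which(chars == "C")                       # 1-based
    nxt1 <- ifelse(pos + 1L <= L, chars[pos + 1L], NA)
    nxt2 <- ifelse(pos + 2L <= L, chars[pos + 2L], NA)
  } else {
    pos <- which(chars == "G")                       # C on the minus strand
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    nxt1 <- ifelse(pos - 1L >= 1L, comp[chars[pmax(pos - 1L, 1L)]], NA)
    nxt2 <- ifelse(pos - 2L >= 1L, comp[chars[pmax(pos - 2L, 1L)]], NA)
  }
  ctx <- dplyr::case_when(
    is.na(nxt1) ~ NA_character_,
    nxt1 == "G" ~ "CG",
    is.na(nxt2) ~ NA_character_,
    nxt1 %in% c("A", "C", "T") & nxt2 == "G" ~ "CHG",
    nxt1 %in% c("A", "C", "T") & nxt2 %in% c("A", "C", "T") ~ "CHH",
    .default = NA_character_)                        # N in flank
  out <- tibble(position = pos - 1L, strand = strand, context = ctx) |>
    filter(.data$position >= start, .data$position < end)
  out
}

#' Call per-cytosine methylation from one conversion-treated clone
#'
#' The clone is compared ungapped against the reference interval (Sanger
#' amplicon clones of a short region; indel-bearing clones are rejected, not
#' realigned). At each reference cytosine: clone `C` is called methylated
#' (conversion protected), clone `T` unmethylated (deaminated), anything
#' else ambiguous. A cap on mismatches at non-cytosine positions guards
#' against misassigned clones.
#'
#' @param clone clone sequence (same length as `reference`).
#' @param reference reference interval sequence.
#' @param strand strand to analyse (default `"+"`, the amplified top strand).
#' @param max_other_mismatch maximum tolerated non-cytosine mismatches
#'   (default 2).
#' @return tibble `position` (0-based within the interval), `context`,
#'   `call` in `{methylated, unmethylated, ambiguous}`.
#' @export
call_clone <- function(clone, reference, strand = "+",
                       max_other_mismatch = 2L) {
  clone <- toupper(as.character(clone))
  reference <- toupper(as.character(reference))
  if (nchar(clone) != nchar(reference)) {
    abort("clone/reference length mismatch: indel-containing clone rejected")
  }
  cc <- strsplit(clone, "")[[1]]
  rc <- strsplit(reference, "")[[1]]
  ctx <- classify_contexts(reference, strand = strand)
  c_base <- if (strand == "+") "C" else "G"
  t_base <- if (strand == "+") "T" else "A"          # converted base
  is_c <- rc == c_base
  other_mm <- sum(cc[!is_c] != rc[!is_c])
  if (other_mm > max_other_mismatch) {
    abort(sprintf("clone has %d non-cytosine mismatches (max %d)",
                  other_mm, max_other_mismatch))
  }
  at_c <- cc[ctx$position + 1L]
  ctx |>
    mutate(call = dplyr::case_when(
      at_c == c_base ~ "methylated",
      at_c == t_base ~ "unmethylated",
      .default = "ambiguous")) |>
    select("position", "context", "call")
}

#' Methylation profile across a set of clones
#'
#' Calls every clone against the reference interval and summarises percent
#' methylation per context over unambiguous calls (cytosines with `NA`
#' context, e.g. terminal ones, are excluded from context percentages and
#' reported separately).
#'
#' @param clones named character vector of clone sequences.
#' @param reference reference interval sequence.
#' @param strand strand to analyse.
#' @param max_other_mismatch passed to [call_clone()].
#' @return object of class `methylation_profile` with elements `calls`
#'   (clone x cytosine tibble), `summary` (per-context n, methylated, pct),
#'   `n_clones`.
#' @export
methylation_profile <- function(clones, reference, strand = "+",
                                max_other_mismatch = 2L) {
  if (is.null(names(clones))) names(clones) <- paste0("clone_", seq_along(clones))
  calls <- imap(clones, function(s, nm) {
    call_clone(s, reference, strand, max_other_mismatch) |>
      mutate(clone = nm, .before = 1L)
  }) |> list_rbind()
  summary <- calls |>
    filter(!is.na(.data$context), .data$call != "ambiguous") |>
    group_by(.data$context) |>
    summarise(n = dplyr::n(),
              methylated = sum(.data$call == "methylated"),
              pct = 100 * .data$methylated / .data$n, .groups = "drop")
  structure(list(calls = calls, summary = summary, n_clones = length(clones),
                 reference = reference, strand = strand),
            class = "methylation_profile")
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat(sprintf("<methylation_profile> %d clone(s), %d bp interval\n",
              x$n_clones, nchar(x$reference)))
  print(x$summary)
  invisible(x)
}

#' Conversion efficiency from unmethylated control clones
#'
#' Fraction of control-reference cytosines read as the converted base across
#' clones of a fully unmethylated control (e.g. lambda spike-in). Libraries
#' below the threshold are flagged.
#'
#' @param control_clones named character vector of control clone sequences.
#' @param control_reference unmethylated control reference sequence.
#' @param strand strand to analyse.
#' @param threshold flag efficiencies below this (default 0.98).
#' @return list with `efficiency` (in `[0,1]`), `n_sites`, `flagged`.
#' @export
conversion_efficiency <- function(control_clones, control_reference,
                                  strand = "+", threshold = 0.98) {
  prof <- methylation_profile(control_clones, control_reference,
                              strand = strand,
                              max_other_mismatch = nchar(control_reference))
  calls <- prof$calls |> filter(.data$call != "ambiguous")
  eff <- mean(calls$call == "unmethylated")
  list(efficiency = eff, n_sites = nrow(calls), flagged = eff < threshold)
}
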