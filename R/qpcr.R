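#' Relative quantification by the 2^-ddCt method
#'
#' Technical replicates are averaged on the Ct scale; per sample,
#' `dCt = Ct_target - Ct_reference`; per-sample `ddCt` subtracts the mean
#' dCt of the calibrator group; fold is `2^-ddCt` (amplification efficiency
#' fixed at 2). Group summaries report mean fold and s.e.m. on the linear
#' scale, and a two-sided two-sample t-test compares the two groups on
#' per-sample folds (or on dCt values with `test_on = "dct"`).
#'
#' @param table tibble with columns `sample`, `group`, `amplicon`,
#'   `replicate`, `ct` (e.g. from [read_ct_table()]).
#' @param target target amplicon id.
#' @param reference reference amplicon id (e.g. a housekeeping gene).
#' @param calibrator group label whose mean dCt anchors ddCt.
#' @param test `"welch"` or `"pooled"`.
#' @param test_on `"fold"` (default, as plotted) or `"dct"`.
#' @return object of class `fold_change_result`: list with `samples`
#'   (per-sample dCt/ddCt/fold), `groups` (mean fold, sem, n), `t`, `p`,
#'   `target`, `reference`, `calibrator`.
#' @export
delta_delta_ct <- function(table, target, reference, calibrator,
                           test = c("welch", "pooled"),
                           test_on = c("fold", "dct")) {
  test <- match.arg(test)
  test_on <- match.arg(test_on)
  stopifnot(all(c("sample", "group", "amplicon", "ct") %in% names(table)))
  ct <- table |>
    filter(.data$amplicon %in% c(target, reference)) |>
    group_by(.data$sample, .data$group, .data$amplicon) |>
    summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "amplicon", values_from = "ct")
  if (!calibrator %in% ct$group) abort("calibrator group absent from table")
  missing_ref <- is.na(ct[[reference]]) | is.na(ct[[target]])
  if (any(missing_ref)) {
    warn(sprintf("%d sample(s) dropped for missing Ct", sum(missing_ref)))
    ct <- ct[!missing_ref, ]
  }
  samples <- ct |>
    mutate(dct = .data[[target]] - .data[[reference]])
  cal_mean <- mean(samples$dct[samples$group == calibrator])
  samples <- samples |>
    mutate(ddct = .data$dct - cal_mean, fold = 2^(-.data$ddct)) |>
    select("sample", "group", "dct", "ddct", "fold")
  groups <- samples |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(), mean_fold = mean(.data$fold),
              sem = sd(.data$fold) / sqrt(dplyr::n()), .groups = "drop")
  gl <- unique(samples$group)
  t_stat <- NA_real_; p <- NA_real_
  if (length(gl) == 2L &&
      all(table(samples$group) >= 2L)) {
    v <- if (test_on == "fold") samples$fold else samples$dct
    a <- v[samples$group == gl[1]]; b <- v[samples$group == gl[2]]
    if (sd(a) == 0 && sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) {
        t_stat <- 0; p <- 1
      } else {
        t_stat <- Inf; p <- 0
      }
    } else {
      tt <- t.test(a, b, var.equal = (test == "pooled"))
      t_stat <- unname(tt$statistic); p <- tt$p.value
    }
  }
  structure(list(samples = samples, groups = groups, t = t_stat, p = p,
                 target = target, reference = reference,
                 calibrator = calibrator, test = test, test_on = test_on),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("<fold_change_result> %s vs %s (calibrator %s)\n",
              x$target, x$reference, x$calibrator))
  print(x$groups)
  cat(sprintf("t = %.3f, p = %.4g (%s t-test on %s)\n",
              x$t, x$p, x$test, x$test_on))
  invisible(x)
}

#' MNase-qPCR enrichment across tiled amplicons
#'
#' Applies the 2^-ddCt arithmetic per tiled amplicon (mono/dinucleosome-bound
#' DNA abundance relative to a reference amplicon, calibrated to one group),
#' with significance per amplicon.
#'
#' @param table Ct tibble as for [delta_delta_ct()].
#' @param amplicons character vector of tiled amplicon ids (e.g. P1..P4).
#' @param reference reference amplicon id.
#' @param calibrator calibrator group label.
#' @param ... passed to [delta_delta_ct()].
#' @return tibble with one row per amplicon and group (mean fold, sem, n)
#'   plus per-amplicon `t`, `p`; full results in attribute `"results"`.
#' @export
mnase_enrichment <- function(table, amplicons, reference, calibrator, ...) {
  res <- map(setNames(amplicons, amplicons), function(a) {
    delta_delta_ct(table, target = a, reference = reference,
                   calibrator = calibrator, ...)
  })
  out <- imap(res, function(r, a) {
    r$groups |> mutate(amplicon = a, t = r$t, p = r$p, .before = 1L)
  }) |> list_rbind()
  attr(out, "results") <- res
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn delta_delta_ct per-sample tidy output (sample, group, dct,
#'   ddct, fold).
#' @param x a `fold_change_result`.
#' @param ... unused.
#' @export
tidy.fold_change_result <- function(x, ...) x$samples

#' @describeIn delta_delta_ct one-row summary: per-group mean folds, t, p.
#' @export
glance.fold_change_result <- function(x, ...) {
  wide <- x$groups |>
    select("group", "mean_fold") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean_fold",
                       names_prefix = "fold_")
  bind_cols(tibble(target = x$target, reference = x$reference,
                   calibrator = x$calibrator), wide,
            tibble(t = x$t, p = x$p))
}

#' @describeIn quantify_and_test tidy per-cluster differential table.
#' @param x an `srna_diff`.
#' @param ... unused.
#' @export
tidy.srna_diff <- function(x, ...) as_tibble(x)

#' @describeIn quantify_and_test one-row summary: clusters tested, number
#'   significant at 0.05/0.01, strongest fold.
#' @export
glance.srna_diff <- function(x, ...) {
  tibble(n_clusters = nrow(x),
         n_sig_05 = sum(x$p < 0.05, na.rm = TRUE),
         n_sig_01 = sum(x$p < 0.01, na.rm = TRUE),
         max_fold = x$fold[which.max(abs(log(x$fold)))][1])
}
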