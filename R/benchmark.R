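#' Benchmark a prediction set against a gold standard
#'
#' True positives are predicted islands overlapping the gold standard in at
#' least 1 bp; every other prediction is counted as a false positive (no
#' complete gold standard exists, so the resulting PPV is a lower bound).
#' False negatives are gold intervals not touched by any prediction, so the
#' sensitivity mixes prediction-side TP with gold-side FN:
#' `SN = TP / (TP + FN)` and `PPV = TP / n_predicted`.
#'
#' @param islands Prediction tibble (`chrom`, `start`, `end`, ...).
#' @param gold Gold-standard interval tibble.
#' @return An object of class `cgi_benchmark`; see [benchmark_from_counts()]
#'   for the fields. Supports [tidy()] and [glance()].
#' @export
benchmark_vs_gold <- function(islands, gold) {
  check_intervals(islands, "islands")
  check_intervals(gold, "gold")
  if (nrow(islands) == 0 || nrow(gold) == 0) {
    abort("benchmark requires non-empty prediction and gold sets",
          class = "cgiscan_insufficient_data")
  }
  tp <- sum(overlap_counts(islands, gold) > 0)
  touched <- sum(overlap_counts(gold, islands) > 0)
  benchmark_from_counts(
    n_predicted = nrow(islands), tp = tp,
    gold_touched = touched, n_gold = nrow(gold)
  )
}

#' Benchmark result from count data
#'
#' Builds the same result object as [benchmark_vs_gold()] from the four
#' counts directly, which is useful when only published counts are
#' available.
#'
#' @param n_predicted Number of predicted islands.
#' @param tp Predictions overlapping the gold standard (>= 1 bp).
#' @param gold_touched Gold intervals overlapped by any prediction.
#' @param n_gold Size of the gold standard.
#' @return A list of class `cgi_benchmark` with the four counts plus
#'   `fn = n_gold - gold_touched`, `sn = tp / (tp + fn)` and
#'   `ppv = tp / n_predicted` (the lower-bound PPV).
#' @examples
#' benchmark_from_counts(37293, 14315, 14942, 17383)  # SN 0.854, PPV 0.384
#' @export
benchmark_from_counts <- function(n_predicted, tp, gold_touched, n_gold) {
  stopifnot(
    tp >= 0, tp <= n_predicted,
    gold_touched >= 0, gold_touched <= n_gold
  )
  fn <- n_gold - gold_touched
  structure(
    list(
      n_predicted = n_predicted, tp = tp,
      gold_touched = gold_touched, n_gold = n_gold, fn = fn,
      sn = tp / (tp + fn), ppv = tp / n_predicted
    ),
    class = "cgi_benchmark"
  )
}

#' @export
print.cgi_benchmark <- function(x, ...) {
  cat("CpG island benchmark vs gold standard\n")
  cat(sprintf("  predictions: %d (TP %d)\n", x$n_predicted, x$tp))
  cat(sprintf("  gold: %d (touched %d, FN %d)\n", x$n_gold, x$gold_touched, x$fn))
  cat(sprintf("  SN  %.3f\n  PPV %.3f (lower bound)\n", x$sn, x$ppv))
  invisible(x)
}

#' @method tidy cgi_benchmark
#' @export
tidy.cgi_benchmark <- function(x, ...) {
  tibble(
    n_predicted = x$n_predicted, tp = x$tp,
    gold_touched = x$gold_touched, n_gold = x$n_gold, fn = x$fn,
    sn = x$sn, ppv = x$ppv
  )
}

#' @method glance cgi_benchmark
#' @export
glance.cgi_benchmark <- function(x, ...) {
  tibble(sn = x$sn, ppv = x$ppv, n_predicted = x$n_predicted, n_gold = x$n_gold)
}

#' Promoter windows around transcription start sites
#'
#' The promoter is the strand-aware window from 1500 bp upstream to 500 bp
#' downstream of the TSS: `[tss - 1500, tss + 500)` on the plus strand and
#' the mirror image `[tss - 500, tss + 1500)` on the minus strand.
#'
#' @param tss Tibble of 1-bp TSS intervals with a `strand` column
#'   (`"+"`/`"-"`).
#' @param upstream,downstream Window extents in bp relative to transcription
#'   direction.
#' @param chrom_lengths Optional named vector (or tibble with `chrom`,
#'   `length`) of chromosome lengths used to clip windows at the right end;
#'   windows are always clipped at 0.
#' @return A tibble of promoter intervals with the TSS position carried in
#'   `tss_pos`.
#' @export
promoters_from_tss <- function(tss, upstream = 1500L, downstream = 500L,
                               chrom_lengths = NULL) {
  check_intervals(tss, "tss")
  if (!"strand" %in% names(tss)) {
    abort("tss must have a strand column", class = "cgiscan_format_error")
  }
  bad <- which(!tss$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    abort(paste0("unknown strand for TSS record(s): ",
                 paste(utils::head(bad, 10), collapse = ", ")),
          class = "cgiscan_format_error")
  }
  pos <- tss$start
  plus <- tss$strand == "+"
  start <- ifelse(plus, pos - upstream, pos - downstream)
  end <- ifelse(plus, pos + downstream, pos + upstream)
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) {
    if (is.data.frame(chrom_lengths)) {
      chrom_lengths <- setNames(chrom_lengths$length, chrom_lengths$chrom)
    }
    lim <- unname(chrom_lengths[tss$chrom])
    end <- ifelse(is.na(lim), end, pmin(end, lim))
  }
  tibble(
    chrom = tss$chrom, start = as.integer(start), end = as.integer(end),
    strand = tss$strand, tss_pos = as.integer(pos)
  )
}

#' Calibrate a p-value threshold to a target island count
#'
#' Sorts islands by p-value and selects the `target_count` most significant
#' ones; the threshold is `-log10` of the p-value at the cut. When several
#' islands tie at the cutoff p-value, all tied islands are included and the
#' tie is reported, so the selected set may exceed `target_count`. Matching
#' set sizes this way makes island sets selected by p-value comparable to
#' sliding-window sets selected by window length.
#'
#' @param islands Island tibble with a `p_value` column.
#' @param target_count Desired number of islands (1 to `nrow(islands)`).
#' @return A list of class `cgi_calibration` with `threshold_log10`,
#'   `p_cutoff`, `selected` (the island subset), `n_selected`,
#'   `target_count` and `tie`.
#' @export
calibrate_pvalue_threshold <- function(islands, target_count) {
  if (!"p_value" %in% names(islands) || anyNA(islands$p_value)) {
    abort("calibration requires islands with p-values",
          class = "cgiscan_missing_pvalue")
  }
  if (target_count <= 0) {
    abort("target_count must be positive", class = "cgiscan_bad_argument")
  }
  if (target_count > nrow(islands)) {
    abort("target_count exceeds the number of islands",
          class = "cgiscan_bad_argument")
  }
  p_sorted <- sort(islands$p_value)
  p_cut <- p_sorted[target_count]
  selected <- dplyr::arrange(
    dplyr::filter(islands, .data$p_value <= p_cut),
    .data$p_value
  )
  structure(
    list(
      threshold_log10 = -log10(p_cut),
      p_cutoff = p_cut,
      selected = selected,
      n_selected = nrow(selected),
      target_count = as.integer(target_count),
      tie = nrow(selected) > target_count
    ),
    class = "cgi_calibration"
  )
}

#' @export
print.cgi_calibration <- function(x, ...) {
  cat(sprintf(
    "p-value calibration: target %d islands -> -log10(p) threshold %.5f (%d selected%s)\n",
    x$target_count, x$threshold_log10, x$n_selected,
    if (x$tie) ", ties at the cutoff" else ""
  ))
  invisible(x)
}

#' Overlap sweep over calibrated island sets
#'
#' A thin driver reproducing threshold-sweep comparisons: for each target
#' set size, islands are calibrated by p-value and the overlap statistics
#' against each element set are recorded.
#'
#' @param islands Island tibble with p-values.
#' @param element_sets Named list of element tibbles.
#' @param target_counts Integer vector of set sizes.
#' @return A tibble with one row per (target size, element set).
#' @export
sweep_overlap <- function(islands, element_sets, target_counts) {
  stopifnot(is.list(element_sets), length(names(element_sets)) == length(element_sets))
  purrr::map_dfr(target_counts, function(tc) {
    cal <- calibrate_pvalue_threshold(islands, tc)
    purrr::map_dfr(names(element_sets), function(nm) {
      dplyr::bind_cols(
        tibble(target_count = tc, threshold_log10 = cal$threshold_log10,
               n_selected = cal$n_selected, element = nm),
        overlap_summary(cal$selected, element_sets[[nm]])
      )
    })
  })
}
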