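# Overlap arithmetic. All user-facing coordinates are 0-based half-open
# (BED convention); IRanges is 1-based closed, so conversion happens here
# and nowhere else. "Overlap" always means >= 1 shared bp: touching
# intervals (end == start) do not overlap.

ir_one <- function(x) IRanges::IRanges(start = x$start + 1L, end = x$end)

check_intervals <- function(x, what = "interval set") {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort(paste0(what, " must have columns chrom, start, end"),
          class = "cgiscan_format_error")
  }
  if (nrow(x) > 0 && any(x$start < 0 | x$start >= x$end)) {
    abort(paste0("invalid intervals in ", what, ": need 0 <= start < end"),
          class = "cgiscan_format_error")
  }
  invisible(x)
}

# number of intervals in `b` overlapping each interval of `a` (>= 1 bp)
overlap_counts <- function(a, b) {
  out <- integer(nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(out)
  for (ch in unique(a$chrom)) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    if (length(ib) == 0) next
    out[ia] <- IRanges::countOverlaps(ir_one(a[ia, ]), ir_one(b[ib, ]))
  }
  out
}

# bp of each interval of `a` covered by the union of `b`
covered_bp <- function(a, b) {
  out <- numeric(nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(out)
  for (ch in unique(a$chrom)) {
    ia <- which(a$chrom == ch)
    ib <- which(b$chrom == ch)
    if (length(ib) == 0) next
    ra <- ir_one(a[ia, ])
    rb <- IRanges::reduce(ir_one(b[ib, ]))
    hits <- IRanges::findOverlaps(ra, rb)
    if (length(hits) == 0) next
    pw <- IRanges::width(IRanges::pintersect(
      ra[S4Vectors::queryHits(hits)], rb[S4Vectors::subjectHits(hits)]
    ))
    cov <- tapply(pw, S4Vectors::queryHits(hits), sum)
    out[ia[as.integer(names(cov))]] <- as.numeric(cov)
  }
  out
}

#' Overlap summary of an island set against a genomic element set
#'
#' Two statistics summarise co-localization: the mean coverage (mean over
#' islands of the fraction of island bases covered by the union of the
#' elements) and the overlap fraction (fraction of islands sharing at least
#' 1 bp with an element).
#'
#' @param islands Island tibble (`chrom`, `start`, `end`, ...).
#' @param elements Element tibble in the same coordinate convention.
#' @return A one-row tibble with `mean_coverage`, `overlap_fraction`,
#'   `n_islands`, `n_elements` and `n_elements_touched`.
#' @export
overlap_summary <- function(islands, elements) {
  check_intervals(islands, "islands")
  check_intervals(elements, "elements")
  if (nrow(islands) == 0) {
    abort("overlap statistics are undefined for an empty island set",
          class = "cgiscan_insufficient_data")
  }
  cov <- covered_bp(islands, elements)
  tibble(
    mean_coverage = mean(cov / (islands$end - islands$start)),
    overlap_fraction = mean(cov > 0),
    n_islands = nrow(islands),
    n_elements = nrow(elements),
    n_elements_touched = sum(overlap_counts(elements, islands) > 0)
  )
}

#' Count inner islands per outer island
#'
#' For each outer island, counts the inner islands overlapping it in at
#' least 1 bp (an inner island straddling two outers is counted once for
#' each). Strict containment is available by flag, since "included within"
#' admits both readings.
#'
#' @param outer_islands,inner_islands Interval tibbles.
#' @param containment If `TRUE`, count only inner islands fully contained in
#'   the outer island.
#' @return A list with `per_outer` (the outer tibble plus `n_inner`),
#'   `histogram` (tibble of `n_inner`, `n_outer`) and `fraction_multiple`
#'   (fraction of outer islands hosting 2 or more inner islands).
#' @export
nesting_counts <- function(outer_islands, inner_islands, containment = FALSE) {
  check_intervals(outer_islands, "outer islands")
  check_intervals(inner_islands, "inner islands")
  if (containment && nrow(inner_islands) > 0 && nrow(outer_islands) > 0) {
    counts <- integer(nrow(outer_islands))
    for (ch in unique(outer_islands$chrom)) {
      io <- which(outer_islands$chrom == ch)
      ii <- which(inner_islands$chrom == ch)
      if (length(ii) == 0) next
      counts[io] <- IRanges::countOverlaps(
        ir_one(outer_islands[io, ]), ir_one(inner_islands[ii, ]),
        type = "within"
      )
    }
  } else {
    counts <- overlap_counts(outer_islands, inner_islands)
  }
  per_outer <- dplyr::mutate(as_tibble(outer_islands), n_inner = counts)
  hist <- dplyr::count(per_outer, .data$n_inner, name = "n_outer")
  list(
    per_outer = per_outer,
    histogram = hist,
    fraction_multiple = if (nrow(per_outer) == 0) 0 else mean(counts >= 2)
  )
}

#' TSS specificity of an island set
#'
#' Classifies islands by the number of transcription start sites (1-bp
#' intervals) they contain: exactly one TSS is "unique", two or more is
#' "multiple". Percentages are relative to islands overlapping at least one
#' TSS, reported to 2 decimals.
#'
#' @param islands Island tibble.
#' @param tss_points Tibble of 1-bp TSS intervals.
#' @return A one-row tibble with `n_overlapping_any`, `n_unique`,
#'   `n_multiple`, `pct_unique` and `pct_multiple`.
#' @export
tss_specificity <- function(islands, tss_points) {
  check_intervals(islands, "islands")
  check_intervals(tss_points, "tss_points")
  if (nrow(tss_points) > 0 && any(tss_points$end - tss_points$start != 1L)) {
    abort("tss_points must be 1-bp intervals", class = "cgiscan_format_error")
  }
  counts <- overlap_counts(islands, tss_points)
  n_any <- sum(counts >= 1)
  n_unique <- sum(counts == 1)
  n_multiple <- sum(counts >= 2)
  tibble(
    n_overlapping_any = n_any,
    n_unique = n_unique,
    n_multiple = n_multiple,
    pct_unique = if (n_any == 0) NA_real_ else round(100 * n_unique / n_any, 2),
    pct_multiple = if (n_any == 0) NA_real_ else round(100 * n_multiple / n_any, 2)
  )
}

#' Extract CpG islets
#'
#' CpG islets are statistically significant clusters shorter than the
#' conventional island length threshold: length below `max_length` and
#' p-value at or below `pvalue_threshold`.
#'
#' @param islands Island tibble carrying a `p_value` column.
#' @param max_length Maximum islet length in bp (exclusive).
#' @param pvalue_threshold Maximum p-value (inclusive).
#' @return The islet subset of `islands`.
#' @export
extract_islets <- function(islands, max_length = 200, pvalue_threshold = 1e-5) {
  check_intervals(islands, "islands")
  if (!"p_value" %in% names(islands) ||
      (nrow(islands) > 0 && anyNA(islands$p_value))) {
    abort("extract_islets requires islands with p-values",
          class = "cgiscan_missing_pvalue")
  }
  len <- islands$end - islands$start
  dplyr::filter(islands, len < max_length, .data$p_value <= pvalue_threshold)
}

#' Islands exclusive to one prediction set
#'
#' @param islands Island tibble.
#' @param other_prediction_sets A tibble, or list of tibbles, of competing
#'   predictions.
#' @return The subset of `islands` overlapping (>= 1 bp) no interval in any
#'   of the other sets.
#' @export
exclusive_islands <- function(islands, other_prediction_sets) {
  check_intervals(islands, "islands")
  if (is.data.frame(other_prediction_sets)) {
    other_prediction_sets <- list(other_prediction_sets)
  }
  keep <- rep(TRUE, nrow(islands))
  for (other in other_prediction_sets) {
    check_intervals(other, "other prediction set")
    keep <- keep & overlap_counts(islands, other) == 0
  }
  islands[keep, , drop = FALSE]
}
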