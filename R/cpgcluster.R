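#' Parameters for the CpG-clustering island detector
#'
#' @param distance_percentile Percentile of the per-chromosome distribution of
#'   consecutive CpG start-to-start distances used as the clustering threshold.
#'   Default 50 (the median), the classic choice for distance-based CpG
#'   clustering.
#' @param pvalue_threshold Maximum cluster p-value for reporting. `1e-5` gives
#'   the relaxed island set, `1e-20` the strict set.
#' @param min_cpgs Minimum number of CpGs per reported cluster. A singleton
#'   CpG has no inter-CpG distance and hence no statistic, so the floor is 2.
#' @param strict_distance If `FALSE` (default), a distance equal to the
#'   threshold still clusters; if `TRUE`, only strictly smaller distances
#'   cluster. The tie rule changes island counts, so it is exposed.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(distance_percentile = 50,
                           pvalue_threshold = 1e-5,
                           min_cpgs = 2L,
                           strict_distance = FALSE) {
  stopifnot(
    is.numeric(distance_percentile), length(distance_percentile) == 1,
    distance_percentile > 0, distance_percentile < 100,
    is.numeric(pvalue_threshold), pvalue_threshold > 0, pvalue_threshold <= 1,
    is.numeric(min_cpgs), min_cpgs >= 2,
    is.logical(strict_distance)
  )
  structure(
    list(
      distance_percentile = distance_percentile,
      pvalue_threshold = pvalue_threshold,
      min_cpgs = as.integer(min_cpgs),
      strict_distance = strict_distance
    ),
    class = "cluster_params"
  )
}

#' Distance threshold from the intra-chromosome CpG distance distribution
#'
#' The threshold is the requested percentile of the consecutive CpG
#' start-to-start distances. For the default median with an even number of
#' distances, the floor of the midpoint average is used (so distances
#' `c(2, 4)` give 3). The result is never below 2, the minimum possible
#' distance between non-overlapping CpGs.
#'
#' @param cpg_positions Strictly increasing CpG start positions (0-based).
#' @param percentile Percentile in (0, 100).
#' @return Integer distance threshold in bp.
#' @export
compute_distance_threshold <- function(cpg_positions, percentile = 50) {
  if (length(cpg_positions) < 2L) {
    abort("need at least 2 CpG positions to compute a distance threshold",
          class = "cgiscan_insufficient_data")
  }
  stopifnot(percentile > 0, percentile < 100)
  d <- diff(cpg_positions)
  thr <- floor(quantile(d, percentile / 100, type = 2, names = FALSE))
  max(2L, as.integer(thr))
}

#' Cluster CpG positions by distance
#'
#' Consecutive CpGs whose start-to-start distance is at most `threshold`
#' (strictly below it when `strict` is `TRUE`) are placed in the same run;
#' runs with fewer than `min_cpgs` CpGs are dropped.
#'
#' @param cpg_positions Strictly increasing CpG start positions.
#' @param threshold Integer distance threshold (bp).
#' @param min_cpgs Minimum run size retained.
#' @param strict Tie rule at the threshold; see [cluster_params()].
#' @return A list of integer vectors, each a retained run of CpG positions.
#' @export
cluster_cpgs <- function(cpg_positions, threshold, min_cpgs = 2L, strict = FALSE) {
  if (length(cpg_positions) == 0L) return(list())
  stopifnot(all(diff(cpg_positions) > 0))
  d <- diff(cpg_positions)
  breaks <- if (strict) d >= threshold else d > threshold
  grp <- cumsum(c(0L, as.integer(breaks)))
  runs <- unname(split(as.integer(cpg_positions), grp))
  runs[lengths(runs) >= min_cpgs]
}

#' Negative-binomial cluster p-value
#'
#' Under the null model, consecutive CpG distances are independent geometric
#' variables on \{1, 2, ...\} with success probability `p_hat` (the
#' per-position CpG start rate). The p-value of a cluster of `n_cpg` CpGs
#' spanning `span = last_start - first_start` bp is the lower tail
#' `P(S <= span)` where `S` is the sum of the `n_cpg - 1` distances, i.e. a
#' shifted negative-binomial tail, evaluated through the regularized
#' incomplete beta function ([stats::pnbinom()]).
#'
#' @param n_cpg Number of CpGs in the cluster (>= 2). Vectorised.
#' @param span Distance in bp between the first and last CpG start.
#' @param p_hat Null per-position CpG start probability, in (0, 1).
#' @return P-values in (0, 1].
#' @examples
#' negbin_pvalue(2, 1, 0.5)  # 0.5
#' negbin_pvalue(3, 2, 0.5)  # 0.25
#' @export
negbin_pvalue <- function(n_cpg, span, p_hat) {
  stopifnot(p_hat > 0, p_hat < 1, all(n_cpg >= 2))
  if (any(span < n_cpg - 1)) {
    abort("impossible geometry: span must be at least n_cpg - 1",
          class = "cgiscan_impossible_geometry")
  }
  pnbinom(span - (n_cpg - 1), size = n_cpg - 1, prob = p_hat)
}

#' Predict CpG islands by distance clustering and statistical significance
#'
#' The two-step procedure: (1) CpGs closer than the distance threshold (a
#' percentile of the chromosome's own distance distribution) are clustered;
#' (2) each cluster receives a negative-binomial p-value under the
#' chromosome's geometric-distance null, and clusters at or below the
#' p-value threshold are reported as islands. Each chromosome is processed
#' independently: the null rate `p_hat = n_cpg / (length - 1)` and the
#' distance threshold are never pooled across records.
#'
#' @param genome A tibble with columns `chrom` and `seq` (see [read_fasta()]).
#' @param params A [cluster_params()] object.
#' @return An island tibble (class `cgi_islands`) with columns `chrom`,
#'   `start`, `end`, `n_cpg`, `length`, `gc_percent`, `oe_ratio`,
#'   `cpg_density`, `p_value`, `source`. Islands start at the C of their
#'   first CpG and end just after the G of their last CpG. The per-chromosome
#'   null model (`p_hat`, distance threshold) is attached as attribute
#'   `"model"`.
#' @export
predict_islands <- function(genome, params = cluster_params()) {
  stopifnot(all(c("chrom", "seq") %in% names(genome)))
  stopifnot(inherits(params, "cluster_params"))
  per_chrom <- purrr::map(seq_len(nrow(genome)), function(i) {
    predict_islands_chrom(genome$chrom[i], genome$seq[i], params)
  })
  islands <- dplyr::bind_rows(purrr::map(per_chrom, "islands"))
  model <- dplyr::bind_rows(purrr::map(per_chrom, "model"))
  if (nrow(islands) == 0) islands <- empty_islands()
  islands <- dplyr::arrange(islands, .data$chrom, .data$start)
  attr(islands, "model") <- model
  new_islands(islands)
}

predict_islands_chrom <- function(chrom, seq, params) {
  pos <- scan_cpg_positions(seq)
  L <- nchar(seq)
  if (length(pos) < 2L) {
    return(list(
      islands = empty_islands(),
      model = tibble(chrom = chrom, n_cpg = length(pos),
                     p_hat = NA_real_, threshold = NA_integer_)
    ))
  }
  p_hat <- length(pos) / (L - 1)
  threshold <- compute_distance_threshold(pos, params$distance_percentile)
  runs <- cluster_cpgs(pos, threshold, params$min_cpgs, params$strict_distance)
  model <- tibble(chrom = chrom, n_cpg = length(pos),
                  p_hat = p_hat, threshold = threshold)
  if (length(runs) == 0L) {
    return(list(islands = empty_islands(), model = model))
  }
  first <- vapply(runs, function(r) r[1L], integer(1))
  last <- vapply(runs, function(r) r[length(r)], integer(1))
  n_cpg <- lengths(runs)
  pval <- negbin_pvalue(n_cpg, last - first, p_hat)
  keep <- pval <= params$pvalue_threshold
  if (!any(keep)) {
    return(list(islands = empty_islands(), model = model))
  }
  start <- first[keep]
  end <- last[keep] + 2L
  ctr <- seq_counters(seq)
  len <- end - start
  nC <- ctr$count_c(start, end)
  nG <- ctr$count_g(start, end)
  nCpG <- n_cpg[keep]
  isl <- tibble(
    chrom = chrom, start = start, end = end,
    n_cpg = as.integer(nCpG), length = as.integer(len),
    gc_percent = 100 * (nC + nG) / len,
    oe_ratio = ifelse(nC * nG == 0, 0, nCpG * len / (nC * nG)),
    cpg_density = nCpG / len,
    p_value = pval[keep],
    source = "cpgcluster"
  )
  list(islands = new_islands(isl), model = model)
}

#' Composition statistics of a sequence region
#'
#' @param seq A DNA string.
#' @param start,end 0-based half-open region bounds within the sequence.
#' @return A one-row tibble with `gc_percent` = 100 (nC + nG) / L,
#'   `oe_ratio` = nCpG L / (nC nG) (0 when nC nG is 0) and
#'   `cpg_density` = nCpG / L, where nCpG counts CpG dimers fully inside
#'   the region.
#' @examples
#' island_properties("CGCG", 0, 4)  # gc 100, oe 2, density 0.5
#' @export
island_properties <- function(seq, start, end) {
  stopifnot(length(seq) == 1L)
  L <- nchar(seq)
  if (start < 0 || end > L || start >= end) {
    abort("region out of sequence bounds", class = "cgiscan_bounds_error")
  }
  sub <- substr(seq, start + 1L, end)
  len <- end - start
  r <- charToRaw(sub)
  nC <- sum(r == as.raw(67L))
  nG <- sum(r == as.raw(71L))
  nCpG <- length(scan_cpg_positions(sub))
  tibble(
    gc_percent = 100 * (nC + nG) / len,
    oe_ratio = if (nC * nG == 0) 0 else nCpG * len / (nC * nG),
    cpg_density = nCpG / len
  )
}
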