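#' Parameters for the sliding-window (Takai-Jones-style) detector
#'
#' Defaults follow the stringent criteria used for mammalian genome scans:
#' islands at least 500 bp long with GC content >= 55%, observed/expected
#' CpG ratio >= 0.65 and at least `0.6 * L / 16` CpGs over their length `L`
#' (the guard against "mathematical" islands that pass GC and O/E thresholds
#' with almost no CpGs).
#'
#' @param min_length Minimum reported island length in bp.
#' @param min_gc Minimum GC percentage.
#' @param min_oe Minimum observed/expected CpG ratio.
#' @param min_cpg_factor Factor `f` in the minimum-CpG rule `nCpG >= f L / 16`.
#' @param window Scanning window size in bp (defaults to `min_length`).
#' @param merge_gap Islands separated by at most this many bp are candidates
#'   for merging (the merged segment must itself meet all criteria).
#' @return A list of class `tj_params`.
#' @export
tj_params <- function(min_length = 500L, min_gc = 55, min_oe = 0.65,
                      min_cpg_factor = 0.6, window = min_length,
                      merge_gap = 100L) {
  stopifnot(
    window > 0, min_length >= window,
    min_gc >= 0, min_gc <= 100, min_oe >= 0,
    min_cpg_factor >= 0, merge_gap >= 0
  )
  structure(
    list(
      min_length = as.integer(min_length), min_gc = min_gc, min_oe = min_oe,
      min_cpg_factor = min_cpg_factor, window = as.integer(window),
      merge_gap = as.integer(merge_gap)
    ),
    class = "tj_params"
  )
}

#' Score one window against the sliding-window criteria
#'
#' @param seq A DNA string.
#' @param start 0-based window start.
#' @param window Window length in bp.
#' @param params A [tj_params()] object.
#' @return A one-row tibble with `qualifies`, `gc_percent`, `oe_ratio`,
#'   `n_cpg` and `min_cpg_required`.
#' @export
window_meets_criteria <- function(seq, start, window = 500L,
                                  params = tj_params(min_length = window,
                                                     window = window)) {
  L <- nchar(seq)
  if (start < 0 || start + window > L) {
    abort("window exceeds sequence bounds", class = "cgiscan_bounds_error")
  }
  ctr <- seq_counters(seq)
  st <- segment_stats(ctr, start, start + window, params)
  tibble(
    qualifies = st$ok, gc_percent = st$gc, oe_ratio = st$oe,
    n_cpg = st$ncpg, min_cpg_required = st$min_cpg
  )
}

# gc/oe/minCpG stats for 0-based half-open [a, b); vectorised over a, b
segment_stats <- function(ctr, a, b, params) {
  len <- b - a
  nC <- ctr$count_c(a, b)
  nG <- ctr$count_g(a, b)
  ncpg <- ctr$count_cpg(a, b)
  gc <- 100 * (nC + nG) / len
  oe <- ifelse(nC * nG == 0, 0, ncpg * len / (nC * nG))
  min_cpg <- params$min_cpg_factor * len / 16
  list(
    gc = gc, oe = oe, ncpg = ncpg, min_cpg = min_cpg,
    ok = gc >= params$min_gc & oe >= params$min_oe & ncpg >= min_cpg
  )
}

#' Predict CpG islands with the sliding-window detector
#'
#' The scan proceeds in five steps per chromosome: (1) slide a window 1 bp at
#' a time until it meets all criteria; (2) jump window-by-window while the
#' criteria hold; (3) on failure, roll the last window back 1 bp at a time
#' until it qualifies, closing a candidate segment; (4) trim the candidate
#' 1 bp per side (ends snapped onto CpGs: the C of the first, the G of the
#' last) until the whole segment meets all criteria; (5) merge islands
#' separated by at most `merge_gap` bp when the merged segment still meets
#' every criterion (never across a run of `merge_gap` or more Ns), and report
#' segments of at least `min_length` bp. Every reported island therefore
#' satisfies all thresholds over its full extent.
#'
#' @param genome A tibble with columns `chrom` and `seq`.
#' @param params A [tj_params()] object.
#' @return An island tibble (class `cgi_islands`); `p_value` is `NA` for
#'   sliding-window islands and `source` is `"tj"`.
#' @export
tj_predict <- function(genome, params = tj_params()) {
  stopifnot(all(c("chrom", "seq") %in% names(genome)))
  stopifnot(inherits(params, "tj_params"))
  islands <- dplyr::bind_rows(purrr::map(seq_len(nrow(genome)), function(i) {
    tj_scan_chrom(genome$chrom[i], genome$seq[i], params)
  }))
  if (nrow(islands) == 0) islands <- empty_islands()
  new_islands(dplyr::arrange(islands, .data$chrom, .data$start))
}

tj_scan_chrom <- function(chrom, seq, params) {
  L <- nchar(seq)
  w <- params$window
  if (L < w) return(empty_islands())
  ctr <- seq_counters(seq)
  starts <- 0:(L - w)
  st <- segment_stats(ctr, starts, starts + w, params)
  qstarts <- starts[st$ok]
  if (length(qstarts) == 0L) return(empty_islands())
  cpgs <- ctr$cpg_starts
  if (length(cpgs) == 0L) return(empty_islands())

  segs <- list()
  pos <- 0L
  max_start <- L - w
  repeat {
    j <- findInterval(pos - 0.5, qstarts) + 1L
    if (j > length(qstarts)) break
    s <- qstarts[j]
    # jump phase
    e <- s
    repeat {
      nxt <- e + w
      if (nxt <= max_start && st$ok[nxt + 1L]) e <- nxt else break
    }
    # rollback: last qualifying start no further than one window past e
    hi <- min(e + w, max_start)
    k <- findInterval(hi + 0.5, qstarts)
    e2 <- qstarts[k]
    seg <- tj_trim(ctr, cpgs, s, e2 + w, params)
    if (!is.null(seg)) segs[[length(segs) + 1L]] <- seg
    pos <- e2 + w
  }
  if (length(segs) == 0L) return(empty_islands())

  segs <- do.call(rbind, segs)
  merged <- tj_merge(ctr, seq, segs, params)
  merged <- merged[merged[, 2] - merged[, 1] >= params$min_length, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty_islands())

  a <- merged[, 1]
  b <- merged[, 2]
  stx <- segment_stats(ctr, a, b, params)
  new_islands(tibble(
    chrom = chrom, start = as.integer(a), end = as.integer(b),
    n_cpg = as.integer(stx$ncpg), length = as.integer(b - a),
    gc_percent = stx$gc, oe_ratio = stx$oe,
    cpg_density = stx$ncpg / (b - a),
    p_value = NA_real_, source = "tj"
  ))
}

# Trim [a, b) 1 bp per side, snapping ends onto CpGs, until the whole
# segment qualifies. NULL if it collapses first.
tj_trim <- function(ctr, cpgs, a, b, params) {
  repeat {
    # snap: a -> first CpG start >= a; b -> last CpG start <= b - 2, plus 2
    ia <- findInterval(a - 0.5, cpgs) + 1L
    ib <- findInterval(b - 2L + 0.5, cpgs)
    if (ia > length(cpgs) || ib < 1L) return(NULL)
    a2 <- cpgs[ia]
    b2 <- cpgs[ib] + 2L
    if (b2 - a2 < 2L) return(NULL)
    st <- segment_stats(ctr, a2, b2, params)
    if (st$ok) return(c(a2, b2))
    a <- a2 + 1L
    b <- b2 - 1L
    if (b - a < 2L) return(NULL)
  }
}

# Merge segments separated by <= merge_gap when the merged whole still
# qualifies; never across a run of >= merge_gap Ns.
tj_merge <- function(ctr, seq, segs, params) {
  if (nrow(segs) <= 1L) return(segs)
  out <- list()
  cur <- segs[1L, ]
  for (i in 2:nrow(segs)) {
    nxt <- segs[i, ]
    gap <- nxt[1] - cur[2]
    mergeable <- gap <= params$merge_gap &&
      !n_run_blocks(seq, cur[2], nxt[1], params$merge_gap) &&
      segment_stats(ctr, cur[1], nxt[2], params)$ok
    if (mergeable) {
      cur[2] <- nxt[2]
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- nxt
    }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, out)
}

# TRUE iff [a, b) contains a run of >= gap Ns
n_run_blocks <- function(seq, a, b, gap) {
  if (b - a < gap || gap <= 0) return(FALSE)
  grepl(paste0("N{", gap, ",}"), substr(seq, a + 1L, b))
}

#' Can a region be reported by the sliding-window detector?
#'
#' Reported islands must start on the C of a CpG and end after the G of a
#' CpG, so the recoverable core of a region is its CpG-bounded span. A
#' region qualifies when that core is at least `min_length` bp long and
#' meets the GC, O/E and minimum-CpG criteria over its full extent; regions
#' whose core falls short (e.g. a 510-bp island whose first and last CpGs
#' are 490 bp apart) are unreportable by construction.
#'
#' @param seq The chromosome sequence containing the region.
#' @param start,end 0-based half-open region bounds.
#' @param params A [tj_params()] object.
#' @return A one-row tibble with the core bounds (`core_start`, `core_end`),
#'   its stats and `qualifies`.
#' @export
tj_block_qualifies <- function(seq, start, end, params = tj_params()) {
  L <- nchar(seq)
  if (start < 0 || end > L || start >= end) {
    abort("region out of sequence bounds", class = "cgiscan_bounds_error")
  }
  pos <- scan_cpg_positions(substr(seq, start + 1L, end)) + start
  no <- tibble(core_start = NA_integer_, core_end = NA_integer_,
               core_length = NA_integer_, gc_percent = NA_real_,
               oe_ratio = NA_real_, n_cpg = NA_integer_, qualifies = FALSE)
  if (length(pos) == 0) return(no)
  a <- pos[1]
  b <- pos[length(pos)] + 2L
  if (b - a < params$min_length) {
    return(dplyr::mutate(no, core_start = a, core_end = b,
                         core_length = b - a))
  }
  ctr <- seq_counters(seq)
  st <- segment_stats(ctr, a, b, params)
  tibble(core_start = a, core_end = b, core_length = b - a,
         gc_percent = st$gc, oe_ratio = st$oe, n_cpg = as.integer(st$ncpg),
         qualifies = st$ok)
}
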