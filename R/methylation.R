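#' Thresholds for methylation-state classification
#'
#' The bisulfite-amplicon rules: per-tissue CpG means of at least 80%
#' are methylated, below 20% unmethylated, in between intermediate (so a
#' mean of exactly 80 is methylated and exactly 20 intermediate). CpGs are
#' only classified when seen in at least `min_clones` clones per measurement
#' and in at least `min_tissues` tissues; cross-tissue calls need a strict
#' majority. Array-style region extraction labels a tissue unmethylated when
#' its scaled 5mC log2 ratio is below `weber_unmeth_max`, and read-based
#' island means use cytosines covered by at least `lister_min_reads` reads.
#'
#' @param methylated_min,unmethylated_max Percent cutoffs for per-tissue
#'   labels.
#' @param min_clones Minimum clones (or reads) per retained measurement.
#' @param min_tissues Minimum tissues with retained data per classified CpG.
#' @param majority Strict-majority fraction for cross-tissue and island
#'   calls.
#' @param island_cpg_coverage Strict minimum fraction of an island's CpGs
#'   with classified states (or read coverage) before the island is labeled.
#' @param weber_unmeth_max Scaled 5mC log2-ratio cutoff below which a region
#'   is unmethylated in a tissue.
#' @param lister_min_reads Minimum read count per counted cytosine.
#' @param pair_test_alpha Significance level for the island-pair rank test.
#' @return A list of class `meth_thresholds`.
#' @export
meth_thresholds <- function(methylated_min = 80, unmethylated_max = 20,
                            min_clones = 2L, min_tissues = 6L,
                            majority = 0.5, island_cpg_coverage = 0.5,
                            weber_unmeth_max = 0.3, lister_min_reads = 10L,
                            pair_test_alpha = 0.05) {
  stopifnot(
    unmethylated_max < methylated_min,
    majority > 0, majority < 1,
    island_cpg_coverage > 0, island_cpg_coverage < 1
  )
  structure(
    list(
      methylated_min = methylated_min, unmethylated_max = unmethylated_max,
      min_clones = as.integer(min_clones), min_tissues = as.integer(min_tissues),
      majority = majority, island_cpg_coverage = island_cpg_coverage,
      weber_unmeth_max = weber_unmeth_max,
      lister_min_reads = as.integer(lister_min_reads),
      pair_test_alpha = pair_test_alpha
    ),
    class = "meth_thresholds"
  )
}

check_meth_table <- function(meth) {
  need <- c("chrom", "position", "tissue", "mean_methylation", "n_support")
  if (!all(need %in% names(meth))) {
    abort(paste0("methylation table must have columns ",
                 paste(need, collapse = ", ")),
          class = "cgiscan_format_error")
  }
  invisible(meth)
}

tissue_label <- function(m, thresholds) {
  dplyr::case_when(
    m >= thresholds$methylated_min ~ "methylated",
    m < thresholds$unmethylated_max ~ "unmethylated",
    TRUE ~ "intermediate"
  )
}

#' Classify the methylation state of each CpG across tissues
#'
#' Records with fewer than `min_clones` supporting clones are discarded;
#' remaining measurements are averaged within tissue (multiple samples per
#' tissue are averaged before labeling) and each tissue is labeled by the
#' 80/20 cutoffs. A CpG seen in fewer than `min_tissues` tissues stays
#' unclassified. Across tissues a CpG is methylated when methylated in a
#' strict majority of tissues and never unmethylated; unmethylated when
#' unmethylated in a strict majority and never methylated; differentially
#' methylated when both labels occur and intermediate tissues are in the
#' minority; intermediate when a strict majority of tissues is intermediate
#' and neither extreme occurs; otherwise unclassified.
#'
#' @param meth Long methylation tibble with columns `chrom`, `position`,
#'   `tissue`, `mean_methylation` (percent), `n_support` and optionally
#'   `sample`.
#' @param thresholds A [meth_thresholds()] object.
#' @return A tibble with one row per CpG: `chrom`, `position`, `n_tissues`,
#'   `n_methylated`, `n_unmethylated`, `n_intermediate`, `state`.
#' @export
classify_cpgs <- function(meth, thresholds = meth_thresholds()) {
  check_meth_table(meth)
  all_cpgs <- dplyr::distinct(meth, .data$chrom, .data$position)
  kept <- dplyr::filter(meth, .data$n_support >= thresholds$min_clones)
  if (nrow(kept) == 0) {
    return(dplyr::mutate(all_cpgs, n_tissues = 0L, n_methylated = 0L,
                         n_unmethylated = 0L, n_intermediate = 0L,
                         state = "unclassified"))
  }
  per_tissue <- kept |>
    group_by(.data$chrom, .data$position, .data$tissue) |>
    summarise(m = mean(.data$mean_methylation), .groups = "drop") |>
    mutate(label = tissue_label(.data$m, thresholds))
  states <- per_tissue |>
    group_by(.data$chrom, .data$position) |>
    summarise(
      n_tissues = dplyr::n(),
      n_methylated = sum(.data$label == "methylated"),
      n_unmethylated = sum(.data$label == "unmethylated"),
      n_intermediate = sum(.data$label == "intermediate"),
      .groups = "drop"
    ) |>
    mutate(state = cpg_state(.data$n_tissues, .data$n_methylated,
                             .data$n_unmethylated, .data$n_intermediate,
                             thresholds))
  all_cpgs |>
    left_join(states, by = c("chrom", "position")) |>
    tidyr::replace_na(list(n_tissues = 0L, n_methylated = 0L,
                           n_unmethylated = 0L, n_intermediate = 0L,
                           state = "unclassified"))
}

cpg_state <- function(n_t, n_m, n_u, n_i, thresholds) {
  maj <- thresholds$majority
  dplyr::case_when(
    n_t < thresholds$min_tissues ~ "unclassified",
    n_m / n_t > maj & n_u == 0 ~ "methylated",
    n_u / n_t > maj & n_m == 0 ~ "unmethylated",
    n_m > 0 & n_u > 0 & n_i / n_t < maj ~ "differential",
    n_i / n_t > maj & n_m == 0 & n_u == 0 ~ "intermediate",
    TRUE ~ "unclassified"
  )
}

#' Classify a single CpG
#'
#' Convenience wrapper around [classify_cpgs()] for the records of one CpG.
#'
#' @param records Methylation records of one CpG (same columns as in
#'   [classify_cpgs()]; `chrom`/`position` may be omitted).
#' @param thresholds A [meth_thresholds()] object.
#' @return The state string.
#' @export
classify_cpg <- function(records, thresholds = meth_thresholds()) {
  if (!"chrom" %in% names(records)) records$chrom <- "chr"
  if (!"position" %in% names(records)) records$position <- 0L
  out <- classify_cpgs(records, thresholds)
  if (nrow(out) != 1L) {
    abort("records must describe a single CpG", class = "cgiscan_bad_argument")
  }
  out$state
}

#' Classify the methylation state of islands
#'
#' An island is labeled only when classified CpG states exist for a strict
#' majority of its CpGs (`n_cpg` column). Among the classified CpGs, the
#' island is methylated when a strict majority is methylated and no
#' unmethylated CpG exists; unmethylated when a strict majority is
#' unmethylated and no methylated CpG exists; differentially methylated when
#' a strict majority is differential; otherwise unclassified.
#'
#' @param islands Island tibble with `chrom`, `start`, `end` and `n_cpg`.
#' @param cpg_states Per-CpG states from [classify_cpgs()].
#' @param thresholds A [meth_thresholds()] object.
#' @return `islands` plus `n_classified`, `cpg_coverage` and `state`.
#' @export
classify_islands <- function(islands, cpg_states,
                             thresholds = meth_thresholds()) {
  check_intervals(islands, "islands")
  if (!"n_cpg" %in% names(islands)) {
    abort("islands must carry an n_cpg column", class = "cgiscan_format_error")
  }
  classified <- dplyr::filter(cpg_states, .data$state != "unclassified")
  out <- as_tibble(islands)
  maj <- thresholds$majority
  states <- purrr::map_chr(seq_len(nrow(out)), function(i) {
    inside <- classified$chrom == out$chrom[i] &
      classified$position >= out$start[i] & classified$position < out$end[i]
    st <- classified$state[inside]
    n_cl <- length(st)
    if (out$n_cpg[i] == 0 ||
        n_cl / out$n_cpg[i] <= thresholds$island_cpg_coverage) {
      return("unclassified")
    }
    n_m <- sum(st == "methylated")
    n_u <- sum(st == "unmethylated")
    n_d <- sum(st == "differential")
    if (n_m / n_cl > maj && n_u == 0) "methylated"
    else if (n_u / n_cl > maj && n_m == 0) "unmethylated"
    else if (n_d / n_cl > maj) "differential"
    else "unclassified"
  })
  n_classified <- purrr::map_int(seq_len(nrow(out)), function(i) {
    sum(classified$chrom == out$chrom[i] &
          classified$position >= out$start[i] &
          classified$position < out$end[i])
  })
  dplyr::mutate(out,
                n_classified = n_classified,
                cpg_coverage = ifelse(.data$n_cpg == 0, 0,
                                      n_classified / .data$n_cpg),
                state = states)
}

#' Extract unmethylated and differential regions from two-tissue array data
#'
#' A region is unmethylated in a tissue when its scaled 5mC log2 ratio is
#' below the cutoff (0.3 by default). Regions unmethylated in at least one
#' tissue are kept; among those, regions unmethylated in some but not all
#' tissues are differentially methylated.
#'
#' @param regions Long tibble with columns `region_id`, `tissue`, `ratio`
#'   (scaled 5mC log2 ratio); at least two tissues per region.
#' @param thresholds A [meth_thresholds()] object.
#' @return A tibble with one row per region: `region_id`, `n_tissues`,
#'   `n_unmethylated`, `kept`, `concordant_unmethylated`, `differential`.
#' @export
extract_weber_regions <- function(regions, thresholds = meth_thresholds()) {
  need <- c("region_id", "tissue", "ratio")
  if (!all(need %in% names(regions))) {
    abort("regions must have columns region_id, tissue, ratio",
          class = "cgiscan_format_error")
  }
  out <- regions |>
    group_by(.data$region_id) |>
    summarise(
      n_tissues = dplyr::n(),
      n_unmethylated = sum(.data$ratio < thresholds$weber_unmeth_max),
      .groups = "drop"
    )
  if (any(out$n_tissues < 2)) {
    abort("every region needs ratios for at least 2 tissues",
          class = "cgiscan_insufficient_data")
  }
  dplyr::mutate(out,
                kept = .data$n_unmethylated >= 1,
                concordant_unmethylated = .data$n_unmethylated == .data$n_tissues,
                differential = .data$kept &
                  .data$n_unmethylated < .data$n_tissues)
}

#' Mean island methylation from read-based data
#'
#' Cytosine records with fewer than `lister_min_reads` reads are discarded;
#' surviving records at the same CpG start (the two strands of one CpG) are
#' averaged. An island mean is reported only when covered CpGs make up a
#' strict majority of the island's CpGs, and is then the mean over covered
#' CpGs. When the table carries a `tissue` column, means are computed per
#' tissue.
#'
#' @param islands Island tibble with `chrom`, `start`, `end`, `n_cpg`.
#' @param reads Read-style methylation tibble: `chrom`, `position`,
#'   `mean_methylation`, `n_support` and optionally `tissue`.
#' @param thresholds A [meth_thresholds()] object.
#' @return A tibble with one row per island (x tissue): island coordinates,
#'   `tissue`, `n_covered`, `cpg_coverage` and `mean_methylation` (`NA` when
#'   the coverage rule fails).
#' @export
island_mean_methylation <- function(islands, reads,
                                    thresholds = meth_thresholds()) {
  check_intervals(islands, "islands")
  if (!"n_cpg" %in% names(islands)) {
    abort("islands must carry an n_cpg column", class = "cgiscan_format_error")
  }
  if (!"tissue" %in% names(reads)) reads$tissue <- "all"
  kept <- dplyr::filter(reads, .data$n_support >= thresholds$lister_min_reads)
  per_cpg <- kept |>
    group_by(.data$chrom, .data$position, .data$tissue) |>
    summarise(m = mean(.data$mean_methylation), .groups = "drop")
  tissues <- unique(reads$tissue)
  grid <- tidyr::expand_grid(island_id = seq_len(nrow(islands)), tissue = tissues)
  res <- purrr::pmap_dfr(grid, function(island_id, tissue) {
    isl <- islands[island_id, ]
    sub <- per_cpg[per_cpg$tissue == tissue &
                     per_cpg$chrom == isl$chrom &
                     per_cpg$position >= isl$start &
                     per_cpg$position < isl$end, ]
    n_cov <- nrow(sub)
    coverage <- if (isl$n_cpg == 0) 0 else n_cov / isl$n_cpg
    tibble(
      island_id = island_id, chrom = isl$chrom, start = isl$start,
      end = isl$end, tissue = tissue, n_covered = n_cov,
      cpg_coverage = coverage,
      mean_methylation = if (coverage > thresholds$island_cpg_coverage) {
        mean(sub$m)
      } else {
        NA_real_
      }
    )
  })
  res
}

#' Methylation heterogeneity of inner islands within outer islands
#'
#' For every outer (sliding-window) island hosting at least two inner
#' (cluster) islands, computes the per-tissue mean methylation of each inner
#' island from amplicon-style data and reports the maximum absolute
#' difference between inner-island means, taken over all tissues and all
#' inner-island pairs. A large maximum suggests the outer island merged
#' distinct methylation domains. Outer islands with fewer than two inner
#' islands (or fewer than two with methylation data in any tissue) are
#' skipped and counted.
#'
#' @param outer_islands,inner_islands Interval tibbles.
#' @param meth Amplicon-style methylation tibble (see [classify_cpgs()]).
#' @param thresholds A [meth_thresholds()] object.
#' @param diff_cutoff Heterogeneity call cutoff in percentage points
#'   (default 30).
#' @return A tibble of class `cgi_heterogeneity` with one row per tested
#'   outer island (`outer_id`, coordinates, `n_inner`, `max_diff`);
#'   attributes `n_skipped` and `diff_cutoff`. [glance()] reports the
#'   fraction of tested islands exceeding the cutoff.
#' @export
swa_heterogeneity <- function(outer_islands, inner_islands, meth,
                              thresholds = meth_thresholds(),
                              diff_cutoff = 30) {
  check_intervals(outer_islands, "outer islands")
  check_intervals(inner_islands, "inner islands")
  check_meth_table(meth)
  kept <- dplyr::filter(meth, .data$n_support >= thresholds$min_clones)
  per_cpg <- kept |>
    group_by(.data$chrom, .data$position, .data$tissue) |>
    summarise(m = mean(.data$mean_methylation), .groups = "drop")
  inner <- as_tibble(inner_islands)
  inner$inner_id <- seq_len(nrow(inner))
  # per inner island x tissue mean over its CpGs with data
  inner_means <- purrr::map_dfr(seq_len(nrow(inner)), function(i) {
    sub <- per_cpg[per_cpg$chrom == inner$chrom[i] &
                     per_cpg$position >= inner$start[i] &
                     per_cpg$position < inner$end[i], ]
    if (nrow(sub) == 0) return(NULL)
    sub |>
      group_by(.data$tissue) |>
      summarise(m = mean(.data$m), .groups = "drop") |>
      mutate(inner_id = i)
  })
  outer <- as_tibble(outer_islands)
  outer$outer_id <- seq_len(nrow(outer))
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(outer))) {
    ids <- inner$inner_id[inner$chrom == outer$chrom[i] &
                            inner$start < outer$end[i] &
                            inner$end > outer$start[i]]
    if (length(ids) < 2L) {
      n_skipped <- n_skipped + 1L
      next
    }
    im <- inner_means[inner_means$inner_id %in% ids, ]
    diffs <- im |>
      group_by(.data$tissue) |>
      summarise(n = dplyr::n(), d = max(.data$m) - min(.data$m),
                .groups = "drop") |>
      dplyr::filter(.data$n >= 2)
    if (nrow(diffs) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      outer_id = i, chrom = outer$chrom[i],
      start = outer$start[i], end = outer$end[i],
      n_inner = length(ids), max_diff = max(diffs$d)
    )
  }
  out <- if (length(rows) == 0) {
    tibble(outer_id = integer(0), chrom = character(0), start = integer(0),
           end = integer(0), n_inner = integer(0), max_diff = numeric(0))
  } else {
    dplyr::bind_rows(rows)
  }
  attr(out, "n_skipped") <- n_skipped
  attr(out, "diff_cutoff") <- diff_cutoff
  class(out) <- unique(c("cgi_heterogeneity", class(tibble())))
  out
}

#' @method glance cgi_heterogeneity
#' @export
glance.cgi_heterogeneity <- function(x, ...) {
  cutoff <- attr(x, "diff_cutoff") %||% 30
  tibble(
    n_tested = nrow(x),
    n_skipped = attr(x, "n_skipped") %||% NA_integer_,
    diff_cutoff = cutoff,
    fraction_above_cutoff = if (nrow(x) == 0) NA_real_
                            else mean(x$max_diff > cutoff)
  )
}

#' Compare the methylation of two islands with a rank-sum test
#'
#' A two-sided Mann-Whitney (Wilcoxon rank-sum) test on the per-CpG
#' methylation values of the two islands. With fewer than 8 values on both
#' sides the permutation null is enumerated exactly (ties handled through
#' midranks); otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param values_a,values_b Per-CpG methylation values of the two islands.
#' @param alpha Significance level.
#' @param exact_max_n Largest per-side size for exact enumeration.
#' @return A list of class `cgi_pair_test` with `u` (the Mann-Whitney U of
#'   the first sample), `p_value`, `significant`, `method`, `n_a`, `n_b`.
#'   Supports [tidy()] and [glance()].
#' @export
compare_island_pair <- function(values_a, values_b, alpha = 0.05,
                                exact_max_n = 7L) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("both islands need at least one covered CpG",
          class = "cgiscan_insufficient_data")
  }
  n <- length(values_a)
  m <- length(values_b)
  r <- rank(c(values_a, values_b))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (n <= exact_max_n && m <= exact_max_n) {
    method <- "exact enumeration"
    combos <- utils::combn(n + m, n)
    us <- colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
  } else {
    method <- "normal approximation with tie correction"
    N <- n + m
    ties <- table(c(values_a, values_b))
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
  }
  structure(
    list(u = u, p_value = p, significant = p <= alpha, alpha = alpha,
         method = method, n_a = n, n_b = m),
    class = "cgi_pair_test"
  )
}

#' @export
print.cgi_pair_test <- function(x, ...) {
  cat("Mann-Whitney island-pair comparison (", x$method, ")\n", sep = "")
  cat(sprintf("  U = %g, n = (%d, %d), p = %.4g%s\n", x$u, x$n_a, x$n_b,
              x$p_value,
              if (x$significant) paste0(" (significant at ", x$alpha, ")") else ""))
  invisible(x)
}

#' @method tidy cgi_pair_test
#' @export
tidy.cgi_pair_test <- function(x, ...) {
  tibble(u = x$u, p_value = x$p_value, significant = x$significant,
         method = x$method, n_a = x$n_a, n_b = x$n_b)
}

#' @method glance cgi_pair_test
#' @export
glance.cgi_pair_test <- function(x, ...) {
  tibble(p_value = x$p_value, significant = x$significant, alpha = x$alpha)
}
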