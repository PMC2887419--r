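# Shared fixtures and independent oracles.

rand_dna <- function(n, probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

rand_intervals <- function(n, max_pos, chrom = "c1", max_len = NULL) {
  max_len <- max_len %||% max(2L, max_pos %/% 5L)
  start <- sample.int(max_pos - 2L, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start,
                 end = pmin(start + len, max_pos))
}

# per-base brute force: bp of `island` covered by the union of `elements`
brute_covered_bp <- function(island, elements) {
  bases <- seq(island$start, island$end - 1L)
  covered <- rep(FALSE, length(bases))
  for (j in seq_len(nrow(elements))) {
    if (elements$chrom[j] != island$chrom) next
    covered <- covered | (bases >= elements$start[j] & bases < elements$end[j])
  }
  sum(covered)
}

brute_overlap_count <- function(interval, others) {
  sum(others$chrom == interval$chrom &
        others$start < interval$end & others$end > interval$start)
}

# naive summation oracle for the cluster p-value: enumerate all vectors of
# n_cpg - 1 geometric distances with sum <= span
enum_negbin <- function(n_cpg, span, p_hat) {
  k <- n_cpg - 1L
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(span)), k)))
  keep <- rowSums(grid) <= span
  sum(apply(grid[keep, , drop = FALSE], 1,
            function(d) prod(p_hat * (1 - p_hat)^(d - 1))))
}

# exact two-sided rank-sum p-value by enumeration, computing U from pairwise
# comparisons (not midranks), as an independent route
enum_mw_pvalue <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  N <- length(pooled)
  u_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(a, b)
  mu <- n * (N - n) / 2
  combos <- utils::combn(N, n)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# one simulated study genome shared across test files (built once per run)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_genome(sim_config(), seed = 101)
      cache <<- list(
        sim = sim,
        cluster = predict_islands(sim$genome),
        tj = tj_predict(sim$genome)
      )
    }
    cache
  }
})
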