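meth_rec <- function(values, tissues = sprintf("T%d", seq_along(values)),
                     clones = 3L, position = 0L) {
  tibble::tibble(chrom = "c1", position = position, tissue = tissues,
                 mean_methylation = values, n_support = clones)
}

test_that("per-CpG classification follows the cross-tissue rules", {
  expect_equal(classify_cpg(meth_rec(rep(90, 6))), "methylated")
  expect_equal(classify_cpg(meth_rec(rep(10, 6))), "unmethylated")
  # 2 methylated, 2 unmethylated, 2 intermediate: differential
  expect_equal(classify_cpg(meth_rec(c(90, 95, 5, 10, 50, 60))), "differential")
  # only 5 tissues: unclassified
  expect_equal(classify_cpg(meth_rec(rep(90, 5))), "unclassified")
  # majority methylated but one unmethylated tissue vetoes
  expect_equal(classify_cpg(meth_rec(c(90, 90, 90, 90, 90, 5))), "differential")
  # intermediate majority blocks the differential call
  expect_equal(classify_cpg(meth_rec(c(90, 5, 50, 50, 50, 50))), "unclassified")
})

test_that("boundary methylation values classify as documented", {
  # exactly 80 is methylated, exactly 20 is intermediate (not unmethylated)
  expect_equal(classify_cpg(meth_rec(rep(80, 6))), "methylated")
  expect_equal(classify_cpg(meth_rec(rep(20, 6))), "intermediate")
  expect_equal(classify_cpg(meth_rec(rep(19.99, 6))), "unmethylated")
})

test_that("the clone filter runs per measurement", {
  # detected everywhere but with a single clone: unclassified
  expect_equal(classify_cpg(meth_rec(rep(90, 8), clones = 1L)), "unclassified")
  # clones counted per record, not summed across tissues
  mixed <- meth_rec(rep(90, 8), clones = c(rep(3L, 5), rep(1L, 3)))
  expect_equal(classify_cpg(mixed), "unclassified") # only 5 valid tissues
})

test_that("samples are averaged within tissue before labeling", {
  rec <- tibble::tibble(
    chrom = "c1", position = 0L,
    tissue = rep(sprintf("T%d", 1:6), each = 2),
    mean_methylation = rep(c(70, 95), 6), # per-tissue mean 82.5 -> methylated
    n_support = 3L
  )
  expect_equal(classify_cpg(rec), "methylated")
})

test_that("island classification uses coverage and classified-CpG majorities", {
  islands <- tibble::tibble(chrom = "c1", start = 0L, end = 100L, n_cpg = 10L)
  states <- function(sts) {
    tibble::tibble(chrom = "c1", position = seq(0, length.out = length(sts), by = 2),
                   state = sts)
  }
  # 6 of 10 classified: 4 unmethylated + 2 intermediate -> unmethylated
  r1 <- classify_islands(islands, states(c(rep("unmethylated", 4),
                                           rep("intermediate", 2))))
  expect_equal(r1$state, "unmethylated")
  # only 4 of 10 classified -> coverage 40%, unclassified
  r2 <- classify_islands(islands, states(rep("unmethylated", 4)))
  expect_equal(r2$state, "unclassified")
  # 6 classified, 4 differential -> differential
  r3 <- classify_islands(islands, states(c(rep("differential", 4),
                                           rep("intermediate", 2))))
  expect_equal(r3$state, "differential")
  # a single methylated CpG vetoes the unmethylated call
  r4 <- classify_islands(islands, states(c(rep("unmethylated", 5),
                                           "methylated")))
  expect_equal(r4$state, "unclassified")
})

test_that("array-style region extraction splits concordant and differential", {
  regions <- tibble::tibble(
    region_id = rep(c("r1", "r2", "r3"), each = 2),
    tissue = rep(c("fibroblast", "sperm"), 3),
    ratio = c(0.1, 0.5, 0.1, 0.2, 0.4, 0.6)
  )
  w <- extract_weber_regions(regions)
  expect_equal(w$kept, c(TRUE, TRUE, FALSE))
  expect_equal(w$differential, c(TRUE, FALSE, FALSE))
  expect_equal(w$concordant_unmethylated, c(FALSE, TRUE, FALSE))
  # conservation: kept = concordant unmethylated + differential
  expect_equal(sum(w$kept), sum(w$concordant_unmethylated) + sum(w$differential))
  expect_error(extract_weber_regions(regions[1, ]),
               class = "cgiscan_insufficient_data")
})

test_that("read-based island means honour the coverage rules", {
  islands <- tibble::tibble(chrom = "c1", start = 0L, end = 40L, n_cpg = 4L)
  reads <- tibble::tibble(
    chrom = "c1", position = c(0L, 10L, 20L, 30L),
    mean_methylation = c(10, 20, 30, 99),
    n_support = c(15L, 20L, 12L, 9L) # last CpG under-covered
  )
  r <- island_mean_methylation(islands, reads)
  expect_equal(r$n_covered, 3L)
  expect_equal(r$mean_methylation, 20)
  # 2 covered of 4 is not a strict majority -> undefined
  reads2 <- dplyr::mutate(reads, n_support = c(15L, 20L, 9L, 9L))
  expect_true(is.na(island_mean_methylation(islands, reads2)$mean_methylation))
  # strands of one CpG are averaged before the island mean
  reads3 <- dplyr::bind_rows(reads,
                             tibble::tibble(chrom = "c1", position = 0L,
                                            mean_methylation = 30,
                                            n_support = 15L))
  r3 <- island_mean_methylation(islands, reads3)
  expect_equal(r3$mean_methylation, mean(c(20, 20, 30)))
})

test_that("heterogeneity reports the max difference over pairs and tissues", {
  outer <- tibble::tibble(chrom = "c1", start = 0L, end = 1000L)
  inner <- tibble::tibble(chrom = "c1", start = c(0L, 400L, 800L),
                          end = c(100L, 500L, 900L))
  mk_meth <- function(means_by_tissue) {
    # means_by_tissue: list(tissue -> per-inner-island means)
    purrr::imap_dfr(means_by_tissue, function(means, tis) {
      tibble::tibble(chrom = "c1",
                     position = c(10L, 410L, 810L)[seq_along(means)],
                     tissue = tis, mean_methylation = means, n_support = 3L)
    })
  }
  # one tissue, means 10/90 on two inner islands -> 80
  h1 <- swa_heterogeneity(outer, inner[1:2, ], mk_meth(list(T1 = c(10, 90))))
  expect_equal(h1$max_diff, 80)
  # two tissues with spreads 15 and 40 -> 40
  h2 <- swa_heterogeneity(outer, inner[1:2, ],
                          mk_meth(list(T1 = c(50, 65), T2 = c(30, 70))))
  expect_equal(h2$max_diff, 40)
  # three inner islands 10/50/90 -> max pairwise 80
  h3 <- swa_heterogeneity(outer, inner, mk_meth(list(T1 = c(10, 50, 90))))
  expect_equal(h3$max_diff, 80)
  expect_equal(h3$n_inner, 3L)
  # outer islands with < 2 inner islands are skipped
  h4 <- swa_heterogeneity(outer, inner[1, ], mk_meth(list(T1 = 10)))
  expect_equal(nrow(h4), 0L)
  expect_equal(attr(h4, "n_skipped"), 1L)
  g <- glance(h3)
  expect_equal(g$fraction_above_cutoff, 1)
})

test_that("island-pair rank test matches hand-derived exact cases", {
  same <- compare_island_pair(c(5, 7, 9), c(5, 7, 9))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  sep <- compare_island_pair(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$u, 0)
  expect_equal(sep$p_value, 0.1) # 2 of the 20 assignments are as extreme
  expect_false(sep$significant)

  big <- compare_island_pair(runif(30, 0, 10), runif(30, 50, 60))
  expect_true(big$significant)
  expect_lt(big$p_value, 1e-6)

  expect_error(compare_island_pair(numeric(0), 1:3),
               class = "cgiscan_insufficient_data")
})

test_that("exact rank-sum p-values match enumeration and wilcox.test", {
  set.seed(51)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    m <- sample(2:6, 1)
    a <- sample(1:20, n, replace = TRUE) # ties likely
    b <- sample(1:20, m, replace = TRUE)
    p <- compare_island_pair(a, b)$p_value
    expect_equal(p, enum_mw_pvalue(a, b), tolerance = 1e-9)
    if (!any(duplicated(c(a, b)))) {
      expect_equal(p, wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-9)
    }
  }
})

test_that("large-sample approximation agrees with the reference test", {
  set.seed(52)
  a <- rnorm(25, 50, 10)
  b <- rnorm(30, 55, 10)
  p <- compare_island_pair(a, b)$p_value
  ref <- wilcox.test(a, b, correct = TRUE, exact = FALSE)$p.value
  expect_equal(p, ref, tolerance = 1e-10)
})

test_that("planted methylation labels are recovered on simulated data", {
  cfg <- sim_config(genome_length = 3e5, n_islands = 20)
  sim <- simulate_genome(cfg, seed = 61)
  meth <- simulate_methylation(sim, cfg, seed = 62)
  states <- classify_cpgs(meth)
  # plantable truth islands with CpG counts from the sequence
  truth <- sim$truth
  truth$n_cpg <- vapply(seq_len(nrow(truth)), function(i) {
    length(scan_cpg_positions(substr(sim$genome$seq[1], truth$start[i] + 1,
                                     truth$end[i])))
  }, integer(1))
  called <- classify_islands(truth, states)
  ok <- called$state == truth$label
  expect_gte(mean(ok), 0.95)
})

test_that("cpg states partition the input", {
  cfg <- sim_config(genome_length = 1e5, n_islands = 5)
  sim <- simulate_genome(cfg, seed = 63)
  meth <- simulate_methylation(sim, cfg, seed = 64)
  states <- classify_cpgs(meth)
  expect_equal(nrow(states), length(scan_cpg_positions(sim$genome$seq[1])))
  expect_equal(anyDuplicated(states$position), 0L)
  expect_true(all(states$state %in% c("methylated", "unmethylated",
                                      "intermediate", "differential",
                                      "unclassified")))
})
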