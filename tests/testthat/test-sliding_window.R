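# deterministic qualifying sequence: repeating unit with known composition
unit_seq <- function(unit, n) strrep(unit, n)

test_that("window_meets_criteria applies the three thresholds jointly", {
  # 500-bp window with 150 C, 150 G, 30 CpG:
  # gc 60 >= 55; oe 30*500/(150*150) = 0.667 >= 0.65; minCpG 18.75 <= 30
  w <- paste0(strrep("G", 120), "A", strrep("CG", 30), "A", strrep("C", 120),
              strrep("T", 198))
  expect_equal(nchar(w), 500L)
  res <- window_meets_criteria(w, 0, 500)
  expect_equal(res$n_cpg, 30L)
  expect_equal(res$gc_percent, 60)
  expect_equal(res$oe_ratio, 30 * 500 / (150 * 150))
  expect_equal(res$min_cpg_required, 0.6 * 500 / 16)
  expect_true(res$qualifies)

  # all-AT window fails
  expect_false(window_meets_criteria(strrep("AT", 250), 0, 500)$qualifies)

  # high GC but O/E below threshold fails (single criterion suffices)
  w2 <- paste0(strrep("G", 150), "A", strrep("C", 150), strrep("T", 199))
  res2 <- window_meets_criteria(w2, 0, 500)
  expect_gte(res2$gc_percent, 55)
  expect_lt(res2$oe_ratio, 0.65)
  expect_false(res2$qualifies)

  expect_error(window_meets_criteria("ACGT", 0, 500),
               class = "cgiscan_bounds_error")
})

test_that("sequences shorter than the window yield no islands", {
  g <- tibble::tibble(chrom = "s", seq = rand_dna(400))
  expect_equal(nrow(tj_predict(g)), 0L)
})

test_that("a planted qualifying block is recovered near its true position", {
  set.seed(21)
  # 100 kb AT-rich background with one 1.2-kb block: unit CGCAT has
  # gc 60, O/E 2.5, CpG density 0.2 -- every window inside qualifies
  block <- unit_seq("CGCAT", 240)
  bg1 <- rand_dna(60000, probs = c(A = 0.5, T = 0.5))
  bg2 <- rand_dna(38800, probs = c(A = 0.5, T = 0.5))
  g <- tibble::tibble(chrom = "s", seq = paste0(bg1, block, bg2))
  isl <- tj_predict(g)
  expect_equal(nrow(isl), 1L)
  expect_lte(abs(isl$start - 60000), 2 * 500)
  expect_lte(abs(isl$end - 61200), 2 * 500)
  st <- window_meets_criteria(g$seq, isl$start, isl$length)
  expect_true(st$qualifies)
})

test_that("nearby islands merge when the merged segment still qualifies", {
  # two 600-bp CGCA blocks (gc 75, O/E ~2) separated by 140 bp of AT;
  # windows across the gap fail, but the merged 1340-bp segment qualifies
  blocks <- paste0(unit_seq("CGCA", 150), strrep("AT", 70), unit_seq("CGCA", 150))
  g <- tibble::tibble(chrom = "s",
                      seq = paste0(strrep("AT", 300), blocks, strrep("AT", 300)))
  merged <- tj_predict(g, tj_params(merge_gap = 150L))
  expect_equal(nrow(merged), 1L)
  expect_gte(merged$length, 1300)

  # same geometry with a leaner unit (CGCAT, gc 60): the merged segment
  # drops to ~53% GC, so the merge is rejected and two islands remain
  blocks2 <- paste0(unit_seq("CGCAT", 120), strrep("AT", 70), unit_seq("CGCAT", 120))
  g2 <- tibble::tibble(chrom = "s",
                       seq = paste0(strrep("AT", 300), blocks2, strrep("AT", 300)))
  split <- tj_predict(g2, tj_params(merge_gap = 150L))
  expect_equal(nrow(split), 2L)
})

test_that("no merging happens across an N run as long as the merge gap", {
  # CGATCG blocks are CG-bounded (gc 66.7, O/E 3), so the trimmed segments
  # end flush with the blocks and the gap is exactly the 100 planted Ns
  block <- unit_seq("CGATCG", 100)
  mk <- function(gap) tibble::tibble(
    chrom = "s",
    seq = paste0(strrep("AT", 300), block, gap, block, strrep("AT", 300))
  )
  # AT gap of the same length: merged segment qualifies -> one island
  isl_at <- tj_predict(mk(strrep("AT", 50)))
  expect_equal(nrow(isl_at), 1L)
  expect_gte(isl_at$length, 1300)
  # all-N gap of merge_gap length: merge is blocked -> two islands
  isl_n <- tj_predict(mk(strrep("N", 100)))
  expect_equal(nrow(isl_n), 2L)
})

test_that("every emitted island re-scores above all thresholds", {
  x <- shared_sim()
  tj <- x$tj
  expect_gt(nrow(tj), 0)
  p <- tj_params()
  for (i in seq_len(nrow(tj))) {
    st <- window_meets_criteria(x$sim$genome$seq[1], tj$start[i], tj$length[i],
                                params = p)
    expect_true(st$qualifies)
    expect_gte(tj$length[i], p$min_length)
    # ends on a CpG: starts with C of a CpG, ends with G of a CpG
    expect_equal(substr(x$sim$genome$seq[1], tj$start[i] + 1, tj$start[i] + 2), "CG")
    expect_equal(substr(x$sim$genome$seq[1], tj$end[i] - 1, tj$end[i]), "CG")
  }
})

test_that("islands are disjoint and separated by gaps or failed merges", {
  x <- shared_sim()
  tj <- x$tj
  p <- tj_params()
  ord <- order(tj$start)
  s <- tj$start[ord]; e <- tj$end[ord]
  expect_true(all(s[-1] >= e[-length(e)]))
  for (i in seq_len(length(s) - 1)) {
    gap <- s[i + 1] - e[i]
    if (gap <= p$merge_gap) {
      merged_ok <- window_meets_criteria(x$sim$genome$seq[1], s[i],
                                         e[i + 1] - s[i], params = p)$qualifies
      expect_false(merged_ok)
    }
  }
})

test_that("raising the GC threshold never increases total island bp", {
  sim <- simulate_genome(sim_config(genome_length = 3e5, n_islands = 15),
                         seed = 17)
  bp <- vapply(c(50, 55, 60, 65), function(gc) {
    isl <- tj_predict(sim$genome, tj_params(min_gc = gc))
    sum(isl$length)
  }, numeric(1))
  expect_true(all(diff(bp) <= 0))
})

test_that("qualifying planted blocks (CpG-bounded core) are all recovered", {
  x <- shared_sim()
  truth <- x$sim$truth
  seq1 <- x$sim$genome$seq[1]
  qual <- vapply(seq_len(nrow(truth)), function(i) {
    tj_block_qualifies(seq1, truth$start[i], truth$end[i])$qualifies
  }, logical(1))
  qt <- truth[qual, ]
  expect_gt(nrow(qt), 10)
  recovered <- vapply(seq_len(nrow(qt)), function(i) {
    any(x$tj$start < qt$end[i] & x$tj$end > qt$start[i])
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
})
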