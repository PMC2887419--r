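#' Configuration for the synthetic-data generators
#'
#' The defaults describe the simulated study conditions used throughout the
#' package tests: a 2-Mb chromosome carrying 100 planted CpG-dense islands
#' of mean length 500 bp against an AT-rich background. The background CpG
#' start rate (0.002) reflects the genome-wide CpG depletion of mammalian
#' DNA and the island rate (0.08) a typical CpG-island density; background
#' GC of 38% and island GC of 60% match bulk mammalian DNA and real CpG
#' islands. Methylation tracks use 12 tissues (the bisulfite-amplicon
#' resource the classification rules come from spans 12 tissues) with
#' unmethylated islands near 5-15%, methylated CpGs near 85-95% and Gaussian
#' noise of 5 percentage points; 20% of islands are differentially
#' methylated and 10% constitutively methylated. Expression uses a 73-tissue
#' healthy panel.
#'
#' @param genome_length Chromosome length in bp.
#' @param n_islands Number of planted islands.
#' @param island_length_mean,island_length_sd Island length distribution
#'   (bp, normal, floored at 100 bp).
#' @param min_island_gap Minimum bp between planted islands.
#' @param cpg_prob_background,cpg_prob_island Per-position CpG start
#'   probabilities (planted CpGs never overlap, so realised density is
#'   marginally lower).
#' @param gc_background,gc_island GC fraction of the filler sequence.
#' @param methylation_noise_sd Gaussian noise (percentage points) added to
#'   per-CpG, per-tissue methylation means.
#' @param tissue_count Number of tissues in the methylation track.
#' @param fraction_differential_islands,fraction_methylated_islands
#'   Fractions of planted islands with differential / constitutive
#'   methylation; the remainder are unmethylated.
#' @param support_min,support_max Clone-count range for well-supported
#'   methylation records.
#' @param support_low_fraction Fraction of records emitted with a single
#'   supporting clone, to exercise the clone filter.
#' @param expression_tissues Tissue-panel size for expression simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 2e6, n_islands = 100,
                       island_length_mean = 500, island_length_sd = 75,
                       min_island_gap = 2000,
                       cpg_prob_background = 0.002, cpg_prob_island = 0.08,
                       gc_background = 0.38, gc_island = 0.60,
                       methylation_noise_sd = 5, tissue_count = 12,
                       fraction_differential_islands = 0.2,
                       fraction_methylated_islands = 0.1,
                       support_min = 2, support_max = 10,
                       support_low_fraction = 0.05,
                       expression_tissues = 73) {
  stopifnot(
    genome_length > 0, n_islands >= 0, island_length_mean > 0,
    cpg_prob_background > 0, cpg_prob_island > cpg_prob_background,
    cpg_prob_island < 1,
    gc_background > 0, gc_background < 1, gc_island > 0, gc_island < 1,
    methylation_noise_sd >= 0, tissue_count >= 1,
    fraction_differential_islands >= 0, fraction_methylated_islands >= 0,
    fraction_differential_islands + fraction_methylated_islands <= 1,
    support_low_fraction >= 0, support_low_fraction < 1
  )
  structure(as.list(environment()), class = "sim_config")
}

sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate a chromosome with planted CpG islands
#'
#' The background is i.i.d. sequence with the configured GC fraction into
#' which CpG dinucleotides are injected by a Bernoulli process at the
#' background rate; planted island segments use the island GC fraction and
#' CpG rate. Accidental CG dimers arising in the filler are broken (the G is
#' replaced by an AT base) so that the realised CpG positions are exactly
#' the planted ones and inter-CpG distances follow the geometric null the
#' cluster p-value assumes. Islands are placed non-overlapping with at
#' least `min_island_gap` bp between them and receive planted methylation
#' labels. Deterministic for a fixed seed.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer RNG seed.
#' @return A list with `genome` (tibble `chrom`, `seq`, `length`), `truth`
#'   (tibble `chrom`, `start`, `end`, `label`) and `seed`.
#' @export
simulate_genome <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  L <- as.integer(config$genome_length)
  n_isl <- as.integer(config$n_islands)

  # island placement
  if (n_isl > 0) {
    len <- pmax(100L, as.integer(round(rnorm(n_isl, config$island_length_mean,
                                             config$island_length_sd))))
    gap <- as.integer(config$min_island_gap)
    slack <- L - sum(len) - (n_isl + 1L) * gap
    if (slack <= n_isl) {
      abort("islands do not fit in the genome; reduce n_islands or lengths",
            class = "cgiscan_bad_argument")
    }
    extra <- sort(sample.int(slack, n_isl))
    starts <- gap * seq_len(n_isl) + cumsum(c(0L, len[-n_isl])) + extra
    truth <- tibble(chrom = "sim1", start = as.integer(starts),
                    end = as.integer(starts + len))
  } else {
    truth <- tibble(chrom = character(0), start = integer(0), end = integer(0))
  }

  # filler sequence
  chars <- sample_bases(L, config$gc_background)
  in_island <- rep(FALSE, L)
  for (i in seq_len(nrow(truth))) {
    idx <- (truth$start[i] + 1L):truth$end[i]
    chars[idx] <- sample_bases(length(idx), config$gc_island)
    in_island[idx] <- TRUE
  }

  # CpG injection: Bernoulli per position, island rate inside islands;
  # a CG occupies two positions, so planted starts are >= 2 bp apart
  p <- ifelse(in_island[seq_len(L - 1L)], config$cpg_prob_island,
              config$cpg_prob_background)
  cand <- which(runif(L - 1L) < p) # 1-based start positions
  keep <- integer(0)
  last <- -2L
  for (i in cand) {
    if (i > last + 1L) {
      keep <- c(keep, i)
      last <- i
    }
  }
  chars[keep] <- "C"
  chars[keep + 1L] <- "G"

  # break accidental CG dimers formed by the filler
  seq1 <- paste(chars, collapse = "")
  all_cg <- scan_cpg_positions(seq1)
  accidental <- setdiff(all_cg, keep - 1L)
  if (length(accidental) > 0) {
    chars[accidental + 2L] <- sample(c("A", "T"), length(accidental),
                                     replace = TRUE)
    seq1 <- paste(chars, collapse = "")
  }

  if (nrow(truth) > 0) {
    labels <- c(
      rep("differential", round(config$fraction_differential_islands * n_isl)),
      rep("methylated", round(config$fraction_methylated_islands * n_isl))
    )
    labels <- c(labels, rep("unmethylated", n_isl - length(labels)))
    truth$label <- sample(labels)
  } else {
    truth$label <- character(0)
  }

  list(
    genome = tibble(chrom = "sim1", seq = seq1, length = L),
    truth = truth,
    seed = seed
  )
}

#' Simulate an amplicon-style methylation table with planted island states
#'
#' Every CpG of the genome receives one record per tissue. CpGs inside
#' unmethylated islands draw per-tissue means near 5-15%, CpGs in
#' methylated islands and in the background near 85-95%, and CpGs in
#' differential islands are low in the first half of the tissue panel and
#' high in the second; Gaussian noise is added and values clamped to
#' [0, 100]. Clone counts are sampled between `support_min` and
#' `support_max` except for a `support_low_fraction` of records that get a
#' single clone, exercising the clone filter downstream.
#'
#' @param sim Result of [simulate_genome()].
#' @param config A [sim_config()] object.
#' @param seed Integer RNG seed.
#' @return A tibble with columns `chrom`, `position`, `tissue`,
#'   `mean_methylation`, `n_support`, `source_type`.
#' @export
simulate_methylation <- function(sim, config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  pos <- scan_cpg_positions(sim$genome$seq[1])
  truth <- sim$truth
  label <- rep("background", length(pos))
  for (i in seq_len(nrow(truth))) {
    label[pos >= truth$start[i] & pos < truth$end[i]] <- truth$label[i]
  }
  n_t <- as.integer(config$tissue_count)
  tissues <- sprintf("T%02d", seq_len(n_t))
  low_tissues <- tissues[seq_len(ceiling(n_t / 2))]

  grid <- tidyr::expand_grid(
    position = pos,
    tissue = tissues
  )
  grid$label <- rep(label, each = n_t)
  low <- grid$label == "unmethylated" |
    (grid$label == "differential" & grid$tissue %in% low_tissues)
  base <- ifelse(low, runif(nrow(grid), 5, 15), runif(nrow(grid), 85, 95))
  value <- pmin(100, pmax(0, base + rnorm(nrow(grid), 0,
                                          config$methylation_noise_sd)))
  n_support <- ifelse(
    runif(nrow(grid)) < config$support_low_fraction,
    1L,
    sample(config$support_min:config$support_max, nrow(grid), replace = TRUE)
  )
  tibble(
    chrom = sim$genome$chrom[1],
    position = grid$position,
    tissue = grid$tissue,
    mean_methylation = value,
    n_support = as.integer(n_support),
    source_type = "amplicon"
  )
}

#' Simulate an expression table with planted coexpression classes
#'
#' Gene pairs sharing a (simulated) bidirectional promoter are planted in
#' three classes: coexpressed pairs share their expressed-tissue set
#' exactly, divergent pairs are expressed in complementary tissue sets, and
#' intermediate pairs agree in roughly 70% of tissues. Two reference genes
#' are always included: a housekeeping gene expressed in 71 of the 73
#' tissues and a tissue-specific gene expressed in 11.
#'
#' @param n_pairs Number of gene pairs.
#' @param config A [sim_config()] object.
#' @param seed Integer RNG seed.
#' @return A list with `expr` (tibble `gene`, `tissue`, `signal`), `pairs`
#'   (tibble `gene_a`, `gene_b`, `planted_class`) and `seed`.
#' @export
simulate_expression <- function(n_pairs = 30, config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n_t <- as.integer(config$expression_tissues)
  tissues <- sprintf("tissue%02d", seq_len(n_t))
  signal_for <- function(expressed) {
    ifelse(expressed, runif(n_t, 300, 3000), runif(n_t, 10, 150))
  }
  classes <- rep(c("coexpressed", "divergent", "intermediate"),
                 length.out = n_pairs)
  rows <- list()
  pair_rows <- list()
  for (i in seq_len(n_pairs)) {
    cls <- classes[i]
    ga <- sprintf("geneA_%03d", i)
    gb <- sprintf("geneB_%03d", i)
    ea <- rep(FALSE, n_t)
    ea[sample.int(n_t, sample(10:60, 1))] <- TRUE
    eb <- switch(cls,
      coexpressed = ea,
      divergent = !ea,
      intermediate = {
        flip <- sample.int(n_t, round(0.3 * n_t))
        out <- ea
        out[flip] <- !out[flip]
        out
      }
    )
    rows[[2 * i - 1]] <- tibble(gene = ga, tissue = tissues,
                                signal = signal_for(ea))
    rows[[2 * i]] <- tibble(gene = gb, tissue = tissues,
                            signal = signal_for(eb))
    pair_rows[[i]] <- tibble(gene_a = ga, gene_b = gb, planted_class = cls)
  }
  hk <- rep(TRUE, n_t)
  hk[sample.int(n_t, 2)] <- FALSE
  ts <- rep(FALSE, n_t)
  ts[sample.int(n_t, 11)] <- TRUE
  rows[[length(rows) + 1]] <- tibble(gene = "housekeeping_ref",
                                     tissue = tissues, signal = signal_for(hk))
  rows[[length(rows) + 1]] <- tibble(gene = "tissue_specific_ref",
                                     tissue = tissues, signal = signal_for(ts))
  list(
    expr = dplyr::bind_rows(rows),
    pairs = dplyr::bind_rows(pair_rows),
    seed = seed
  )
}
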