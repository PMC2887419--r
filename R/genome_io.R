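#' Read a (multi-record) FASTA file
#'
#' Reads genomic sequence into a tibble with one row per record. Sequences are
#' uppercased and any character outside `A`, `C`, `G`, `T`, `N` (e.g. IUPAC
#' ambiguity codes) is collapsed to `N`; CpGs are never called across an `N`.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `chrom` (first word of the header line),
#'   `seq` (uppercase DNA string) and `length` (bp).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTacgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "cgiscan_io_error")
  }
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      abort(paste0("not a valid FASTA file: ", path, " (", conditionMessage(e), ")"),
            class = "cgiscan_format_error")
    }
  )
  if (length(ss) == 0) {
    abort(paste0("FASTA file contains no records: ", path),
          class = "cgiscan_format_error")
  }
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0)) {
    bad <- names(ss)[nchar(seqs) == 0]
    abort(paste0("FASTA record with empty sequence: ", paste(bad, collapse = ", ")),
          class = "cgiscan_format_error")
  }
  seqs <- gsub("[^ACGTN]", "N", seqs)
  chrom <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(chrom))) {
    abort("FASTA record with empty name", class = "cgiscan_format_error")
  }
  seqs <- unname(seqs)
  tibble(chrom = unname(chrom), seq = seqs, length = nchar(seqs))
}

#' Positions of CpG dinucleotides in a sequence
#'
#' @param seq A single DNA string (uppercase).
#' @return Strictly increasing integer vector of 0-based start positions `i`
#'   such that `substr(seq, i + 1, i + 2) == "CG"`. Dimers containing `N`
#'   never match.
#' @examples
#' scan_cpg_positions("ACGT")  # 1
#' scan_cpg_positions("CGCG")  # 0 2
#' @export
scan_cpg_positions <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  n <- nchar(seq)
  if (n < 2L) return(integer(0))
  r <- charToRaw(seq)
  isC <- r == as.raw(67L) # "C"
  isG <- r == as.raw(71L) # "G"
  which(isC[-n] & isG[-1L]) - 1L
}

# Per-chromosome prefix sums used by window/segment scoring.
# Returns closures counting C, G and fully-contained CpG dimers on
# 0-based half-open [a, b).
seq_counters <- function(seq) {
  n <- nchar(seq)
  r <- charToRaw(seq)
  isC <- r == as.raw(67L)
  isG <- r == as.raw(71L)
  cC <- c(0, cumsum(isC))
  cG <- c(0, cumsum(isG))
  # cpg[i] == 1 iff a CpG starts at 0-based position i - 1 (i in 1..n-1)
  cpg <- if (n >= 2L) as.integer(isC[-n] & isG[-1L]) else integer(0)
  cCG <- c(0, cumsum(cpg))
  list(
    n = n,
    count_c = function(a, b) cC[b + 1L] - cC[a + 1L],
    count_g = function(a, b) cG[b + 1L] - cG[a + 1L],
    # CpG starts p with a <= p <= b - 2 (dimer fully inside [a, b));
    # cCG[b] - cCG[a + 1] is 0 whenever b == a + 1, so no guard is needed
    count_cpg = function(a, b) cCG[b] - cCG[a + 1L],
    cpg_starts = which(cpg == 1L) - 1L
  )
}

#' Read a BED file of genomic intervals
#'
#' Accepts BED3+ with 0-based half-open coordinates. Columns beyond the first
#' three are kept: columns 4-6 are named `name`, `score`, `strand` when
#' present, and any further columns keep positional names (`V7`, `V8`, ...).
#'
#' @param path Path to a tab-delimited BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and any extra
#'   columns present in the file.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("BED file not found: ", path), class = "cgiscan_io_error")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    abort(paste0("BED line ", which(ncol < 3L)[1], " has fewer than 3 columns"),
          class = "cgiscan_format_error")
  }
  k <- min(ncol)
  mat <- t(vapply(fields, function(f) f[seq_len(k)], character(k)))
  start <- suppressWarnings(as.numeric(mat[, 2]))
  end <- suppressWarnings(as.numeric(mat[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(paste0("invalid BED interval at line ", bad[1],
                 ": start must satisfy 0 <= start < end"),
          class = "cgiscan_format_error")
  }
  out <- tibble(chrom = mat[, 1], start = as.integer(start), end = as.integer(end))
  std <- c("name", "score", "strand")
  if (k > 3L) {
    for (j in 4:k) {
      nm <- if (j <= 6L) std[j - 3L] else paste0("V", j)
      val <- mat[, j]
      num <- suppressWarnings(as.numeric(val))
      out[[nm]] <- if (!anyNA(num)) num else val
    }
  }
  out
}

#' Write predicted islands as BED6+4
#'
#' Emits `chrom`, `start`, `end`, `name`, `score` (0), `strand` (`.`) plus the
#' extra columns `n_cpg`, `gc_percent`, `oe_ratio`, `p_value`. The p-value is
#' printed in scientific notation with 6 significant digits; islands without
#' a p-value (sliding-window predictions) print `.`.
#'
#' @param islands Island tibble as produced by [predict_islands()] or
#'   [tj_predict()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_islands_bed <- function(islands, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(islands)))
  n <- nrow(islands)
  src <- if ("source" %in% names(islands)) islands$source else rep("island", n)
  pv <- if ("p_value" %in% names(islands)) islands$p_value else rep(NA_real_, n)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t0\t.\t%d\t%.17g\t%.17g\t%s",
    islands$chrom, islands$start, islands$end,
    paste0(src, "_", seq_len(max(n, 0L))[seq_len(n)]),
    islands$n_cpg, islands$gc_percent, islands$oe_ratio,
    ifelse(is.na(pv), ".", sprintf("%.6e", pv))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read islands written by [write_islands_bed()]
#'
#' @param path Path to a BED6+4 island file.
#' @return An island tibble with the usual columns (`chrom`, `start`, `end`,
#'   `n_cpg`, `length`, `gc_percent`, `oe_ratio`, `cpg_density`, `p_value`,
#'   `source`).
#' @export
read_islands_bed <- function(path) {
  bed <- read_bed(path)
  need <- c("name", "V7", "V8", "V9", "V10")
  if (!all(need %in% names(bed))) {
    abort(paste0("not an island BED6+4 file: ", path), class = "cgiscan_format_error")
  }
  pv <- suppressWarnings(as.numeric(bed$V10))
  new_islands(tibble(
    chrom = bed$chrom, start = bed$start, end = bed$end,
    n_cpg = as.integer(bed$V7),
    length = bed$end - bed$start,
    gc_percent = as.numeric(bed$V8),
    oe_ratio = as.numeric(bed$V9),
    cpg_density = as.integer(bed$V7) / (bed$end - bed$start),
    p_value = pv,
    source = sub("_[0-9]+$", "", bed$name)
  ))
}

new_islands <- function(x) {
  class(x) <- unique(c("cgi_islands", class(tibble())))
  x
}

empty_islands <- function() {
  new_islands(tibble(
    chrom = character(0), start = integer(0), end = integer(0),
    n_cpg = integer(0), length = integer(0),
    gc_percent = numeric(0), oe_ratio = numeric(0), cpg_density = numeric(0),
    p_value = numeric(0), source = character(0)
  ))
}
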