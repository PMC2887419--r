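#' Parameters for expression breadth and coexpression analysis
#'
#' @param expressed_min_signal A gene counts as expressed in a tissue when
#'   its signal strictly exceeds this level (microarray signal units).
#' @param divergent_max Coexpression values at or below this are classed
#'   divergent.
#' @param coexpressed_value Coexpression value required for the coexpressed
#'   class (complete concordance).
#' @return A list of class `expression_params`.
#' @export
expression_params <- function(expressed_min_signal = 200,
                              divergent_max = 0.2,
                              coexpressed_value = 1.0) {
  stopifnot(expressed_min_signal > 0, divergent_max > 0, coexpressed_value > 0)
  structure(
    list(expressed_min_signal = expressed_min_signal,
         divergent_max = divergent_max,
         coexpressed_value = coexpressed_value),
    class = "expression_params"
  )
}

#' Expression breadth of a gene
#'
#' @param signals Per-tissue signal levels; `NA` tissues are excluded.
#' @param params An [expression_params()] object.
#' @return Fraction of tissues with signal above the expression cutoff.
#' @examples
#' expression_breadth(c(rep(1000, 71), rep(50, 2)))  # 0.973
#' @export
expression_breadth <- function(signals, params = expression_params()) {
  signals <- signals[!is.na(signals)]
  if (length(signals) == 0) {
    abort("no tissues with expression data", class = "cgiscan_insufficient_data")
  }
  mean(signals > params$expressed_min_signal)
}

#' Coexpression value of a gene pair
#'
#' The coexpression value is the fraction of tissues in which the two genes
#' are concordant: both expressed (signal above the cutoff) or both not
#' expressed, out of the tissues with data for both genes. A value of 1 is
#' complete coexpression; values at or below `divergent_max` indicate a
#' completely divergent pair.
#'
#' @param signals_a,signals_b Per-tissue signals on the same tissue panel
#'   (aligned by name when both are named, by position otherwise).
#' @param params An [expression_params()] object.
#' @return A one-row tibble with `value`, `n_tissues` and `class`
#'   (`"divergent"`, `"coexpressed"` or `"intermediate"`).
#' @export
coexpression_value <- function(signals_a, signals_b,
                               params = expression_params()) {
  if (!is.null(names(signals_a)) && !is.null(names(signals_b))) {
    if (!setequal(names(signals_a), names(signals_b))) {
      abort("the two genes must share the same tissue panel",
            class = "cgiscan_format_error")
    }
    signals_b <- signals_b[names(signals_a)]
  } else if (length(signals_a) != length(signals_b)) {
    abort("the two genes must share the same tissue panel",
          class = "cgiscan_format_error")
  }
  ok <- !is.na(signals_a) & !is.na(signals_b)
  if (!any(ok)) {
    abort("no tissues with expression data for both genes",
          class = "cgiscan_insufficient_data")
  }
  a <- signals_a[ok] > params$expressed_min_signal
  b <- signals_b[ok] > params$expressed_min_signal
  value <- mean(a == b)
  tibble(
    value = value,
    n_tissues = sum(ok),
    class = if (value <= params$divergent_max) "divergent"
            else if (value >= params$coexpressed_value) "coexpressed"
            else "intermediate"
  )
}

#' Coexpression of many gene pairs from a long expression table
#'
#' @param expr Long tibble with columns `gene`, `tissue`, `signal`.
#' @param pairs Tibble with columns `gene_a`, `gene_b`.
#' @param params An [expression_params()] object.
#' @return `pairs` with `value`, `n_tissues` and `class` appended.
#' @export
coexpression_table <- function(expr, pairs, params = expression_params()) {
  stopifnot(all(c("gene", "tissue", "signal") %in% names(expr)))
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  sig <- function(g) {
    sub <- expr[expr$gene == g, ]
    setNames(sub$signal, sub$tissue)
  }
  res <- purrr::map2_dfr(pairs$gene_a, pairs$gene_b, function(a, b) {
    coexpression_value(sig(a), sig(b), params)
  })
  dplyr::bind_cols(as_tibble(pairs), res)
}
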