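#' Events per position per generation
#'
#' The event rate of the palindrome process: number of events divided by
#' the generations spanned by the tree and the length of sequence
#' analysed (for an arm pair, twice the arm length). The quotient is
#' exact; printing rounds to three significant figures.
#'
#' @param n_events event count (>= 0).
#' @param generations generations spanned by all branches of the tree.
#' @param length_bp analysed sequence length, bp.
#' @return object of class `"rate_estimate"` with fields `n_events`,
#'   `generations`, `length_bp`, `rate`.
#' @examples
#' estimate_rate(416, 12265, 2.8e6)   # gene-conversion rate
#' estimate_rate(603, 12265, 2.8e6)   # palindrome mutation rate
#' @export
estimate_rate <- function(n_events, generations, length_bp) {
  check_scalar(n_events, "n_events", min = 0)
  check_scalar(generations, "generations")
  check_scalar(length_bp, "length_bp")
  if (generations <= 0 || length_bp <= 0)
    stop("generations and length_bp must be positive", call. = FALSE)
  structure(list(n_events = n_events, generations = generations,
                 length_bp = length_bp,
                 rate = n_events / (generations * length_bp)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%g events / (%g generations x %g bp) = %.3g per position per generation\n",
              x$n_events, x$generations, x$length_bp, signif(x$rate, 3)))
  invisible(x)
}

#' Chi-square goodness-of-fit test of two counts against 1:1
#'
#' One-degree-of-freedom goodness-of-fit test of two observed counts
#' against equal expectation, without continuity correction; the p-value
#' is the upper tail of the chi-square distribution. Used for every bias
#' contrast: conversion polarity, conversion GC direction and mutation
#' GC direction.
#'
#' @param count_a,count_b non-negative observed counts (not both zero).
#' @return object of class `"chisq_bias"` with `observed`, `expected`,
#'   `statistic` and `p_value`.
#' @examples
#' chi_square_gof(100, 171)   # ancestral-bias contrast
#' chi_square_gof(259, 158)   # GC-bias contrast
#' @export
chi_square_gof <- function(count_a, count_b) {
  check_scalar(count_a, "count_a", min = 0)
  check_scalar(count_b, "count_b", min = 0)
  if (count_a + count_b == 0)
    stop("both counts are zero", call. = FALSE)
  ct <- suppressWarnings(chisq.test(c(count_a, count_b), p = c(0.5, 0.5),
                                    correct = FALSE))
  structure(list(observed = c(count_a, count_b),
                 expected = rep((count_a + count_b) / 2, 2),
                 statistic = unname(ct$statistic),
                 p_value = ct$p.value),
            class = "chisq_bias")
}

#' @export
print.chisq_bias <- function(x, ...) {
  cat(sprintf("counts %g vs %g: chi-square = %.4g (1 df), p = %.3g\n",
              x$observed[1], x$observed[2], x$statistic, x$p_value))
  invisible(x)
}

bias_table <- function(counts, test = TRUE) {
  total <- sum(counts)
  pct <- if (total > 0) round(100 * counts / total) else counts * NA
  res <- list(counts = counts, pct = pct, statistic = NA_real_,
              p_value = NA_real_)
  if (test && total >= 2 && all(!is.na(counts))) {
    cs <- chi_square_gof(counts[1], counts[2])
    res$statistic <- cs$statistic
    res$p_value <- cs$p_value
  }
  res
}

#' Summarise conversion and mutation biases
#'
#' Tabulates and chi-square-tests the directional biases of a classified
#' event list: conversion polarity (ancestral-to-derived vs
#' derived-to-ancestral), conversion GC direction, mutation GC direction
#' (all mutations and the private-only subset), and - reported without a
#' significance claim - the polarity of GC-neutral conversions.
#' Percentages are rounded to the nearest integer; a table with fewer
#' than two events skips its test.
#'
#' @param events classified events (from [classify_events()],
#'   [pal_events()] or [truth_to_events()]).
#' @return object of class `"bias_report"`: a list of tables, each with
#'   `counts`, `pct`, `statistic`, `p_value`.
#' @export
summarize_biases <- function(events) {
  if (is.null(events) || nrow(events) == 0L) {
    warning("no events to summarise", call. = FALSE)
    return(structure(list(), class = "bias_report"))
  }
  conv <- events[events$kind == "conversion", , drop = FALSE]
  mut <- events[events$kind == "mutation", , drop = FALSE]
  cnt <- function(x, lv) vapply(lv, function(l) sum(x == l, na.rm = TRUE), 0)

  rep_ <- list(
    conversion_polarity =
      bias_table(cnt(conv$polarity, c(anc_to_der = "anc_to_der",
                                      der_to_anc = "der_to_anc"))),
    conversion_gc =
      bias_table(cnt(conv$gc_direction, c(to_GC = "to_GC", to_AT = "to_AT"))),
    mutation_gc =
      bias_table(cnt(mut$gc_direction, c(to_AT = "to_AT", to_GC = "to_GC"))),
    mutation_gc_private =
      bias_table(cnt(mut$gc_direction[mut$privacy == "private"],
                     c(to_AT = "to_AT", to_GC = "to_GC"))),
    gc_neutral_polarity =
      bias_table(cnt(conv$polarity[conv$gc_direction == "neutral"],
                     c(der_to_anc = "der_to_anc", anc_to_der = "anc_to_der")),
                 test = FALSE)
  )
  rep_$n_conversions <- nrow(conv)
  rep_$n_mutations <- nrow(mut)
  rep_$n_ambiguous_polarity <- sum(conv$polarity == "ambiguous", na.rm = TRUE)
  structure(rep_, class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  if (!length(x)) {
    cat("empty bias report\n")
    return(invisible(x))
  }
  show <- function(name, tab) {
    cat(sprintf("  %s: %s", name,
                paste(sprintf("%s %g (%g%%)", names(tab$counts), tab$counts,
                              tab$pct), collapse = ", ")))
    if (!is.na(tab$p_value))
      cat(sprintf("; chi-square p = %.3g", tab$p_value))
    cat("\n")
  }
  cat("Bias summary\n")
  show("conversion polarity", x$conversion_polarity)
  cat(sprintf("    (+ %d conversions with ambiguous polarity)\n",
              x$n_ambiguous_polarity))
  show("conversion GC direction", x$conversion_gc)
  show("mutation GC direction", x$mutation_gc)
  show("  private mutations only", x$mutation_gc_private)
  show("GC-neutral conversion polarity", x$gc_neutral_polarity)
  invisible(x)
}
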