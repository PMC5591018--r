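#' Infer palindrome mutation and gene-conversion events on a phylogeny
#'
#' The package's central fitting function. Given pseudo-diploid
#' palindrome-arm genotypes and a rooted sample phylogeny it (i) masks
#' genotypes outside the depth window, (ii) reconstructs ancestral
#' pseudo-diploid states with the bottom-up/top-down Fitch passes,
#' (iii) calls one event per (branch, site) state change - a mutation
#' where a homozygous parent yields a heterozygous child, a gene
#' conversion where a heterozygous parent yields a homozygous child -
#' (iv) classifies every event by GC direction, substitution class,
#' conversion polarity against the ancestral allele and privacy, and
#' (v) turns the counts into per-position per-generation rates and
#' chi-square bias tests.
#'
#' @param geno a [pseudo_geno()] matrix, or directly a `"pal_sim"`
#'   object from [simulate_palindrome()] (then `tree`,
#'   `outgroup_states`, `families` and `length_bp` default to the
#'   simulation's own).
#' @param tree rooted binary `phylo` whose tips are samples of `geno`;
#'   branch lengths, when present, are generations.
#' @param outgroup_states optional per-site outgroup genotypes (vector
#'   or matrix, states `HOM_REF`/`HET`/`HOM_ALT`/`MISSING`); without
#'   them the root is resolved by the fixed preference order and
#'   conversion polarity degrades to `ambiguous`.
#' @param families optional data frame (`sample`, `family`) for the
#'   private/common split.
#' @param min_depth,max_depth inclusive depth window applied when the
#'   matrix carries depths (see [depth_filter()]).
#' @param apply_depth_filter set `FALSE` to skip depth masking.
#' @param generations generations spanned by the tree; defaults to the
#'   sum of branch lengths.
#' @param length_bp analysed arm-pair length (2 x arm length) for rate
#'   estimation; rates are omitted when unknown.
#' @return an object of class `"pal_events"` with components `events`
#'   (the classified calls), `counts`, `rates` (mutation and conversion
#'   [estimate_rate()] objects), `biases` (a [summarize_biases()]
#'   report), `generations`, `length_bp`, `n_sites` and `tree`. Methods:
#'   `print`, `summary`, `coef` (the two rates), `plot`.
#' @examples
#' p <- sim_params(n_samples = 8, n_families = 2, arm_length_bp = 1e5,
#'                 het0_density = 1e-3, seed = 7)
#' sim <- simulate_palindrome(simulate_tree(p), p, seed = 8)
#' fit <- pal_events(sim)
#' fit
#' coef(fit)
#' @export
pal_events <- function(geno, tree = NULL, outgroup_states = NULL,
                       families = NULL, min_depth = 50, max_depth = 250,
                       apply_depth_filter = TRUE, generations = NULL,
                       length_bp = NULL) {
  if (inherits(geno, "pal_sim")) {
    sim <- geno
    geno <- sim$geno
    if (is.null(tree)) tree <- sim$tree
    if (is.null(outgroup_states)) outgroup_states <- sim$root_gt
    if (is.null(families)) families <- attr(sim$tree, "families")
    if (is.null(length_bp)) length_bp <- 2 * sim$params$arm_length_bp
  }
  stopifnot(inherits(geno, "pseudo_geno"), inherits(tree, "phylo"))
  if (apply_depth_filter && !is.null(geno$dp))
    geno <- depth_filter(geno, min_depth, max_depth)
  assign <- resolve_top_down(fitch_bottom_up(tree, geno), outgroup_states)
  calls <- call_events(assign)
  events <- classify_events(calls, assign, families)
  if (is.null(generations) && !is.null(tree$edge.length))
    generations <- sum(tree$edge.length)

  counts <- list(
    n_mutation = sum(events$kind == "mutation"),
    n_conversion = sum(events$kind == "conversion"),
    n_complex = sum(events$kind == "complex"),
    n_event_sites = length(unique(events$site)),
    n_unpolarizable = attr(calls, "n_unpolarizable"))
  rates <- NULL
  if (!is.null(generations) && !is.null(length_bp) && generations > 0)
    rates <- list(
      mutation = estimate_rate(counts$n_mutation, generations, length_bp),
      conversion = estimate_rate(counts$n_conversion, generations, length_bp))
  biases <- if (nrow(events)) summarize_biases(events) else
    suppressWarnings(summarize_biases(events))

  structure(list(events = events, counts = counts, rates = rates,
                 biases = biases, generations = generations,
                 length_bp = length_bp, n_sites = ncol(geno$gt),
                 tree = tree, assign = assign, call = match.call()),
            class = "pal_events")
}

#' @export
print.pal_events <- function(x, ...) {
  cat("Palindrome event inference\n")
  cat(sprintf("  %d samples, %d sites\n", length(x$tree$tip.label), x$n_sites))
  cat(sprintf("  %d mutations, %d gene conversions, %d complex changes in %d positions\n",
              x$counts$n_mutation, x$counts$n_conversion, x$counts$n_complex,
              x$counts$n_event_sites))
  if (x$counts$n_unpolarizable > 0)
    cat(sprintf("  (%d root-branch changes unpolarizable without outgroup)\n",
                x$counts$n_unpolarizable))
  if (!is.null(x$rates)) {
    cat(sprintf("  mutation rate:   %.3g per position per generation\n",
                signif(x$rates$mutation$rate, 3)))
    cat(sprintf("  conversion rate: %.3g per position per generation\n",
                signif(x$rates$conversion$rate, 3)))
    cat(sprintf("  (over %.0f generations and %g bp)\n", x$generations,
                x$length_bp))
  }
  invisible(x)
}

#' @export
summary.pal_events <- function(object, ...) {
  structure(list(fit = object), class = "summary.pal_events")
}

#' @export
print.summary.pal_events <- function(x, ...) {
  print(x$fit)
  if (length(x$fit$biases)) print(x$fit$biases)
  invisible(x)
}

#' @export
coef.pal_events <- function(object, ...) {
  if (is.null(object$rates))
    return(c(mutation_rate = NA_real_, conversion_rate = NA_real_))
  c(mutation_rate = object$rates$mutation$rate,
    conversion_rate = object$rates$conversion$rate)
}

#' @export
plot.pal_events <- function(x, ...) {
  ev <- x$events[x$events$kind %in% c("mutation", "conversion"), ]
  if (!nrow(ev)) {
    warning("no events to plot", call. = FALSE)
    return(invisible(x))
  }
  tab <- table(factor(ev$gc_direction, c("to_AT", "neutral", "to_GC")),
               factor(ev$kind, c("mutation", "conversion")))
  op <- par(no.readonly = TRUE)
  on.exit(par(op))
  barplot(tab, beside = TRUE, col = c("#d95f02", "grey70", "#1b9e77"),
          ylab = "events", main = "Event spectrum by GC direction", ...)
  legend("topright", rownames(tab), fill = c("#d95f02", "grey70", "#1b9e77"),
         bty = "n")
  invisible(x)
}
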