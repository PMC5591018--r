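#' Simulation parameters for the palindrome forward model
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' cohort like the one the inference machinery targets: a tree spanning
#' 12265 generations in total branch length, haploid X-degenerate SNVs at
#' 3.14e-8 per position per generation (PPPG), palindrome arm-pair
#' mutations at 1.76e-8 PPPG with an AT bias of 56:44, gene conversions at
#' 1.21e-8 PPPG with a GC bias of 259/417 (~62:38) and an ancestral bias
#' of 171/271 (~63:37), and ~60X coverage over two-copy arms (30X per
#' sequence copy).
#'
#' Palindrome rates are quoted per arm-pair position with the arm pair
#' counted at twice the arm length, matching how rates are estimated from
#' called events (events / (generations x 2 x arm length)).
#'
#' @param n_samples number of samples (leaves of the tree).
#' @param n_families number of father-son pairs; each becomes a cherry
#'   whose two terminal branches are one generation long.
#' @param total_generations total branch length of the tree, generations.
#' @param mu_xdeg haploid SNV rate, PPPG.
#' @param mu_pal palindrome arm-pair mutation rate, PPPG (positions counted
#'   as 2 x `arm_length_bp`).
#' @param gamma gene-conversion rate, PPPG (same position convention).
#' @param b_at probability a new mutation creates an A or T allele.
#' @param b_gc probability a conversion at a GC-vs-AT heterozygous site
#'   resolves to the G/C allele.
#' @param b_anc probability a conversion resolves toward the ancestral
#'   allele, applied jointly with `b_gc` (see Details).
#' @param arm_length_bp length of one palindrome arm, bp.
#' @param xdeg_length_bp callable X-degenerate length, bp.
#' @param depth_per_copy expected read depth per sequence copy.
#' @param het0_density standing pseudo-heterozygous density at the root,
#'   per arm-pair position. Real palindrome arms are >99.9% but not 100%
#'   identical, so the root carries a pool of arm differences; without it
#'   early conversions would have no heterozygous target.
#' @param seed integer seed; `NULL` leaves the RNG stream untouched.
#'
#' @details At a heterozygous site with alleles `x` and `y` the conversion
#' survivor is drawn with probability proportional to
#' `w_gc(x) * w_anc(x)`, where `w_gc` is `b_gc` for a G/C allele and
#' `1 - b_gc` for an A/T allele when the two alleles differ in GC class
#' (1 otherwise), and `w_anc` is `b_anc` for the ancestral allele and
#' `1 - b_anc` for the derived one. The factorised form reproduces both
#' marginal biases.
#'
#' @return an object of class `"sim_params"` (a validated list).
#' @examples
#' p <- sim_params(n_samples = 8, n_families = 2, seed = 1)
#' p$mu_pal
#' @export
sim_params <- function(n_samples = 62,
                       n_families = 17,
                       total_generations = 12265,
                       mu_xdeg = 3.14e-8,
                       mu_pal = 1.76e-8,
                       gamma = 1.21e-8,
                       b_at = 0.56,
                       b_gc = 259 / 417,
                       b_anc = 171 / 271,
                       arm_length_bp = 1.4e6,
                       xdeg_length_bp = 8.1e6,
                       depth_per_copy = 30,
                       het0_density = 1e-4,
                       seed = NULL) {
  check_scalar(n_samples, "n_samples", min = 2, integer = TRUE)
  check_scalar(n_families, "n_families", min = 0, integer = TRUE)
  if (n_families > n_samples / 2)
    stop("'n_families' must be at most n_samples/2", call. = FALSE)
  check_scalar(total_generations, "total_generations", min = 1)
  for (r in c("mu_xdeg", "mu_pal", "gamma", "het0_density"))
    check_scalar(get(r), r, min = 0)
  for (p in c("b_at", "b_gc", "b_anc"))
    check_scalar(get(p), p, min = 0, max = 1)
  check_scalar(arm_length_bp, "arm_length_bp", min = 1)
  check_scalar(xdeg_length_bp, "xdeg_length_bp", min = 1)
  check_scalar(depth_per_copy, "depth_per_copy", min = 0)
  if (!is.null(seed)) check_scalar(seed, "seed", integer = TRUE)
  structure(list(
    n_samples = as.integer(n_samples),
    n_families = as.integer(n_families),
    total_generations = total_generations,
    mu_xdeg = mu_xdeg, mu_pal = mu_pal, gamma = gamma,
    b_at = b_at, b_gc = b_gc, b_anc = b_anc,
    arm_length_bp = as.integer(arm_length_bp),
    xdeg_length_bp = as.integer(xdeg_length_bp),
    depth_per_copy = depth_per_copy,
    het0_density = het0_density,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Palindrome simulation parameters\n")
  cat(sprintf("  samples: %d (%d father-son families)\n", x$n_samples, x$n_families))
  cat(sprintf("  tree span: %s generations (total branch length)\n",
              format(x$total_generations)))
  cat(sprintf("  rates PPPG: SNV %.3g, palindrome mutation %.3g, conversion %.3g\n",
              x$mu_xdeg, x$mu_pal, x$gamma))
  cat(sprintf("  biases: AT mutation %.2f, GC conversion %.3f, ancestral %.3f\n",
              x$b_at, x$b_gc, x$b_anc))
  cat(sprintf("  lengths: arm %s bp, X-degenerate %s bp; depth/copy %g\n",
              format(x$arm_length_bp), format(x$xdeg_length_bp), x$depth_per_copy))
  invisible(x)
}
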