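#' Pairwise substitution-count distances from a haploid SNV matrix
#'
#' Distance between two samples is the number of sites where both are
#' called and carry different alleles (number-of-substitutions model with
#' pairwise deletion of missing data).
#'
#' @param mat character matrix, samples x sites, alleles in A/C/G/T with
#'   `NA` (or `"N"`/`"-"`) for missing.
#' @param allow_undefined if `TRUE`, a pair with no jointly-called site
#'   gets `NA` instead of an error.
#' @return symmetric numeric matrix of substitution counts.
#' @examples
#' m <- rbind(s1 = c("A", "C", "G", "T"), s2 = c("A", "C", "G", "A"))
#' snv_distance(m)["s1", "s2"]
#' @export
snv_distance <- function(mat, allow_undefined = FALSE) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2L) stop("need at least two samples", call. = FALSE)
  mat[mat %in% c("N", "-", "")] <- NA
  n <- nrow(mat)
  labs <- rownames(mat)
  if (is.null(labs)) labs <- paste0("S", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    xi <- mat[i, ]
    for (j in (i + 1L):n) {
      xj <- mat[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      d <- if (any(ok)) sum(xi[ok] != xj[ok]) else NA_real_
      D[i, j] <- D[j, i] <- d
    }
  }
  if (any(is.na(D)) && !allow_undefined)
    stop("some sample pairs share no called sites; ",
         "set allow_undefined = TRUE to keep NA distances", call. = FALSE)
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining on substitution-count distances, rooted on
#' the outgroup edge when an outgroup is named, otherwise by midpoint.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param outgroup optional tip label(s) to root on.
#' @return rooted `phylo`.
#' @export
nj_tree <- function(d, outgroup = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (any(is.na(d))) stop("undefined distances in the matrix", call. = FALSE)
  tr <- ape::nj(stats::as.dist(d))
  if (!is.null(outgroup)) {
    if (!all(outgroup %in% tr$tip.label))
      stop("outgroup not among the taxa", call. = FALSE)
    ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  } else {
    phangorn::midpoint(tr)
  }
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples sites with replacement, rebuilds the NJ tree per replicate
#' and reports, for every internal node, the percentage of replicates
#' containing its bipartition.
#'
#' @param mat haploid SNV matrix as in [snv_distance()].
#' @param n_reps number of bootstrap replicates.
#' @param seed optional integer seed.
#' @param outgroup optional rooting outgroup for the reference tree.
#' @return the reference tree with supports (0-100) in `node.label`.
#' @export
bootstrap_support <- function(mat, n_reps = 500, seed = NULL, outgroup = NULL) {
  check_scalar(n_reps, "n_reps", min = 1, integer = TRUE)
  base <- ape::nj(stats::as.dist(snv_distance(mat)))
  if (!is.null(seed)) set.seed(seed)
  counts <- ape::boot.phylo(base, mat,
                            function(m) ape::nj(stats::as.dist(snv_distance(m))),
                            B = n_reps, quiet = TRUE, rooted = FALSE)
  base$node.label <- round(100 * counts / n_reps)
  if (!is.null(outgroup)) {
    if (!all(outgroup %in% base$tip.label))
      stop("outgroup not among the taxa", call. = FALSE)
    ape::root(base, outgroup = outgroup, resolve.root = TRUE, edgelabel = TRUE)
  } else {
    phangorn::midpoint(base, node.labels = "support")
  }
}

#' Calibrate the generations spanned by the tree
#'
#' Converts a count of non-recurrent X-degenerate SNVs into the total
#' number of generations spanned by all branches of the phylogeny:
#' `generations = n_snvs / (mu * callable_bp)`. Downstream rate
#' estimates divide event counts by this span.
#'
#' @param n_snvs number of non-recurrent SNVs placed on the tree.
#' @param mu haploid SNV mutation rate, per position per generation.
#' @param callable_bp callable X-degenerate length in bp.
#' @return generations (real, unrounded).
#' @examples
#' calibrate_generations(3126, 3.14e-8, 8.1e6)
#' @export
calibrate_generations <- function(n_snvs, mu, callable_bp) {
  check_scalar(n_snvs, "n_snvs", min = 0)
  check_scalar(mu, "mu")
  check_scalar(callable_bp, "callable_bp")
  if (mu <= 0 || callable_bp <= 0)
    stop("mu and callable_bp must be positive", call. = FALSE)
  n_snvs / (mu * callable_bp)
}

#' Flag SNV sites whose carriers do not form a clade
#'
#' A site is non-recurrent when the set of samples carrying its derived
#' (minor, if unpolarized) allele is a clade of the tree; recurrent or
#' back-mutated sites violate this and are excluded from generation
#' calibration. Missing entries disqualify no site: the carrier set is
#' taken over called samples only.
#'
#' @param mat haploid SNV matrix.
#' @param tree rooted `phylo` over the samples.
#' @return logical vector per site, `TRUE` when the carrier set is a
#'   clade (site usable for calibration).
#' @export
nonrecurrent_sites <- function(mat, tree) {
  stopifnot(is.matrix(mat), inherits(tree, "phylo"))
  clades <- c(lapply(seq_along(tree$tip.label), function(i) i),
              phangorn::Descendants(tree, length(tree$tip.label) +
                                      seq_len(tree$Nnode), type = "tips"))
  clade_keys <- vapply(clades, function(x) paste(sort(x), collapse = ","), "")
  apply(mat, 2, function(col) {
    col <- col[tree$tip.label]
    tab <- table(col[!is.na(col)])
    if (length(tab) != 2L) return(length(tab) == 1L)
    carrier <- names(tab)[which.min(tab)]
    idx <- which(!is.na(col) & col == carrier)
    paste(sort(idx), collapse = ",") %in% clade_keys
  })
}

#' Select calibration sites by an iterative clade filter
#'
#' Builds an NJ tree from all sites, flags sites whose carriers are not a
#' clade on it, rebuilds the tree once from the clean sites and re-flags.
#' The surviving sites are the non-recurrent set used for generation
#' calibration.
#'
#' @inheritParams nonrecurrent_sites
#' @param outgroup optional rooting outgroup.
#' @return list with `keep` (logical per site) and `tree` (the rebuilt
#'   rooted tree).
#' @export
calibration_sites <- function(mat, outgroup = NULL) {
  tr <- nj_tree(snv_distance(mat), outgroup = outgroup)
  keep <- nonrecurrent_sites(mat, tr)
  tr2 <- nj_tree(snv_distance(mat[, keep, drop = FALSE]), outgroup = outgroup)
  keep2 <- keep
  keep2[keep] <- nonrecurrent_sites(mat[, keep, drop = FALSE], tr2)
  list(keep = keep2, tree = tr2)
}
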