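#' Per-position coverage track
#'
#' @param depth non-negative numeric vector of per-position read depths.
#' @param start 1-based start coordinate of the track.
#' @param sample,region optional identifiers.
#' @return object of class `"coverage_track"`.
#' @export
coverage_track <- function(depth, start = 1L, sample = NA_character_,
                           region = NA_character_) {
  depth <- as.numeric(depth)
  if (any(depth < 0, na.rm = TRUE)) stop("depths must be >= 0", call. = FALSE)
  check_scalar(start, "start", min = 1, integer = TRUE)
  structure(list(depth = depth, start = as.integer(start),
                 end = as.integer(start) + length(depth) - 1L,
                 sample = sample, region = region),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("Coverage track %s:%s [%d-%d], median depth %g\n",
              x$sample, x$region, x$start, x$end, median(x$depth)))
  invisible(x)
}

as_depth <- function(x) {
  if (inherits(x, "coverage_track")) x$depth else as.numeric(x)
}

#' Copy number from normalised median coverage
#'
#' A gene's copy number is estimated as the median of its per-position
#' read depth divided by the median depth of a single-copy X-degenerate
#' reference region; because the reference is single-copy, the ratio is
#' the copy number, rounded half-up to an integer.
#'
#' @param gene_track coverage over the gene ([coverage_track()] or
#'   numeric vector).
#' @param reference_track coverage over the single-copy reference region.
#' @return list with `normalized_coverage` (real) and `copy_number`
#'   (integer).
#' @examples
#' estimate_copy_number(rep(90, 100), rep(30, 100))
#' @export
estimate_copy_number <- function(gene_track, reference_track) {
  g <- as_depth(gene_track)
  r <- as_depth(reference_track)
  mr <- median(r, na.rm = TRUE)
  if (!is.finite(mr) || mr <= 0)
    stop("reference region median depth must be positive", call. = FALSE)
  norm <- median(g, na.rm = TRUE) / mr
  list(normalized_coverage = norm,
       copy_number = as.integer(round_half_up(norm)))
}

#' Father-son copy-number concordance
#'
#' A (pair, gene) is concordant when the father's and son's normalised
#' coverages differ by less than `threshold` (strictly; a difference of
#' exactly 0.5 is discordant). The rate is reported as a percentage to
#' one decimal.
#'
#' @param table data frame with columns `sample`, `gene`,
#'   `normalized_coverage`.
#' @param pairs data frame with columns `father`, `son`.
#' @param threshold concordance threshold on normalised coverage.
#' @return object of class `"cn_concordance"`: `rate_pct`, `n_total`,
#'   `n_discordant` and the `discordant` pair-gene table.
#' @export
cn_concordance <- function(table, pairs, threshold = 0.5) {
  stopifnot(all(c("sample", "gene", "normalized_coverage") %in% names(table)),
            all(c("father", "son") %in% names(pairs)))
  rows <- list()
  n_total <- 0L
  for (i in seq_len(nrow(pairs))) {
    f <- table[table$sample == pairs$father[i], ]
    s <- table[table$sample == pairs$son[i], ]
    genes <- union(f$gene, s$gene)
    for (g in genes) {
      nf <- f$normalized_coverage[f$gene == g]
      ns <- s$normalized_coverage[s$gene == g]
      if (length(nf) != 1L || length(ns) != 1L || is.na(nf) || is.na(ns)) {
        warning(sprintf("pair %s/%s gene %s: member missing, skipped",
                        pairs$father[i], pairs$son[i], g), call. = FALSE)
        next
      }
      n_total <- n_total + 1L
      if (abs(nf - ns) >= threshold)
        rows[[length(rows) + 1L]] <-
          data.frame(father = pairs$father[i], son = pairs$son[i], gene = g,
                     father_norm = nf, son_norm = ns)
    }
  }
  disc <- if (length(rows)) do.call(rbind, rows) else
    data.frame(father = character(0), son = character(0), gene = character(0),
               father_norm = numeric(0), son_norm = numeric(0))
  structure(list(rate_pct = round(100 * (n_total - nrow(disc)) / n_total, 1),
                 n_total = n_total, n_discordant = nrow(disc),
                 discordant = disc),
            class = "cn_concordance")
}

#' @export
print.cn_concordance <- function(x, ...) {
  cat(sprintf("Copy-number concordance: %.1f%% (%d of %d pair-genes; %d discordant)\n",
              x$rate_pct, x$n_total - x$n_discordant, x$n_total, x$n_discordant))
  invisible(x)
}

# minimum number of unit-cost state changes explaining leaf states on a
# rooted binary tree (Fitch set count)
fitch_change_count <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree))
    stop("tree must be binary", call. = FALSE)
  states <- states[tree$tip.label]
  if (any(is.na(states)))
    stop("every leaf needs a state", call. = FALSE)
  lv <- sort(unique(states))
  ntip <- length(tree$tip.label)
  sets <- matrix(FALSE, ntip + tree$Nnode, length(lv))
  sets[cbind(seq_len(ntip), match(states, lv))] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2], po$edge[, 1])
  changes <- 0L
  for (p in unique(po$edge[, 1])) {
    ch <- kids[[as.character(p)]]
    A <- sets[ch[1], ]
    O <- A
    for (k in ch[-1]) {
      A <- A & sets[k, ]
      O <- O | sets[k, ]
    }
    if (any(A)) sets[p, ] <- A
    else {
      sets[p, ] <- O
      changes <- changes + 1L
    }
  }
  changes
}

#' Collapse copy numbers toward their group baseline
#'
#' The conservative rule for high-copy genes (such as the TSPY array,
#' where depth cannot resolve single-copy differences): values within
#' one copy of the group's rounded mean are replaced by that mean, so
#' only changes of more than one copy from the group baseline survive.
#'
#' @param values numeric copy numbers, named by sample.
#' @param groups grouping factor (for example haplogroup), same names.
#' @return collapsed integer copy numbers.
#' @export
collapse_to_baseline <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  out <- round_half_up(values)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    m <- round_half_up(mean(values[idx]))
    close <- idx[abs(out[idx] - m) <= 1]
    out[close] <- m
  }
  out
}

#' Count copy-number changes on the phylogeny
#'
#' Minimum number of integer copy-number changes on the tree explaining
#' the leaf values (small parsimony with unbounded integer states and
#' unit cost per change). With `groups` given, leaf values are first
#' collapsed toward the group baseline via [collapse_to_baseline()] -
#' the conservative rule for high-copy genes.
#'
#' @param tree rooted binary `phylo`.
#' @param cn either a named integer vector of copy numbers per leaf, or
#'   a data frame with columns `sample`, `gene`, `copy_number` (then
#'   `gene` selects the rows).
#' @param gene gene name when `cn` is a table.
#' @param groups optional named grouping vector enabling the collapse
#'   rule.
#' @return integer change count.
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
#' count_cn_changes(tr, c(a = 2, b = 2, c = 2, d = 3))
#' @export
count_cn_changes <- function(tree, cn, gene = NULL, groups = NULL) {
  if (is.data.frame(cn)) {
    stopifnot(all(c("sample", "gene", "copy_number") %in% names(cn)))
    if (is.null(gene)) stop("specify the gene", call. = FALSE)
    cn <- cn[cn$gene == gene, ]
    if (nrow(cn) == 0L) stop("gene not in the table: ", gene, call. = FALSE)
    cn <- setNames(cn$copy_number, cn$sample)
  }
  if (!is.null(groups))
    cn <- collapse_to_baseline(cn, groups[names(cn)])
  fitch_change_count(tree, cn)
}

#' Segment a coverage track into copy-number levels
#'
#' Computes the median depth in non-overlapping windows, divides by the
#' single-copy baseline depth and merges consecutive windows whose
#' rounded ratio agrees into segments - the way an arm loss shows up as
#' a long stretch at half coverage and a duplication at 1.5x.
#'
#' @param track [coverage_track()] or numeric depth vector.
#' @param baseline_depth expected single-copy depth (> 0).
#' @param window_bp window size, bp; a track shorter than one window
#'   yields a single whole-track segment.
#' @return data frame: `start`, `end` (1-based inclusive, in track
#'   coordinates), `ratio` (mean window ratio) and `copy_number`.
#' @export
detect_segment_cnv <- function(track, baseline_depth, window_bp = 5000) {
  check_scalar(baseline_depth, "baseline_depth")
  if (baseline_depth <= 0) stop("baseline_depth must be positive", call. = FALSE)
  check_scalar(window_bp, "window_bp", min = 1, integer = TRUE)
  d <- as_depth(track)
  offset <- if (inherits(track, "coverage_track")) track$start - 1L else 0L
  n <- length(d)
  starts <- seq(1L, n, by = window_bp)
  ends <- pmin(starts + window_bp - 1L, n)
  ratio <- vapply(seq_along(starts),
                  function(i) median(d[starts[i]:ends[i]]) / baseline_depth, 0)
  cn <- round_half_up(ratio)
  r <- rle(cn)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  data.frame(
    start = starts[idx_start] + offset,
    end = ends[idx_end] + offset,
    ratio = vapply(seq_along(idx_start), function(i)
      mean(ratio[idx_start[i]:idx_end[i]]), 0),
    copy_number = as.integer(r$values))
}
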