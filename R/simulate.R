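BASES <- c("A", "C", "G", "T")

# draw derived alleles: the new allele is A/T with probability b_at, else G/C,
# and always differs from `from`
mutate_base <- function(from, b_at) {
  n <- length(from)
  if (n == 0L) return(character(0))
  to_at <- runif(n) < b_at
  vapply(seq_len(n), function(i) {
    cand <- setdiff(if (to_at[i]) c("A", "T") else c("G", "C"), from[i])
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }, character(1))
}

#' Simulate a sample phylogeny with father-son cherries
#'
#' Generates a rooted binary tree whose leaves are the cohort samples.
#' Each father-son family is a cherry whose two terminal branches are one
#' generation long (father and son sit one meiosis from their common
#' ancestor); above the family level the topology is a random coalescent
#' tree. Branch lengths are in generations and are rescaled so that the
#' total branch length of the tree equals `params$total_generations` - the
#' span that calibrated rate estimates divide by.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed (defaults to `params$seed`); `NULL` uses the
#'   current RNG state.
#' @return an `ape` `phylo` object with branch lengths in generations.
#'   Fathers are labelled `famXX-01`, sons `famXX-03`, unrelated samples
#'   `indXX`. A `data.frame` mapping samples to families is attached as
#'   attribute `"families"`.
#' @examples
#' tr <- simulate_tree(sim_params(n_samples = 6, n_families = 2, seed = 1))
#' sum(tr$edge.length)
#' @export
simulate_tree <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  S <- params$n_samples
  nf <- params$n_families
  G <- params$total_generations
  fam_ids <- sprintf("fam%02d", seq_len(nf))
  singles <- if (S - 2L * nf > 0L) sprintf("ind%02d", seq_len(S - 2L * nf)) else character(0)
  units <- c(fam_ids, singles)

  if (length(units) == 1L) {
    # a single family: the whole tree is one cherry
    tr <- ape::read.tree(text = sprintf("(%s-01:1,%s-03:1);", fam_ids, fam_ids))
  } else {
    inner <- G - 2 * nf
    if (inner <= 0)
      stop("total_generations too small for the family cherries", call. = FALSE)
    base <- ape::rcoal(length(units), tip.label = units)
    base$edge.length <- base$edge.length * (inner / sum(base$edge.length))
    txt <- ape::write.tree(base, digits = 12)
    for (f in fam_ids)
      txt <- sub(paste0(f, ":"), sprintf("(%s-01:1,%s-03:1):", f, f),
                 txt, fixed = TRUE)
    tr <- ape::read.tree(text = txt)
  }
  fams <- data.frame(
    sample = tr$tip.label,
    family = ifelse(grepl("^fam", tr$tip.label),
                    sub("-.*$", "", tr$tip.label), tr$tip.label),
    stringsAsFactors = FALSE
  )
  attr(tr, "families") <- fams
  tr
}

#' Simulate haploid X-degenerate SNVs on a phylogeny
#'
#' Places SNVs on the tree under an infinite-sites model: each branch
#' receives `Poisson(mu_xdeg * xdeg_length_bp * generations)` mutations,
#' every mutation hits a fresh position, and all leaves descending from
#' the branch carry the derived allele. This is the calibration substrate
#' for [calibrate_generations()] and the input for [snv_distance()] /
#' [nj_tree()].
#'
#' @param tree rooted `phylo` with branch lengths in generations.
#' @param params a [sim_params()] object.
#' @param seed optional integer seed.
#' @return a list of class `"xdeg_sim"` with elements `matrix` (character
#'   matrix, samples x sites, colnames = 1-based positions), `truth`
#'   (data frame of the placed mutations), `tree` and `params`.
#' @examples
#' p <- sim_params(n_samples = 4, n_families = 0, xdeg_length_bp = 1e5, seed = 2)
#' sim <- simulate_xdeg_snvs(simulate_tree(p), p, seed = 3)
#' dim(sim$matrix)
#' @export
simulate_xdeg_snvs <- function(tree, params, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "sim_params"))
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths in generations", call. = FALSE)
  if (params$xdeg_length_bp < 1L)
    stop("xdeg_length_bp must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  L <- params$xdeg_length_bp
  ne <- nrow(tree$edge)
  counts <- rpois(ne, params$mu_xdeg * L * tree$edge.length)
  N <- sum(counts)
  if (N > L)
    stop("more mutations than sites: increase xdeg_length_bp", call. = FALSE)
  tips <- tree$tip.label
  if (N == 0L) {
    mat <- matrix(character(0), nrow = length(tips), ncol = 0,
                  dimnames = list(tips, NULL))
    truth <- data.frame(branch = integer(0), site = integer(0),
                        kind = character(0), from = character(0),
                        to = character(0), anc = character(0))
    return(structure(list(matrix = mat, truth = truth, tree = tree,
                          params = params), class = "xdeg_sim"))
  }
  pos <- sample.int(L, N)           # infinite sites: all distinct
  edge_of <- rep(seq_len(ne), counts)
  anc <- sample(BASES, N, replace = TRUE)
  der <- mutate_base(anc, params$b_at)

  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  mat <- matrix(rep(anc, each = length(tips)), nrow = length(tips),
                dimnames = list(tips, pos))
  for (i in seq_len(N)) {
    carriers <- desc[[edge_of[i]]]
    mat[carriers, i] <- der[i]
  }
  ord <- order(pos)
  mat <- mat[, ord, drop = FALSE]
  truth <- data.frame(branch = tree$edge[edge_of, 2], site = pos,
                      kind = "mutation", from = anc, to = der, anc = anc,
                      stringsAsFactors = FALSE)[ord, ]
  rownames(truth) <- NULL
  structure(list(matrix = mat, truth = truth, tree = tree, params = params),
            class = "xdeg_sim")
}

# survivor choice at a heterozygous site {anc, der}:
# P(survivor = x) proportional to w_gc(x) * w_anc(x)
prob_anc_survives <- function(anc, der, b_gc, b_anc) {
  wa <- b_anc
  wd <- 1 - b_anc
  if (is_gc(anc) != is_gc(der)) {
    wa <- wa * if (is_gc(anc)) b_gc else 1 - b_gc
    wd <- wd * if (is_gc(der)) b_gc else 1 - b_gc
  }
  wa / (wa + wd)
}

#' Simulate pseudo-diploid palindrome-arm genotypes with an event truth log
#'
#' Forward-simulates a palindrome arm pair along a phylogeny. The root
#' starts homozygous everywhere except for a standing pool of
#' pseudo-heterozygous arm differences (`het0_density` per arm position;
#' real arms are >99.9% but not 100% identical). Along every branch,
#' arm-pair mutations arrive at rate `mu_pal * 2 * arm_length_bp` per
#' generation and flip one arm base at a fresh position, creating a
#' pseudo-heterozygous site; gene-conversion events arrive at rate
#' `gamma * 2 * arm_length_bp` per generation, pick a currently
#' heterozygous site uniformly and resolve it to one allele, the survivor
#' drawn with the factorised GC/ancestral bias of [sim_params()]. A
#' conversion drawn while no site is heterozygous is discarded (counted in
#' `n_discarded`). Events within a branch occur at sampled times, so a
#' conversion can only target a site that is heterozygous at that moment.
#'
#' Sites stay biallelic over their whole history: a mutation re-hitting
#' any previously touched position is redrawn.
#'
#' @inheritParams simulate_xdeg_snvs
#' @return a list of class `"pal_sim"`: `geno` (a [pseudo_geno()] matrix
#'   with depths drawn as `Poisson(2 * depth_per_copy)`), `truth` (data
#'   frame: `branch` = child node of the edge carrying the event, `site`,
#'   `kind`, `from`, `to`, `anc`, `time` = generations from the root),
#'   `root_gt` (the root's genotype per emitted site, usable as outgroup
#'   states), `tree`, `params`, `n_discarded`.
#' @examples
#' p <- sim_params(n_samples = 4, n_families = 0, arm_length_bp = 1e5, seed = 5)
#' sim <- simulate_palindrome(simulate_tree(p), p, seed = 6)
#' head(sim$truth)
#' @export
simulate_palindrome <- function(tree, params, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "sim_params"))
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths in generations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  L <- params$arm_length_bp
  if (L < 1L) stop("arm_length_bp must be >= 1", call. = FALSE)
  rate_mut <- params$mu_pal * 2 * L
  rate_conv <- params$gamma * 2 * L

  # site registry: every position that ever segregates, with its allele pair
  reg <- new.env(parent = emptyenv())
  reg$site <- integer(0)
  reg$ref <- character(0)     # root (ancestral) allele
  reg$alt <- character(0)     # derived allele
  reg$ev <- vector("list", 256L)
  reg$nev <- 0L
  reg$discarded <- 0L

  register_site <- function(s, ref, alt) {
    reg$site <- c(reg$site, s)
    reg$ref <- c(reg$ref, ref)
    reg$alt <- c(reg$alt, alt)
    length(reg$site)
  }
  log_event <- function(child, site, kind, from, to, anc, time) {
    reg$nev <- reg$nev + 1L
    if (reg$nev > length(reg$ev)) reg$ev <- c(reg$ev, vector("list", length(reg$ev)))
    reg$ev[[reg$nev]] <- list(branch = child, site = site, kind = kind,
                              from = from, to = to, anc = anc, time = time)
  }

  # standing arm differences at the root
  n0 <- rpois(1L, params$het0_density * L)
  if (n0 > L) stop("het0_density too high for arm_length_bp", call. = FALSE)
  if (n0 > 0L) {
    s0 <- sample.int(L, n0)
    r0 <- sample(BASES, n0, replace = TRUE)
    a0 <- mutate_base(r0, params$b_at)
    for (i in seq_len(n0)) register_site(s0[i], r0[i], a0[i])
  }
  root_state <- list(het = seq_len(n0), hom_idx = integer(0), hom_base = character(0))

  evolve <- function(state, len, child, t0) {
    t <- 0
    total <- rate_mut + rate_conv
    if (total <= 0) return(state)
    while (TRUE) {
      t <- t + rexp(1L, total)
      if (t > len) break
      if (runif(1L) < rate_mut / total) {
        repeat {
          s <- sample.int(L, 1L)
          if (!(s %in% reg$site)) break
        }
        from <- sample(BASES, 1L)
        to <- mutate_base(from, params$b_at)
        idx <- register_site(s, from, to)
        state$het <- c(state$het, idx)
        log_event(child, s, "mutation", from, to, from, t0 + t)
      } else {
        if (length(state$het) == 0L) {
          reg$discarded <- reg$discarded + 1L
          next
        }
        k <- state$het[sample.int(length(state$het), 1L)]
        anc <- reg$ref[k]
        der <- reg$alt[k]
        surv <- if (runif(1L) < prob_anc_survives(anc, der, params$b_gc, params$b_anc))
          anc else der
        lost <- if (surv == anc) der else anc
        state$het <- state$het[state$het != k]
        state$hom_idx <- c(state$hom_idx, k)
        state$hom_base <- c(state$hom_base, surv)
        log_event(child, reg$site[k], "conversion", lost, surv, anc, t0 + t)
      }
    }
    state
  }

  ntip <- length(tree$tip.label)
  leaf_states <- vector("list", ntip)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  recurse <- function(node, state, t0) {
    for (e in kids[[as.character(node)]]) {
      child <- tree$edge[e, 2]
      st <- evolve(state, tree$edge.length[e], child, t0)
      if (child <= ntip) leaf_states[[child]] <<- st
      else recurse(child, st, t0 + tree$edge.length[e])
    }
  }
  recurse(ntip + 1L, root_state, 0)

  ns <- length(reg$site)
  ord <- order(reg$site)
  sites <- data.frame(pos = reg$site[ord], ref = reg$ref[ord],
                      alt = reg$alt[ord], stringsAsFactors = FALSE)
  col_of <- integer(ns)            # registry index -> matrix column
  col_of[ord] <- seq_len(ns)

  gt <- matrix("HOM_REF", nrow = ntip, ncol = ns,
               dimnames = list(tree$tip.label, sites$pos))
  for (i in seq_len(ntip)) {
    st <- leaf_states[[i]]
    if (length(st$het)) gt[i, col_of[st$het]] <- "HET"
    if (length(st$hom_idx))
      gt[i, col_of[st$hom_idx]] <-
        ifelse(st$hom_base == reg$ref[st$hom_idx], "HOM_REF", "HOM_ALT")
  }
  root_gt <- rep("HOM_REF", ns)
  if (n0 > 0L) root_gt[col_of[seq_len(n0)]] <- "HET"
  dp <- matrix(rpois(ntip * ns, 2 * params$depth_per_copy), nrow = ntip,
               dimnames = dimnames(gt))

  truth <- if (reg$nev > 0L) {
    ev <- reg$ev[seq_len(reg$nev)]
    data.frame(branch = vapply(ev, `[[`, 0, "branch"),
               site = vapply(ev, `[[`, 0, "site"),
               kind = vapply(ev, `[[`, "", "kind"),
               from = vapply(ev, `[[`, "", "from"),
               to = vapply(ev, `[[`, "", "to"),
               anc = vapply(ev, `[[`, "", "anc"),
               time = vapply(ev, `[[`, 0, "time"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(branch = integer(0), site = integer(0), kind = character(0),
               from = character(0), to = character(0), anc = character(0),
               time = numeric(0))
  }
  structure(list(geno = pseudo_geno(sites, gt, dp), truth = truth,
                 root_gt = root_gt, tree = tree, params = params,
                 n_discarded = reg$discarded),
            class = "pal_sim")
}

#' Simulate per-position read-depth tracks
#'
#' Draws per-position depth as `Poisson(depth_per_copy * copy_number)`
#' for each (sample, region) of a copy-number specification - the
#' coverage model behind depth-based copy-number estimation, where a
#' two-copy arm pair at 30X per copy reads ~60X and a three-copy segment
#' ~90X.
#'
#' @param cn_spec data frame with columns `sample`, `region`, `start`,
#'   `end` (1-based inclusive) and `copy_number` (non-negative integers).
#' @param params a [sim_params()] object (supplies `depth_per_copy`).
#' @param seed optional integer seed.
#' @return a named list (`"sample:region"`) of [coverage_track()] objects.
#' @examples
#' spec <- data.frame(sample = "s1", region = "arm", start = 1, end = 1000,
#'                    copy_number = 2)
#' tr <- simulate_depth(spec, sim_params(seed = 1), seed = 1)
#' mean(tr[["s1:arm"]]$depth)
#' @export
simulate_depth <- function(cn_spec, params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  need <- c("sample", "region", "start", "end", "copy_number")
  if (!all(need %in% names(cn_spec)))
    stop("cn_spec needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(cn_spec$copy_number < 0))
    stop("copy numbers must be non-negative", call. = FALSE)
  if (any(cn_spec$copy_number != floor(cn_spec$copy_number)))
    stop("copy numbers must be integers", call. = FALSE)
  if (any(cn_spec$end < cn_spec$start))
    stop("region end before start", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nrow(cn_spec))
  for (i in seq_len(nrow(cn_spec))) {
    n <- cn_spec$end[i] - cn_spec$start[i] + 1L
    out[[i]] <- coverage_track(
      rpois(n, params$depth_per_copy * cn_spec$copy_number[i]),
      start = cn_spec$start[i],
      sample = cn_spec$sample[i], region = cn_spec$region[i])
  }
  names(out) <- paste(cn_spec$sample, cn_spec$region, sep = ":")
  out
}

#' Convert a simulation truth log into classified event calls
#'
#' Recasts the ground-truth log of [simulate_palindrome()] in the same
#' shape as the calls produced by [pal_events()], with direction labels
#' (`gc_direction`, `substitution_class`, `polarity`, `privacy`) computed
#' from the logged alleles. Useful for calibration checks: running
#' [summarize_biases()] on the truth recovers the generator's bias
#' parameters without going through inference.
#'
#' @param sim a `"pal_sim"` object.
#' @param families optional data frame (`sample`, `family`); defaults to
#'   the family map attached to the simulated tree.
#' @return a data frame of classified events.
#' @export
truth_to_events <- function(sim, families = attr(sim$tree, "families")) {
  stopifnot(inherits(sim, "pal_sim"))
  tr <- sim$truth
  if (nrow(tr) == 0L)
    return(data.frame(site = integer(0), child_node = integer(0),
                      kind = character(0), from = character(0),
                      to = character(0), gc_direction = character(0),
                      substitution_class = character(0),
                      polarity = character(0), privacy = character(0)))
  pol <- ifelse(tr$kind != "conversion", NA_character_,
                ifelse(tr$to == tr$anc, "der_to_anc", "anc_to_der"))
  data.frame(
    site = tr$site, child_node = tr$branch, kind = tr$kind,
    from = tr$from, to = tr$to,
    gc_direction = gc_direction_of(tr$from, tr$to),
    substitution_class = substitution_class_of(tr$from, tr$to),
    polarity = pol,
    privacy = privacy_of(sim$tree, tr$branch, families),
    stringsAsFactors = FALSE)
}
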