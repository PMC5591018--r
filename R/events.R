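# bit codes for pseudo-diploid genotype state sets
GT_BIT <- c(HOM_REF = 1L, HET = 2L, HOM_ALT = 4L, MISSING = 7L)
BIT_GT <- c(`1` = "HOM_REF", `2` = "HET", `4` = "HOM_ALT")

lowest_state_bit <- function(m) {
  # tie-break preference HOM_REF > HET > HOM_ALT
  ifelse(bitwAnd(m, 1L) > 0L, 1L, ifelse(bitwAnd(m, 2L) > 0L, 2L, 4L))
}

#' Pseudo-diploid palindrome genotype matrix
#'
#' Container for collapsed palindrome-arm genotypes: each position of one
#' arm is treated as a diploid locus whose two "alleles" are the bases on
#' the two arms, so an arm difference appears as a heterozygote.
#'
#' @param sites data frame with columns `pos` (1-based arm position),
#'   `ref`, `alt` (the two segregating bases).
#' @param gt character matrix (samples x sites) with entries `HOM_REF`,
#'   `HET`, `HOM_ALT` or `MISSING`.
#' @param dp optional numeric matrix of read depths, same shape as `gt`.
#' @return an object of class `"pseudo_geno"`.
#' @export
pseudo_geno <- function(sites, gt, dp = NULL) {
  stopifnot(is.data.frame(sites), all(c("pos", "ref", "alt") %in% names(sites)),
            is.matrix(gt), ncol(gt) == nrow(sites))
  bad <- !(gt %in% c(names(GT_BIT)))
  if (any(bad)) stop("invalid genotype codes: ",
                     paste(unique(gt[bad]), collapse = ", "), call. = FALSE)
  if (!is.null(dp)) {
    stopifnot(is.matrix(dp), all(dim(dp) == dim(gt)))
    if (any(dp < 0, na.rm = TRUE)) stop("depths must be >= 0", call. = FALSE)
  }
  if (is.null(rownames(gt))) stop("gt must have sample rownames", call. = FALSE)
  structure(list(sites = sites, gt = gt, dp = dp), class = "pseudo_geno")
}

#' @export
print.pseudo_geno <- function(x, ...) {
  cat(sprintf("Pseudo-diploid genotypes: %d samples x %d sites\n",
              nrow(x$gt), ncol(x$gt)))
  if (ncol(x$gt)) {
    tab <- table(factor(x$gt, levels = names(GT_BIT)))
    cat("  ", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Mask genotypes outside a depth-of-coverage window
#'
#' Sets the genotype to `MISSING` wherever the per-sample read depth
#' falls outside `[min_depth, max_depth]` (bounds inclusive). Collapsed
#' palindrome arms should carry roughly twice the single-copy depth, so
#' positions far from that expectation are unreliable: too shallow means
#' one arm is absent or diverged, too deep means extra copies attract
#' reads.
#'
#' @param geno a [pseudo_geno()] object with depths.
#' @param min_depth,max_depth inclusive depth bounds.
#' @return the filtered [pseudo_geno()] object.
#' @examples
#' sites <- data.frame(pos = 1, ref = "A", alt = "G")
#' g <- pseudo_geno(sites, matrix("HET", 1, 1, dimnames = list("s1", NULL)),
#'                  matrix(49, 1, 1))
#' depth_filter(g)$gt
#' @export
depth_filter <- function(geno, min_depth = 50, max_depth = 250) {
  stopifnot(inherits(geno, "pseudo_geno"))
  if (min_depth > max_depth)
    stop("min_depth must not exceed max_depth", call. = FALSE)
  if (is.null(geno$dp)) stop("no depths present in the matrix", call. = FALSE)
  drop <- geno$dp < min_depth | geno$dp > max_depth
  drop[is.na(drop)] <- TRUE
  geno$gt[drop] <- "MISSING"
  geno
}

#' Bottom-up Fitch state sets for pseudo-diploid genotypes
#'
#' First pass of the ancestral reconstruction: walking the tree from the
#' leaves, each internal node receives the intersection of its children's
#' state sets when non-empty, otherwise their union. Leaves contribute
#' the singleton of their observed state; a `MISSING` leaf contributes
#' the full state universe and so never forces a change.
#'
#' @param tree rooted binary `phylo`; its tips must all be samples of
#'   `geno`.
#' @param geno a [pseudo_geno()] object.
#' @return an object of class `"pal_assign"` holding the per-node,
#'   per-site state sets; finish it with [resolve_top_down()].
#' @export
fitch_bottom_up <- function(tree, geno) {
  stopifnot(inherits(tree, "phylo"), inherits(geno, "pseudo_geno"))
  missing_tips <- setdiff(tree$tip.label, rownames(geno$gt))
  if (length(missing_tips))
    stop("tree tips absent from genotype matrix: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
  ntip <- length(tree$tip.label)
  ns <- ncol(geno$gt)
  S <- matrix(0L, nrow = ntip + tree$Nnode, ncol = ns)
  S[seq_len(ntip), ] <- GT_BIT[geno$gt[tree$tip.label, , drop = FALSE]]
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2], po$edge[, 1])
  for (p in unique(po$edge[, 1])) {        # parents appear in postorder
    ch <- kids[[as.character(p)]]
    A <- S[ch[1], ]
    O <- A
    for (k in ch[-1]) {
      A <- bitwAnd(A, S[k, ])
      O <- bitwOr(O, S[k, ])
    }
    S[p, ] <- ifelse(A > 0L, A, O)
  }
  structure(list(tree = tree, geno = geno, sets = S, resolved = NULL),
            class = "pal_assign")
}

# consensus of one or more per-site outgroup state vectors: the most
# frequent non-missing state, NA on ties or all-missing
outgroup_consensus <- function(outgroup_states, ns) {
  if (is.null(outgroup_states)) return(rep(NA_character_, ns))
  m <- if (is.matrix(outgroup_states)) outgroup_states
       else matrix(outgroup_states, nrow = 1)
  if (ncol(m) != ns)
    stop("outgroup states must cover every site", call. = FALSE)
  apply(m, 2, function(col) {
    col <- col[!is.na(col) & col != "MISSING"]
    if (!length(col)) return(NA_character_)
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) NA_character_ else names(tab)[1]
  })
}

#' Top-down resolution of ancestral pseudo-diploid states
#'
#' Second pass of the reconstruction. The root takes the outgroup
#' consensus state when that state lies in its Fitch set, otherwise the
#' first state in the fixed preference order `HOM_REF > HET > HOM_ALT`;
#' every other node takes its parent's resolved state when that state is
#' in its own set, else the preference order again. The per-site
#' ancestral allele is the allele of the resolved root state when the
#' root is homozygous, else the outgroup's homozygous allele when one is
#' available, else unknown (which downgrades conversion polarity to
#' `ambiguous`).
#'
#' @param assign a `"pal_assign"` from [fitch_bottom_up()].
#' @param outgroup_states optional character vector (or matrix, one row
#'   per outgroup) of per-site outgroup states in
#'   `HOM_REF`/`HET`/`HOM_ALT`/`MISSING`/`NA`.
#' @return the `"pal_assign"` with resolved states, per-site ancestral
#'   alleles and a per-site flag saying whether the outgroup fixed the
#'   root.
#' @export
resolve_top_down <- function(assign, outgroup_states = NULL) {
  stopifnot(inherits(assign, "pal_assign"))
  tree <- assign$tree
  S <- assign$sets
  ntip <- length(tree$tip.label)
  ns <- ncol(S)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  og <- outgroup_consensus(outgroup_states, ns)
  ogc <- unname(GT_BIT[og])

  R <- matrix(0L, nrow = nrow(S), ncol = ns)
  use_og <- !is.na(ogc) & bitwAnd(S[root, ], ogc) > 0L
  R[root, ] <- ifelse(use_og, ogc, lowest_state_bit(S[root, ]))
  pr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pr$edge))) {
    p <- pr$edge[e, 1]
    ch <- pr$edge[e, 2]
    keep <- bitwAnd(S[ch, ], R[p, ]) > 0L
    R[ch, ] <- ifelse(keep, R[p, ], lowest_state_bit(S[ch, ]))
  }

  ref <- assign$geno$sites$ref
  alt <- assign$geno$sites$alt
  anc <- rep(NA_character_, ns)
  anc[R[root, ] == 1L] <- ref[R[root, ] == 1L]
  anc[R[root, ] == 4L] <- alt[R[root, ] == 4L]
  het_root <- R[root, ] == 2L
  anc[het_root & !is.na(og) & og == "HOM_REF"] <- ref[het_root & !is.na(og) & og == "HOM_REF"]
  anc[het_root & !is.na(og) & og == "HOM_ALT"] <- alt[het_root & !is.na(og) & og == "HOM_ALT"]

  assign$resolved <- R
  assign$anc_allele <- anc
  assign$root_by_outgroup <- use_og
  assign$outgroup <- og
  assign
}

#' Call mutation and gene-conversion events on the tree
#'
#' Emits one event per (branch, site) where the resolved parent and child
#' states differ: a homozygous parent with a heterozygous child is a
#' mutation (an arm difference is born), a heterozygous parent with a
#' homozygous child is a gene conversion (an arm difference is erased),
#' and the rare homozygous-to-opposite-homozygous change is labelled
#' `complex` and excluded from rate tallies. Events on the root's two
#' branches are only callable where the outgroup fixed the root state;
#' elsewhere they are suppressed and counted as unpolarizable.
#'
#' @param assign a resolved `"pal_assign"` (see [resolve_top_down()]).
#' @param suppress_root set to `FALSE` to keep root-branch events even
#'   where no outgroup resolved the root (used when comparing change
#'   counts against plain parsimony).
#' @return data frame of events ordered by site then preorder branch,
#'   with attributes `n_unpolarizable` (suppressed root-branch events)
#'   and `n_changes` (all state changes before suppression).
#' @export
call_events <- function(assign, suppress_root = TRUE) {
  stopifnot(inherits(assign, "pal_assign"))
  if (is.null(assign$resolved))
    stop("run resolve_top_down() before calling events", call. = FALSE)
  tree <- assign$tree
  R <- assign$resolved
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  pr <- ape::reorder.phylo(tree, "cladewise")
  rows <- vector("list", nrow(pr$edge))
  for (e in seq_len(nrow(pr$edge))) {
    p <- pr$edge[e, 1]
    ch <- pr$edge[e, 2]
    hit <- which(R[p, ] != R[ch, ])
    if (length(hit))
      rows[[e]] <- data.frame(site_index = hit, parent_node = p,
                              child_node = ch, edge_order = e,
                              parent_code = R[p, hit], child_code = R[ch, hit])
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev))
    ev <- data.frame(site_index = integer(0), parent_node = integer(0),
                     child_node = integer(0), edge_order = integer(0),
                     parent_code = integer(0), child_code = integer(0))
  n_changes <- nrow(ev)
  n_unpol <- 0L
  if (suppress_root && nrow(ev)) {
    bad <- ev$parent_node == root & !assign$root_by_outgroup[ev$site_index]
    n_unpol <- sum(bad)
    ev <- ev[!bad, , drop = FALSE]
  }
  ev <- ev[order(ev$site_index, ev$edge_order), , drop = FALSE]
  out <- data.frame(
    site = assign$geno$sites$pos[ev$site_index],
    site_index = ev$site_index,
    parent_node = ev$parent_node,
    child_node = ev$child_node,
    parent_state = BIT_GT[as.character(ev$parent_code)],
    child_state = BIT_GT[as.character(ev$child_code)],
    stringsAsFactors = FALSE)
  out$kind <- ifelse(out$parent_state != "HET" & out$child_state == "HET",
                     "mutation",
                     ifelse(out$parent_state == "HET" & out$child_state != "HET",
                            "conversion", "complex"))
  rownames(out) <- NULL
  attr(out, "n_unpolarizable") <- n_unpol
  attr(out, "n_changes") <- n_changes
  out
}

gc_direction_of <- function(from, to) {
  ifelse(is_gc(to) & !is_gc(from), "to_GC",
         ifelse(!is_gc(to) & is_gc(from), "to_AT", "neutral"))
}

substitution_class_of <- function(from, to) {
  pur <- c("A", "G")
  ifelse((from %in% pur) == (to %in% pur), "transition", "transversion")
}

# private iff all leaves below the event branch belong to one individual
# or one father-son family
privacy_of <- function(tree, child_nodes, families = NULL) {
  fam <- setNames(tree$tip.label, tree$tip.label)
  if (!is.null(families)) {
    stopifnot(all(c("sample", "family") %in% names(families)))
    fam[families$sample] <- families$family
  }
  desc <- phangorn::Descendants(tree, child_nodes, type = "tips")
  vapply(desc, function(tips) {
    if (length(unique(fam[tree$tip.label[tips]])) == 1L) "private" else "common"
  }, character(1))
}

#' Classify called events with direction labels
#'
#' Fills in, for every call of [call_events()]: the lost and gained
#' alleles; the GC direction (`to_GC` when a G/C allele replaces an A/T
#' allele, `to_AT` for the reverse, `neutral` for A-T or G-C changes);
#' the substitution class (transition for A-G and C-T, else
#' transversion); the conversion polarity against the site's ancestral
#' allele (`der_to_anc` when the ancestral allele survives,
#' `anc_to_der` when the derived allele overwrites it, `ambiguous` when
#' the ancestral allele is unknown); and privacy (`private` when every
#' leaf below the event branch belongs to one individual or one
#' father-son family).
#'
#' @param events data frame from [call_events()].
#' @param assign the resolved `"pal_assign"` the events came from.
#' @param families optional data frame (`sample`, `family`).
#' @return the events data frame with columns `from`, `to`,
#'   `gc_direction`, `substitution_class`, `polarity`, `privacy` added.
#' @export
classify_events <- function(events, assign, families = NULL) {
  stopifnot(inherits(assign, "pal_assign"))
  sites <- assign$geno$sites
  if (!all(c(sites$ref, sites$alt) %in% BASES))
    stop("site alleles must be A, C, G or T", call. = FALSE)
  if (nrow(events) == 0L) {
    events$from <- character(0); events$to <- character(0)
    events$gc_direction <- character(0); events$substitution_class <- character(0)
    events$polarity <- character(0); events$privacy <- character(0)
    return(events)
  }
  ref <- sites$ref[events$site_index]
  alt <- sites$alt[events$site_index]
  anc <- assign$anc_allele[events$site_index]

  from <- to <- character(nrow(events))
  mut <- events$kind == "mutation"
  conv <- events$kind == "conversion"
  cplx <- events$kind == "complex"
  # mutation: the parent's homozygous allele gains a partner on one arm
  from[mut] <- ifelse(events$parent_state[mut] == "HOM_REF", ref[mut], alt[mut])
  to[mut] <- ifelse(events$parent_state[mut] == "HOM_REF", alt[mut], ref[mut])
  # conversion: the surviving allele overwrites the lost one
  to[conv] <- ifelse(events$child_state[conv] == "HOM_REF", ref[conv], alt[conv])
  from[conv] <- ifelse(events$child_state[conv] == "HOM_REF", alt[conv], ref[conv])
  from[cplx] <- ifelse(events$parent_state[cplx] == "HOM_REF", ref[cplx], alt[cplx])
  to[cplx] <- ifelse(events$child_state[cplx] == "HOM_REF", ref[cplx], alt[cplx])

  events$from <- from
  events$to <- to
  events$gc_direction <- gc_direction_of(from, to)
  events$substitution_class <- substitution_class_of(from, to)
  events$polarity <- NA_character_
  events$polarity[conv] <-
    ifelse(is.na(anc[conv]), "ambiguous",
           ifelse(to[conv] == anc[conv], "der_to_anc",
                  ifelse(from[conv] == anc[conv], "anc_to_der", "ambiguous")))
  events$privacy <- privacy_of(assign$tree, events$child_node, families)
  events
}

#' Merge same-branch conversions into candidate tracts
#'
#' Adjacent conversions on one branch are more parsimoniously explained
#' by a single long conversion tract than by many independent events.
#' This joins conversions called on the same branch whose sites lie
#' within `max_gap` of each other.
#'
#' @param events classified events data frame.
#' @param max_gap maximum distance (bp) between consecutive conversion
#'   sites merged into one tract.
#' @return data frame with one row per tract: branch, tract bounds and
#'   the number of converted sites it spans.
#' @export
merge_conversion_tracts <- function(events, max_gap = 1000) {
  conv <- events[events$kind == "conversion", , drop = FALSE]
  if (nrow(conv) == 0L)
    return(data.frame(parent_node = integer(0), child_node = integer(0),
                      start = integer(0), end = integer(0), n_sites = integer(0)))
  out <- lapply(split(conv, paste(conv$parent_node, conv$child_node)), function(d) {
    d <- d[order(d$site), ]
    grp <- cumsum(c(1, diff(d$site) > max_gap))
    do.call(rbind, lapply(split(d, grp), function(g)
      data.frame(parent_node = g$parent_node[1], child_node = g$child_node[1],
                 start = min(g$site), end = max(g$site), n_sites = nrow(g))))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$child_node, out$start), ]
}
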