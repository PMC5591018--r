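# independent oracles and fixture builders used across the suite

STATES3 <- c("HOM_REF", "HET", "HOM_ALT")

# leaf-state codes (1..3, NA = missing) -> pseudo_geno over dummy alleles
geno_from_codes <- function(codes, tip_labels = letters[seq_len(nrow(codes))]) {
  gt <- matrix(STATES3[codes], nrow = nrow(codes))
  gt[is.na(gt)] <- "MISSING"
  rownames(gt) <- tip_labels
  ns <- ncol(gt)
  pseudo_geno(data.frame(pos = seq_len(ns), ref = "A", alt = "G",
                         stringsAsFactors = FALSE), gt)
}

# every leaf-state assignment for n tips, one column per combination
all_state_combos <- function(n, states = 1:3) {
  t(as.matrix(expand.grid(rep(list(states), n))))
}

# per-site state-change counts implied by the package's reconstruction
implied_changes <- function(tree, geno) {
  a <- resolve_top_down(fitch_bottom_up(tree, geno))
  ev <- call_events(a, suppress_root = FALSE)
  tabulate(ev$site_index, nbins = ncol(geno$gt))
}

# brute-force minimum parsimony: enumerate every internal labelling over
# three states; NA leaves are unconstrained (they can copy their parent)
brute_force_parsimony <- function(tree, leaf_states, states = 1:3) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  ed <- tree$edge
  int_e <- ed[ed[, 2] > ntip, , drop = FALSE]
  leaf_e <- ed[ed[, 2] <= ntip, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(states), nn)))
  ns <- ncol(leaf_states)
  best <- rep(Inf, ns)
  lf <- leaf_states[leaf_e[, 2], , drop = FALSE]
  for (r in seq_len(nrow(grid))) {
    st <- grid[r, ]
    ic <- sum(st[int_e[, 1] - ntip] != st[int_e[, 2] - ntip])
    pa <- st[leaf_e[, 1] - ntip]
    best <- pmin(best, ic + colSums(lf != pa, na.rm = TRUE))
  }
  as.integer(best)
}

# brute-force minimum number of unit-cost copy-number changes
brute_cn_changes <- function(tree, cn) {
  cn <- cn[tree$tip.label]
  states <- seq(min(cn), max(cn))
  leaf <- matrix(match(cn, states), ncol = 1)
  brute_force_parsimony(tree, leaf, states = seq_along(states))
}

# replay a palindrome simulation's truth log along each root-to-leaf path
replay_leaf_gt <- function(sim) {
  tree <- sim$tree
  ntip <- length(tree$tip.label)
  sites <- sim$geno$sites
  out <- matrix("", ntip, nrow(sites),
                dimnames = list(tree$tip.label, sites$pos))
  for (i in seq_len(ntip)) {
    cur <- ifelse(sim$root_gt == "HET", "HET", "R")
    path <- ape::nodepath(tree, ntip + 1L, i)
    evs <- sim$truth[sim$truth$branch %in% path, , drop = FALSE]
    evs <- evs[order(evs$time), , drop = FALSE]
    for (k in seq_len(nrow(evs))) {
      j <- match(evs$site[k], sites$pos)
      cur[j] <- if (evs$kind[k] == "mutation") "HET"
                else if (evs$to[k] == sites$ref[j]) "R" else "A"
    }
    out[i, ] <- ifelse(cur == "HET", "HET",
                       ifelse(cur == "R", "HOM_REF", "HOM_ALT"))
  }
  out
}

# tiny rooted fixtures built in code
tree_txt <- function(txt) ape::read.tree(text = txt)
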