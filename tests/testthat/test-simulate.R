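test_that("a single family yields one cherry with 1-generation branches", {
  p <- sim_params(n_samples = 2, n_families = 1, seed = 1)
  tr <- simulate_tree(p)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("fam01-01", "fam01-03"))
  expect_equal(tr$edge.length, c(1, 1))
})

test_that("the tree is deterministic under a fixed seed and spans the requested generations", {
  p <- sim_params(n_samples = 62, n_families = 17, seed = 42)
  t1 <- simulate_tree(p)
  t2 <- simulate_tree(p)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_lt(abs(sum(t1$edge.length) - 12265) / 12265, 0.10)
  expect_true(all(t1$edge.length > 0))
  expect_true(ape::is.rooted(t1) && ape::is.binary(t1))
  # every family is a cherry with two 1-generation terminal branches
  fams <- attr(t1, "families")
  for (f in unique(fams$family[grepl("^fam", fams$family)])) {
    tips <- which(t1$tip.label %in% fams$sample[fams$family == f])
    parents <- t1$edge[match(tips, t1$edge[, 2]), 1]
    expect_equal(parents[1], parents[2])
    expect_equal(t1$edge.length[match(tips, t1$edge[, 2])], c(1, 1))
  }
  expect_error(sim_params(n_samples = 4, n_families = 3), "n_families")
})

test_that("X-degenerate SNV counts follow the Poisson oracle", {
  tr <- tree_txt("((a:500,b:500):500,(c:500,d:500):500);")
  G <- sum(tr$edge.length)
  p <- sim_params(n_samples = 4, n_families = 0, mu_xdeg = 3.14e-8,
                  xdeg_length_bp = 5e5, seed = 1)
  expected <- p$mu_xdeg * p$xdeg_length_bp * G
  set.seed(11)
  counts <- vapply(1:200, function(i) ncol(simulate_xdeg_snvs(tr, p)$matrix), 0)
  se <- sqrt(expected / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)

  # disabled process
  p0 <- sim_params(n_samples = 4, n_families = 0, mu_xdeg = 0, seed = 2)
  expect_equal(ncol(simulate_xdeg_snvs(tr, p0)$matrix), 0)

  # on a two-leaf tree every mutation separates the pair
  tr2 <- tree_txt("(a:1000,b:1000);")
  p2 <- sim_params(n_samples = 2, n_families = 1, mu_xdeg = 2e-6,
                   xdeg_length_bp = 1e4, seed = 3)
  sim2 <- simulate_xdeg_snvs(tr2, p2, seed = 3)
  expect_equal(sum(sim2$matrix["a", ] != sim2$matrix["b", ]), nrow(sim2$truth))
})

test_that("palindrome simulator honours disabled processes", {
  tr <- tree_txt("((a:500,b:500):500,(c:500,d:500):500);")
  p0 <- sim_params(n_samples = 4, n_families = 0, mu_pal = 0, gamma = 0,
                   het0_density = 0, arm_length_bp = 1e5, seed = 4)
  sim0 <- simulate_palindrome(tr, p0, seed = 4)
  expect_equal(nrow(sim0$truth), 0)
  expect_equal(ncol(sim0$geno$gt), 0)

  # without conversions every event is a mutation and no site ever goes HOM_ALT
  pm <- sim_params(n_samples = 4, n_families = 0, gamma = 0,
                   arm_length_bp = 1e5, mu_pal = 5e-7, het0_density = 0, seed = 5)
  simm <- simulate_palindrome(tr, pm, seed = 5)
  expect_true(all(simm$truth$kind == "mutation"))
  expect_true(all(simm$geno$gt %in% c("HOM_REF", "HET")))
})

test_that("conversion direction is symmetric when both biases are off", {
  tr <- tree_txt("(((a:1,b:1):2000,(c:1,d:1):2000):2000,(e:1,f:1):4000);")
  p <- sim_params(n_samples = 6, n_families = 3, b_gc = 0.5, b_anc = 0.5,
                  arm_length_bp = 2e4, het0_density = 5e-3, seed = 6)
  set.seed(21)
  gc_counts <- c(to_GC = 0, to_AT = 0)
  for (i in 1:200) {
    s <- simulate_palindrome(tr, p)
    conv <- s$truth[s$truth$kind == "conversion", ]
    dir <- gsub(" ", "", ifelse(conv$to %in% c("G", "C") & conv$from %in% c("A", "T"),
                                "to_GC",
                                ifelse(conv$to %in% c("A", "T") & conv$from %in% c("G", "C"),
                                       "to_AT", "neutral")))
    gc_counts["to_GC"] <- gc_counts["to_GC"] + sum(dir == "to_GC")
    gc_counts["to_AT"] <- gc_counts["to_AT"] + sum(dir == "to_AT")
  }
  n <- sum(gc_counts)
  expect_gt(n, 100)
  # difference of two symmetric binomial halves has SD sqrt(n)
  expect_lt(abs(gc_counts["to_GC"] - gc_counts["to_AT"]), 3 * sqrt(n))
})

test_that("per-branch palindrome event counts match their Poisson means", {
  tr <- tree_txt("((a:2000,b:2000):2000,(c:2000,d:2000):2000);")
  G <- sum(tr$edge.length)
  p <- sim_params(n_samples = 4, n_families = 0, arm_length_bp = 1e5,
                  het0_density = 1e-3, seed = 7)
  set.seed(31)
  nm <- nc <- numeric(150)
  for (i in 1:150) {
    s <- simulate_palindrome(tr, p)
    nm[i] <- sum(s$truth$kind == "mutation")
    nc[i] <- sum(s$truth$kind == "conversion")
  }
  em <- p$mu_pal * 2 * p$arm_length_bp * G
  ec <- p$gamma * 2 * p$arm_length_bp * G
  expect_lt(abs(mean(nm) - em), 3 * sqrt(em / 150))
  expect_lt(abs(mean(nc) - ec), 3 * sqrt(ec / 150))
})

test_that("palindrome genotypes replay exactly from the truth log", {
  p <- sim_params(n_samples = 8, n_families = 2, arm_length_bp = 5e4,
                  het0_density = 2e-3, seed = 8)
  tr <- simulate_tree(p)
  for (s in 1:3) {
    sim <- simulate_palindrome(tr, p, seed = 800 + s)
    expect_identical(replay_leaf_gt(sim), sim$geno$gt)
    # time-ordering of per-site event lists
    for (site in unique(sim$truth$site)) {
      tt <- sim$truth$time[sim$truth$site == site]
      expect_true(all(diff(sort(tt)) >= 0))
    }
  }
})

test_that("fixed seeds make simulation outputs identical", {
  p <- sim_params(n_samples = 6, n_families = 1, arm_length_bp = 5e4,
                  het0_density = 1e-3, seed = 9)
  tr <- simulate_tree(p)
  s1 <- simulate_palindrome(tr, p, seed = 99)
  s2 <- simulate_palindrome(tr, p, seed = 99)
  expect_identical(s1$geno$gt, s2$geno$gt)
  expect_identical(s1$truth, s2$truth)
  x1 <- simulate_xdeg_snvs(tr, p, seed = 99)
  x2 <- simulate_xdeg_snvs(tr, p, seed = 99)
  expect_identical(x1$matrix, x2$matrix)
})

test_that("simulated depth follows the per-copy Poisson model", {
  p <- sim_params(depth_per_copy = 30, seed = 10)
  spec <- data.frame(sample = "s", region = c("two", "zero", "three"),
                     start = 1, end = 10000, copy_number = c(2, 0, 3))
  trks <- simulate_depth(spec, p, seed = 10)
  expect_lt(abs(mean(trks[["s:two"]]$depth) - 60), 3 * sqrt(60 / 1e4))
  expect_true(all(trks[["s:zero"]]$depth == 0))
  expect_lt(abs(mean(trks[["s:three"]]$depth) - 90), 3 * sqrt(90 / 1e4))
  spec$copy_number <- c(-1, 0, 1)
  expect_error(simulate_depth(spec, p), "non-negative")
})
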