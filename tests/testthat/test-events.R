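make_geno <- function(states, ref = "A", alt = "G", dp = NULL) {
  # states: named character vector or sample x site matrix
  if (!is.matrix(states)) states <- matrix(states, ncol = 1,
                                           dimnames = list(names(states), NULL))
  pseudo_geno(data.frame(pos = seq_len(ncol(states)),
                         ref = rep(ref, length.out = ncol(states)),
                         alt = rep(alt, length.out = ncol(states)),
                         stringsAsFactors = FALSE),
              states, dp)
}

test_that("the depth filter masks outside the inclusive 50-250 window", {
  st <- matrix("HET", 1, 5, dimnames = list("s1", NULL))
  dp <- matrix(c(49, 50, 60, 250, 251), 1)
  g <- depth_filter(make_geno(st, dp = dp))
  expect_equal(unname(g$gt[1, ]),
               c("MISSING", "HET", "HET", "HET", "MISSING"))
  dp60 <- matrix(60, 1, 5)
  expect_identical(depth_filter(make_geno(st, dp = dp60))$gt, st)
  expect_error(depth_filter(make_geno(st, dp = dp60), 100, 50), "min_depth")
  expect_error(depth_filter(make_geno(st)), "no depths")
})

test_that("bottom-up sets intersect when possible and unite otherwise", {
  tr <- tree_txt("(a:1,b:1);")
  a1 <- fitch_bottom_up(tr, make_geno(c(a = "HET", b = "HET")))
  expect_equal(a1$sets[3, 1], 2L)                 # {HET}
  a2 <- fitch_bottom_up(tr, make_geno(c(a = "HOM_REF", b = "HET")))
  expect_equal(a2$sets[3, 1], 3L)                 # {HOM_REF, HET}
  a3 <- fitch_bottom_up(tr, make_geno(c(a = "MISSING", b = "HOM_ALT")))
  expect_equal(a3$sets[3, 1], 4L)                 # missing leaf constrains nothing
  expect_error(fitch_bottom_up(tr, make_geno(c(x = "HET", y = "HET"))),
               "absent")
})

test_that("the root resolves by outgroup when possible, else by preference order", {
  tr <- tree_txt("(a:1,b:1);")
  g <- make_geno(c(a = "HOM_REF", b = "HET"))
  r1 <- resolve_top_down(fitch_bottom_up(tr, g), outgroup_states = "HOM_REF")
  expect_equal(r1$resolved[3, 1], 1L)
  expect_true(r1$root_by_outgroup[1])
  expect_equal(r1$anc_allele[1], "A")
  # heterozygous root without a homozygous outgroup: ancestral allele unknown
  gh <- make_geno(c(a = "HET", b = "HET"))
  r2 <- resolve_top_down(fitch_bottom_up(tr, gh), outgroup_states = "HET")
  expect_equal(r2$resolved[3, 1], 2L)
  expect_true(is.na(r2$anc_allele[1]))
  r3 <- resolve_top_down(fitch_bottom_up(tr, gh))
  expect_true(is.na(r3$anc_allele[1]))
  # preference order HOM_REF > HET > HOM_ALT on ties
  r4 <- resolve_top_down(fitch_bottom_up(tr, g))
  expect_equal(r4$resolved[3, 1], 1L)
})

test_that("the worked three-individual panel yields the expected calls", {
  tr <- tree_txt("((i1:1,i2:1):1,i3:2);")
  ntip <- 3L
  mrca12 <- 5L
  states <- rbind(
    i1 = c("HOM_REF", "HET",     "HET", "HOM_REF"),
    i2 = c("HOM_REF", "HOM_REF", "HOM_ALT", "HOM_REF"),
    i3 = c("HET",     "HOM_REF", "HET", "HOM_REF"))
  g <- make_geno(states, ref = "A", alt = "G")
  og <- c("HET", "HOM_REF", "HET", "HOM_REF")
  assign <- resolve_top_down(fitch_bottom_up(tr, g), og)
  ev <- classify_events(call_events(assign), assign)
  # position 1: a shared conversion on the branch to the (i1,i2) ancestor
  # position 2: a mutation private to individual 1
  # position 3: a conversion in individual 2; position 4: nothing
  expect_equal(nrow(ev), 3)
  e1 <- ev[ev$site == 1, ]
  expect_equal(e1$kind, "conversion")
  expect_equal(e1$child_node, mrca12)
  e2 <- ev[ev$site == 2, ]
  expect_equal(e2$kind, "mutation")
  expect_equal(e2$child_node, match("i1", tr$tip.label))
  e3 <- ev[ev$site == 3, ]
  expect_equal(e3$kind, "conversion")
  expect_equal(e3$child_node, match("i2", tr$tip.label))
  expect_equal(e3$polarity, "ambiguous")   # outgroup heterozygous at site 3
})

test_that("event kinds follow the parent/child state contract and are conserved", {
  tr <- tree_txt("((a:1,b:1):1,c:2);")
  # complex change: homozygous parent to the opposite homozygote
  g <- make_geno(rbind(a = "HOM_ALT", b = "HOM_ALT", c = "HOM_REF"))
  assign <- resolve_top_down(fitch_bottom_up(tr, g), "HOM_REF")
  ev <- call_events(assign)
  expect_equal(ev$kind, "complex")
  expect_equal(ev$parent_state, "HOM_REF")
  expect_equal(ev$child_state, "HOM_ALT")

  # conservation: rows partition the state changes
  p <- sim_params(n_samples = 10, n_families = 3, arm_length_bp = 5e4,
                  het0_density = 2e-3, seed = 17)
  trs <- simulate_tree(p)
  sim <- simulate_palindrome(trs, p, seed = 18)
  a <- resolve_top_down(fitch_bottom_up(trs, sim$geno), sim$root_gt)
  allev <- call_events(a, suppress_root = FALSE)
  expect_equal(nrow(allev), attr(allev, "n_changes"))
  kept <- call_events(a, suppress_root = TRUE)
  expect_equal(nrow(kept) + attr(kept, "n_unpolarizable"),
               attr(kept, "n_changes"))
  expect_true(all(kept$kind %in% c("mutation", "conversion", "complex")))
})

test_that("reconstruction attains the exhaustive parsimony minimum on 4-leaf fixtures", {
  trees <- phangorn::allTrees(4, rooted = TRUE, tip.label = letters[1:4])
  lf <- all_state_combos(4)
  g <- geno_from_codes(lf)
  for (i in seq_along(trees))
    expect_equal(implied_changes(trees[[i]], g),
                 brute_force_parsimony(trees[[i]], lf))
  # with missing leaves (unconstrained in the oracle)
  lfm <- all_state_combos(4, states = c(1:3, NA))
  lfm <- lfm[, colSums(is.na(lfm)) < 4, drop = FALSE]
  gm <- geno_from_codes(lfm)
  tr1 <- trees[[1]]
  expect_equal(implied_changes(tr1, gm), brute_force_parsimony(tr1, lfm))
})

test_that("classification labels conversions and mutations correctly", {
  # conversion G/A -> GG with ancestral G: derived-to-ancestral, to_GC, transition
  tr <- tree_txt("((a:1,b:1):1,c:2);")
  g <- make_geno(rbind(a = "HOM_REF", b = "HET", c = "HET"),
                 ref = "G", alt = "A")
  assign <- resolve_top_down(fitch_bottom_up(tr, g), "HOM_REF")
  ev <- classify_events(call_events(assign), assign)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "conversion")
  expect_equal(ev$to, "G")
  expect_equal(ev$from, "A")
  expect_equal(ev$polarity, "der_to_anc")
  expect_equal(ev$gc_direction, "to_GC")
  expect_equal(ev$substitution_class, "transition")
  expect_equal(ev$privacy, "private")

  # mutation CC -> C/T on the branch to a father-son cherry: private, to_AT
  tr2 <- tree_txt("((f:1,s:1):2,(x:1,y:1):2);")
  fam <- data.frame(sample = c("f", "s", "x", "y"),
                    family = c("fam1", "fam1", "x", "y"))
  g2 <- make_geno(rbind(f = "HET", s = "HET", x = "HOM_REF", y = "HOM_REF"),
                  ref = "C", alt = "T")
  a2 <- resolve_top_down(fitch_bottom_up(tr2, g2), "HOM_REF")
  ev2 <- classify_events(call_events(a2), a2, fam)
  expect_equal(ev2$kind, "mutation")
  expect_equal(ev2$from, "C")
  expect_equal(ev2$to, "T")
  expect_equal(ev2$gc_direction, "to_AT")
  expect_equal(ev2$substitution_class, "transition")
  expect_equal(ev2$privacy, "private")
  # same event without the family map is shared across two individuals
  ev2b <- classify_events(call_events(a2), a2)
  expect_equal(ev2b$privacy, "common")
})

test_that("sites with a single true event are called exactly", {
  p <- sim_params(n_samples = 12, n_families = 3, arm_length_bp = 1e5,
                  het0_density = 5e-3, seed = 19)
  tr <- simulate_tree(p)
  sim <- simulate_palindrome(tr, p, seed = 20)
  fit <- pal_events(sim, apply_depth_filter = FALSE)
  single <- names(which(table(sim$truth$site) == 1))
  tru <- sim$truth[sim$truth$site %in% as.integer(single), ]
  ev_key <- paste(fit$events$site, fit$events$child_node, fit$events$kind)
  tru_key <- paste(tru$site, tru$branch, tru$kind)
  hit <- tru_key %in% ev_key
  expect_gt(mean(hit), 0.99)
})

test_that("a missing leaf contributes no event on its terminal branch", {
  tr <- tree_txt("((a:1,b:1):1,c:2);")
  g <- make_geno(rbind(a = "MISSING", b = "HOM_REF", c = "HOM_REF"))
  assign <- resolve_top_down(fitch_bottom_up(tr, g), "HOM_REF")
  expect_equal(nrow(call_events(assign)), 0)
})

test_that("tightening the depth filter never increases the number of calls", {
  p <- sim_params(n_samples = 10, n_families = 2, arm_length_bp = 5e4,
                  het0_density = 2e-3, seed = 21)
  tr <- simulate_tree(p)
  for (s in 1:3) {
    sim <- simulate_palindrome(tr, p, seed = 300 + s)
    n_loose <- nrow(pal_events(sim, min_depth = 40, max_depth = 300)$events)
    n_mid <- nrow(pal_events(sim, min_depth = 50, max_depth = 250)$events)
    n_tight <- nrow(pal_events(sim, min_depth = 58, max_depth = 100)$events)
    expect_lte(n_mid, n_loose)
    expect_lte(n_tight, n_mid)
  }
})

test_that("adjacent same-branch conversions merge into tracts", {
  ev <- data.frame(site = c(100, 200, 5000, 300),
                   parent_node = c(9, 9, 9, 9),
                   child_node = c(3, 3, 3, 4),
                   kind = c("conversion", "conversion", "conversion", "conversion"))
  tr <- merge_conversion_tracts(ev, max_gap = 1000)
  expect_equal(nrow(tr), 3)
  t3 <- tr[tr$child_node == 3, ]
  expect_equal(t3$start, c(100, 5000))
  expect_equal(t3$end, c(200, 5000))
  expect_equal(t3$n_sites, c(2, 1))
})
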