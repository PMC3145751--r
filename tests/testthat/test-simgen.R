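test_that("tree simulation is deterministic and binary", {
  t1 <- simulate_tree(10, seed = 42)
  t2 <- simulate_tree(10, seed = 42)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(simulate_tree(10, seed = 43)),
                         ape::write.tree(t1)))
  expect_length(t1$tip.label, 10)
  expect_equal(nrow(ape::unroot(t1)$edge), 2 * 10 - 3)
  expect_true(all(t1$edge.length > 0))
  expect_error(simulate_tree(2), "n_taxa")
})

test_that("near-infinite gamma shape collapses category rates to 1", {
  ## Gamma sd is 1/sqrt(alpha), so the outer category means sit about
  ## 1.65/sqrt(alpha) from 1; at alpha = 1e8 every rate is within 1e-3
  r <- discrete_gamma_rates(1e8, 8)
  expect_true(all(abs(r - 1) < 1e-3))
  expect_lt(max(abs(discrete_gamma_rates(1e6, 8) - 1)),
            max(abs(discrete_gamma_rates(1e4, 8) - 1)))
  expect_equal(mean(discrete_gamma_rates(0.3, 8)), 1, tolerance = 1e-9)
  expect_true(all(diff(discrete_gamma_rates(0.5, 8)) > 0))
})

test_that("zero-length star tree yields invariant columns", {
  star <- ape::read.tree(text = "(a:0,b:0,c:0,d:0);")
  sim <- simulate_alignment(star, subst_model("jc", k = 1), 50, seed = 5)
  expect_true(all(apply(sim$alignment$seq, 2,
                        function(col) length(unique(col)) == 1)))
})

test_that("simulated residues follow the stationary frequencies", {
  freq <- c(0.4, 0.3, 0.2, 0.1)
  mod <- subst_model("gtr", frequencies = freq, k = 1)
  tr <- ape::read.tree(text = "(a:2.0,b:2.0);")
  sim <- simulate_alignment(tr, mod, 50000, seed = 6)
  counts <- table(factor(sim$alignment$seq, levels = c("A", "C", "G", "T")))
  expect_gt(chisq.test(counts, p = freq)$p.value, 0.01)
})

test_that("rate classes are drawn uniformly and recorded", {
  tr <- simulate_tree(6, seed = 2)
  sim <- simulate_alignment(tr, subst_model("gtr", alpha = 0.5, k = 8), 10000,
                            seed = 2)
  expect_length(sim$true_site_rates, 10000)
  expect_true(all(sim$true_site_class %in% 0:7))
  counts <- table(factor(sim$true_site_class, levels = 0:7))
  expect_gt(chisq.test(counts)$p.value, 0.01)
  ## rates match the class discretization
  r <- discrete_gamma_rates(0.5, 8)
  expect_equal(sim$true_site_rates, r[sim$true_site_class + 1])
})

test_that("same config and seed give bit-identical simulations", {
  tr <- simulate_tree(8, seed = 3)
  s1 <- simulate_alignment(tr, subst_model("gtr", alpha = 1, k = 4), 100, seed = 9)
  s2 <- simulate_alignment(tr, subst_model("gtr", alpha = 1, k = 4), 100, seed = 9)
  expect_identical(s1$alignment$seq, s2$alignment$seq)
  expect_identical(s1$true_site_class, s2$true_site_class)
})

test_that("estimated JC distance converges to the true path length", {
  tr <- ape::read.tree(text = "(a:0.15,b:0.15);")
  mod <- subst_model("jc", k = 1)
  errs <- vapply(c(1e3, 1e5), function(n) {
    sim <- simulate_alignment(tr, mod, n, seed = 11)
    d <- jc_distance_matrix(sim$alignment)
    abs(d["a", "b"] - 0.3)
  }, numeric(1))
  ## 3 SE of the JC estimator at n = 1e5, d = 0.3
  p <- 3 / 4 * (1 - exp(-4 * 0.3 / 3))
  se <- sqrt(p * (1 - p) / 1e5) / (1 - 4 * p / 3)
  expect_lt(errs[2], 3 * se)
})

test_that("long-branch injection scales terminals and dominates rankings", {
  tr <- simulate_tree(12, outgroup = "OUT", seed = 13)
  expect_identical(inject_long_branches(tr, "t03", 1), tr)
  before <- root_to_tip_lengths(tr, "OUT")
  aug <- inject_long_branches(tr, "t03", 10)
  after <- root_to_tip_lengths(aug, "OUT")
  term <- tr$edge.length[match(match("t03", tr$tip.label), tr$edge[, 2])]
  expect_equal(after[["t03"]] - before[["t03"]], 9 * term)
  ## multiplier >= 5 puts injected taxa on top of root-to-tip ranks
  targets <- c("t01", "t05", "t09")
  aug2 <- inject_long_branches(tr, targets, 5)
  rt <- root_to_tip_lengths(aug2, "OUT")
  rt <- rt[setdiff(names(rt), "OUT")]
  expect_setequal(names(sort(rt, decreasing = TRUE))[1:3], targets)
  expect_error(inject_long_branches(tr, "nope", 2), "unknown")
})

test_that("rogue injection moves only the named taxon", {
  base <- rand_tree(8, seed = 21)
  ts <- as_treeset(lapply(1:30, function(i) base))
  expect_identical(inject_rogue(ts, "t1", 0, seed = 1), ts)
  moved <- inject_rogue(ts, "t1", 1, seed = 1)
  ## non-rogue quartets unaffected
  others <- setdiff(base$tip.label, "t1")
  for (tr in moved[1:5]) {
    expect_identical(newick_splits(ape::write.tree(ape::drop.tip(tr, "t1")))$splits,
                     newick_splits(ape::write.tree(ape::drop.tip(base, "t1")))$splits)
  }
  ## determinism
  moved2 <- inject_rogue(ts, "t1", 1, seed = 1)
  expect_identical(vapply(moved, ape::write.tree, character(1)),
                   vapply(moved2, ape::write.tree, character(1)))
  expect_error(inject_rogue(ts, "zz", 0.5), "absent")
})

test_that("environmental pools hit their identity targets", {
  ref <- c(r1 = paste(rep(c("A", "C", "G", "T"), 25), collapse = ""))
  pool <- make_environmental_pool(ref, c(1.0, 0.5), seed = 7)
  exact <- pool[grep("q100", names(pool))]
  expect_identical(unname(exact), unname(ref))
  half <- strsplit(pool[grep("q050", names(pool))], "")[[1]]
  refc <- strsplit(ref, "")[[1]]
  expect_equal(mean(half == refc), 0.5, tolerance = 0.01)
  expect_error(make_environmental_pool(character(0), 1), "empty")
})
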