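test_that("two-taxon site likelihoods match the Jukes-Cantor closed form", {
  m <- subst_model("jc", k = 1)
  tr <- ape::read.tree(text = "(A:0.05,B:0.05);")
  same <- site_likelihoods(phy_alignment(c(A = "A", B = "A")), tr, m)$site_lnl
  diff <- site_likelihoods(phy_alignment(c(A = "A", B = "C")), tr, m)$site_lnl
  expect_equal(same, log(0.25 * (0.25 + 0.75 * exp(-0.4 / 3))), tolerance = 1e-9)
  expect_equal(diff, log(0.25 * 0.25 * (1 - exp(-0.4 / 3))), tolerance = 1e-9)
})

test_that("fully missing columns carry no information", {
  m <- subst_model("jc", k = 2, alpha = 0.5)
  tr <- rand_tree(5, seed = 2)
  aln <- phy_alignment(stats::setNames(rep("-", 5), tr$tip.label))
  expect_equal(site_likelihoods(aln, tr, m)$site_lnl, 0, tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration on random 4-5 taxon instances", {
  for (i in 1:6) {
    n <- sample(4:5, 1)
    tr <- rand_tree(n, seed = 300 + i)
    mod <- subst_model("gtr", frequencies = c(0.3, 0.25, 0.25, 0.2),
                       exchangeabilities = c(1.2, 2.5, 0.7, 1.1, 3.0, 1.0),
                       alpha = 0.6, k = 2)
    aln <- rand_aln(tr$tip.label, 5, seed = 400 + i, gap_frac = 0.1)
    expect_equal(total_loglik(aln, tr, mod), brute_force_total(aln, tr, mod),
                 tolerance = 1e-10)
  }
})

test_that("total log-likelihood agrees with an independent ML engine", {
  tr <- rand_tree(8, seed = 5)
  mod <- subst_model("gtr", alpha = 0.7, k = 4)
  sim <- simulate_alignment(tr, mod, 200, seed = 5)
  ours <- total_loglik(sim$alignment, tr, mod)
  pd <- phangorn::phyDat(sim$alignment$seq, type = "DNA")
  ref <- phangorn::pml(tr, pd, k = 4, shape = 0.7)$logLik
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("likelihood is invariant to column order and to re-rooting", {
  tr <- rand_tree(7, seed = 8)
  mod <- subst_model("gtr", alpha = 0.5, k = 4)
  sim <- simulate_alignment(tr, mod, 60, seed = 8)
  aln <- sim$alignment
  perm <- phy_alignment(aln$seq[, sample(60)], alphabet = "dna")
  expect_equal(total_loglik(aln, tr, mod), total_loglik(perm, tr, mod),
               tolerance = 1e-9)
  ## pulley principle: root placement cannot change the likelihood
  base_lnl <- sort(site_likelihoods(aln, tr, mod)$site_lnl)
  for (og in sample(tr$tip.label, 3)) {
    rerooted <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(sort(site_likelihoods(aln, rerooted, mod)$site_lnl),
                 base_lnl, tolerance = 1e-9)
  }
})

test_that("partitioned datasets sum per-partition log-likelihoods", {
  tr <- rand_tree(6, seed = 12)
  mod <- subst_model("gtr", alpha = 1, k = 2)
  sim <- simulate_alignment(tr, mod, 40, seed = 12)
  aln <- sim$alignment
  two <- concatenate(list(p1 = phy_alignment(aln$seq[, 1:25]),
                          p2 = phy_alignment(aln$seq[, 26:40])))
  expect_equal(total_loglik(two, tr, list(p1 = mod, p2 = mod)),
               total_loglik(aln, tr, mod), tolerance = 1e-9)
})

test_that("posterior rate classification behaves as an empirical Bayes rule", {
  m <- subst_model("jc", alpha = 0.5, k = 8)
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  aln <- phy_alignment(c(A = "AAAA", B = "AAAC"))
  cls <- classify_site_rates(aln, tr, m)
  post <- attr(cls, "posterior")
  expect_equal(colSums(post), rep(1, 4), tolerance = 1e-9)
  ## variable column gets a higher posterior-mean rate than invariant ones
  expect_gt(cls$post_mean_rate[4], cls$post_mean_rate[1])
  expect_true(all(cls$class %in% 0:7))
  ## class labels: 0 slowest .. 7 fastest
  expect_lt(cls$class[1], cls$class[4])
})

test_that("classification is permutation-equivariant", {
  tr <- rand_tree(6, seed = 31)
  mod <- subst_model("gtr", alpha = 0.5, k = 4)
  sim <- simulate_alignment(tr, mod, 50, seed = 31)
  cls <- classify_site_rates(sim$alignment, tr, mod)
  perm <- sample(50)
  aln2 <- phy_alignment(sim$alignment$seq[, perm], alphabet = "dna")
  cls2 <- classify_site_rates(aln2, tr, mod)
  expect_equal(cls2$post_mean_rate, cls$post_mean_rate[perm], tolerance = 1e-9)
  expect_equal(cls2$class, cls$class[perm])
})

test_that("rate-class stripping filters the right columns and guards inputs", {
  aln <- rand_aln(letters[1:5], 10, seed = 17)
  tr <- rand_tree(5, seed = 17); tr$tip.label <- letters[1:5]
  mod <- subst_model("gtr", alpha = 0.5, k = 8)
  cls <- classify_site_rates(aln, tr, mod)
  expect_identical(strip_rate_classes(aln, cls, remove = integer(0))$seq, aln$seq)
  fake <- cls
  fake$class <- c(0L, 0L, 7L, 0L, 0L, 0L, 7L, 0L, 0L, 0L)
  stripped <- strip_rate_classes(aln, fake, remove = 7L, restrict_to = "all")
  expect_equal(ncol(stripped$seq), 8)
  expect_equal(stripped$source_index, setdiff(1:10, c(3, 7)))
  ## classification built on different data is rejected
  other <- rand_aln(letters[1:5], 10, seed = 18)
  expect_error(strip_rate_classes(other, cls, remove = 7L, restrict_to = "all"),
               "checksum")
})

test_that("gamma shape recovery and optimality", {
  tr <- simulate_tree(12, seed = 19)
  mod <- subst_model("gtr", alpha = 0.5, k = 4)
  sim <- simulate_alignment(tr, mod, 2000, seed = 19)
  ah <- fit_gamma_shape(sim$alignment, tr, mod, bounds = c(0.05, 10))
  expect_gt(as.numeric(ah), 0.3)
  expect_lt(as.numeric(ah), 0.8)
  ## the optimum beats a coarse grid
  lls <- vapply(c(0.1, 0.3, 1, 3, 8), function(a) {
    total_loglik(sim$alignment, tr, subst_model("gtr", alpha = a, k = 4))
  }, numeric(1))
  expect_true(all(attr(ah, "loglik") >= lls - 1e-6))
})

test_that("invariant-only data pins the shape at the lower bound", {
  tr <- rand_tree(5, seed = 23)
  aln <- phy_alignment(stats::setNames(rep("AAAAAAAAAA", 5), tr$tip.label))
  expect_warning(ah <- fit_gamma_shape(aln, tr, subst_model("jc", k = 4),
                                       bounds = c(0.05, 5)),
                 "pinned")
  expect_equal(as.numeric(ah), 0.05, tolerance = 1e-6)
})
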