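test_that("treeness and tree length follow their definitions", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  quartet <- ape::read.tree(text = "((A:1,B:1):0.5,C:1,D:1);")
  expect_equal(treeness(star), 0)
  expect_equal(tree_length(star), 4)
  expect_equal(treeness(quartet), 0.5 / 4.5, tolerance = 1e-12)
  expect_equal(tree_length(quartet), 4.5)
  scaled <- quartet; scaled$edge.length <- scaled$edge.length * 7
  expect_equal(treeness(scaled), treeness(quartet), tolerance = 1e-12)
  ## internal + terminal sums decompose the total
  ut <- ape::unroot(quartet)
  internal <- ut$edge[, 2] > ape::Ntip(ut)
  expect_equal(sum(ut$edge.length[internal]) + sum(ut$edge.length[!internal]),
               tree_length(quartet))
  expect_error(treeness(ape::read.tree(text = "(A:0,B:0,C:0);")), "zero")
})

test_that("root-to-tip lengths split the outgroup stem at its midpoint", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:4);")
  expect_equal(root_to_tip_lengths(tr, "C"), c(A = 4, B = 5, C = 2))
  ## ultrametric ingroup: all ingroup depths equal
  clock <- simulate_tree(10, depth = 0.5, outgroup = "OG", seed = 2)
  rt <- root_to_tip_lengths(clock, "OG")
  expect_equal(unname(diff(range(rt[setdiff(names(rt), "OG")]))), 0,
               tolerance = 1e-9)
  ## a x10 long branch taxon tops the ranking
  aug <- inject_long_branches(clock, "t04", 10)
  rt2 <- root_to_tip_lengths(aug, "OG")
  expect_equal(names(which.max(rt2[setdiff(names(rt2), "OG")])), "t04")
  expect_error(root_to_tip_lengths(tr, "Z"), "absent")
})

test_that("non-monophyletic outgroups are rejected by name", {
  tr <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_error(root_to_tip_lengths(tr, c("A", "B")), "not a clade")
})

test_that("long-branch ranking averages across reconstructions", {
  tr <- simulate_tree(10, outgroup = "OG", seed = 6)
  aug <- inject_long_branches(tr, c("t02", "t07"), 10)
  ranks <- rank_long_branches(list(a = aug), "OG", 2)
  expect_setequal(ranks, c("t02", "t07"))
  expect_identical(rank_long_branches(list(a = aug), "OG", 0), character(0))
  ## single tree ordering matches root_to_tip ordering
  rt <- sort(root_to_tip_lengths(aug, "OG")[paste0("t", sprintf("%02d", 1:10))],
             decreasing = TRUE)
  expect_identical(rank_long_branches(list(a = aug), "OG", 4), names(rt)[1:4])
  expect_error(rank_long_branches(list(), "OG", 2), "empty")
})

test_that("leaf stability matches exhaustive quartet frequencies", {
  t1 <- ape::read.tree(text = "((X:1,a:1):1,(b:1,c:1):1);")
  t2 <- ape::read.tree(text = "((X:1,b:1):1,(a:1,c:1):1);")
  even <- as_treeset(c(t1, t1, t2, t2))
  expect_equal(leaf_stability(even, mode = "exact")$stability, rep(0, 4))
  lop <- leaf_stability(as_treeset(c(t1, t1, t1, t2)), mode = "exact")
  expect_equal(lop$stability, rep(0.5, 4))
  same <- leaf_stability(as_treeset(c(t1, t1, t1)), mode = "exact")
  expect_equal(same$stability, rep(1, 4))
  expect_equal(attr(same, "ci_half"), 0)
  ## larger random tree sets against the enumeration oracle
  ts <- as_treeset(lapply(1:15, function(i) rand_tree(7, seed = 600 + i %% 4)))
  mine <- leaf_stability(ts, mode = "exact")
  oracle <- oracle_leaf_stability(ts)
  expect_equal(stats::setNames(mine$stability, mine$taxon), oracle,
               tolerance = 1e-9)
})

test_that("stability handles missing taxa by per-quartet renormalization", {
  t1 <- ape::read.tree(text = "((X:1,a:1):1,(b:1,c:1):1);")
  t3 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")  # no X
  ts <- as_treeset(c(t1, t1, t3))
  ## quartets involving both X and d occur in no tree: excluded, warned
  expect_warning(rep_ <- leaf_stability(ts, mode = "exact"),
                 "present in no tree")
  ## quartet {X,a,b,c} only occurs in the two t1 trees: fully consistent
  expect_equal(rep_$stability[rep_$taxon == "X"], 1)
})

test_that("instability ranking finds an injected rogue", {
  base <- rand_tree(8, seed = 71)
  ts <- as_treeset(lapply(1:60, function(i) base))
  moved <- inject_rogue(ts, "t5", 1, seed = 3)
  expect_identical(rank_unstable(moved, 1, mode = "exact"), "t5")
  expect_identical(rank_unstable(moved, 0), character(0))
  ## order of trees in the set is irrelevant
  shuffled <- as_treeset(moved[rev(seq_along(moved))])
  expect_identical(rank_unstable(shuffled, 1, mode = "exact"), "t5")
})

test_that("clade support counts bipartitions and respects symmetry", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  ts <- as_treeset(c(rep(list(t1), 7), rep(list(t2), 3)))
  expect_equal(clade_support(ts, c("A", "B")), 70)
  expect_equal(clade_support(ts, c("C", "D")), 70)
  ## complement of a single taxon is a trivial split
  expect_equal(clade_support(ts, c("A", "B", "C")), 100)
  expect_equal(clade_support(ts, c("B", "C", "D")), 100)
  st <- clade_support(ts, c("A", "zz"))
  expect_true(is.na(st))
  expect_identical(attr(st, "status"), "-")
})

test_that("support tables use the nm / - cell codes", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  boot <- as_treeset(c(rep(list(t1), 83), rep(list(t2), 17)))
  hyps <- list(clade_hypothesis("AB", c("A", "B")),
               clade_hypothesis("AC", c("A", "C")),
               clade_hypothesis("solo", c("A", "nothere")))
  st <- support_table(hyps, list(main = list(best = t1, boot = boot)))
  expect_identical(st["AB", "main"], "83")
  expect_identical(st["AC", "main"], "nm")   # not in the best tree
  expect_identical(st["solo", "main"], "-")
  expect_true(all(unclass(st) %in% c(as.character(0:100), "nm", "-")))
})

test_that("majority-rule consensus agrees with clade support on its edges", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,((C:1,D:1):1,E:1):1);")
  t2 <- ape::read.tree(text = "((A:1,B:1):1,((C:1,E:1):1,D:1):1);")
  ts <- as_treeset(c(rep(list(t1), 8), rep(list(t2), 2)))
  cons <- majority_rule_consensus(ts)
  expect_s3_class(cons, "phylo")
  ## every internal edge's support equals the direct bipartition count
  ntip <- ape::Ntip(cons)
  for (node in (ntip + 2):(ntip + cons$Nnode)) {
    tips <- ape::extract.clade(cons, node)$tip.label
    lab <- cons$node.label[node - ntip]
    if (length(tips) >= 2 && length(tips) <= ntip - 2 && !is.na(lab)) {
      expect_equal(as.numeric(lab), clade_support(ts, tips))
    }
  }
  ## all-identical input returns that topology with 100s everywhere
  same <- majority_rule_consensus(as_treeset(c(t1, t1, t1)))
  expect_identical(newick_splits(ape::write.tree(same))$splits,
                   newick_splits(ape::write.tree(t1))$splits)
  ## no majority: 2x(AB|CD) + 2x(AC|BD) collapses to a star
  q1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  q2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  star <- majority_rule_consensus(as_treeset(c(q1, q1, q2, q2)))
  expect_equal(ape::Ntip(star) + star$Nnode, 5)  # single internal node
})

test_that("pruning the rogue raises mean stability", {
  base <- rand_tree(9, seed = 81)
  ts <- as_treeset(lapply(1:50, function(i) base))
  moved <- inject_rogue(ts, "t3", 1, seed = 9)
  before <- attr(leaf_stability(moved, mode = "exact"), "mean")
  pruned <- remove_taxa(moved, "t3")
  after <- attr(leaf_stability(pruned, mode = "exact"), "mean")
  expect_gt(after, before)
})
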