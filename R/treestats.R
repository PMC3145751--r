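#' Total tree length
#'
#' @param tree A `phylo` with branch lengths.
#' @return Sum of all branch lengths.
#' @export
tree_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  sum(tree$edge.length %||% 0)
}

#' Treeness (proportion of tree length in internal branches)
#'
#' Computed on the unrooted topology: a root bisecting an edge is
#' suppressed first, so the two root edges count as one. Low treeness means
#' most substitutions sit on terminal branches, a signature of weak stem
#' signal.
#'
#' @param tree A `phylo` with branch lengths.
#' @return A number in `[0,1]`.
#' @export
treeness <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  tot <- sum(ut$edge.length)
  if (tot <= 0) stop("tree has zero total length")
  internal <- ut$edge[, 2] > ape::Ntip(ut)
  sum(ut$edge.length[internal]) / tot
}

#' Root-to-tip path lengths under outgroup rooting
#'
#' The tree is rooted at the midpoint of the outgroup's stem edge (the
#' edge separating the outgroup clade from the rest), then the path length
#' from that root to every leaf is returned. The outgroup must form a
#' clade on the unrooted topology.
#'
#' @param tree A `phylo`.
#' @param outgroup Non-empty set of tip labels.
#' @return Named numeric vector, one entry per leaf.
#' @export
root_to_tip_lengths <- function(tree, outgroup) {
  stopifnot(length(outgroup) >= 1)
  missing_og <- setdiff(outgroup, tree$tip.label)
  if (length(missing_og)) stop("outgroup taxa absent: ",
                               paste(missing_og, collapse = ", "))
  if (!.is_split(if (ape::is.rooted(tree)) ape::unroot(tree) else tree,
                 outgroup)) {
    stop("outgroup is not a clade; conflicting taxa among: ",
         paste(outgroup, collapse = ", "))
  }
  rooted <- tree
  rerooted <- !.root_separates(rooted, outgroup)
  if (rerooted) {
    ut <- if (ape::is.rooted(rooted)) ape::unroot(rooted) else rooted
    rooted <- ape::root(ut, outgroup = outgroup, resolve.root = TRUE)
  }
  ntip <- ape::Ntip(rooted)
  root <- ntip + 1L
  kids <- which(rooted$edge[, 1] == root)
  if (rerooted) {
    ## the root bisects the single stem edge of the unrooted topology:
    ## place it at the midpoint of the combined length
    half <- sum(rooted$edge.length[kids]) / 2
    rooted$edge.length[kids] <- half
  } else {
    ## already outgroup-rooted: the stem is the root-child edge on the
    ## outgroup side; move the root to its midpoint
    og_side <- vapply(kids, function(e) {
      node <- rooted$edge[e, 2]
      tips <- if (node <= ntip) rooted$tip.label[node] else
        ape::extract.clade(rooted, node)$tip.label
      all(tips %in% outgroup)
    }, logical(1))
    e_og <- kids[og_side][1]
    half <- rooted$edge.length[e_og] / 2
    rooted$edge.length[e_og] <- half
    others <- setdiff(kids, e_og)
    rooted$edge.length[others] <- rooted$edge.length[others] + half
  }
  depths <- ape::node.depth.edgelength(rooted)
  stats::setNames(depths[seq_len(ntip)], rooted$tip.label)
}

## is the root's induced bipartition exactly {outgroup | rest}?
.root_separates <- function(tree, outgroup) {
  if (!ape::is.rooted(tree)) return(FALSE)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  kids <- which(tree$edge[, 1] == root)
  if (length(kids) != 2) return(FALSE)
  for (e in kids) {
    node <- tree$edge[e, 2]
    tips <- if (node <= ntip) tree$tip.label[node] else
      ape::extract.clade(tree, node)$tip.label
    if (setequal(tips, outgroup)) return(TRUE)
  }
  FALSE
}

## does `side` form a bipartition of the unrooted tree?
.is_split <- function(tree, side) {
  side <- intersect(side, tree$tip.label)
  other <- setdiff(tree$tip.label, side)
  if (length(side) < 1 || length(other) < 1) return(TRUE)
  if (length(side) == 1 || length(other) == 1) return(TRUE)
  ape::is.monophyletic(tree, side) || ape::is.monophyletic(tree, other)
}

#' Rank taxa by mean root-to-tip length
#'
#' Root-to-tip lengths are averaged over the supplied reconstructions
#' (taxa missing from a tree are averaged over the trees that contain
#' them); the top-n taxa by mean length are returned, ties broken by
#' label. Outgroup taxa are never ranked.
#'
#' @param trees Named list of `phylo` objects (the reconstructions).
#' @param outgroup Outgroup tip labels (used to root each tree).
#' @param n Number of taxa to return.
#' @return Character vector of length `n` (longest first).
#' @export
rank_long_branches <- function(trees, outgroup, n) {
  if (!length(trees)) stop("empty tree list")
  if (n == 0) return(character(0))
  vals <- list()
  for (tr in trees) {
    og <- intersect(outgroup, tr$tip.label)
    rt <- root_to_tip_lengths(tr, og)
    vals[[length(vals) + 1L]] <- rt[setdiff(names(rt), outgroup)]
  }
  all_tax <- sort(unique(unlist(lapply(vals, names))))
  if (n >= length(all_tax)) stop("n must be smaller than the ingroup size")
  means <- vapply(all_tax, function(tx) {
    v <- unlist(lapply(vals, function(x) x[tx]))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  ord <- order(-means, names(means))
  names(means)[ord][seq_len(n)]
}

#' Quartet-based leaf stability
#'
#' For each taxon X, over quartets \{X,a,b,c\}, the three unrooted
#' resolutions have relative frequencies f1 >= f2 >= f3 across the tree
#' set (trees lacking any of the four taxa are skipped for that quartet).
#' The quartet score under the default "difference" variant is f1 - f2;
#' stability(X) is the mean score over its quartets. The "max" variant
#' scores f1, and "entropy" scores 1 - H(f)/log(3).
#'
#' @param ts A `multiPhylo` (>= 2 trees over >= 4 shared taxa).
#' @param mode "auto" (exact unless the quartet count exceeds
#'   `max_exact`), "exact", or "sampled".
#' @param m Number of quartets sampled per taxon in sampled mode
#'   (default 1000 * n_taxa overall, split across taxa).
#' @param variant "difference", "max", or "entropy".
#' @param max_exact Quartet-count threshold for auto mode (default 2e6).
#' @param seed Integer seed for sampled mode.
#' @return A `leaf_stability_report` data frame (taxon, stability, rank)
#'   with attributes `mean`, `ci_half` (1.96 sd / sqrt(n_taxa)),
#'   `n_quartets` ("exact" or the sample size), `variant`.
#' @export
leaf_stability <- function(ts, mode = c("auto", "exact", "sampled"),
                           m = NULL, variant = c("difference", "max", "entropy"),
                           max_exact = 2e6, seed = 1) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  ts <- as_treeset(ts)
  if (length(ts) < 2) stop("need at least 2 trees")
  taxa <- attr(ts, "taxon_universe")
  n <- length(taxa)
  if (n < 4) stop("need at least 4 taxa")
  n_quart <- choose(n, 4)
  if (mode == "auto") mode <- if (n_quart <= max_exact) "exact" else "sampled"
  ## per-tree topological distance matrices over the universe (NA = absent)
  dists <- lapply(ts, function(tr) {
    t1 <- tr; t1$edge.length <- rep(1, nrow(t1$edge))
    d <- stats::cophenetic(t1)
    full <- matrix(NA_real_, n, n, dimnames = list(taxa, taxa))
    full[rownames(d), colnames(d)] <- d
    full
  })
  if (mode == "exact") {
    qs <- t(utils::combn(n, 4))
  } else {
    if (is.null(m)) m <- 1000L * n
    qs <- .with_seed(derive_seed(seed, "leaf_stability"), {
      matrix(replicate(m, sample.int(n, 4)), ncol = 4, byrow = TRUE)
    })
  }
  scores <- .quartet_scores(qs, dists, variant)
  keep <- !is.na(scores)
  if (!any(keep)) stop("every quartet is absent from the tree set")
  if (any(!keep)) warning(sum(!keep), " quartet(s) present in no tree; excluded")
  qs <- qs[keep, , drop = FALSE]
  scores <- scores[keep]
  stab <- vapply(seq_len(n), function(i) {
    inq <- qs[, 1] == i | qs[, 2] == i | qs[, 3] == i | qs[, 4] == i
    if (!any(inq)) return(NA_real_)
    mean(scores[inq])
  }, numeric(1))
  df <- data.frame(taxon = taxa, stability = stab)
  df$rank <- rank(-df$stability, ties.method = "first")
  mu <- mean(df$stability, na.rm = TRUE)
  ci <- 1.96 * stats::sd(df$stability, na.rm = TRUE) / sqrt(sum(!is.na(stab)))
  structure(df, mean = mu, ci_half = ci,
            n_quartets = if (mode == "exact") "exact" else nrow(qs),
            variant = variant,
            class = c("leaf_stability_report", class(df)))
}

## scores for quartet rows (indices into the taxon universe); NA when the
## quartet occurs in no tree
.quartet_scores <- function(qs, dists, variant) {
  nq <- nrow(qs)
  counts <- matrix(0, nq, 3)
  a <- qs[, 1]; b <- qs[, 2]; c_ <- qs[, 3]; d <- qs[, 4]
  for (D in dists) {
    s1 <- D[cbind(a, b)] + D[cbind(c_, d)]   # ab|cd
    s2 <- D[cbind(a, c_)] + D[cbind(b, d)]   # ac|bd
    s3 <- D[cbind(a, d)] + D[cbind(b, c_)]   # ad|bc
    ok <- !is.na(s1) & !is.na(s2) & !is.na(s3)
    ## four-point condition on topological distances: the smallest pairing
    ## sum names the split; equal minima = unresolved (counted for none)
    m12 <- pmin(s1, s2); mn <- pmin(m12, s3)
    r1 <- ok & s1 == mn & s2 > mn & s3 > mn
    r2 <- ok & s2 == mn & s1 > mn & s3 > mn
    r3 <- ok & s3 == mn & s1 > mn & s2 > mn
    counts[, 1] <- counts[, 1] + r1
    counts[, 2] <- counts[, 2] + r2
    counts[, 3] <- counts[, 3] + r3
  }
  tot <- rowSums(counts)
  out <- rep(NA_real_, nq)
  pos <- tot > 0
  f <- counts[pos, , drop = FALSE] / tot[pos]
  f <- t(apply(f, 1, sort, decreasing = TRUE))
  out[pos] <- switch(variant,
    difference = f[, 1] - f[, 2],
    max = f[, 1],
    entropy = {
      h <- -rowSums(ifelse(f > 0, f * log(f), 0))
      1 - h / log(3)
    })
  out
}

#' Rank the least stable taxa
#'
#' @param ts A `multiPhylo`.
#' @param n Number of taxa to return (bottom-n by stability, ties broken
#'   by label).
#' @param exclude Taxa never returned (e.g. the outgroup).
#' @param ... Passed to [leaf_stability].
#' @return Character vector of length `n` (least stable first).
#' @export
rank_unstable <- function(ts, n, exclude = character(0), ...) {
  if (n == 0) return(character(0))
  rep_ <- leaf_stability(ts, ...)
  rep_ <- rep_[!rep_$taxon %in% exclude, ]
  if (n >= nrow(rep_)) stop("n must be smaller than the taxon count")
  ord <- order(rep_$stability, rep_$taxon)
  rep_$taxon[ord][seq_len(n)]
}

#' Bootstrap support for a clade hypothesis
#'
#' Percentage of trees in which the hypothesis members present in that
#' tree form one side of a bipartition of the unrooted topology. Trees
#' containing fewer than 2 members are skipped.
#'
#' @param ts A `multiPhylo`.
#' @param members Taxon label set.
#' @return Percent in `[0,100]`, or `NA` with attribute `status = "-"`
#'   when fewer than 2 members exist in the tree set's universe.
#' @export
clade_support <- function(ts, members) {
  ts <- as_treeset(ts)
  members <- intersect(members, attr(ts, "taxon_universe"))
  if (length(members) < 2) {
    return(structure(NA_real_, status = "-"))
  }
  hits <- 0L; used <- 0L
  for (tr in ts) {
    pres <- intersect(members, tr$tip.label)
    if (length(pres) < 2) next
    used <- used + 1L
    if (.is_split(ape::unroot(tr), pres)) hits <- hits + 1L
  }
  if (used == 0) return(structure(NA_real_, status = "-"))
  100 * hits / used
}

#' Define a clade hypothesis
#'
#' @param name Hypothesis name.
#' @param members Taxon labels (>= 1; unknown labels are flagged at table
#'   time, not dropped).
#' @param category Grouping category, e.g. "higher-level", "proposed",
#'   "morphogroup".
#' @return A `clade_hypothesis` list.
#' @export
clade_hypothesis <- function(name, members, category = "proposed") {
  stopifnot(nzchar(name), length(members) >= 1)
  structure(list(name = name, members = unique(members), category = category),
            class = "clade_hypothesis")
}

#' Read clade hypotheses from a YAML file
#'
#' The file is a YAML list of \{name, category, members\} entries.
#'
#' @param path YAML file path.
#' @return List of [clade_hypothesis] objects.
#' @export
read_hypotheses <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read hypothesis files")
  }
  raw <- yaml::read_yaml(path)
  lapply(raw, function(h) {
    clade_hypothesis(h$name, unlist(h$members), h$category %||% "proposed")
  })
}

#' Tabulate clade support across reconstructions
#'
#' One row per hypothesis, one column per reconstruction. A cell is "-"
#' when fewer than 2 members are present in that reconstruction, "nm" when
#' the members are present but not monophyletic in its best tree, and
#' otherwise the bootstrap percentage (rounded to integer, as such tables
#' are conventionally printed; raw values are kept in the `raw` attribute).
#'
#' @param hypotheses List of [clade_hypothesis] objects.
#' @param reconstructions Named list; each element a list with `best` (a
#'   `phylo`) and `boot` (a `multiPhylo`).
#' @return A character matrix of class `support_table` with attribute
#'   `raw` (numeric matrix).
#' @export
support_table <- function(hypotheses, reconstructions) {
  if (anyDuplicated(names(reconstructions))) stop("reconstruction names must be unique")
  hn <- vapply(hypotheses, `[[`, character(1), "name")
  out <- matrix("-", length(hypotheses), length(reconstructions),
                dimnames = list(hn, names(reconstructions)))
  raw <- matrix(NA_real_, length(hypotheses), length(reconstructions),
                dimnames = dimnames(out))
  for (j in seq_along(reconstructions)) {
    rec <- reconstructions[[j]]
    best <- rec$best
    for (i in seq_along(hypotheses)) {
      pres <- intersect(hypotheses[[i]]$members, best$tip.label)
      if (length(pres) < 2) { out[i, j] <- "-"; next }
      if (!.is_split(ape::unroot(best), pres)) { out[i, j] <- "nm"; next }
      sup <- clade_support(rec$boot, hypotheses[[i]]$members)
      raw[i, j] <- sup
      out[i, j] <- as.character(round(sup))
    }
  }
  structure(out, raw = raw, class = c("support_table", class(out)))
}

#' Majority-rule consensus with support values
#'
#' Wraps the standard majority-rule consensus and attaches, to each
#' internal edge, the percentage of input trees containing that
#' bipartition.
#'
#' @param ts A `multiPhylo`.
#' @param threshold Minimum bipartition frequency (>= 0.5).
#' @return A `phylo` whose `node.label` carries percent supports.
#' @export
majority_rule_consensus <- function(ts, threshold = 0.5) {
  ts <- as_treeset(ts)
  stopifnot(threshold >= 0.5)
  cons <- ape::consensus(ts, p = threshold + 1e-9)
  pp <- ape::prop.clades(cons, ts, rooted = FALSE)
  pp[is.na(pp)] <- length(ts)
  cons$node.label <- round(100 * pp / length(ts))
  cons
}
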