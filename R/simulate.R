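#' Per-operation random seed derivation
#'
#' Each stochastic operation draws from its own stream, derived from the
#' user seed and the operation name, so adding a stage to a workflow never
#' perturbs the draws of another stage.
#'
#' @param seed Integer user seed.
#' @param op Operation name.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, op) {
  h <- 0
  for (cc in utf8ToInt(op)) h <- (h * 131 + cc) %% 1009871
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% (2^31 - 1))
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a random phylogeny
#'
#' A pure-birth (Yule) tree conditioned on the number of tips, rescaled to
#' a target root-to-tip depth in expected substitutions per site, with an
#' optional single outgroup attached below the ingroup root.
#'
#' @param n_taxa Number of ingroup tips (>= 3).
#' @param birth Yule birth rate (default 1; affects node-depth profile
#'   before rescaling).
#' @param depth Root-to-tip depth after rescaling (default 0.5
#'   substitutions/site). Use `NA` to keep the raw Yule depth.
#' @param outgroup Label of an outgroup tip to attach on a stem of length
#'   `depth` below the root, or NULL.
#' @param seed Integer seed (deterministic output).
#' @return A rooted binary `phylo`.
#' @export
simulate_tree <- function(n_taxa, birth = 1, depth = 0.5, outgroup = NULL,
                          seed = 1) {
  if (n_taxa < 3) stop("n_taxa must be >= 3")
  tr <- .with_seed(derive_seed(seed, "simulate_tree"), {
    t0 <- ape::rphylo(n_taxa, birth = birth, death = 0)
    t0$tip.label <- sprintf("t%02d", seq_len(n_taxa))
    t0
  })
  if (!is.na(depth)) {
    h <- max(ape::node.depth.edgelength(tr)[seq_len(n_taxa)])
    tr$edge.length <- tr$edge.length / h * depth
  }
  if (!is.null(outgroup)) {
    stem <- if (is.na(depth)) max(ape::node.depth.edgelength(tr)) else depth
    og <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = outgroup,
               edge.length = stem, Nnode = 1L)
    class(og) <- "phylo"
    tr <- ape::bind.tree(tr, og, where = ape::Ntip(tr) + 1L)
  }
  tr
}

#' Simulate sequences along a tree
#'
#' Each column draws a rate class uniformly from the model's k categories,
#' takes that category's rate, draws the root state from the stationary
#' frequencies, and evolves down the tree with transition probabilities
#' exp(Q * rate * t). True per-site rates and classes are recorded so
#' downstream rate-classification can be validated against ground truth.
#'
#' @param tree A `phylo` with branch lengths in substitutions/site.
#' @param model A [subst_model].
#' @param n_sites Number of columns.
#' @param seed Integer seed.
#' @return A `simulated_dataset`: list with `true_tree`, `alignment`
#'   ([phy_alignment]), `true_site_rates`, `true_site_class` (0-based, 0 =
#'   slowest), and `config`.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "subst_model"),
            n_sites >= 1)
  if (any(abs(rowSums(model$Q)) > 1e-8)) stop("rate matrix rows must sum to 0")
  s <- model$s
  k <- model$k
  .with_seed(derive_seed(seed, "simulate_alignment"), {
    classes <- sample.int(k, n_sites, replace = TRUE)  # uniform class prior
    rates <- model$rates[classes]
    ntip <- ape::Ntip(tree)
    nnode <- ntip + tree$Nnode
    root <- ntip + 1L
    states <- matrix(0L, nnode, n_sites)
    states[root, ] <- sample.int(s, n_sites, replace = TRUE, prob = model$freq)
    ord <- rev(ape::postorder(tree))  # parent-before-child edge order
    ## unique rates -> shared transition matrices per (edge, class)
    for (e in ord) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      len <- tree$edge.length[e]
      for (j in unique(classes)) {
        idx <- which(classes == j)
        P <- transition_prob(model, len * model$rates[j])
        cum <- t(apply(P, 1, cumsum))
        u <- stats::runif(length(idx))
        from <- states[par, idx]
        ## inverse-CDF draw of child states
        states[child, idx] <- max.col(cum[from, , drop = FALSE] >= u,
                                      ties.method = "first")
      }
    }
    m <- matrix(model$states[states[seq_len(ntip), , drop = FALSE]],
                ntip, n_sites, dimnames = list(tree$tip.label, NULL))
    aln <- phy_alignment(m, alphabet = if (s == 4) "dna" else "aa")
    structure(list(true_tree = tree, alignment = aln,
                   true_site_rates = rates,
                   true_site_class = classes - 1L,
                   config = list(model = model$type, alpha = model$alpha,
                                 k = k, n_sites = n_sites, seed = seed)),
              class = "simulated_dataset")
  })
}

#' Scale the terminal branches of named taxa
#'
#' Used to plant artificial long-branch taxa that the root-to-tip ranking
#' stage should then detect.
#'
#' @param tree A `phylo`.
#' @param taxa Tip labels whose terminal branch is scaled.
#' @param multiplier Scale factor (>= 1).
#' @return The modified `phylo`.
#' @export
inject_long_branches <- function(tree, taxa, multiplier) {
  stopifnot(multiplier >= 1)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  tips <- match(taxa, tree$tip.label)
  e <- match(tips, tree$edge[, 2])
  tree$edge.length[e] <- tree$edge.length[e] * multiplier
  tree
}

#' Make a taxon rogue across a tree set
#'
#' In each tree, independently with probability `p_move`, the taxon is
#' pruned and regrafted onto a uniformly random branch (at a random point
#' along it, keeping its original terminal branch length). This emulates
#' the positional wandering of unstable taxa across bootstrap replicates.
#'
#' @param treeset A `multiPhylo`.
#' @param taxon Tip label.
#' @param p_move Per-tree regraft probability in `[0,1]`.
#' @param seed Integer seed.
#' @return A `multiPhylo`.
#' @export
inject_rogue <- function(treeset, taxon, p_move, seed = 1) {
  stopifnot(p_move >= 0, p_move <= 1)
  treeset <- as_treeset(treeset)
  if (!taxon %in% attr(treeset, "taxon_universe")) stop("taxon absent: ", taxon)
  if (p_move == 0) return(treeset)
  out <- .with_seed(derive_seed(seed, "inject_rogue"), {
    lapply(treeset, function(tr) {
      if (!taxon %in% tr$tip.label || stats::runif(1) > p_move) return(tr)
      tip <- match(taxon, tr$tip.label)
      tlen <- tr$edge.length[match(tip, tr$edge[, 2])]
      pruned <- ape::drop.tip(tr, taxon)
      e <- sample.int(nrow(pruned$edge), 1)
      pos <- stats::runif(1) * pruned$edge.length[e]
      graft <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = taxon,
                    edge.length = tlen, Nnode = 1L)
      class(graft) <- "phylo"
      ape::bind.tree(pruned, graft, where = pruned$edge[e, 2], position = pos)
    })
  })
  as_treeset(out)
}

#' Build an identity-controlled sequence pool
#'
#' For every reference sequence and every identity target q, emits a copy
#' with round((1-q)*L) random substitutions (at distinct positions, to a
#' different residue). Used to exercise dereplication with known pairwise
#' identities.
#'
#' @param reference Named character vector of sequences.
#' @param identity_targets Numeric vector of target identities in `[0,1]`.
#' @param n_copies Copies per (reference, target) pair (default 1).
#' @param alphabet "dna" or "aa".
#' @param seed Integer seed.
#' @return Named character vector: the pool (references not included).
#' @export
make_environmental_pool <- function(reference, identity_targets, n_copies = 1,
                                    alphabet = "dna", seed = 1) {
  if (!length(reference)) stop("empty reference set")
  stopifnot(all(identity_targets >= 0 & identity_targets <= 1))
  letters_ <- if (alphabet == "dna") DNA_STATES else AA_STATES
  .with_seed(derive_seed(seed, "make_environmental_pool"), {
    pool <- character(0)
    for (rn in names(reference)) {
      base <- strsplit(reference[[rn]], "")[[1]]
      L <- length(base)
      for (q in identity_targets) {
        nmut <- round((1 - q) * L)
        for (cp in seq_len(n_copies)) {
          x <- base
          if (nmut > 0) {
            pos <- sample.int(L, nmut)
            x[pos] <- vapply(x[pos], function(ch) {
              sample(setdiff(letters_, ch), 1)
            }, character(1))
          }
          pool[sprintf("%s_q%03d_c%d", rn, round(q * 100), cp)] <-
            paste(x, collapse = "")
        }
      }
    }
    pool
  })
}
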