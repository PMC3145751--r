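#' Per-site likelihoods by Felsenstein pruning
#'
#' Computes, for every alignment column c and rate class j, the likelihood
#' L[c,j] of the column under the model with rate multiplier r_j, by
#' postorder pruning with per-node rescaling (log accumulators) so large
#' trees do not underflow. The site log-likelihood is
#' log( (1/k) * sum_j L[c,j] ): rate classes have a uniform prior. Gap,
#' '?' and ambiguity characters are marginalized (partial vectors of ones /
#' indicator sums).
#'
#' @param aln A [phy_alignment] (single alphabet; for partitioned data see
#'   [total_loglik]).
#' @param tree A `phylo`; its leaves must all be present in `aln`. Branch
#'   lengths are used as given (not re-optimized).
#' @param model A [subst_model] matching the alphabet.
#' @return A list: `site_lnl` (length-S vector), `class_loglik` (k x S
#'   matrix of log L[c,j]), `rates`, `k`.
#' @export
site_likelihoods <- function(aln, tree, model) {
  stopifnot(inherits(aln, "phy_alignment"), inherits(tree, "phylo"),
            inherits(model, "subst_model"))
  missing_tax <- setdiff(tree$tip.label, aln$taxa)
  if (length(missing_tax)) {
    stop("tree leaves absent from alignment: ",
         paste(missing_tax, collapse = ", "))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths")
  }
  alphabet <- if (model$s == 4) "dna" else "aa"
  S <- ncol(aln$seq)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  ## tip partials, shared across rate classes
  tip_part <- lapply(seq_len(ntip), function(i) {
    .char_partials(aln$seq[tree$tip.label[i], ], alphabet)
  })
  po <- ape::postorder(tree)
  k <- model$k
  class_loglik <- matrix(NA_real_, k, S)
  for (j in seq_len(k)) {
    part <- vector("list", nnode)
    logscale <- matrix(0, 1, S)
    for (i in (ntip + 1L):nnode) part[[i]] <- matrix(1, model$s, S)
    for (e in po) {
      par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      P <- transition_prob(model, tree$edge.length[e] * model$rates[j])
      cp <- if (child <= ntip) tip_part[[child]] else part[[child]]
      part[[par]] <- part[[par]] * (P %*% cp)
      ## rescale the parent once all-children products start shrinking
      mx <- do.call(pmax, asplit(part[[par]], 1))
      small <- mx < 1e-80
      if (any(small)) {
        part[[par]][, small] <- sweep(part[[par]][, small, drop = FALSE],
                                      2, mx[small], "/")
        logscale[small] <- logscale[small] + log(mx[small])
      }
    }
    lik <- colSums(model$freq * part[[root]])
    class_loglik[j, ] <- log(lik) + as.numeric(logscale)
  }
  ## logSumExp over classes with uniform prior 1/k
  mx <- apply(class_loglik, 2, max)
  site_lnl <- mx + log(colSums(exp(sweep(class_loglik, 2, mx)))) - log(k)
  if (any(!is.finite(site_lnl))) {
    stop("zero total likelihood in at least one column")
  }
  list(site_lnl = as.numeric(site_lnl), class_loglik = class_loglik,
       rates = model$rates, k = k)
}

#' Total log-likelihood of an alignment on a tree
#'
#' Sum of per-site log-likelihoods. For partitioned alignments, pass a
#' named list of models (one per partition); each partition is scored under
#' its own model and the parts are summed.
#'
#' @param aln A [phy_alignment].
#' @param tree A `phylo`.
#' @param model A [subst_model], or a named list of them keyed by partition
#'   name.
#' @return A single number.
#' @export
total_loglik <- function(aln, tree, model) {
  if (inherits(model, "subst_model")) {
    return(sum(site_likelihoods(aln, tree, model)$site_lnl))
  }
  stopifnot(is.list(model), all(names(model) %in% names(aln$partitions)))
  sum(vapply(names(model), function(nm) {
    sum(site_likelihoods(get_partition(aln, nm), tree, model[[nm]])$site_lnl)
  }, numeric(1)))
}

#' Empirical-Bayes site-rate classification
#'
#' For each column, the posterior probability of each of the k discrete
#' gamma rate classes (uniform prior), the posterior-mean rate, and the MAP
#' class assignment. Classes are labeled 0 (slowest) through k-1 (fastest);
#' posterior ties are broken toward the slower class.
#'
#' @param aln A [phy_alignment] (one alphabet).
#' @param tree A `phylo` (branch lengths taken as given).
#' @param model A [subst_model] with k >= 2 categories.
#' @return A `site_rate_classification`: data frame with columns
#'   `original_index`, `post_mean_rate`, `class`, plus attributes
#'   `posterior` (k x S matrix), `k`, `rates`, `checksum`.
#' @export
classify_site_rates <- function(aln, tree, model) {
  stopifnot(model$k >= 2)
  sl <- site_likelihoods(aln, tree, model)
  k <- sl$k
  ## posterior \propto L[c,j]; softmax in log space
  mx <- apply(sl$class_loglik, 2, max)
  w <- exp(sweep(sl$class_loglik, 2, mx))
  post <- sweep(w, 2, colSums(w), "/")
  post_mean <- as.numeric(colSums(post * sl$rates))
  cls <- apply(post, 2, which.max) - 1L  # which.max takes the first (slower) tie
  df <- data.frame(original_index = aln$source_index,
                   post_mean_rate = post_mean,
                   class = as.integer(cls))
  structure(df, posterior = post, k = k, rates = sl$rates,
            checksum = .aln_checksum(aln), class = c("site_rate_classification",
                                                     class(df)))
}

#' Write a site-rate classification report
#'
#' TSV with 1-based original column index, partition, posterior-mean rate,
#' MAP class, and the per-class posterior probabilities.
#'
#' @param cls A `site_rate_classification`.
#' @param aln The classified [phy_alignment] (for partition names).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_rate_report <- function(cls, aln, path) {
  part <- character(ncol(aln$seq))
  for (p in names(aln$partitions)) part[aln$partitions[[p]]] <- p
  post <- t(attr(cls, "posterior"))
  colnames(post) <- paste0("p_class", seq_len(ncol(post)) - 1L)
  df <- cbind(data.frame(original_index = cls$original_index,
                         partition = part,
                         post_mean_rate = cls$post_mean_rate,
                         class = cls$class), round(post, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove columns assigned to given rate classes
#'
#' Deletes alignment columns whose MAP rate class is in `remove`,
#' optionally only inside one partition (by default all nucleotide
#' partitions, the usual target of fast-site stripping; protein partitions
#' are left untouched). Source indices are preserved.
#'
#' @param aln The [phy_alignment] the classification was computed on.
#' @param cls A `site_rate_classification` from [classify_site_rates] (run
#'   on `aln` itself or on the partition named in `restrict_to`).
#' @param remove Integer vector of class labels (0-based) to delete.
#' @param restrict_to Partition name, "dna" (default: every nucleotide
#'   partition), or "all".
#' @return A [phy_alignment] with the surviving columns.
#' @export
strip_rate_classes <- function(aln, cls, remove, restrict_to = "dna") {
  stopifnot(inherits(cls, "site_rate_classification"))
  k <- attr(cls, "k")
  if (!all(remove %in% 0:(k - 1))) stop("remove must be within 0..k-1")
  target_cols <- if (identical(restrict_to, "all")) {
    seq_len(ncol(aln$seq))
  } else if (identical(restrict_to, "dna")) {
    unlist(aln$partitions[aln$part_alphabet == "dna"], use.names = FALSE)
  } else {
    stopifnot(restrict_to %in% names(aln$partitions))
    aln$partitions[[restrict_to]]
  }
  ## classification may have been computed on the restricted partition only:
  ## match columns through original source indices
  if (nrow(cls) == ncol(aln$seq)) {
    if (!identical(attr(cls, "checksum"), .aln_checksum(aln))) {
      stop("classification does not match this alignment (checksum mismatch)")
    }
  } else if (!all(cls$original_index %in% aln$source_index[target_cols])) {
    stop("classification columns not found in the targeted partition")
  }
  hit <- cls$original_index[cls$class %in% remove]
  drop_cols <- target_cols[aln$source_index[target_cols] %in% hit]
  if (!length(drop_cols)) return(aln)
  keep <- setdiff(seq_len(ncol(aln$seq)), drop_cols)
  new_parts <- lapply(aln$partitions, function(p) {
    match(intersect(keep, p), keep)
  })
  for (nm in names(new_parts)) attr(new_parts[[nm]], "alphabet") <- aln$part_alphabet[[nm]]
  out <- phy_alignment(aln$seq[, keep, drop = FALSE], alphabet = aln$alphabet,
                       partitions = new_parts,
                       source_index = aln$source_index[keep])
  out$part_alphabet <- aln$part_alphabet
  out
}

#' Estimate the gamma shape parameter
#'
#' One-dimensional maximum-likelihood estimate of the discrete-gamma shape
#' alpha on a fixed tree and fixed model parameters, by Brent search
#' (tolerance 1e-4). All other model parameters are taken from `model`.
#'
#' @param aln A [phy_alignment].
#' @param tree A `phylo`.
#' @param model A [subst_model]; its alpha is ignored.
#' @param bounds Search interval `c(lo, hi)`, 0 < lo < hi.
#' @return The estimate `alpha_hat` with attribute `loglik`; a warning is
#'   issued when the optimum is pinned at a bound (e.g. invariant-only
#'   data pushing alpha to the lower bound).
#' @export
fit_gamma_shape <- function(aln, tree, model, bounds = c(0.05, 20)) {
  stopifnot(bounds[1] > 0, bounds[1] < bounds[2])
  f <- function(a) {
    m <- subst_model(model$type, frequencies = model$freq,
                     exchangeabilities = if (model$type == "gtr") model$exch else NULL,
                     alpha = a, k = model$k)
    ll <- sum(site_likelihoods(aln, tree, m)$site_lnl)
    if (!is.finite(ll)) stop("non-finite likelihood at alpha=", a)
    -ll
  }
  opt <- stats::optimize(f, interval = bounds, tol = 1e-4)
  a <- opt$minimum
  span <- bounds[2] - bounds[1]
  if (a - bounds[1] < 0.02 * span || bounds[2] - a < 0.02 * span) {
    ## check the bound itself: optimize() never returns the endpoints
    end <- if (a - bounds[1] < 0.02 * span) bounds[1] else bounds[2]
    if (f(end) <= opt$objective) a <- end
    warning("alpha estimate pinned at search bound (", format(a), ")")
  }
  structure(a, loglik = -opt$objective)
}
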