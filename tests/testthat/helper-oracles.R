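## Independent oracles used across the suite. Everything here is written
## against the definitions, not against the package implementation.

## ---- brute-force likelihood by exhaustive state enumeration -------------
## Sums over every assignment of states to internal nodes, for every rate
## class, exactly as the likelihood definition reads. Exponential cost;
## only for tiny trees.
brute_force_site_lik <- function(column, tree, model) {
  s <- model$s
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  tipstate <- lapply(seq_len(ntip), function(i) {
    ch <- column[tree$tip.label[i]]
    v <- phylorobust:::.char_partials(ch, if (s == 4) "dna" else "aa")
    which(v[, 1] > 0)
  })
  total <- 0
  for (j in seq_len(model$k)) {
    P <- lapply(seq_len(nrow(tree$edge)), function(e) {
      transition_prob(model, tree$edge.length[e] * model$rates[j])
    })
    internal <- (ntip + 1L):nnode
    grid <- as.matrix(expand.grid(rep(list(seq_len(s)), length(internal))))
    lik_j <- 0
    for (g in seq_len(nrow(grid))) {
      assign_state <- integer(nnode)
      assign_state[internal] <- grid[g, ]
      prob_assign <- model$freq[assign_state[root]]
      for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
        if (child <= ntip) {
          prob_assign <- prob_assign * sum(P[[e]][assign_state[par], tipstate[[child]]])
        } else {
          prob_assign <- prob_assign * P[[e]][assign_state[par], assign_state[child]]
        }
      }
      lik_j <- lik_j + prob_assign
    }
    total <- total + lik_j / model$k
  }
  log(total)
}

brute_force_total <- function(aln, tree, model) {
  sum(vapply(seq_len(ncol(aln$seq)), function(c_) {
    brute_force_site_lik(aln$seq[, c_], tree, model)
  }, numeric(1)))
}

## ---- minimal independent Newick parser ----------------------------------
## Token-level recursive parser returning the set of non-trivial splits
## (each split = sorted ";"-joined labels of the smaller side) plus tip
## branch lengths. Used to cross-check the reader/writer round trip.
newick_splits <- function(txt) {
  txt <- sub(";\\s*$", "", trimws(txt))
  pos <- 1L
  n <- nchar(txt)
  tips <- character(0)
  splits <- character(0)
  lens <- numeric(0)
  peek <- function() substr(txt, pos, pos)
  read_until <- function(stops) {
    start <- pos
    while (pos <= n && !(substr(txt, pos, pos) %in% stops)) pos <<- pos + 1L
    substr(txt, start, pos - 1L)
  }
  parse_clade <- function() {
    members <- character(0)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        members <- c(members, parse_clade())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("bad newick")
      }
      read_until(c(":", ",", ")", ""))  # internal label
      if (peek() == ":") { pos <<- pos + 1L; read_until(c(",", ")", "")) }
      splits <<- c(splits, paste(sort(members), collapse = ";"))
      members
    } else {
      lab <- read_until(c(":", ",", ")", ""))
      blen <- 0
      if (peek() == ":") { pos <<- pos + 1L; blen <- as.numeric(read_until(c(",", ")", ""))) }
      tips <<- c(tips, lab)
      lens[lab] <<- blen
      lab
    }
  }
  parse_clade()
  ## canonicalize: represent each split by its smaller side (or
  ## lexicographically first at equal size), drop trivial ones
  all_tips <- sort(tips)
  canon <- vapply(splits, function(sp) {
    a <- strsplit(sp, ";")[[1]]
    b <- setdiff(all_tips, a)
    if (length(a) < 2 || length(b) < 2) return(NA_character_)
    sa <- paste(sort(a), collapse = ";"); sb <- paste(sort(b), collapse = ";")
    if (length(a) < length(b) || (length(a) == length(b) && sa < sb)) sa else sb
  }, character(1))
  list(tips = all_tips, splits = sort(unique(canon[!is.na(canon)])),
       tip_lengths = lens[all_tips])
}

## ---- quartet resolution oracle ------------------------------------------
## Resolution of quartet {a,b,c,d} in a tree by reduction to the induced
## 4-tip tree and cherry detection; returns "ab", "ac", "ad" (partner of a)
## or NA for unresolved/absent.
quartet_resolution <- function(tree, q) {
  if (!all(q %in% tree$tip.label)) return(NA_character_)
  qt <- ape::unroot(ape::keep.tip(tree, q))
  if (qt$Nnode < 2) return(NA_character_)  # star
  tipidx <- match(q[1], qt$tip.label)
  par <- qt$edge[match(tipidx, qt$edge[, 2]), 1]
  sibs <- qt$edge[qt$edge[, 1] == par, 2]
  partner <- setdiff(sibs[sibs <= ape::Ntip(qt)], tipidx)
  if (!length(partner)) {
    ## a's parent subtends the other cherry's parent; partner is the
    ## remaining tip hanging off a's parent side
    others <- setdiff(seq_len(4), tipidx)
    cherries <- lapply(others, function(t2) {
      p2 <- qt$edge[match(t2, qt$edge[, 2]), 1]
      s2 <- qt$edge[qt$edge[, 1] == p2, 2]
      setdiff(s2[s2 <= ape::Ntip(qt)], t2)
    })
    for (i in seq_along(others)) {
      if (length(cherries[[i]]) && all(cherries[[i]] != tipidx)) {
        ## others[i] pairs with cherries[[i]]; a pairs with the leftover
        paired <- c(others[i], cherries[[i]][1])
        partner <- setdiff(others, paired)
        break
      }
    }
  }
  if (!length(partner)) return(NA_character_)
  paste0("q", match(qt$tip.label[partner[1]], q))
}

## leaf stability by direct enumeration of the definition
oracle_leaf_stability <- function(ts, variant = "difference") {
  taxa <- sort(unique(unlist(lapply(ts, `[[`, "tip.label"))))
  n <- length(taxa)
  combs <- utils::combn(n, 4)
  qscore <- numeric(ncol(combs))
  for (ci in seq_len(ncol(combs))) {
    q <- taxa[combs[, ci]]
    res <- table(factor(vapply(ts, function(tr) {
      r <- quartet_resolution(tr, q)
      if (is.na(r)) "na" else r
    }, character(1)), levels = c("q2", "q3", "q4", "na")))
    f <- res[c("q2", "q3", "q4")]
    if (sum(f) == 0) { qscore[ci] <- NA; next }
    f <- sort(as.numeric(f / sum(f)), decreasing = TRUE)
    qscore[ci] <- switch(variant,
                         difference = f[1] - f[2],
                         max = f[1])
  }
  vapply(seq_len(n), function(i) {
    inq <- colSums(combs == i) > 0
    mean(qscore[inq], na.rm = TRUE)
  }, numeric(1)) -> st
  stats::setNames(st, taxa)
}

## ---- affine-gap global alignment score oracle (Gotoh, free ends) --------
oracle_overlap_score <- function(a, b, match = 1, mismatch = 0,
                                 gap_open = 5, gap_ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0; M[, 1] <- 0  # free leading gaps
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
    }
  }
  ## free trailing gaps: best over last row/column
  max(M[n + 1, ], M[, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## random resolved tree with exponential branch lengths
rand_tree <- function(n, seed, mean_len = 0.2) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::rexp(nrow(tr$edge), 1 / mean_len)
  tr
}

## random DNA alignment (uniform residues, optional gap fraction)
rand_aln <- function(taxa, n_sites, seed, gap_frac = 0) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), length(taxa) * n_sites, replace = TRUE)
  if (gap_frac > 0) {
    gaps <- sample(length(chars), round(gap_frac * length(chars)))
    chars[gaps] <- "-"
  }
  m <- matrix(chars, length(taxa), n_sites, dimnames = list(taxa, NULL))
  phy_alignment(m, alphabet = "dna")
}
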