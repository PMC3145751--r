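#' Jukes-Cantor distance matrix
#'
#' Pairwise JC69 distances computed on the columns where both taxa carry a
#' definite residue (gap, '?' and ambiguity characters are excluded
#' pairwise). Saturated pairs (mismatch proportion >= 0.75) are capped at
#' `cap` with a warning. On mixed nucleotide+protein datasets the 4-state
#' correction is applied to the pooled mismatch proportion; this is part
#' of the deliberately simple distance stand-in, not a likelihood-grade
#' protein distance.
#'
#' @param aln A [phy_alignment] (>= 2 taxa).
#' @param cap Distance assigned to saturated pairs (default 5
#'   substitutions/site).
#' @param weights Optional per-column non-negative weights (used by the
#'   bootstrap; default all 1).
#' @param zero_shared "error" (default) or "cap": what to do with taxon
#'   pairs sharing no scored columns. Bootstrap replicates of very
#'   fragmentary taxa can hit such pairs, where capping is the only
#'   sensible continuation.
#' @return Symmetric matrix with zero diagonal.
#' @export
jc_distance_matrix <- function(aln, cap = 5, weights = NULL,
                               zero_shared = c("error", "cap")) {
  zero_shared <- match.arg(zero_shared)
  stopifnot(inherits(aln, "phy_alignment"), nrow(aln$seq) >= 2)
  m <- aln$seq
  n <- nrow(m); S <- ncol(m)
  w <- weights %||% rep(1, S)
  stopifnot(length(w) == S, all(w >= 0))
  definite <- !(m %in% c("-", "?", ".", "N", "X"))
  dim(definite) <- dim(m)
  lv <- sort(unique(as.vector(m[definite])))
  matches <- matrix(0, n, n)
  for (ch in lv) {
    I <- (m == ch) & definite
    storage.mode(I) <- "double"
    matches <- matches + tcrossprod(sweep(I, 2, w, "*"), I)
  }
  D <- definite; storage.mode(D) <- "double"
  shared <- tcrossprod(sweep(D, 2, w, "*"), D)
  none <- shared == 0 & upper.tri(shared)
  if (any(none)) {
    if (zero_shared == "error") {
      stop("at least one taxon pair shares no scored columns")
    }
    warning(sum(none), " pair(s) share no scored columns; capped at ", cap)
  }
  p <- 1 - matches / pmax(shared, 1)
  p[none | t(none)] <- 1  # forced into the saturation cap below
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- p >= 0.75 - 1e-12
  ok <- !sat
  d[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  if (any(sat & upper.tri(sat))) {
    warning(sum(sat & upper.tri(sat)), " saturated pair(s) capped at ", cap)
    d[sat] <- cap
  }
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Neighbor-joining tree (stand-in inference)
#'
#' Standard NJ on a distance matrix. This is the package's deliberately
#' lightweight stand-in for full ML/Bayesian inference: robustness
#' workflows that have externally inferred trees should ingest them
#' instead. Negative NJ branch lengths are clamped to 0 with the deficit
#' moved to the sibling edge, preserving path lengths through the parent.
#'
#' @param d Symmetric distance matrix (>= 3 taxa).
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(d) {
  if (any(!is.finite(d))) stop("non-finite distances")
  stopifnot(nrow(d) >= 3)
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    sibs <- setdiff(which(tr$edge[, 1] == tr$edge[e, 1]), e)
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- max(0, tr$edge.length[sibs[1]] + deficit)
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Bootstrap tree set under the NJ stand-in
#'
#' Resamples alignment columns with replacement, recomputes the JC
#' distance matrix (via column weights) and the NJ tree for each
#' replicate. Deterministic given the seed.
#'
#' @param aln A [phy_alignment].
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @param cap Saturation cap passed to [jc_distance_matrix].
#' @return A `multiPhylo` of `n_reps` trees.
#' @export
bootstrap_trees <- function(aln, n_reps, seed = 1, cap = 5) {
  stopifnot(n_reps >= 1)
  S <- ncol(aln$seq)
  .with_seed(derive_seed(seed, "bootstrap_trees"), {
    trees <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      w <- tabulate(sample.int(S, S, replace = TRUE), nbins = S)
      d <- suppressWarnings(jc_distance_matrix(aln, cap = cap, weights = w,
                                               zero_shared = "cap"))
      trees[[r]] <- nj_tree(d)
    }
    as_treeset(trees)
  })
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch with free terminal gaps (match 1, mismatch 0, affine
#' gap open 5 / extend 1): identity = matches / aligned columns, where the
#' aligned region excludes terminal-gap overhangs.
#'
#' @param a,b Non-empty sequences (character strings).
#' @return Identity in `[0,1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  letters_ <- unique(strsplit(paste0(toupper(a), toupper(b)), "")[[1]])
  sm <- diag(1, length(letters_))
  dimnames(sm) <- list(letters_, letters_)
  pa <- Biostrings::pairwiseAlignment(toupper(a), toupper(b), type = "overlap",
                                      substitutionMatrix = sm,
                                      gapOpening = 5, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  sum(p == s & p != "-") / length(p)
}

#' Greedy dereplication of a sequence pool
#'
#' Scans sequences in the stated order; a sequence is retained iff its
#' identity to every already-retained sequence is below `threshold`.
#' Discarded sequences are recorded against the retained representative
#' that absorbed them (the first one at or above threshold).
#'
#' @param seqs Named character vector.
#' @param threshold Identity threshold in (0, 1].
#' @param order "input" or "length-desc".
#' @return List: `retained` (named character vector) and `clusters`
#'   (data frame member / representative / identity).
#' @export
dereplicate <- function(seqs, threshold = 0.98, order = c("input", "length-desc")) {
  order <- match.arg(order)
  stopifnot(threshold > 0, threshold <= 1)
  if (order == "length-desc") seqs <- seqs[order(-nchar(seqs), names(seqs))]
  retained <- character(0)
  clusters <- data.frame(member = character(0), representative = character(0),
                         identity = numeric(0))
  for (nm in names(seqs)) {
    absorbed <- FALSE
    for (rn in names(retained)) {
      id <- pairwise_identity(seqs[[nm]], retained[[rn]])
      if (id >= threshold) {
        clusters <- rbind(clusters, data.frame(member = nm, representative = rn,
                                               identity = id))
        absorbed <- TRUE
        break
      }
    }
    if (!absorbed) {
      retained[nm] <- seqs[[nm]]
      clusters <- rbind(clusters, data.frame(member = nm, representative = nm,
                                             identity = 1))
    }
  }
  list(retained = retained, clusters = clusters)
}

#' Configuration for a synthetic robustness experiment
#'
#' Defines the simulated study conditions and the dataset-variant grid.
#' Defaults describe a two-partition (nucleotide + protein) dataset with a
#' handful of planted long-branch taxa and fragmentary ("rogue") taxa,
#' analyzed at bootstrap depth suitable for desk-scale replication.
#'
#' @param n_taxa Ingroup taxa (an outgroup tip "OUT" is added).
#' @param n_sites Named vector: columns for the `dna` and `aa` partitions.
#' @param alpha_dna,alpha_aa Gamma shapes for the two partitions.
#' @param k_dna,k_aa Rate categories (k = 8 for the nucleotide partition,
#'   matching the 0..7 class labels of fast-site stripping).
#' @param tree_depth Ingroup root-to-tip depth (substitutions/site).
#' @param long_branch List `n`, `multiplier`: taxa whose terminal branch
#'   is scaled.
#' @param rogue List `n`, `keep_fraction`: taxa made unstable by erasing
#'   all but that fraction of their columns (fragmentary sequences, the
#'   situation of partial environmental reads or single-gene taxa, whose
#'   sparse signal lets their placement wander across replicates).
#' @param n_boot Bootstrap replicates per variant.
#' @param n_remove_lb,n_remove_us Taxa removed in the -LB / -us variants.
#' @param strip_levels List of rate-class sets for the stripping variants.
#' @param include_env Add the environmental-pool variant?
#' @param env List `n_refs`, `identity_targets`, `threshold` for pool
#'   construction and dereplication.
#' @param stability_m Quartets sampled for leaf-stability scoring.
#' @param hypotheses Optional list of [clade_hypothesis]; default derives
#'   a few true clades from the simulated tree.
#' @param seed Integer seed governing every stage.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_taxa = 40,
                              n_sites = c(dna = 1000, aa = 300),
                              alpha_dna = 0.5, alpha_aa = 0.5,
                              k_dna = 8L, k_aa = 4L,
                              tree_depth = 0.8,
                              long_branch = list(n = 5, multiplier = 10),
                              rogue = list(n = 3, keep_fraction = 0.06),
                              n_boot = 200,
                              n_remove_lb = 5, n_remove_us = 3,
                              strip_levels = list(7L, c(7L, 6L), c(7L, 6L, 5L)),
                              include_env = TRUE,
                              env = list(n_refs = 3,
                                         identity_targets = c(1, 0.99, 0.90),
                                         threshold = 0.98),
                              stability_m = 12000,
                              hypotheses = NULL,
                              seed = 1) {
  stopifnot(n_taxa >= 8, all(n_sites >= 1), n_boot >= 1,
            n_remove_lb < n_taxa, n_remove_us < n_taxa)
  structure(as.list(environment()), class = "experiment_config")
}

#' Simulate the base dataset of an experiment
#'
#' Yule ingroup tree plus outgroup, with planted long-branch taxa and
#' planted rogue taxa; a GTR+Gamma nucleotide partition and an LG+Gamma
#' protein partition evolved on that tree and concatenated. Long-branch
#' taxa are the ingroup tips that already carry the longest terminal
#' branches, scaled by the configured multiplier (so the planted signal
#' dominates stochastic branch-length variation). Rogue taxa are made
#' fragmentary: all but a configured fraction of their columns is erased,
#' leaving too little signal for a stable placement without creating a
#' long branch.
#'
#' @param cfg An [experiment_config].
#' @return List: `alignment`, `true_tree`, `outgroup`, `lb_taxa`,
#'   `rogue_taxa`, `true_site_class` (nucleotide partition), models.
#' @export
simulate_experiment_data <- function(cfg) {
  tree <- simulate_tree(cfg$n_taxa, depth = cfg$tree_depth, outgroup = "OUT",
                        seed = cfg$seed)
  ingroup <- setdiff(tree$tip.label, "OUT")
  term <- tree$edge.length[match(match(ingroup, tree$tip.label), tree$edge[, 2])]
  lb_taxa <- sort(ingroup[order(-term)][seq_len(cfg$long_branch$n)])
  rogue_taxa <- .with_seed(derive_seed(cfg$seed, "plant_taxa"), {
    sort(sample(setdiff(ingroup, lb_taxa), cfg$rogue$n))
  })
  tree <- inject_long_branches(tree, lb_taxa, cfg$long_branch$multiplier)
  model_dna <- subst_model("gtr", alpha = cfg$alpha_dna, k = cfg$k_dna)
  model_aa <- subst_model("lg", alpha = cfg$alpha_aa, k = cfg$k_aa)
  sim_dna <- simulate_alignment(tree, model_dna, cfg$n_sites[["dna"]],
                                seed = derive_seed(cfg$seed, "part_dna"))
  sim_aa <- simulate_alignment(tree, model_aa, cfg$n_sites[["aa"]],
                               seed = derive_seed(cfg$seed, "part_aa"))
  aln <- concatenate(list(dna = sim_dna$alignment, aa = sim_aa$alignment))
  ## fragment the rogues: keep only a sparse random subset of their columns
  .with_seed(derive_seed(cfg$seed, "fragment"), {
    S <- ncol(aln$seq)
    for (rg in rogue_taxa) {
      drop <- sample.int(S, round((1 - cfg$rogue$keep_fraction) * S))
      aln$seq[rg, drop] <- "-"
    }
  })
  list(alignment = aln, true_tree = tree, outgroup = "OUT",
       lb_taxa = lb_taxa, rogue_taxa = rogue_taxa,
       true_site_class = sim_dna$true_site_class,
       model_dna = model_dna, model_aa = model_aa)
}

## default hypotheses: true ingroup clades of the simulated tree, one per
## size band, named H1..; gives the support table something real to score
.default_hypotheses <- function(true_tree, outgroup, k = 5) {
  ntip <- ape::Ntip(true_tree)
  clades <- list()
  for (node in (ntip + 2L):(ntip + true_tree$Nnode)) {
    tips <- ape::extract.clade(true_tree, node)$tip.label
    if (length(tips) >= 3 && length(tips) <= ntip - 3 &&
        !any(outgroup %in% tips)) {
      clades[[length(clades) + 1L]] <- tips
    }
  }
  sizes <- vapply(clades, length, integer(1))
  keep <- clades[order(-sizes)][unique(round(seq(1, length(clades),
                                                 length.out = min(k, length(clades)))))]
  lapply(seq_along(keep), function(i) {
    clade_hypothesis(sprintf("H%d", i), keep[[i]], "true-clade")
  })
}

#' Run the dataset-variant experiment grid
#'
#' Builds the variant grid in dependency order -- base, rate-stripped
#' (-7, -76, -765), long-branch-removed (-LB), unstable-removed (-us),
#' combined (-LB-us), and environmental-pool (+Env) -- infers a best tree
#' and bootstrap set per variant with the NJ stand-in (or ingests supplied
#' trees), and scores every variant with tree length, treeness, and mean
#' leaf stability with its 95% CI, plus a clade-support table across
#' variants. Removal lists are frozen from the base variant's trees before
#' any derived variant is built. Fully deterministic given the seed.
#'
#' @param cfg An [experiment_config].
#' @param data Optional pre-simulated data from
#'   [simulate_experiment_data] (so several grids can share one dataset).
#' @param ingest Optional named list `variant -> list(best, boot)` of
#'   externally inferred trees, bypassing the NJ stand-in for those
#'   variants.
#' @param variants Variant names to build (default the full grid).
#' @return An `experiment_report`: list with `variants` (metrics data
#'   frame), `support` ([support_table]), `manifests`, `trees`,
#'   `provenance`.
#' @export
run_experiment <- function(cfg, data = NULL, ingest = NULL, variants = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(data)) data <- simulate_experiment_data(cfg)
  aln <- data$alignment
  outgroup <- data$outgroup
  grid <- variants %||% c("base",
                          paste0("-", vapply(cfg$strip_levels, paste, "", collapse = "")),
                          "-LB", "-us", "-LB-us", if (cfg$include_env) "+Env")
  if (!"base" %in% grid) grid <- c("base", grid)
  if (anyDuplicated(grid)) stop("variant names must be unique")

  infer <- function(a, variant) {
    if (!is.null(ingest)) {
      if (is.null(ingest[[variant]])) {
        stop("ingest map missing variant(s): ",
             paste(setdiff(grid, names(ingest)), collapse = ", "))
      }
      return(ingest[[variant]])
    }
    ## fragmentary (rogue) taxa can share no scored columns with each
    ## other; inside the pipeline such pairs take the saturation cap,
    ## exactly as in the bootstrap replicates
    d <- suppressWarnings(jc_distance_matrix(a, zero_shared = "cap"))
    list(best = nj_tree(d),
         boot = bootstrap_trees(a, cfg$n_boot,
                                seed = derive_seed(cfg$seed, paste0("boot", variant))))
  }

  trees <- list()
  alns <- list(base = aln)
  trees$base <- infer(aln, "base")

  manifests <- list()
  ## frozen removal lists, computed from the base variant's trees only
  lb_list <- us_list <- character(0)
  if (any(grid %in% c("-LB", "-LB-us"))) {
    lb_list <- rank_long_branches(list(base = trees$base$best), outgroup,
                                  cfg$n_remove_lb)
    manifests$long_branch_removed <- lb_list
  }
  if (any(grid %in% c("-us", "-LB-us"))) {
    us_list <- rank_unstable(trees$base$boot, cfg$n_remove_us,
                             exclude = outgroup,
                             mode = "sampled", m = cfg$stability_m,
                             seed = derive_seed(cfg$seed, "rank_unstable"))
    manifests$unstable_removed <- us_list
  }
  ## site-rate classification of the nucleotide partition on the base tree
  cls <- NULL
  strip_names <- paste0("-", vapply(cfg$strip_levels, paste, "", collapse = ""))
  if (any(strip_names %in% grid)) {
    dna <- get_partition(aln, "dna")
    cls <- classify_site_rates(dna, trees$base$best, data$model_dna)
    manifests$site_classes <- table(factor(cls$class, levels = 0:(cfg$k_dna - 1)))
  }

  for (v in setdiff(grid, "base")) {
    a <- if (v %in% strip_names) {
      lev <- cfg$strip_levels[[match(v, strip_names)]]
      strip_rate_classes(aln, cls, remove = lev, restrict_to = "dna")
    } else if (v == "-LB") {
      remove_taxa(aln, lb_list)
    } else if (v == "-us") {
      remove_taxa(aln, us_list)
    } else if (v == "-LB-us") {
      remove_taxa(aln, union(lb_list, us_list))
    } else if (v == "+Env") {
      .add_env_pool(aln, cfg)
    } else {
      stop("unknown variant: ", v)
    }
    alns[[v]] <- a
    trees[[v]] <- infer(a, v)
  }

  hyps <- cfg$hypotheses %||% .default_hypotheses(data$true_tree, outgroup)
  metrics <- do.call(rbind, lapply(grid, function(v) {
    a <- alns[[v]]
    ls <- leaf_stability(trees[[v]]$boot, mode = "sampled", m = cfg$stability_m,
                         seed = derive_seed(cfg$seed, paste0("ls", v)))
    widths <- vapply(a$partitions, length, integer(1))
    data.frame(variant = v, n_taxa = nrow(a$seq),
               sites_dna = if ("dna" %in% names(widths)) widths[["dna"]] else NA_integer_,
               sites_aa = if ("aa" %in% names(widths)) widths[["aa"]] else NA_integer_,
               tree_length = tree_length(trees[[v]]$best),
               treeness = treeness(trees[[v]]$best),
               leaf_stability = attr(ls, "mean"),
               ci95 = attr(ls, "ci_half"))
  }))
  rownames(metrics) <- NULL
  sup <- support_table(hyps, trees)
  structure(list(variants = metrics, support = sup, manifests = manifests,
                 trees = trees, hypotheses = hyps,
                 provenance = list(seed = cfg$seed, n_boot = cfg$n_boot,
                                   n_taxa = cfg$n_taxa,
                                   n_sites = as.list(cfg$n_sites),
                                   inference = if (is.null(ingest)) "nj-bootstrap"
                                               else "ingested")),
            class = "experiment_report")
}

.add_env_pool <- function(aln, cfg) {
  dna_cols <- aln$partitions[["dna"]]
  ingroup <- setdiff(rownames(aln$seq), "OUT")
  refs <- ingroup[seq_len(cfg$env$n_refs)]
  ref_seqs <- stats::setNames(
    apply(aln$seq[refs, dna_cols, drop = FALSE], 1, paste, collapse = ""), refs)
  pool <- make_environmental_pool(ref_seqs, cfg$env$identity_targets,
                                  seed = derive_seed(cfg$seed, "env_pool"))
  keep <- dereplicate(pool, cfg$env$threshold)$retained
  ## drop retained pool entries that still match an existing taxon's row
  keep <- keep[vapply(keep, function(sq) {
    all(vapply(ref_seqs, function(r) pairwise_identity(sq, r) < cfg$env$threshold,
               logical(1)))
  }, logical(1))]
  if (!length(keep)) return(aln)
  dna_part <- get_partition(aln, "dna")
  env_m <- do.call(rbind, strsplit(unname(keep), ""))
  rownames(env_m) <- names(keep)
  dna_env <- phy_alignment(rbind(dna_part$seq, env_m), alphabet = "dna",
                           source_index = dna_part$source_index)
  concatenate(list(dna = dna_env, aa = get_partition(aln, "aa")))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report:", nrow(x$variants), "variants, seed",
      x$provenance$seed, "\n")
  print(x$variants, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Render an experiment report to files
#'
#' Writes the metrics table (columns Tree Length, Treeness, LStability,
#' 95% CI), the support table (cells restricted to integer percents, "nm"
#' and "-"), the removal manifests, and/or a JSON serialization that
#' round-trips through [read_experiment_report].
#'
#' @param rep An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @param format Subset of "tsv", "markdown", "json".
#' @return Invisibly, the written file paths.
#' @export
render_report <- function(rep, dir, format = c("tsv", "markdown", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  metrics <- rep$variants
  disp <- data.frame(Analysis = metrics$variant,
                     `Tree Length` = round(metrics$tree_length, 2),
                     Treeness = round(metrics$treeness, 2),
                     LStability = round(metrics$leaf_stability, 2),
                     `95% CI` = round(metrics$ci95, 2),
                     check.names = FALSE)
  if ("tsv" %in% format) {
    p <- file.path(dir, "metrics.tsv")
    utils::write.table(disp, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(dir, "support.tsv")
    utils::write.table(cbind(hypothesis = rownames(rep$support),
                             as.data.frame(unclass(rep$support))),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    if (length(rep$manifests)) {
      p <- file.path(dir, "manifests.tsv")
      mf <- data.frame(
        item = rep(names(rep$manifests),
                   vapply(rep$manifests, length, integer(1))),
        value = unlist(lapply(rep$manifests, function(x) {
          if (is.table(x)) paste0(names(x), "=", as.integer(x)) else as.character(x)
        }), use.names = FALSE))
      utils::write.table(mf, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if ("markdown" %in% format) {
    p <- file.path(dir, "report.md")
    md <- c("# Experiment report", "",
            .md_table(disp), "",
            .md_table(cbind(Hypothesis = rownames(rep$support),
                            as.data.frame(unclass(rep$support)))))
    writeLines(md, p)
    paths <- c(paths, p)
  }
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(list(
      variants = rep$variants,
      support = list(cells = as.data.frame(unclass(rep$support)),
                     hypotheses = rownames(rep$support)),
      manifests = lapply(rep$manifests, function(x) {
        if (is.table(x)) stats::setNames(as.list(as.integer(x)), names(x))
        else as.character(x)
      }),
      provenance = rep$provenance
    ), p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

.md_table <- function(df) {
  hdr <- paste("|", paste(colnames(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(hdr, sep, rows)
}

#' Read back a JSON experiment report
#'
#' @param path Path written by [render_report] with the "json" format.
#' @return A list with `variants`, `support`, `manifests`, `provenance`
#'   fields matching the originals.
#' @export
read_experiment_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sup <- as.matrix(raw$support$cells)
  rownames(sup) <- raw$support$hypotheses
  list(variants = raw$variants, support = sup,
       manifests = raw$manifests, provenance = raw$provenance)
}
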