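#' Per-site log-likelihood matrix for candidate topologies
#'
#' Row i holds the per-site log-likelihoods of the alignment under
#' candidate tree i. Partitioned alignments are scored per partition under
#' the matching model and the per-site values concatenated in column
#' order.
#'
#' @param aln A [phy_alignment].
#' @param candidates Named list of `phylo` objects (>= 2).
#' @param model A [subst_model] or named list of them (one per partition).
#' @return A `site_lnl_matrix`: candidates x columns numeric matrix.
#' @export
site_lnl_matrix <- function(aln, candidates, model) {
  stopifnot(length(candidates) >= 2, !is.null(names(candidates)))
  rows <- lapply(candidates, function(tr) {
    foreign <- setdiff(tr$tip.label, aln$taxa)
    if (length(foreign)) {
      stop("candidate contains taxa absent from the alignment: ",
           paste(foreign, collapse = ", "))
    }
    if (inherits(model, "subst_model")) {
      site_likelihoods(aln, tr, model)$site_lnl
    } else {
      unlist(lapply(names(model), function(nm) {
        site_likelihoods(get_partition(aln, nm), tr, model[[nm]])$site_lnl
      }), use.names = FALSE)
    }
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(candidates)
  structure(m, checksum = .aln_checksum(aln),
            class = c("site_lnl_matrix", class(m)))
}

#' RELL resampling of per-site log-likelihoods
#'
#' Each replicate draws ceil(r * n_sites) columns with replacement -- the
#' same column draw for every candidate, which is what preserves the
#' between-candidate correlation of the replicate totals -- and sums each
#' candidate's entries.
#'
#' @param m Candidates x sites matrix of per-site log-likelihoods.
#' @param n_reps Number of replicates.
#' @param scale Resampling scale r > 0 (r = 1 is the ordinary bootstrap).
#' @param seed Integer seed.
#' @return Candidates x n_reps matrix of replicate total log-likelihoods.
#' @export
rell_resample <- function(m, n_reps, scale = 1, seed = 1) {
  stopifnot(n_reps >= 1, scale > 0)
  S <- ncol(m)
  draw_n <- ceiling(scale * S)
  .with_seed(derive_seed(seed, paste0("rell", scale)), {
    ## shared column draw across candidates, realized as per-replicate
    ## column count vectors so the totals come from one matrix product
    counts <- matrix(0, S, n_reps)
    for (r in seq_len(n_reps)) {
      counts[, r] <- tabulate(sample.int(S, draw_n, replace = TRUE), nbins = S)
    }
    out <- unclass(m) %*% counts
    dimnames(out) <- list(rownames(m), NULL)
    out
  })
}

#' RELL-based KH and SH topology tests
#'
#' Computes, for every candidate, the (weighted) Kishino-Hasegawa p-value
#' against the maximum-likelihood candidate and the (weighted)
#' Shimodaira-Hasegawa p-value with multiplicity correction. The null
#' distribution is built from centered RELL replicate totals. In the
#' weighted variants each log-likelihood difference is standardized by its
#' replicate standard deviation. The SH-type null maximizes the centered
#' (standardized) differences over candidates, so p_sh >= p_kh holds for
#' every candidate by construction.
#'
#' @param m A [site_lnl_matrix] (or plain candidates x sites matrix).
#' @param n_reps RELL replicates (default 10000).
#' @param weighted Standardize differences by replicate sd (default TRUE).
#' @param seed Integer seed.
#' @return Data frame: candidate, lnl, delta, p_kh, p_sh (columns named
#'   p_wkh/p_wsh when `weighted`).
#' @export
kh_sh_tests <- function(m, n_reps = 10000, weighted = TRUE, seed = 1) {
  stopifnot(nrow(m) >= 2)
  tot <- rowSums(m)
  best <- which.max(tot)
  R <- rell_resample(m, n_reps, scale = 1, seed = seed)
  C <- R - rowMeans(R)  # centered replicate totals
  nc <- nrow(m)
  p_kh <- p_sh <- numeric(nc)
  for (i in seq_len(nc)) {
    ## the ML candidate is compared against the runner-up; everyone else
    ## against the ML candidate
    jref <- if (i == best) which.max(replace(tot, i, -Inf)) else best
    delta <- tot[jref] - tot[i]
    zb <- C[jref, ] - C[i, ]           # centered pairwise null
    s_ib <- stats::sd(zb)
    if (s_ib < 1e-12) {                # identical rows: degenerate by convention
      p_kh[i] <- 1; p_sh[i] <- 1
      next
    }
    if (weighted) {
      t_obs <- delta / s_ib
      null_kh <- zb / s_ib
      null_sh <- rep(-Inf, n_reps)
      for (j in seq_len(nc)) {
        if (j == i) next
        zj <- C[j, ] - C[i, ]
        sj <- stats::sd(zj)
        if (sj < 1e-12) next
        null_sh <- pmax(null_sh, zj / sj)
      }
    } else {
      t_obs <- delta
      null_kh <- zb
      null_sh <- apply(C, 2, max) - C[i, ]
    }
    p_kh[i] <- mean(null_kh >= t_obs)
    p_sh[i] <- mean(null_sh >= t_obs)
  }
  out <- data.frame(candidate = rownames(m) %||% as.character(seq_len(nc)),
                    lnl = tot, delta = tot[best] - tot)
  if (weighted) { out$p_wkh <- p_kh; out$p_wsh <- p_sh }
  else { out$p_kh <- p_kh; out$p_sh <- p_sh }
  rownames(out) <- NULL
  out
}

#' Approximately unbiased (AU) test via multiscale RELL bootstrap
#'
#' For each candidate and each scale r, the bootstrap probability BP(r) of
#' the candidate having the highest replicate total is computed from RELL
#' replicates of ceil(r * n_sites) columns. The signed distance d and
#' curvature c are then fit by weighted least squares of
#' z(r) = qnorm(1 - BP(r)) against sqrt(r) and 1/sqrt(r) (weights from the
#' binomial variance of BP through the delta method), and
#' p_au = 1 - pnorm(d - c). BP values of 0 or 1 at a scale receive the
#' continuity correction 1/(2 * n_reps).
#'
#' @param m A [site_lnl_matrix] (or plain matrix).
#' @param scales Resampling scales; need >= 3 spanning values below and
#'   above 1 (default 0.5..1.4 by 0.1).
#' @param n_reps Replicates per scale (default 2000).
#' @param seed Integer seed.
#' @return Data frame: candidate, p_au, d, c, degenerate (logical flag for
#'   fits where BP was 0 or 1 at every scale).
#' @export
au_test <- function(m, scales = seq(0.5, 1.4, by = 0.1), n_reps = 2000,
                    seed = 1) {
  stopifnot(length(scales) >= 3, any(scales < 1), any(scales > 1))
  nc <- nrow(m)
  bp <- matrix(0, nc, length(scales))
  for (si in seq_along(scales)) {
    R <- rell_resample(m, n_reps, scale = scales[si], seed = seed + si)
    mx <- apply(R, 2, max)
    is_best <- R >= matrix(mx, nc, ncol(R), byrow = TRUE) - 1e-9
    nbest <- colSums(is_best)
    ## ties split evenly so BPs sum to 1 across candidates
    bp[, si] <- rowSums(sweep(is_best, 2, nbest, "/")) / n_reps
  }
  eps <- 1 / (2 * n_reps)
  p_au <- d_out <- c_out <- numeric(nc)
  degenerate <- logical(nc)
  for (i in seq_len(nc)) {
    b <- bp[i, ]
    degenerate[i] <- all(b <= 0) || all(b >= 1)
    b <- pmin(pmax(b, eps), 1 - eps)
    z <- stats::qnorm(1 - b)
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    w <- n_reps * stats::dnorm(z)^2 / (b * (1 - b))
    fit <- stats::lm.wfit(X, z, w)
    d <- fit$coefficients[1]; cc <- fit$coefficients[2]
    d_out[i] <- d; c_out[i] <- cc
    p_au[i] <- if (degenerate[i]) {
      if (all(bp[i, ] <= 0)) 0 else 1
    } else {
      1 - stats::pnorm(d - cc)
    }
  }
  data.frame(candidate = rownames(m) %||% as.character(seq_len(nc)),
             p_au = p_au, d = d_out, c = c_out, degenerate = degenerate,
             row.names = NULL)
}

#' Combined topology-test report
#'
#' Runs the weighted KH/SH battery and the AU test and formats one row per
#' candidate with columns in the order wkh, au, wsh, flagging p < 0.05.
#' When nothing is rejected the summary line says so.
#'
#' @param m A [site_lnl_matrix].
#' @param n_reps Replicates for KH/SH (AU uses `au_reps` per scale).
#' @param au_reps Replicates per AU scale.
#' @param alpha Rejection threshold for flags (default 0.05).
#' @param seed Integer seed.
#' @return A `topology_test_report` data frame (candidate, lnl, delta,
#'   wkh, au, wsh, rejected) with a `summary` attribute.
#' @export
test_report <- function(m, n_reps = 10000, au_reps = 2000, alpha = 0.05,
                        seed = 1) {
  if (is.null(dim(m)) || nrow(m) < 1) stop("empty candidate list")
  ks <- kh_sh_tests(m, n_reps = n_reps, weighted = TRUE, seed = seed)
  au <- au_test(m, n_reps = au_reps, seed = seed)
  out <- data.frame(candidate = ks$candidate, lnl = ks$lnl, delta = ks$delta,
                    wkh = ks$p_wkh, au = au$p_au, wsh = ks$p_wsh)
  out$rejected <- pmin(out$wkh, out$au, out$wsh) < alpha
  summary_line <- if (!any(out$rejected)) {
    sprintf("no hypothesis rejected at %.2f", alpha)
  } else {
    sprintf("%d of %d hypotheses rejected at %.2f",
            sum(out$rejected), nrow(out), alpha)
  }
  structure(out, summary = summary_line,
            class = c("topology_test_report", class(out)))
}

#' @export
print.topology_test_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$wkh <- signif(df$wkh, 3); df$au <- signif(df$au, 3); df$wsh <- signif(df$wsh, 3)
  print.data.frame(df, row.names = FALSE)
  cat("--", attr(x, "summary"), "\n")
  invisible(x)
}
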