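#' @keywords internal
"_PACKAGE"

DNA_STATES <- c("A", "C", "G", "T")
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## IUPAC ambiguity -> indicator over A,C,G,T. Gap and '?' are fully missing.
DNA_AMBIG <- list(
  A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
  U = c(0, 0, 0, 1),
  R = c(1, 0, 1, 0), Y = c(0, 1, 0, 1), S = c(0, 1, 1, 0), W = c(1, 0, 0, 1),
  K = c(0, 0, 1, 1), M = c(1, 1, 0, 0),
  B = c(0, 1, 1, 1), D = c(1, 0, 1, 1), H = c(1, 1, 0, 1), V = c(1, 1, 1, 0),
  N = c(1, 1, 1, 1), "-" = c(1, 1, 1, 1), "?" = c(1, 1, 1, 1), X = c(1, 1, 1, 1)
)

#' Discrete-gamma category rates
#'
#' Rates of the k equal-probability categories of a Gamma(alpha, alpha)
#' distribution (mean 1), using category means (Yang's mean method), so the
#' average rate across categories is exactly 1.
#'
#' @param alpha Gamma shape parameter (> 0).
#' @param k Number of categories (>= 1).
#' @return Numeric vector of k increasing rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1) return(1)
  ## category borders at quantiles j/k; mean within each bin via the
  ## incomplete-gamma identity  int x f(x; a, b) dx = (a/b) F(x; a+1, b)
  q <- stats::qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  p <- stats::pgamma(c(0, q, Inf), shape = alpha + 1, rate = alpha)
  r <- k * diff(p)
  r / mean(r) * 1  # guard against rounding; mean is 1 analytically
}

#' Construct a reversible substitution model
#'
#' Builds a time-reversible substitution model with discrete-gamma
#' among-site rate variation. DNA models are parameterized by GTR
#' exchangeabilities; amino-acid models use the bundled empirical LG or WAG
#' exchangeabilities (with their published frequencies unless overridden).
#' The rate matrix Q is rescaled so branch lengths are in expected
#' substitutions per site.
#'
#' @param type One of "gtr", "jc", "lg", "wag".
#' @param frequencies Stationary frequencies (length 4 or 20, sum 1).
#'   Defaults: uniform for "gtr"/"jc", published values for "lg"/"wag".
#' @param exchangeabilities Symmetric non-negative matrix (or the 6-vector
#'   AC,AG,AT,CG,CT,GT for DNA). Ignored for "jc"/"lg"/"wag".
#' @param alpha Gamma shape; `Inf` (default) means rate homogeneity.
#' @param k Number of discrete rate categories (default 4). With infinite
#'   `alpha` every category rate is 1.
#' @return An object of class `subst_model`.
#' @export
subst_model <- function(type = c("gtr", "jc", "lg", "wag"),
                        frequencies = NULL, exchangeabilities = NULL,
                        alpha = Inf, k = 4L) {
  type <- match.arg(type)
  if (type %in% c("gtr", "jc")) {
    states <- DNA_STATES
    s <- 4L
    if (is.null(frequencies)) frequencies <- rep(0.25, 4)
    if (type == "jc") {
      ex <- matrix(1, 4, 4)
    } else if (is.null(exchangeabilities)) {
      ex <- matrix(1, 4, 4)
    } else if (is.matrix(exchangeabilities)) {
      ex <- exchangeabilities
    } else {
      stopifnot(length(exchangeabilities) == 6)
      ex <- matrix(0, 4, 4)
      ex[lower.tri(ex)] <- exchangeabilities[c(1, 2, 3, 4, 5, 6)]
      ex <- ex + t(ex)
    }
  } else {
    states <- AA_STATES
    s <- 20L
    aa <- .aa_empirical(type)
    ex <- aa$exch
    if (is.null(frequencies)) frequencies <- aa$freq
  }
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) != s || abs(sum(frequencies) - 1) > 1e-6 ||
      any(frequencies <= 0)) {
    stop("frequencies must be a positive simplex of length ", s)
  }
  frequencies <- frequencies / sum(frequencies)
  if (!isTRUE(all.equal(ex, t(ex))) || any(ex < 0)) {
    stop("exchangeabilities must be symmetric and non-negative")
  }
  diag(ex) <- 0
  Q <- ex %*% diag(frequencies)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(frequencies * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix")
  Q <- Q / mu
  rates <- if (is.finite(alpha)) discrete_gamma_rates(alpha, k) else rep(1, k)
  ## symmetric eigen-decomposition for fast, stable transition probabilities
  sp <- sqrt(frequencies)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(
    type = type, states = states, s = s, freq = frequencies, exch = ex,
    Q = Q, alpha = alpha, k = as.integer(k), rates = rates,
    eigval = eig$values,
    U = diag(1 / sp) %*% eig$vectors,
    Uinv = t(eig$vectors) %*% diag(sp)
  ), class = "subst_model")
}

.aa_empirical <- function(type) {
  ## published empirical exchangeabilities/frequencies, as shipped by phangorn
  getAA <- utils::getFromNamespace("getModelAA", "phangorn")
  env <- environment()
  Q <- NULL; bf <- NULL
  local({
    getAA(toupper(type), bf = TRUE, Q = TRUE)
    assign("Q", Q, envir = env)
    assign("bf", bf, envir = env)
  })
  ex <- matrix(0, 20, 20)
  ex[lower.tri(ex)] <- Q
  ex <- ex + t(ex)
  dimnames(ex) <- list(AA_STATES, AA_STATES)
  freq <- as.numeric(bf)
  list(exch = ex, freq = freq)
}

#' Transition probability matrix P(t) = exp(Q t)
#'
#' @param model A `subst_model`.
#' @param t Branch length (expected substitutions per site), already scaled
#'   by any rate multiplier.
#' @return s x s stochastic matrix.
#' @export
transition_prob <- function(model, t) {
  stopifnot(inherits(model, "subst_model"), t >= 0)
  P <- model$U %*% (exp(model$eigval * t) * model$Uinv)
  ## clip tiny negative round-off
  P[P < 0] <- 0
  P
}

#' @export
print.subst_model <- function(x, ...) {
  cat("Reversible substitution model [", toupper(x$type), "], ",
      x$s, " states\n", sep = "")
  cat("  gamma shape:", if (is.finite(x$alpha)) format(x$alpha) else "none (homogeneous)",
      " categories:", x$k, "\n")
  cat("  category rates:", paste(signif(x$rates, 4), collapse = " "), "\n")
  invisible(x)
}

## map a character vector of residues to an s x n matrix of partial
## likelihood indicators (ones row for missing data)
.char_partials <- function(chars, alphabet) {
  if (alphabet == "dna") {
    out <- vapply(chars, function(ch) {
      v <- DNA_AMBIG[[ch]]
      if (is.null(v)) stop("unknown DNA character '", ch, "'")
      v
    }, numeric(4))
  } else {
    out <- vapply(chars, function(ch) {
      if (ch %in% c("-", "?", "X", "*")) return(rep(1, 20))
      i <- match(ch, AA_STATES)
      if (is.na(i)) stop("unknown amino-acid character '", ch, "'")
      v <- numeric(20); v[i] <- 1
      v
    }, numeric(20))
  }
  out
}
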