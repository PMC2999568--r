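#' Construct an amino-acid substitution rate model
#'
#' Builds a reversible 20-state rate matrix from symmetric exchangeabilities
#' and stationary frequencies, normalized to one expected substitution per
#' unit branch length, with optional discrete-gamma rate heterogeneity and an
#' invariant-site proportion. The default exchangeabilities and frequencies
#' are the published LG model values (Le & Gascuel 2008).
#'
#' @param model one of `"LG"`, `"LG+G"`, `"LG+I+G"`.
#' @param alpha gamma shape parameter (> 0); ignored for `"LG"`.
#' @param k number of discrete gamma categories (>= 1).
#' @param p_inv proportion of invariant sites in `[0, 1)`; only used by
#'   `"LG+I+G"`.
#' @param exchangeabilities symmetric nonnegative 20 x 20 matrix (or `NULL`
#'   for LG); the diagonal is ignored.
#' @param frequencies positive stationary frequencies summing to 1 (or `NULL`
#'   for the LG values).
#' @return an object of class `"rate_model"`: the normalized rate matrix `Q`,
#'   its cached eigendecomposition, stationary frequencies `pi`, discrete
#'   category `rates` and `weights`, `alpha`, `p_inv`.
#' @examples
#' m <- rate_model("LG+G", alpha = 0.8)
#' range(rowSums(m$Q))           # rows sum to 0
#' sum(m$rates * m$weights)      # mean rate 1
#' @export
rate_model <- function(model = c("LG", "LG+G", "LG+I+G"), alpha = 1, k = 4,
                       p_inv = 0, exchangeabilities = NULL,
                       frequencies = NULL) {
  model <- match.arg(model)
  if (is.null(exchangeabilities)) {
    S <- matrix(0, 20, 20, dimnames = list(AA, AA))
    S[lower.tri(S)] <- LG_EXCH_LOWER
    S <- S + t(S)
  } else {
    S <- as.matrix(exchangeabilities)
    if (nrow(S) != 20L || ncol(S) != 20L)
      stop("exchangeabilities must be a 20 x 20 matrix", call. = FALSE)
    diag(S) <- 0
    if (any(S < 0)) stop("exchangeabilities must be nonnegative", call. = FALSE)
    if (max(abs(S - t(S))) > 1e-10)
      stop("exchangeabilities must be symmetric", call. = FALSE)
    dimnames(S) <- list(AA, AA)
  }
  pi <- if (is.null(frequencies)) LG_FREQS else as.numeric(frequencies)
  if (length(pi) != 20L || any(pi <= 0))
    stop("frequencies must be 20 positive values", call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-8)
    stop("frequencies must sum to 1", call. = FALSE)
  pi <- pi / sum(pi)
  names(pi) <- AA

  Q <- S * rep(pi, each = 20)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale

  # eigendecomposition via the symmetrized matrix diag(sqrt(pi)) Q diag(1/sqrt(pi))
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U <- eig$vectors / sp          # diag(1/sqrt(pi)) %*% V
  Uinv <- t(eig$vectors) * rep(sp, each = 20)

  if (model == "LG") {
    alpha <- NULL
    rates <- 1
    k <- 1L
  } else {
    if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
    rates <- discretize_gamma(alpha, k)
  }
  if (model != "LG+I+G") p_inv <- 0
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)", call. = FALSE)

  structure(list(model = model, Q = Q, pi = pi, exchangeabilities = S,
                 U = U, Uinv = Uinv, eval = eig$values,
                 alpha = alpha, k = as.integer(k), rates = rates,
                 weights = rep(1 / k, k), p_inv = p_inv),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("Amino-acid substitution model:", x$model, "\n")
  if (!is.null(x$alpha))
    cat("  gamma shape alpha =", format(x$alpha), "with", x$k, "categories\n")
  if (x$p_inv > 0) cat("  proportion invariant =", format(x$p_inv), "\n")
  invisible(x)
}

#' Transition probability matrix P(t)
#'
#' `P = exp(Q * t * rate)` from the model's cached eigendecomposition.
#'
#' @param model a [rate_model()].
#' @param t branch length (>= 0, expected substitutions per site at rate 1).
#' @param rate positive rate multiplier (e.g. a gamma category rate).
#' @return 20 x 20 row-stochastic matrix.
#' @export
transition_probabilities <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "rate_model"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("branch length t must be a single nonnegative number", call. = FALSE)
  P <- cpp_pmat(model$U, model$Uinv, model$eval, t * rate)
  dimnames(P) <- list(AA, AA)
  P
}

#' Discrete-gamma rate categories
#'
#' Splits a Gamma(alpha, alpha) rate distribution (mean 1) into `k`
#' equal-probability categories and returns the mean rate of each, so that
#' the mean of the returned rates is exactly 1.
#'
#' @param alpha gamma shape (> 0).
#' @param k number of categories (>= 1).
#' @return numeric vector of `k` category rates.
#' @examples
#' discretize_gamma(0.5, 4)
#' @export
discretize_gamma <- function(alpha, k) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.numeric(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  k <- as.integer(k)
  if (k == 1L) return(1)
  bounds <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # mean of Gamma(alpha, alpha) over (l, u] = F(u; alpha+1) - F(l; alpha+1)
  cum <- pgamma(bounds, shape = alpha + 1, rate = alpha)
  rates <- k * diff(cum)
  rates / sum(rates) * k  # enforce mean exactly 1 against tail round-off
}
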