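#' General time-reversible substitution model with discrete-Gamma rates
#'
#' Builds the GTR rate matrix `Q[i,j] = r[ij] * pi[j]` (i != j), diagonal
#' minus row sums, rescaled so the expected substitution rate at
#' stationarity is 1 (`-sum(pi_i Q_ii) = 1`). Among-site rate heterogeneity
#' uses `k` discrete Gamma categories whose rates are the means of the
#' quantile classes of a Gamma(shape = alpha, mean = 1) distribution;
#' `k = 1` disables heterogeneity.
#'
#' @param rates exchangeabilities in the order AC, AG, AT, CG, CT, GT
#'   (non-negative; scale is arbitrary).
#' @param freqs stationary base frequencies (A, C, G, T), summing to 1.
#' @param alpha Gamma shape (> 0); ignored when `k = 1`.
#' @param k number of rate categories (>= 1), default 4.
#' @return object of class `gtr_model` with the eigen-decomposition of the
#'   symmetrized rate matrix cached for fast `P(t) = exp(Qt)`.
#' @export
gtr_model <- function(rates = rep(1, 6), freqs = rep(0.25, 4),
                      alpha = 1, k = 4L) {
  stopifnot(length(rates) == 6L, all(rates >= 0), length(freqs) == 4L)
  if (abs(sum(freqs) - 1) > 1e-8) stop("base frequencies must sum to 1")
  if (any(freqs <= 0)) stop("base frequencies must be positive")
  if (alpha <= 0) stop("alpha must be > 0")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  Q <- matrix(0, 4L, 4L, dimnames = list(DNA_STATES, DNA_STATES))
  Q[1L, 2L] <- Q[2L, 1L] <- rates[1L]  # AC
  Q[1L, 3L] <- Q[3L, 1L] <- rates[2L]  # AG
  Q[1L, 4L] <- Q[4L, 1L] <- rates[3L]  # AT
  Q[2L, 3L] <- Q[3L, 2L] <- rates[4L]  # CG
  Q[2L, 4L] <- Q[4L, 2L] <- rates[5L]  # CT
  Q[3L, 4L] <- Q[4L, 3L] <- rates[6L]  # GT
  Q <- Q * rep(freqs, each = 4L)       # Q_ij = r_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix (all exchangeabilities zero?)")
  Q <- Q / mu
  # reversible: symmetrize with sqrt(pi) similarity transform
  sp <- sqrt(freqs)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(rates = rates, freqs = freqs, alpha = alpha, k = k,
                 Q = Q,
                 eval = eig$values,
                 evec = diag(1 / sp) %*% eig$vectors,
                 ivec = t(eig$vectors) %*% diag(sp),
                 cat_rates = discrete_gamma_rates(alpha, k)),
            class = "gtr_model")
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("GTR+Gamma model\n")
  cat("  exchangeabilities (AC AG AT CG CT GT):",
      paste(signif(x$rates, 4), collapse = " "), "\n")
  cat("  base frequencies (A C G T):",
      paste(signif(x$freqs, 4), collapse = " "), "\n")
  cat(sprintf("  gamma: alpha = %g, %d categories\n", x$alpha, x$k))
  invisible(x)
}

DNA_STATES <- c("A", "C", "G", "T")

#' Mean rates of the discrete-Gamma quantile classes
#'
#' For a Gamma(shape = alpha, rate = alpha) distribution (mean 1) split into
#' `k` equal-probability classes, returns the mean rate of each class.
#'
#' @param alpha shape parameter.
#' @param k number of classes.
#' @return numeric vector of length `k`, mean 1.
#' @export
discrete_gamma_rates <- function(alpha, k) {
  if (k == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  # E[X | class] via the incomplete-gamma identity, X ~ Gamma(alpha, alpha)
  up <- stats::pgamma(b[-1L], shape = alpha + 1, rate = alpha)
  lo <- stats::pgamma(b[-(k + 1L)], shape = alpha + 1, rate = alpha)
  k * (up - lo)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [gtr_model()].
#' @param t branch length in expected substitutions per site (>= 0).
#' @return 4x4 row-stochastic matrix over A, C, G, T.
#' @export
transition_matrix <- function(model, t) {
  if (t < 0) stop("branch length must be >= 0")
  P <- model$evec %*% (exp(model$eval * t) * model$ivec)
  P[P < 0] <- 0
  dimnames(P) <- list(DNA_STATES, DNA_STATES)
  P
}

# IUPAC symbol -> 0/1 partial-likelihood row over (A, C, G, T).
# Gap, '?' and 'N' are fully missing by design.
iupac_partials <- local({
  tab <- list(
    A = c(1, 0, 0, 0), C = c(0, 1, 0, 0), G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
    U = c(0, 0, 0, 1),
    R = c(1, 0, 1, 0), Y = c(0, 1, 0, 1), S = c(0, 1, 1, 0), W = c(1, 0, 0, 1),
    K = c(0, 0, 1, 1), M = c(1, 1, 0, 0),
    B = c(0, 1, 1, 1), D = c(1, 0, 1, 1), H = c(1, 1, 0, 1), V = c(1, 1, 1, 0),
    N = c(1, 1, 1, 1), `-` = c(1, 1, 1, 1), `?` = c(1, 1, 1, 1))
  do.call(rbind, tab)
})

#' Empirical base frequencies of an alignment
#'
#' Counts over unambiguous A/C/G/T cells only (missing and ambiguity codes
#' ignored).
#'
#' @param aln a [dna_alignment()].
#' @param pseudocount added to each count (default 0.01, avoids zeros).
#' @return numeric vector (A, C, G, T) summing to 1.
#' @export
empirical_freqs <- function(aln, pseudocount = 0.01) {
  cnt <- vapply(DNA_STATES, function(s) sum(aln == s), numeric(1L)) + pseudocount
  cnt / sum(cnt)
}
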