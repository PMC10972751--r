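#' Amino-acid substitution models
#'
#' Constructs a time-reversible 20-state substitution model from an
#' exchangeability matrix and stationary frequencies. The rate matrix is
#' normalized so branch lengths are in expected substitutions per site.
#' The default \code{poisson_model()} has equal exchangeabilities and uniform
#' frequencies, for which transition probabilities have the closed form
#' \eqn{P_{ii}(t) = 1/20 + (19/20) e^{-20t/19}} and
#' \eqn{P_{ij}(t) = 1/20 - (1/20) e^{-20t/19}}; empirical matrices can be
#' supplied through \code{exchangeabilities} or loaded from a PAML-style
#' rate-matrix file with \code{read_rate_matrix()}.
#'
#' @param exchangeabilities Symmetric 20x20 matrix of exchangeabilities
#'   (diagonal ignored). Default: all equal.
#' @param freqs Stationary frequencies, length 20, summing to 1.
#' @param gamma_shape Optional shape for discrete-gamma rate heterogeneity.
#' @param gamma_categories Number of discrete gamma categories (default 4).
#' @return An object of class \code{"subst_model"} with elements \code{Q}
#'   (normalized rate matrix), \code{freqs}, eigen-decomposition cache and
#'   rate-category definitions.
#' @examples
#' m <- poisson_model()
#' p <- transition_probabilities(m, 0.1)
#' stopifnot(abs(rowSums(p) - 1) < 1e-12)
#' @export
substitution_model <- function(exchangeabilities = NULL, freqs = rep(1 / 20, 20),
                               gamma_shape = NULL, gamma_categories = 4L) {
  n <- 20L
  if (is.null(exchangeabilities)) exchangeabilities <- matrix(1, n, n)
  stopifnot(is.matrix(exchangeabilities), all(dim(exchangeabilities) == n))
  if (max(abs(exchangeabilities - t(exchangeabilities))) > 1e-9)
    stop("exchangeability matrix must be symmetric")
  if (length(freqs) != n || any(freqs <= 0))
    stop("freqs must be 20 positive values")
  freqs <- freqs / sum(freqs)
  Q <- exchangeabilities %*% diag(freqs)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  ## normalize: expected rate 1 substitution / site / unit branch length
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  ## symmetrized eigendecomposition for reversible Q
  sq <- sqrt(freqs)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  B <- (B + t(B)) / 2
  ed <- eigen(B, symmetric = TRUE)
  rates <- 1
  probs <- 1
  if (!is.null(gamma_shape)) {
    stopifnot(gamma_shape > 0, gamma_categories >= 1)
    k <- gamma_categories
    ## discrete gamma, category means of equal-probability quantile slices
    q <- stats::qgamma((seq_len(k) - 0.5) / k, shape = gamma_shape,
                       rate = gamma_shape)
    rates <- q / mean(q)
    probs <- rep(1 / k, k)
  }
  uniform <- all(abs(exchangeabilities[upper.tri(exchangeabilities)] -
                       exchangeabilities[2, 1]) < 1e-12) &&
    all(abs(freqs - 1 / 20) < 1e-12)
  structure(list(Q = Q, freqs = freqs,
                 evec = diag(1 / sq) %*% ed$vectors,
                 ivec = t(ed$vectors) %*% diag(sq),
                 evals = ed$values,
                 rates = rates, rate_probs = probs,
                 poisson = uniform),
            class = "subst_model")
}

#' @rdname substitution_model
#' @export
poisson_model <- function(gamma_shape = NULL, gamma_categories = 4L) {
  substitution_model(gamma_shape = gamma_shape,
                     gamma_categories = gamma_categories)
}

#' @rdname substitution_model
#' @param file Path to a PAML-style amino-acid rate file: 19 lines of
#'   lower-triangular exchangeabilities followed by a line of 20 frequencies.
#' @export
read_rate_matrix <- function(file, gamma_shape = NULL, gamma_categories = 4L) {
  vals <- scan(file, quiet = TRUE)
  if (length(vals) < 190 + 20) stop("rate file must hold 190 exchangeabilities and 20 frequencies")
  ex <- matrix(0, 20, 20)
  ex[lower.tri(ex)] <- vals[1:190]
  ex <- ex + t(ex)
  freqs <- vals[191:210]
  substitution_model(ex, freqs, gamma_shape, gamma_categories)
}

#' Transition probability matrix
#'
#' @param model A \code{subst_model}.
#' @param t Branch length (expected substitutions per site), \code{t >= 0}.
#' @return 20x20 matrix of transition probabilities.
#' @export
transition_probabilities <- function(model, t) {
  stopifnot(inherits(model, "subst_model"), t >= 0)
  if (model$poisson) {
    e <- exp(-20 * t / 19)
    P <- matrix((1 - e) / 20, 20, 20)
    diag(P) <- (1 + 19 * e) / 20
    return(P)
  }
  P <- model$evec %*% (exp(model$evals * t) * model$ivec)
  P[P < 0] <- 0
  P
}
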