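#' Thresholds for a K-category ordinal scale
#'
#' Assemble the full interior threshold vector `theta[1..K-1]` from the free
#' interior thresholds. The latent scale is anchored by fixing the two extreme
#' thresholds at the bounds of the response scale: `theta[1] = 1.5` and
#' `theta[K-1] = K - 0.5`. Categories are coded `1..K`, so category k occupies
#' the latent bin (theta[k-1], theta[k]] with virtual thresholds at -Inf and
#' +Inf. For K = 3 there are no free thresholds.
#'
#' @param K Number of ordinal categories (>= 3).
#' @param free Numeric vector of the K - 3 free interior thresholds
#'   (theta 2, ..., theta K-2), possibly empty.
#' @return Numeric vector of length K - 1 of strictly increasing thresholds
#'   (not checked here; the prior enforces ordering by rejection).
#' @export
make_thresholds <- function(K, free = numeric(0)) {
  K <- check_K(K)
  if (length(free) != n_free_thresholds(K)) {
    stop("expected ", n_free_thresholds(K), " free thresholds for K = ", K,
         ", got ", length(free), call. = FALSE)
  }
  c(1.5, as.numeric(free), K - 0.5)[seq_len(K - 1L)]
}

n_free_thresholds <- function(K) max(0L, as.integer(K) - 3L)

check_K <- function(K) {
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 3L) {
    stop("K must be a single integer >= 3", call. = FALSE)
  }
  K
}

#' Ordinal category probabilities under the latent-normal model
#'
#' Probability of each ordinal category k = 1..K when the latent opinion is
#' normal with mean `mu` and standard deviation `sigma` and is partitioned by
#' the strictly increasing thresholds `theta`:
#' `p(k) = Phi((theta[k] - mu)/sigma) - Phi((theta[k-1] - mu)/sigma)` with
#' virtual thresholds theta[0] = -Inf and theta[K] = +Inf.
#'
#' @param mu Latent mean.
#' @param sigma Latent standard deviation (> 0).
#' @param theta Full interior threshold vector, length K - 1, strictly
#'   increasing (e.g. from [make_thresholds()]).
#' @return Probability vector of length K summing to 1.
#' @examples
#' category_probs(3, 1, make_thresholds(5, c(2.5, 3.5)))
#' @export
category_probs <- function(mu, sigma, theta) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  if (is.unsorted(theta, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  cuts <- c(-Inf, theta, Inf)
  diff(stats::pnorm((cuts - mu) / sigma))
}

#' Fold a "don't know" probability into a category-probability vector
#'
#' The DK answer is modelled as a separate mixture component, not an ordinal
#' category: with probability `delta` the respondent answers DK, otherwise an
#' ordinal category drawn from `p`. Returns `c(delta, (1 - delta) * p)`, a
#' (K + 1)-vector whose first element is the DK probability.
#'
#' @param p Ordinal probability vector (sums to 1).
#' @param delta DK probability in \[0, 1\].
#' @export
dk_adjust <- function(p, delta) {
  if (length(delta) != 1L || is.na(delta) || delta < 0 || delta > 1) {
    stop("delta must be a single probability in [0, 1]", call. = FALSE)
  }
  c(delta, (1 - delta) * p)
}

#' Prior specification for the latent ordinal model
#'
#' Weakly informative defaults: the latent mean gets a normal prior centred at
#' the midpoint (K + 1)/2 of the response scale with a wide sd (default K);
#' sigma a uniform prior over a broad range (default 0.01 to 10 K); each free
#' interior threshold j a normal prior centred at j + 0.5 with sd `theta_sd`;
#' the DK probability a uniform prior on \[0, 1\]. Linear-predictor
#' coefficients get near-flat normal priors: sd `10 K` around 0 (and around the
#' scale midpoint for the intercept).
#'
#' @param K Number of ordinal categories.
#' @param mu_mean,mu_sd Normal prior for the latent mean.
#' @param sigma_lower,sigma_upper Uniform prior bounds for sigma.
#' @param theta_sd Normal prior sd for each free interior threshold.
#' @param delta_lower,delta_upper Uniform prior bounds for the DK probability.
#' @param beta_sd Normal prior sd for linear-predictor coefficients.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(K,
                       mu_mean = (K + 1) / 2, mu_sd = K,
                       sigma_lower = 0.01, sigma_upper = 10 * K,
                       theta_sd = K,
                       delta_lower = 0, delta_upper = 1,
                       beta_sd = 10 * K) {
  K <- check_K(K)
  stopifnot(mu_sd > 0, theta_sd > 0, beta_sd > 0,
            sigma_lower < sigma_upper, sigma_lower > 0,
            delta_lower < delta_upper, delta_lower >= 0, delta_upper <= 1)
  structure(
    list(K = K, mu_mean = mu_mean, mu_sd = mu_sd,
         sigma_lower = sigma_lower, sigma_upper = sigma_upper,
         theta_sd = theta_sd,
         delta_lower = delta_lower, delta_upper = delta_upper,
         beta_sd = beta_sd),
    class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Prior specification (K = ", x$K, ")\n", sep = "")
  cat("  mu    ~ normal(", x$mu_mean, ", sd = ", x$mu_sd, ")\n", sep = "")
  cat("  sigma ~ uniform(", x$sigma_lower, ", ", x$sigma_upper, ")\n", sep = "")
  cat("  free theta_j ~ normal(j + 0.5, sd = ", x$theta_sd, ")\n", sep = "")
  cat("  delta ~ uniform(", x$delta_lower, ", ", x$delta_upper, ")\n", sep = "")
  cat("  coefficients ~ normal(0, sd = ", x$beta_sd, ")\n", sep = "")
  invisible(x)
}

# Log-density of the uniform prior, -Inf outside support.
dunif_log <- function(x, lower, upper) {
  ifelse(x >= lower & x <= upper, -log(upper - lower), -Inf)
}

#' Log prior density for one group's latent-model parameters
#'
#' Sum of the log prior densities of mu, sigma, the free interior thresholds
#' and (if present) the DK probability. Returns `-Inf` outside the support:
#' sigma outside its uniform bounds, delta outside \[0, 1\], or a threshold
#' vector that is not strictly increasing once the fixed extremes are attached
#' (ordering is enforced by rejection, not reparameterization).
#'
#' @param mu,sigma Latent mean and sd.
#' @param theta_free Free interior thresholds (length K - 3).
#' @param delta DK probability or `NULL` when the question has no DK option.
#' @param prior A [prior_spec()].
#' @return A single log density.
#' @export
log_prior <- function(mu, sigma, theta_free, delta = NULL, prior) {
  K <- prior$K
  lp <- dunif_log(sigma, prior$sigma_lower, prior$sigma_upper)
  if (!is.finite(lp)) return(-Inf)
  theta <- make_thresholds(K, theta_free)
  if (is.unsorted(theta, strictly = TRUE)) return(-Inf)
  lp <- lp + stats::dnorm(mu, prior$mu_mean, prior$mu_sd, log = TRUE)
  if (length(theta_free)) {
    centres <- seq(2L, K - 2L) + 0.5
    lp <- lp + sum(stats::dnorm(theta_free, centres, prior$theta_sd, log = TRUE))
  }
  if (!is.null(delta)) {
    ld <- dunif_log(delta, prior$delta_lower, prior$delta_upper)
    if (!is.finite(ld)) return(-Inf)
    lp <- lp + ld
  }
  lp
}

# Category counts from an encoded vector (length K).
encoded_counts <- function(encoded) {
  tabulate(encoded$codes, nbins = encoded$K)
}

#' Ordinal log-likelihood with an optional DK channel
#'
#' For the ordinal observations the log-likelihood is
#' `sum_k n_k log((1 - delta) p_k)`; each DK answer contributes `log(delta)`.
#' Without a DK channel (`delta = NULL`) it is `sum_k n_k log(p_k)`. When an
#' observed category has zero probability the result is `-Inf`.
#'
#' @param encoded An [encoded_responses] object (see [encode_responses()]).
#' @param mu,sigma,theta_free,delta Parameters as in [log_prior()].
#' @return A single log-likelihood value.
#' @export
log_likelihood <- function(encoded, mu, sigma, theta_free = numeric(0),
                           delta = NULL) {
  if (encoded$n_total == 0L) {
    stop("cannot evaluate a likelihood on an empty stratum", call. = FALSE)
  }
  theta <- make_thresholds(encoded$K, theta_free)
  p <- category_probs(mu, sigma, theta)
  counts <- encoded_counts(encoded)
  ll <- loglik_from_counts(counts, p)
  if (is.null(delta)) {
    if (encoded$dk_count > 0L) {
      stop("encoded data contain DK answers but no delta was supplied",
           call. = FALSE)
    }
    return(ll)
  }
  n_ord <- sum(counts)
  ll + dk_loglik(encoded$dk_count, n_ord, delta)
}

loglik_from_counts <- function(counts, p) {
  used <- counts > 0L
  if (any(p[used] <= 0)) return(-Inf)
  sum(counts[used] * log(p[used]))
}

dk_loglik <- function(dk_count, n_ord, delta) {
  ll <- 0
  if (dk_count > 0L) {
    if (delta <= 0) return(-Inf)
    ll <- ll + dk_count * log(delta)
  }
  if (n_ord > 0L) {
    if (delta >= 1) return(-Inf)
    ll <- ll + n_ord * log1p(-delta)
  }
  ll
}
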