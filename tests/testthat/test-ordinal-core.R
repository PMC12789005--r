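# The latent-normal cell probabilities, DK mixture, likelihood and priors.

test_that("cell probabilities match the standard-normal CDF oracle", {
  th <- make_thresholds(5, c(2.5, 3.5))
  p <- category_probs(3, 1, th)
  # centred symmetric case: middle cell is Phi(0.5) - Phi(-0.5)
  expect_equal(p, c(0.066807, 0.241731, 0.382925, 0.241731, 0.066807),
               tolerance = 1e-5)
  expect_equal(p[3], pnorm(0.5) - pnorm(-0.5), tolerance = 1e-12)
  # off-centre, tight: lowest cell is Phi((1.5 - 2) / 0.5) = Phi(-1)
  p2 <- category_probs(2, 0.5, th)
  expect_equal(p2[1], pnorm(-1), tolerance = 1e-12)
  expect_equal(unname(p2[1]), 0.158655, tolerance = 1e-5)
})

test_that("cell probabilities agree with numerical integration of the normal density", {
  set.seed(42)
  for (rep in 1:50) {
    K <- sample(3:7, 1)
    mu <- runif(1, 0, K + 1)
    sigma <- runif(1, 0.2, 2 * K)
    free <- sort(runif(max(0, K - 3), 1.6, K - 0.6))
    th <- make_thresholds(K, free)
    if (is.unsorted(th, strictly = TRUE)) next
    p <- category_probs(mu, sigma, th)
    cuts <- c(-Inf, th, Inf)
    p_num <- vapply(seq_len(K), function(k) {
      stats::integrate(dnorm, cuts[k], cuts[k + 1], mean = mu, sd = sigma,
                       rel.tol = 1e-12)$value
    }, 0)
    expect_equal(p, p_num, tolerance = 1e-8)
    expect_valid_probs(p)
  }
})

test_that("symmetric thresholds give symmetric probabilities for any sigma", {
  th <- make_thresholds(5, c(2.5, 3.5))
  for (sigma in c(0.3, 1, 2.7, 10)) {
    p <- category_probs(3, sigma, th)
    expect_lt(abs(p[1] - p[5]), 1e-15)
    expect_lt(abs(p[2] - p[4]), 1e-15)
  }
})

test_that("raising the latent mean never lowers any upper-tail probability", {
  th <- make_thresholds(6, c(2.5, 3.2, 4.5))
  mus <- seq(0.5, 6.5, by = 0.25)
  for (sigma in c(0.4, 1, 3)) {
    surv <- sapply(mus, function(m) rev(cumsum(rev(category_probs(m, sigma, th)))))
    # each row of surv is P(y >= k) as a function of mu
    expect_true(all(diff(t(surv)) >= -1e-12))
  }
})

test_that("as sigma shrinks, mass concentrates on the bin containing mu", {
  th <- make_thresholds(5, c(2.5, 3.5))
  p <- category_probs(2.8, 1e-4, th)
  expect_equal(unname(p[3]), 1, tolerance = 1e-9)
  p_edge <- category_probs(4.9, 1e-4, th)
  expect_equal(unname(p_edge[5]), 1, tolerance = 1e-9)
})

test_that("threshold validation and assembly are enforced", {
  expect_error(category_probs(3, 1, c(2.5, 2.5, 3.5)), "strictly increasing")
  expect_error(category_probs(3, 0, make_thresholds(5, c(2.5, 3.5))), "sigma")
  expect_equal(make_thresholds(5, c(2.5, 3.5)), c(1.5, 2.5, 3.5, 4.5))
  expect_equal(make_thresholds(3), c(1.5, 2.5))
  expect_error(make_thresholds(5, c(2.5)), "free thresholds")
})

test_that("DK adjustment is the stated mixture", {
  p <- rep(0.2, 5)
  expect_equal(dk_adjust(p, 0), c(0, p))
  expect_equal(dk_adjust(p, 0.25), c(0.25, rep(0.15, 5)))
  expect_equal(dk_adjust(p, 1), c(1, rep(0, 5)))
  expect_valid_probs(dk_adjust(category_probs(3.3, 0.8, make_thresholds(5, c(2.5, 3.5))), 0.37))
  expect_error(dk_adjust(p, 1.2), "delta")
})

test_that("log-likelihood matches the hand-derived worked example", {
  enc <- encoded_responses(c(3L, 3L, 1L), K = 5)
  ll <- log_likelihood(enc, mu = 3, sigma = 1, theta_free = c(2.5, 3.5))
  p <- category_probs(3, 1, make_thresholds(5, c(2.5, 3.5)))
  expect_equal(ll, 2 * log(p[3]) + log(p[1]), tolerance = 1e-12)
  expect_equal(ll, -4.6258, tolerance = 1e-4)
})

test_that("the DK mixture reduces to the plain likelihood when delta is absent from the data", {
  enc_dk <- encoded_responses(c(2L, 4L, 4L), K = 5, has_dont_know = TRUE)
  enc_plain <- encoded_responses(c(2L, 4L, 4L), K = 5)
  ll0 <- log_likelihood(enc_plain, 3, 1, c(2.5, 3.5))
  ll_dk <- log_likelihood(enc_dk, 3, 1, c(2.5, 3.5), delta = 0)
  expect_equal(ll_dk, ll0)
  # a single DK observation contributes log(delta)
  enc1 <- encoded_responses(integer(0), 1L, K = 5)
  expect_equal(log_likelihood(enc1, 3, 1, c(2.5, 3.5), delta = 0.2),
               log(0.2), tolerance = 1e-12)
  expect_equal(log(0.2), -1.60944, tolerance = 1e-5)
})

test_that("impossible observations give -Inf and empty data an error", {
  enc <- encoded_responses(c(1L, 5L), K = 5)
  # sigma tiny, mu centred: extreme categories have zero probability
  expect_identical(log_likelihood(enc, 3, 1e-8, c(2.5, 3.5)), -Inf)
  empty <- encoded_responses(integer(0), K = 5)
  expect_error(log_likelihood(empty, 3, 1, c(2.5, 3.5)), "empty")
  enc_dk <- encoded_responses(2L, 3L, K = 5)
  expect_error(log_likelihood(enc_dk, 3, 1, c(2.5, 3.5)), "delta")
})

test_that("the prior density has the stated shape and support", {
  pr <- prior_spec(5)
  # sigma outside its uniform bounds is rejected
  expect_identical(log_prior(3, 0.001, c(2.5, 3.5), NULL, pr), -Inf)
  expect_identical(log_prior(3, 51, c(2.5, 3.5), NULL, pr), -Inf)
  # unordered thresholds are rejected
  expect_identical(log_prior(3, 1, c(3.6, 2.5), NULL, pr), -Inf)
  expect_identical(log_prior(3, 1, c(1.2, 3.5), NULL, pr), -Inf)
  # delta outside [0, 1] is rejected
  expect_identical(log_prior(3, 1, c(2.5, 3.5), 1.4, pr), -Inf)
  # at the prior modes each normal term contributes -log(K sqrt(2 pi))
  lp_mode <- log_prior(3, 1, c(2.5, 3.5), NULL, pr)
  lp_off <- log_prior(4, 1, c(2.5, 3.5), NULL, pr)
  expect_equal(lp_mode - lp_off, dnorm(3, 3, 5, log = TRUE) - dnorm(4, 3, 5, log = TRUE))
  mu_term <- dnorm(3, 3, 5, log = TRUE)
  expect_equal(mu_term, -log(5 * sqrt(2 * pi)))
  # moving a free threshold off its centre j + 0.5 lowers the density
  expect_lt(log_prior(3, 1, c(2.7, 3.5), NULL, pr), lp_mode)
})

test_that("prior defaults follow the response scale", {
  pr <- prior_spec(7)
  expect_equal(pr$mu_mean, 4)
  expect_equal(pr$mu_sd, 7)
  expect_equal(pr$sigma_upper, 70)
  expect_error(prior_spec(5, sigma_lower = 2, sigma_upper = 1))
})
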