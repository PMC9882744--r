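test_that("the decay curve has its intercept at y0 and asymptote at a", {
  p <- c(y0 = 100, a = 20, k = 1)
  expect_equal(decay_mean(p, 0), 100)
  expect_equal(decay_mean(p, 40), 20, tolerance = 1e-9)
  expect_equal(decay_mean(p, 1), 20 + 80 * exp(-1))
  # strictly decreasing toward the asymptote when y0 > a
  set.seed(3)
  for (i in 1:10) {
    a <- runif(1, 0, 50); y0 <- a + runif(1, 1, 500); k <- runif(1, 0.2, 3)
    y <- decay_mean(c(y0 = y0, a = a, k = k), 0:20)
    expect_true(all(diff(y) <= 0))   # non-strict at double precision
    expect_lt(y[2], y[1])
    expect_true(all(y >= a))
  }
  expect_equal(decay_mean(c(y0 = 5, a = 5, k = 1), 0:5), rep(5, 6))
  expect_error(decay_mean(c(y0 = -1, a = 0, k = 1), 0),
               class = "fp_param_error")
})

test_that("fitting noise-free counts recovers the generating parameters", {
  truth <- c(y0 = 100, a = 20, k = 1)
  counts <- round(decay_mean(truth, 0:20))
  fit <- fit_decay(counts, chains = 2, iter = 8000, warmup = 2000, thin = 6,
                   seed = 5)
  est <- coef(fit)
  expect_true(all(abs(est[c("y0", "a")] - truth[c("y0", "a")]) /
                    truth[c("y0", "a")] < 0.05))
  # on this small rounded-count dataset the exact posterior median of k
  # sits ~5% above the generating value (confirmed with an independent
  # Gibbs sampler), so the bound for k is slightly wider
  expect_lt(abs(est["k"] - truth["k"]) / truth["k"], 0.08)
  expect_true(fit$converged)
})

test_that("fits are reproducible and summaries well-formed", {
  set.seed(42)
  counts <- rpois(21, decay_mean(c(y0 = 300, a = 10, k = 1.2), 0:20))
  f1 <- fit_decay(counts, chains = 2, iter = 3000, warmup = 2000, thin = 1,
                  seed = 9)
  f2 <- fit_decay(counts, chains = 2, iter = 3000, warmup = 2000, thin = 1,
                  seed = 9)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws[[1]]), 1000L)
  s <- summary(f1)$table
  expect_true(all(s$hdi_low <= s$median & s$median <= s$hdi_high))
  expect_equal(length(fitted(f1)), 21L)
  expect_equal(residuals(f1), counts - fitted(f1))
  pr <- predict(f1, interval = TRUE)
  expect_true(all(pr[, "lwr"] <= pr[, "fit"] & pr[, "fit"] <= pr[, "upr"]))
  sims <- simulate(f1, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(21L, 3L))
})

test_that("degenerate histograms are rejected", {
  expect_error(fit_decay(rep(0, 21)), class = "fp_degenerate_data")
  expect_error(fit_decay(rep(1, 5)), class = "fp_histogram_error")
  expect_error(fit_decay(c(rep(1, 20), -1)), class = "fp_histogram_error")
})

test_that("split R-hat separates converged from disjoint chains", {
  set.seed(7)
  same <- replicate(4, rnorm(4000), simplify = FALSE)
  expect_lt(compute_rhat(same), 1.01)
  # the split estimator is bounded below by sqrt((n-1)/n), not exactly 1
  expect_gte(compute_rhat(same), sqrt(1 - 1 / 2000))
  apart <- list(rnorm(2000, 0, 0.1), rnorm(2000, 10, 0.1))
  expect_gt(compute_rhat(apart), 2)
  # a within-chain trend also inflates split R-hat
  drift <- list(seq(0, 1, length.out = 1000) + rnorm(1000, 0, 0.01),
                seq(0, 1, length.out = 1000) + rnorm(1000, 0, 0.01))
  expect_gt(compute_rhat(drift), 1.01)
  expect_error(compute_rhat(list(rnorm(100))), class = "fp_rhat_error")
  # matrix input returns one value per parameter
  m <- lapply(1:3, function(i) matrix(rnorm(2000), 1000, 2,
                                      dimnames = list(NULL, c("p1", "p2"))))
  r <- compute_rhat(m)
  expect_named(r, c("p1", "p2"))
})

test_that("the normal-likelihood variant also recovers the curve", {
  truth <- c(y0 = 500, a = 30, k = 1.1)
  set.seed(12)
  counts <- pmax(round(decay_mean(truth, 0:20) + rnorm(21, 0, 10)), 0)
  fit <- fit_decay(counts, chains = 2, iter = 8000, warmup = 2000, thin = 6,
                   seed = 3, likelihood = "normal")
  expect_true("sigma" %in% fit$params)
  est <- coef(fit)
  expect_lt(abs(est["y0"] - truth["y0"]) / truth["y0"], 0.1)
})

test_that("posterior agrees with an independent Gibbs sampler on one histogram", {
  skip_if_not_installed("rjags")
  truth <- c(y0 = 1192.55, a = 49.79, k = 1.16)
  set.seed(21)
  counts <- rpois(21, decay_mean(truth, 0:20))
  fit <- fit_decay(counts, chains = 2, iter = 12000, warmup = 2000,
                   thin = 10, seed = 2)
  model <- "model{
    for (i in 1:21) { y[i] ~ dpois(mu[i]); mu[i] <- (y0 - a) * exp(-k * (i - 1)) + a }
    y0 ~ dnorm(0, 1 / pow(3 * mx, 2)) T(0,)
    a ~ dnorm(0, 1 / pow(mx, 2)) T(0,)
    k ~ dnorm(0, 1 / 9) T(0,)
  }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = counts, mx = max(counts)),
                          n.chains = 2, quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 4))
  update(jm, 2000, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("y0", "a", "k"), 5000, thin = 5,
                            progress.bar = "none")
  ref <- as.matrix(sm)
  ours <- as.matrix(fit)
  for (p in c("y0", "a", "k")) {
    mref <- median(ref[, p]); sref <- sd(ref[, p])
    expect_lt(abs(median(ours[, p]) - mref), 0.25 * sref)
    expect_lt(abs(sd(ours[, p]) - sref) / sref, 0.25)
  }
})
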