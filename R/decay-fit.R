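#' Exponential-decay mean curve for binned reply counts
#'
#' The expected reply count in latency bin `x` is
#' `y(x) = (y0 - a) * exp(-k * x) + a`: `y0` is the intercept (expected
#' count in the first 8-hour bin), `a` the asymptote the curve settles to
#' across the week, and `k` the decay rate per bin. The curve decreases
#' monotonically toward `a` whenever `y0 > a`.
#'
#' @param params named vector or list with elements `y0`, `a` and `k`
#'   (`y0 > 0`, `a >= 0`, `k > 0`).
#' @param x bin index (0-based; vectorised).
#' @return expected counts, same length as `x`.
#' @examples
#' decay_mean(c(y0 = 100, a = 20, k = 1), 0:3)
#' @export
decay_mean <- function(params, x) {
  p <- as.list(params)
  stopifnot(all(c("y0", "a", "k") %in% names(p)))
  y0 <- as.numeric(p$y0); a <- as.numeric(p$a); k <- as.numeric(p$k)
  if (y0 <= 0 || a < 0 || k <= 0)
    fp_stop("fp_param_error", "require y0 > 0, a >= 0, k > 0")
  (y0 - a) * exp(-k * x) + a
}

# log posterior on theta = log(y0, a, k[, sigma]); half-normal priors on the
# natural scale plus the log-transform Jacobian keep all parameters positive
make_log_posterior <- function(counts, likelihood, prior_scales) {
  x <- seq_along(counts) - 1
  if (likelihood == "poisson") {
    function(theta) {
      p <- exp(theta)
      mu <- (p[1] - p[2]) * exp(-p[3] * x) + p[2]
      if (any(!is.finite(mu)) || any(mu <= 0)) return(-Inf)
      sum(stats::dpois(counts, mu, log = TRUE)) -
        0.5 * sum((p / prior_scales)^2) + sum(theta)
    }
  } else {
    function(theta) {
      p <- exp(theta)
      mu <- (p[1] - p[2]) * exp(-p[3] * x) + p[2]
      if (any(!is.finite(mu))) return(-Inf)
      sum(stats::dnorm(counts, mu, p[4], log = TRUE)) -
        0.5 * sum((p / prior_scales)^2) + sum(theta)
    }
  }
}

# one adaptive random-walk Metropolis chain on the log scale; the proposal
# covariance and global scale adapt only during warmup and are frozen after
run_chain <- function(log_post, theta0, iter, warmup, thin, param_names) {
  d <- length(theta0)
  theta <- theta0
  lp <- log_post(theta)
  if (!is.finite(lp)) {
    theta <- rep(0, d)
    lp <- log_post(theta)
  }
  scale <- 2.38 / sqrt(d)
  L <- diag(0.1, d)
  hist_mat <- matrix(NA_real_, warmup, d)
  keep <- matrix(NA_real_, (iter - warmup) %/% thin, d,
                 dimnames = list(NULL, param_names))
  n_acc <- 0L; win_acc <- 0L; kept <- 0L
  for (i in seq_len(iter)) {
    prop <- theta + scale * as.vector(L %*% stats::rnorm(d))
    lp_prop <- log_post(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      theta <- prop; lp <- lp_prop
      n_acc <- n_acc + 1L; win_acc <- win_acc + 1L
    }
    if (i <= warmup) {
      hist_mat[i, ] <- theta
      if (i %% 50L == 0L) {
        # scale toward ~30% acceptance, covariance from warmup history
        scale <- scale * exp((win_acc / 50 - 0.3))
        win_acc <- 0L
        if (i >= 150L) {
          cv <- stats::cov(hist_mat[seq_len(i), , drop = FALSE]) +
            diag(1e-8, d)
          ch <- tryCatch(chol(cv), error = function(e) NULL)
          if (!is.null(ch)) L <- t(ch)
        }
      }
    } else if ((i - warmup) %% thin == 0L) {
      kept <- kept + 1L
      keep[kept, ] <- theta
    }
  }
  list(draws = exp(keep), accept = n_acc / iter)
}

#' Fit the Bayesian exponential-decay model to a latency histogram
#'
#' Samples the posterior of `(y0, a, k)` under a Poisson likelihood on the
#' 21 bin counts with mean [decay_mean()] and weakly informative,
#' scale-adaptive half-normal priors (`y0 ~ HN(3 * max(count))`,
#' `a ~ HN(max(count))`, `k ~ HN(3)`). Sampling uses adaptive random-walk
#' Metropolis on the log scale; proposal adaptation stops after warmup.
#' Convergence is assessed with the split-chain potential scale reduction
#' factor ([compute_rhat()]); a fit with any R-hat above 1.01 is returned
#' but flagged as non-converged.
#'
#' @param hist a `latency_histogram` (see [bin_latencies()]) or a plain
#'   vector of 21 non-negative bin counts.
#' @param chains number of chains (default 4).
#' @param iter total iterations per chain, including warmup (default 4000).
#' @param warmup adaptation iterations discarded per chain (default 2000).
#' @param thin keep every `thin`-th post-warmup draw (default 2).
#' @param seed integer seed; the same seed reproduces the draws exactly.
#' @param likelihood `"poisson"` (counts; default) or `"normal"`
#'   (adds an observation-noise parameter `sigma`), the latter available
#'   for sensitivity checks.
#' @return an object of class `decay_fit` with components `draws` (list of
#'   per-chain matrices on the natural scale), `rhat`, `converged`,
#'   `accept`, `counts`, and the sampler configuration. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `simulate`, `plot`, `as.matrix`.
#' @examples
#' counts <- round(decay_mean(c(y0 = 100, a = 20, k = 1), 0:20))
#' fit <- fit_decay(counts, chains = 2, iter = 1500, warmup = 1000,
#'                  thin = 1, seed = 1)
#' coef(fit)
#' @export
fit_decay <- function(hist, chains = 4, iter = 4000, warmup = 2000, thin = 2,
                      seed = 1L, likelihood = c("poisson", "normal")) {
  likelihood <- match.arg(likelihood)
  counts <- if (inherits(hist, "latency_histogram")) hist$counts
            else as.numeric(hist)
  if (length(counts) != LATENCY_N_BINS)
    fp_stop("fp_histogram_error", "expected %d bin counts, got %d",
            LATENCY_N_BINS, length(counts))
  if (any(counts < 0) || any(!is.finite(counts)))
    fp_stop("fp_histogram_error", "bin counts must be finite and >= 0")
  if (all(counts == 0))
    fp_stop("fp_degenerate_data", "all bin counts are zero; nothing to fit")
  stopifnot(chains >= 1, warmup >= 1, iter > warmup, thin >= 1)

  param_names <- c("y0", "a", "k")
  prior_scales <- c(3 * max(counts), max(counts), 3)
  if (likelihood == "normal") {
    param_names <- c(param_names, "sigma")
    prior_scales <- c(prior_scales, 3 * stats::sd(counts) + 1)
  }
  log_post <- make_log_posterior(counts, likelihood, prior_scales)

  # moment-based starting values, jittered per chain
  a0 <- max(mean(counts[15:21]), 0.2)
  y00 <- max(counts[1], a0 + 0.5, 0.5)
  k0 <- if (counts[1] > a0 && counts[2] > a0 && counts[1] > counts[2])
    min(max(log((counts[1] - a0) / (counts[2] - a0)), 0.05), 5) else 1
  init <- log(c(y00, a0, k0))
  if (likelihood == "normal")
    init <- c(init, log(stats::sd(counts) + 1))

  set.seed(as.integer(seed))
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    theta0 <- init + stats::rnorm(length(init), 0, 0.05)
    res[[ch]] <- run_chain(log_post, theta0, iter, warmup, thin, param_names)
  }
  draws <- lapply(res, `[[`, "draws")
  rhat <- compute_rhat(draws)

  structure(list(
    draws = draws,
    params = param_names,
    rhat = rhat,
    converged = all(rhat <= 1.01, na.rm = FALSE),
    accept = vapply(res, `[[`, numeric(1), "accept"),
    counts = counts,
    bin_index = seq_along(counts) - 1,
    likelihood = likelihood,
    prior_scales = stats::setNames(prior_scales, param_names),
    config = list(chains = chains, iter = iter, warmup = warmup,
                  thin = thin, seed = as.integer(seed))
  ), class = "decay_fit")
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Gelman--Rubin diagnostic on split chains: each chain is halved, the
#' between- and within-half variances compared, and
#' `R-hat = sqrt(((n-1)/n * W + B/n) / W)`. Values at or below 1.01
#' indicate convergence. Because chains are split, permuting draws within a
#' chain changes the statistic through the half assignment.
#'
#' @param draws a list with one element per chain: either numeric vectors
#'   (single parameter) or matrices with one column per parameter.
#' @return named numeric vector of R-hat values (single unnamed value for
#'   vector input).
#' @export
compute_rhat <- function(draws) {
  stopifnot(is.list(draws))
  if (length(draws) < 2)
    fp_stop("fp_rhat_error", "R-hat requires at least 2 chains")
  if (is.matrix(draws[[1]])) {
    pn <- colnames(draws[[1]])
    out <- vapply(seq_len(ncol(draws[[1]])), function(j) {
      compute_rhat(lapply(draws, function(m) m[, j]))
    }, numeric(1))
    return(stats::setNames(out, pn))
  }
  n <- min(lengths(draws))
  if (n < 4)
    fp_stop("fp_rhat_error", "R-hat requires at least 4 draws per chain")
  half <- n %/% 2
  halves <- unlist(lapply(draws, function(v) {
    v <- v[seq_len(2 * half)]
    list(v[seq_len(half)], v[half + seq_len(half)])
  }), recursive = FALSE)
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' All retained draws of a fit as one matrix
#' @param x a `decay_fit`.
#' @param ... unused.
#' @return numeric matrix, chains stacked, one column per parameter.
#' @export
as.matrix.decay_fit <- function(x, ...) do.call(rbind, x$draws)

#' @export
coef.decay_fit <- function(object, ...) {
  apply(as.matrix(object), 2, stats::median)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Exponential-decay fit (%s likelihood, %d chains x %d retained)\n",
              x$likelihood, x$config$chains, nrow(x$draws[[1]])))
  est <- coef(x)
  for (p in x$params)
    cat(sprintf("  %-5s median %10.3f   rhat %.4f\n", p, est[p], x$rhat[p]))
  cat(if (x$converged) "  converged (all rhat <= 1.01)\n"
      else "  WARNING: not converged (rhat > 1.01)\n")
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, mass = 0.95, ...) {
  m <- as.matrix(object)
  tab <- data.frame(
    parameter = object$params,
    median = apply(m, 2, stats::median),
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    hdi_low = NA_real_, hdi_high = NA_real_,
    rhat = object$rhat[object$params],
    row.names = NULL, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(tab))) {
    h <- hdi(m[, i], mass)
    tab$hdi_low[i] <- h[1]; tab$hdi_high[i] <- h[2]
  }
  structure(list(table = tab, mass = mass, converged = object$converged,
                 config = object$config),
            class = "summary.decay_fit")
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  cat(sprintf("Posterior summary (%.0f%% HDIs)\n", 100 * x$mass))
  print(x$table, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
fitted.decay_fit <- function(object, ...) {
  decay_mean(coef(object)[c("y0", "a", "k")], object$bin_index)
}

#' @export
residuals.decay_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$counts - mu
  if (type == "pearson") r <- r / sqrt(mu)
  r
}

#' Posterior predictive curve of a decay fit
#'
#' @param object a `decay_fit`.
#' @param newdata bin indices (default the fitted 0..20).
#' @param interval add a 95% HDI band computed across posterior draws of
#'   the mean curve.
#' @param ... unused.
#' @return vector of posterior-median curve values, or a matrix with
#'   columns `fit`, `lwr`, `upr` when `interval = TRUE`.
#' @export
predict.decay_fit <- function(object, newdata = NULL, interval = FALSE, ...) {
  x <- if (is.null(newdata)) object$bin_index else as.numeric(newdata)
  m <- as.matrix(object)
  curves <- vapply(x, function(xi) {
    (m[, "y0"] - m[, "a"]) * exp(-m[, "k"] * xi) + m[, "a"]
  }, numeric(nrow(m)))
  fit <- apply(curves, 2, stats::median)
  if (!interval) return(fit)
  band <- apply(curves, 2, hdi, mass = 0.95)
  cbind(fit = fit, lwr = band[1, ], upr = band[2, ])
}

#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- as.matrix(object)
  idx <- sample.int(nrow(m), nsim, replace = TRUE)
  out <- vapply(idx, function(i) {
    mu <- (m[i, "y0"] - m[i, "a"]) * exp(-m[i, "k"] * object$bin_index) +
      m[i, "a"]
    if (object$likelihood == "poisson") stats::rpois(length(mu), mu)
    else stats::rnorm(length(mu), mu, m[i, "sigma"])
  }, numeric(length(object$bin_index)))
  out
}

#' @export
plot.decay_fit <- function(x, ...) {
  pr <- predict(x, interval = TRUE)
  graphics::plot(x$bin_index, x$counts, pch = 16,
                 xlab = "latency bin (8 h)", ylab = "reply count",
                 main = "Reply-latency decay fit", ...)
  graphics::polygon(c(x$bin_index, rev(x$bin_index)),
                    c(pr[, "lwr"], rev(pr[, "upr"])),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::lines(x$bin_index, pr[, "fit"], col = "steelblue", lwd = 2)
  invisible(x)
}
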