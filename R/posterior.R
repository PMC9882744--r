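#' Highest-density interval of a sample
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws. For unimodal posteriors this is the usual HDI; it is never
#' longer than the equal-tailed interval of the same mass and always
#' contains the sample median.
#'
#' @param draws numeric sample (at least a handful of draws).
#' @param mass interval probability mass in (0, 1), default 0.95.
#' @return numeric `c(low, high)`.
#' @examples
#' hdi(rnorm(1e4))
#' @export
hdi <- function(draws, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1)
    fp_stop("fp_hdi_error", "mass must lie strictly between 0 and 1")
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 2) fp_stop("fp_hdi_error", "need at least 2 finite draws")
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}

#' Directional Bayes factor from posterior draws
#'
#' Ratio of posterior mass consistent with a hypothesised direction of
#' change to the mass opposing it: for `direction = "increase"`, the mass
#' above zero divided by the mass below zero. A value of 10 means the
#' stated direction is ten times more likely than its opposite. The
#' `"proportion"` method counts draws; the `"kde"` method integrates a
#' Gaussian kernel density estimate (Scott's bandwidth, trapezoidal rule on
#' a 2048-point grid spanning the draws plus/minus 3 bandwidths). When the
#' opposing side carries no mass the ratio is capped at the number of draws
#' and flagged via the `"capped"` attribute.
#'
#' @param draws numeric posterior draws of a difference (at least 100).
#' @param direction `"increase"` (mass above 0 in the numerator) or
#'   `"decrease"`.
#' @param method `"proportion"` (default) or `"kde"`.
#' @return positive number with logical attribute `capped`.
#' @examples
#' directional_bayes_factor(c(rep(1, 300), rep(-1, 100)) + rnorm(400, 0, .1))
#' @export
directional_bayes_factor <- function(draws,
                                     direction = c("increase", "decrease"),
                                     method = c("proportion", "kde")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100)
    fp_stop("fp_dbf_error", "need at least 100 draws, got %d", n)
  if (all(draws == 0))
    fp_stop("fp_dbf_error", "all draws are zero; direction undefined")

  if (method == "proportion") {
    pos <- mean(draws > 0)
    neg <- mean(draws < 0)
  } else {
    bw <- stats::bw.nrd(draws)
    if (!is.finite(bw) || bw <= 0) bw <- stats::sd(draws) / 10 + 1e-12
    de <- stats::density(draws, bw = bw, n = 2048,
                         from = min(draws) - 3 * bw, to = max(draws) + 3 * bw)
    dx <- diff(de$x)
    trap <- c(0, cumsum((de$y[-1] + de$y[-length(de$y)]) / 2 * dx))
    total <- trap[length(trap)]
    below <- stats::approx(de$x, trap, xout = 0, rule = 2)$y
    neg <- below / total
    pos <- 1 - neg
  }
  floor_mass <- 1 / (10 * n)
  capped <- FALSE
  if (pos < floor_mass) { pos <- floor_mass; capped <- TRUE }
  if (neg < floor_mass) { neg <- floor_mass; capped <- TRUE }
  ratio <- if (direction == "increase") pos / neg else neg / pos
  if (capped) ratio <- min(ratio, n)
  structure(ratio, capped = capped)
}

#' Difference distribution of a parameter between two fits
#'
#' Elementwise difference (lockdown minus pre-lockdown) of the two fits'
#' posterior draws for one parameter. The fits are independent, so each
#' draw array is shuffled with a seeded permutation before pairing; if the
#' fits retain different numbers of draws the larger set is subsampled.
#'
#' @param fit_lockdown,fit_pre converged `decay_fit` objects.
#' @param parameter `"y0"`, `"a"` or `"k"`.
#' @param seed seed for the pairing permutation.
#' @param require_converged refuse non-converged fits (default TRUE).
#' @return numeric vector of difference draws.
#' @export
difference_distribution <- function(fit_lockdown, fit_pre, parameter,
                                    seed = 1L, require_converged = TRUE) {
  stopifnot(inherits(fit_lockdown, "decay_fit"), inherits(fit_pre, "decay_fit"))
  if (!parameter %in% intersect(fit_lockdown$params, fit_pre$params))
    fp_stop("fp_param_error", "unknown parameter '%s'", parameter)
  if (require_converged && !(fit_lockdown$converged && fit_pre$converged))
    fp_stop("fp_convergence_error",
            "difference distribution requires converged fits")
  a <- as.matrix(fit_lockdown)[, parameter]
  b <- as.matrix(fit_pre)[, parameter]
  n <- min(length(a), length(b))
  set.seed(as.integer(seed))
  a <- a[sample.int(length(a), n)]
  b <- b[sample.int(length(b), n)]
  a - b
}

#' Compare two phases via their latency decay fits
#'
#' Fits the decay model to a pre-lockdown and a lockdown histogram and
#' summarises, for each parameter, the lockdown-minus-pre-lockdown
#' difference distribution: posterior median, 95% HDI, and the directional
#' Bayes factor for the hypothesised direction of change.
#'
#' @param hist_pre,hist_lockdown `latency_histogram`s (or 21-bin count
#'   vectors) for the two phases.
#' @param directions named character vector giving the hypothesised
#'   direction (`"increase"`/`"decrease"`) per parameter.
#' @param chains,iter,warmup,thin,seed sampler settings, see [fit_decay()];
#'   the two fits use `seed + 1` and `seed + 2`.
#' @param dbf_method `"proportion"` or `"kde"`, see
#'   [directional_bayes_factor()].
#' @param mass HDI mass (default 0.95).
#' @return a `phase_comparison`: data frame with one row per parameter and
#'   columns `parameter`, `median`, `hdi_low`, `hdi_high`, `direction`,
#'   `dbf`, `dbf_capped`; the two fits are attached as attributes.
#' @export
compare_phases <- function(hist_pre, hist_lockdown,
                           directions = c(y0 = "increase", a = "increase",
                                          k = "increase"),
                           chains = 4, iter = 4000, warmup = 2000, thin = 2,
                           seed = 1L, dbf_method = c("proportion", "kde"),
                           mass = 0.95) {
  dbf_method <- match.arg(dbf_method)
  fit_pre <- fit_decay(hist_pre, chains = chains, iter = iter,
                       warmup = warmup, thin = thin, seed = seed + 1L)
  fit_lock <- fit_decay(hist_lockdown, chains = chains, iter = iter,
                        warmup = warmup, thin = thin, seed = seed + 2L)
  pars <- c("y0", "a", "k")
  out <- data.frame(parameter = pars, median = NA_real_,
                    hdi_low = NA_real_, hdi_high = NA_real_,
                    direction = unname(directions[pars]),
                    dbf = NA_real_, dbf_capped = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pars)) {
    dd <- difference_distribution(fit_lock, fit_pre, pars[i],
                                  seed = seed + 10L + i)
    h <- hdi(dd, mass)
    bf <- directional_bayes_factor(dd, out$direction[i], dbf_method)
    out$median[i] <- stats::median(dd)
    out$hdi_low[i] <- h[1]; out$hdi_high[i] <- h[2]
    out$dbf[i] <- as.numeric(bf)
    out$dbf_capped[i] <- isTRUE(attr(bf, "capped"))
  }
  structure(out, class = c("phase_comparison", "data.frame"),
            fit_pre = fit_pre, fit_lockdown = fit_lock, mass = mass)
}

#' @export
print.phase_comparison <- function(x, ...) {
  cat(sprintf("Lockdown minus pre-lockdown differences (%.0f%% HDIs)\n",
              100 * (attr(x, "mass") %||% 0.95)))
  df <- as.data.frame(x)
  df$median <- round(df$median, 2)
  df$hdi_low <- round(df$hdi_low, 2)
  df$hdi_high <- round(df$hdi_high, 2)
  df$dbf <- round(df$dbf, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
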