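#' Run the full lockdown-analysis pipeline
#'
#' Orchestrates every stage on a synthetic corpus: generate (or accept) a
#' dataset, summarise it, classify user types, build the phase-by-subforum
#' descriptive table and percent changes, the weekly registration series,
#' the four reply-latency histograms, the four decay fits, and the two
#' lockdown-versus-pre-lockdown comparison tables. All randomness flows
#' from `seed`; rerunning with the same config and seed reproduces every
#' number.
#'
#' @param config a [generator_config()] (default: the study-mirroring
#'   [lockdown_study_config()]).
#' @param dataset optionally, an existing [forum_dataset()] to analyse
#'   instead of generating one (the generator stage is then skipped).
#' @param seed integer seed overriding `config$seed`.
#' @param chains,iter,warmup,thin sampler settings for the decay fits, see
#'   [fit_decay()].
#' @param dbf_method directional-Bayes-factor estimator, see
#'   [directional_bayes_factor()].
#' @param outdir optional directory; when given, the bundle's tables are
#'   written as CSV/JSON artifacts.
#' @param verbose log per-stage record counts via [message()].
#' @return a list of class `pipeline_bundle` with elements `summary`,
#'   `user_types`, `phase_table`, `percent_changes`, `registrations`,
#'   `histograms`, `fits`, `comparisons`, `ledger` (when generated) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = lockdown_study_config(), dataset = NULL,
                         seed = config$seed, chains = 4, iter = 4000,
                         warmup = 2000, thin = 2,
                         dbf_method = c("proportion", "kde"),
                         outdir = NULL, verbose = FALSE) {
  dbf_method <- match.arg(dbf_method)
  stopifnot(inherits(config, "generator_config"))
  periods <- config$periods
  validate_periods(periods)
  if (any(periods$end - periods$start + 1 < 7))
    fp_stop("fp_config_error", "periods must span at least one whole week")
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  ledger <- NULL
  if (is.null(dataset)) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    gen <- generate_dataset(cfg)
    dataset <- gen$dataset
    ledger <- gen$ledger
    say("generate: %d users, %d threads, %d posts",
        nrow(dataset$users), nrow(dataset$threads), nrow(dataset$posts))
  }

  summ <- dataset_summary(dataset)
  types <- type_distribution(dataset)
  say("classify: %d classifiable users", sum(types$n))
  tab <- phase_table(dataset, periods)

  pc <- percent_change_table(dataset, periods)
  regs <- registrations_per_week(dataset)
  say("describe: %d phase cells, %d registration weeks", nrow(tab), nrow(regs))

  hists <- lapply(periods$period, function(p)
    latency_histogram(dataset, p, periods))
  names(hists) <- periods$period
  say("bin: %s replies per period",
      paste(vapply(hists, function(h) sum(h$counts), numeric(1)),
            collapse = "/"))

  fits <- vector("list", length(hists))
  names(fits) <- names(hists)
  for (i in seq_along(hists)) {
    fits[[i]] <- fit_decay(hists[[i]], chains = chains, iter = iter,
                           warmup = warmup, thin = thin,
                           seed = seed + 100L + i)
    say("fit %s: rhat max %.4f", names(fits)[i], max(fits[[i]]$rhat))
  }

  comparisons <- list(
    phase_1 = phase_difference_table(
      fits[["lockdown_1"]], fits[["pre_lockdown_1"]],
      directions = c(y0 = "increase", a = "increase", k = "increase"),
      seed = seed + 200L, dbf_method = dbf_method),
    phase_2 = phase_difference_table(
      fits[["lockdown_2"]], fits[["pre_lockdown_2"]],
      directions = c(y0 = "decrease", a = "decrease", k = "increase"),
      seed = seed + 300L, dbf_method = dbf_method)
  )

  manifest <- list(
    package = "forumpulse",
    version = as.character(utils::packageVersion("forumpulse")),
    seed = as.integer(seed),
    sampler = list(chains = chains, iter = iter, warmup = warmup,
                   thin = thin, dbf_method = dbf_method),
    periods = periods,
    generated = is.null(dataset$metadata$source) ||
      identical(dataset$metadata$source, "forumpulse synthetic generator"),
    config_digest = config_digest(config)
  )

  bundle <- structure(list(summary = summ, user_types = types,
                           phase_table = tab, percent_changes = pc,
                           registrations = regs, histograms = hists,
                           fits = fits, comparisons = comparisons,
                           ledger = ledger, manifest = manifest),
                      class = "pipeline_bundle")
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

# per-parameter difference summaries from two already-fitted phases
phase_difference_table <- function(fit_lock, fit_pre, directions, seed,
                                   dbf_method = "proportion", mass = 0.95) {
  pars <- c("y0", "a", "k")
  out <- data.frame(parameter = pars, median = NA_real_, hdi_low = NA_real_,
                    hdi_high = NA_real_, direction = unname(directions[pars]),
                    dbf = NA_real_, dbf_capped = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pars)) {
    dd <- difference_distribution(fit_lock, fit_pre, pars[i],
                                  seed = seed + i,
                                  require_converged = FALSE)
    h <- hdi(dd, mass)
    bf <- directional_bayes_factor(dd, out$direction[i], dbf_method)
    out$median[i] <- stats::median(dd)
    out$hdi_low[i] <- h[1]; out$hdi_high[i] <- h[2]
    out$dbf[i] <- as.numeric(bf); out$dbf_capped[i] <- attr(bf, "capped")
  }
  structure(out, class = c("phase_comparison", "data.frame"), mass = mass)
}

# the printed-style percent-change comparisons: post counts, mean lengths
# and registrations, lockdown vs matching pre-lockdown phase
percent_change_table <- function(dataset, periods = default_periods()) {
  pairs <- list(phase_1 = c("pre_lockdown_1", "lockdown_1"),
                phase_2 = c("pre_lockdown_2", "lockdown_2"))
  rows <- list()
  for (ph in names(pairs)) {
    pre <- pairs[[ph]][1]; lock <- pairs[[ph]][2]
    for (s in c("entire_forum", subforum_levels())) {
      n0 <- posts_in(dataset, pre, s, periods)
      n1 <- posts_in(dataset, lock, s, periods)
      rows[[length(rows) + 1L]] <- data.frame(
        phase = ph, quantity = "n_posts", subforum = s,
        before = n0, after = n1,
        change_pct = if (n0 > 0) percent_change(n0, n1) else NA_real_,
        stringsAsFactors = FALSE)
      m0 <- tryCatch(length_stats(dataset, pre, s, periods)$mean_words,
                     error = function(e) NA_real_)
      m1 <- tryCatch(length_stats(dataset, lock, s, periods)$mean_words,
                     error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        phase = ph, quantity = "mean_words", subforum = s,
        before = m0, after = m1,
        change_pct = if (!is.na(m0) && m0 > 0 && !is.na(m1))
          percent_change(m0, m1) else NA_real_,
        stringsAsFactors = FALSE)
    }
    r0 <- registrations_in(dataset, pre, periods)
    r1 <- registrations_in(dataset, lock, periods)
    rows[[length(rows) + 1L]] <- data.frame(
      phase = ph, quantity = "registrations", subforum = "entire_forum",
      before = r0, after = r1,
      change_pct = if (r0 > 0) percent_change(r0, r1) else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

config_digest <- function(config) {
  # stable fingerprint of the numeric content, without external digest deps
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(list(
    registrations = config$registrations, activity = config$activity,
    decay = config$decay, mix = config$user_type_mix,
    anon_share = config$anon_share, seed = config$seed,
    periods = data.frame(period = config$periods$period,
                         start = as.character(config$periods$start),
                         end = as.character(config$periods$end))),
    digits = NA, auto_unbox = TRUE), f)
  unname(tools::md5sum(f))
}

write_bundle <- function(bundle, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  utils::write.csv(bundle$phase_table, file.path(outdir, "phase_table.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$user_types, file.path(outdir, "user_types.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$registrations,
                   file.path(outdir, "registrations_per_week.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(bundle$percent_changes, digits = NA,
                              dataframe = "rows", na = "null"),
             file.path(outdir, "percent_changes.json"))
  for (p in names(bundle$histograms))
    histogram_to_json(bundle$histograms[[p]],
                      file.path(outdir, paste0("histogram_", p, ".json")))
  for (ph in names(bundle$comparisons))
    utils::write.csv(as.data.frame(bundle$comparisons[[ph]]),
                     file.path(outdir, paste0("comparison_", ph, ".csv")),
                     row.names = FALSE)
  fitsum <- do.call(rbind, lapply(names(bundle$fits), function(p) {
    tb <- summary(bundle$fits[[p]])$table
    tb$period <- p
    tb
  }))
  utils::write.csv(fitsum, file.path(outdir, "decay_posteriors.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(bundle$manifest, digits = NA,
                              auto_unbox = TRUE, dataframe = "rows",
                              na = "null", force = TRUE),
             file.path(outdir, "manifest.json"))
  invisible(outdir)
}

#' Render a human-readable pipeline report
#'
#' @param bundle a `pipeline_bundle` from [run_pipeline()].
#' @return character vector of report lines (also printable via `cat`).
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  need <- c("summary", "phase_table", "percent_changes", "histograms",
            "fits", "comparisons", "manifest")
  miss <- need[vapply(need, function(n) is.null(bundle[[n]]), logical(1))]
  if (length(miss))
    fp_stop("fp_bundle_error", "incomplete bundle; missing: %s",
            paste(miss, collapse = ", "))
  missing_fits <- names(bundle$histograms)[
    !names(bundle$histograms) %in% names(bundle$fits)]
  if (length(missing_fits))
    fp_stop("fp_bundle_error", "missing decay fit(s) for period(s): %s",
            paste(missing_fits, collapse = ", "))
  fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)
  lines <- c(
    "Forum lockdown analysis report",
    sprintf("seed %d | config %s", bundle$manifest$seed,
            bundle$manifest$config_digest),
    "",
    sprintf("Corpus: %d posts, %d threads, %d registered users (%d anonymous/blocked posts)",
            bundle$summary$n_posts, bundle$summary$n_threads,
            bundle$summary$n_registered_users,
            bundle$summary$n_anonymous_blocked_posts),
    "",
    "Posts and mean post length by phase and subforum:")
  tb <- bundle$phase_table
  for (p in unique(tb$period)) {
    row <- tb[tb$period == p, ]
    lines <- c(lines, sprintf(
      "  %-15s %s", p,
      paste(sprintf("%s=%d (%s w)", substr(row$subforum, 1, 3), row$n_posts,
                    ifelse(is.na(row$mean_words), "-",
                           fmt(row$mean_words, 1))),
            collapse = "  ")))
  }
  lines <- c(lines, "", "Lockdown vs pre-lockdown changes (%):")
  pcs <- bundle$percent_changes
  pcs <- pcs[!is.na(pcs$change_pct), ]
  lines <- c(lines, sprintf("  %-7s %-13s %-16s %+.2f", pcs$phase,
                            pcs$quantity, pcs$subforum, pcs$change_pct))
  lines <- c(lines, "", "Decay posteriors (median y0/a/k, rhat max):")
  for (p in names(bundle$fits)) {
    est <- coef(bundle$fits[[p]])
    lines <- c(lines, sprintf("  %-15s %9.2f %8.2f %6.3f   %.4f", p,
                              est["y0"], est["a"], est["k"],
                              max(bundle$fits[[p]]$rhat)))
  }
  for (ph in names(bundle$comparisons)) {
    cmp <- bundle$comparisons[[ph]]
    lines <- c(lines, "", sprintf("%s differences (median [95%% HDI], dBF %s):",
                                  ph, paste(cmp$direction, collapse = "/")))
    lines <- c(lines, sprintf("  %-3s %+9.2f [%+9.2f, %+9.2f]  dBF %.2f%s",
                              cmp$parameter, cmp$median, cmp$hdi_low,
                              cmp$hdi_high, cmp$dbf,
                              ifelse(cmp$dbf_capped, " (capped)", "")))
  }
  lines
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
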