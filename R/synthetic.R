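#' Configuration for the synthetic forum generator
#'
#' Describes the statistical structure the generator emulates: user
#' registrations as a weekly-rate point process, per-period per-subforum
#' expected post volumes, heavy-tailed (log-normal) post lengths matched to
#' target means/SDs, an exponential-decay law for reply latencies per
#' period, and a target mix of behavioural user types.
#'
#' @param registrations data frame `(year, week, rate)`: expected new
#'   registrations per ISO calendar week.
#' @param activity data frame `(period, subforum, posts, word_mean,
#'   word_sd)`: expected total posts (initial plus within-week replies) and
#'   word-count targets per period and subforum.
#' @param decay data frame `(period, y0, a, k)`: reply-latency decay curve
#'   per period — expected count in the first 8-hour bin, asymptotic count,
#'   and decay rate per bin.
#' @param user_type_mix named proportions over the eight
#'   [user_type_levels()], summing to 1.
#' @param anon_share fraction of posts authored by the pooled
#'   anonymous/blocked sentinel (excluded from user-level analyses).
#' @param status_probs probabilities of regular/starter/verified status for
#'   generated users.
#' @param seed integer seed; the same config generates the same dataset.
#' @param periods period table, see [default_periods()].
#' @return an object of class `generator_config`.
#' @seealso [lockdown_study_config()], [generate_dataset()]
#' @export
generator_config <- function(registrations, activity, decay, user_type_mix,
                             anon_share = 0.22,
                             status_probs = c(regular = 0.61, starter = 0.35,
                                              verified = 0.04),
                             seed = 1L, periods = default_periods()) {
  validate_periods(periods)
  stopifnot(is.data.frame(registrations),
            all(c("year", "week", "rate") %in% names(registrations)),
            is.data.frame(activity),
            all(c("period", "subforum", "posts", "word_mean", "word_sd") %in%
                  names(activity)),
            is.data.frame(decay),
            all(c("period", "y0", "a", "k") %in% names(decay)))
  if (any(registrations$rate < 0) || any(activity$posts < 0))
    fp_stop("fp_config_error", "all rates must be non-negative")
  if (any(activity$word_sd < 0, na.rm = TRUE))
    fp_stop("fp_config_error", "word-count SDs must be non-negative")
  if (nrow(decay) > 0 && (any(decay$k <= 0) || any(decay$y0 < 0) ||
                          any(decay$a < 0)))
    fp_stop("fp_config_error", "decay parameters require y0, a >= 0, k > 0")
  if (!setequal(names(user_type_mix), user_type_levels()))
    fp_stop("fp_config_error", "user_type_mix must name all eight user types")
  if (any(user_type_mix < 0) || abs(sum(user_type_mix) - 1) > 1e-9)
    fp_stop("fp_config_error",
            "user_type_mix proportions must be >= 0 and sum to 1")
  if (anon_share < 0 || anon_share >= 1)
    fp_stop("fp_config_error", "anon_share must lie in [0, 1)")
  bad_p <- setdiff(unique(c(activity$period, decay$period)), periods$period)
  if (length(bad_p))
    fp_stop("fp_config_error", "unknown period(s) in config: %s",
            paste(bad_p, collapse = ", "))
  if (!all(activity$subforum %in% subforum_levels()))
    fp_stop("fp_config_error", "unknown subforum in activity table")

  # feasibility: the reply mass implied by the decay curve must fit inside
  # the configured total post volume of each period
  for (p in unique(activity$period)) {
    t_tot <- sum(activity$posts[activity$period == p])
    r_tot <- expected_replies(decay, p)
    if (t_tot == 0 && r_tot > 0)
      fp_stop("fp_config_error",
              "period '%s': zero posts configured but nonzero reply rates", p)
    if (t_tot > 0 && t_tot <= r_tot)
      fp_stop("fp_config_error",
              "period '%s': expected replies (%.1f) exceed expected posts (%d)",
              p, r_tot, t_tot)
  }
  structure(list(registrations = registrations, activity = activity,
                 decay = decay, user_type_mix = user_type_mix,
                 anon_share = anon_share, status_probs = status_probs,
                 seed = as.integer(seed), periods = periods),
            class = "generator_config")
}

# total expected within-week replies in a period = decay curve summed over bins
expected_replies <- function(decay, period) {
  row <- decay[decay$period == period, , drop = FALSE]
  if (nrow(row) == 0) return(0)
  sum(decay_curve_vec(row$y0[1], row$a[1], row$k[1]))
}

decay_curve_vec <- function(y0, a, k) {
  (y0 - a) * exp(-k * (seq_len(LATENCY_N_BINS) - 1)) + a
}

#' Generator configuration mirroring the 2020 German gambling-forum study
#'
#' Returns a [generator_config()] whose expectations reproduce the observed
#' conditions of a large German gambling discussion board around the 2020
#' COVID-19 casino closures: per-period per-subforum post volumes and mean
#' post lengths, weekly registration rates (including the marked lockdown-1
#' registration burst), and the four fitted reply-latency decay triples
#' (e.g. pre-lockdown 1: y0 = 1192.55, a = 49.79, k = 1.16). Quantities the
#' study does not pin down (per-period word-count SDs, the user-type mix,
#' baseline registration rates outside the four analysis windows) are
#' filled with realistic values documented in the package vignette.
#'
#' @param seed integer seed stored in the config.
#' @param scale multiplier applied to post volumes, registration rates and
#'   the decay curve's y0/a (not k), for quick reduced-size runs.
#' @return a `generator_config`.
#' @export
lockdown_study_config <- function(seed = 1L, scale = 1) {
  stopifnot(scale > 0)
  periods <- default_periods()
  pn <- period_names()

  entire <- c(17628, 9489, 10783, 8737)
  og <- c(4836, 6842, 7981, 6480)
  tg <- c(98, 36, 194, 22)
  pg <- c(246, 3, 161, 102)
  other <- entire - og - tg - pg

  m_entire <- c(49.91, 40.25, 46.96, 43.76)
  m_og <- c(39.27, 35.09, 43.71, 40.75)
  m_tg <- c(118.55, 69.44, 72.38, 39.73)
  m_pg <- c(147.78, 15.33, 56.58, 69.55)
  # "other" sections' mean implied by the entire-forum weighted mean
  m_other <- (entire * m_entire - og * m_og - tg * m_tg - pg * m_pg) / other
  # per-period SDs are not reported; reuse each subforum's corpus-level
  # coefficient of variation (e.g. online: 65.28 / 43.75)
  cv <- c(online = 65.28 / 43.75, terrestrial = 112.93 / 81.89,
          problem_gambling = 127.78 / 100.73, other = 76.44 / 50.12)

  activity <- data.frame(
    period = rep(pn, times = 4),
    subforum = rep(subforum_levels(), each = 4),
    posts = round(scale * c(og, tg, pg, other)),
    word_mean = c(m_og, m_tg, m_pg, m_other),
    stringsAsFactors = FALSE
  )
  activity$word_sd <- activity$word_mean * cv[activity$subforum]

  decay <- data.frame(
    period = pn,
    y0 = scale * c(1192.55, 1345.42, 1639.89, 1410.60),
    a  = scale * c(49.79, 73.17, 104.05, 60.75),
    k  = c(1.16, 1.28, 1.25, 1.42),
    stringsAsFactors = FALSE
  )

  # weekly registrations: observed period totals spread over their 7 weeks,
  # a baseline community rate outside the analysis windows
  period_reg <- c(pre_lockdown_1 = 175, lockdown_1 = 281,
                  pre_lockdown_2 = 199, lockdown_2 = 215) / 7
  mondays <- seq(as.Date("2019-09-30"), as.Date("2020-12-14"), by = 7)
  in_period <- assign_period(mondays, periods)
  rate <- ifelse(is.na(in_period), 20, period_reg[in_period])
  cw <- calendar_week(mondays)
  registrations <- data.frame(year = cw$year, week = cw$week,
                              rate = scale * as.numeric(rate))

  mix <- c(online_only = 0.41, terrestrial_only = 0.01, mixed = 0.025,
           online_only_pg = 0.03, terrestrial_only_pg = 0,
           mixed_pg = 0.055, pg_only = 0.01, other = 0.46)

  generator_config(registrations, activity, decay, mix,
                   anon_share = 0.22, seed = seed, periods = periods)
}

# substream seed for stage i of a dataset seed: an LCG scramble keeps the
# five stage streams of one dataset and those of neighbouring seeds from
# ever sharing a raw stream (seed+k schemes collide across adjacent seeds)
stream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1103515245 + 12345 * i) %% 2147483629)
}

# subforums a user of each type must post in / may post in
type_required <- function() list(
  online_only = "online", terrestrial_only = "terrestrial",
  mixed = c("online", "terrestrial"),
  online_only_pg = c("online", "problem_gambling"),
  terrestrial_only_pg = c("terrestrial", "problem_gambling"),
  mixed_pg = c("online", "terrestrial", "problem_gambling"),
  pg_only = "problem_gambling", other = "other")

type_allowed <- function() list(
  online_only = "online", terrestrial_only = "terrestrial",
  mixed = c("online", "terrestrial", "other"),
  online_only_pg = c("online", "problem_gambling"),
  terrestrial_only_pg = c("terrestrial", "problem_gambling"),
  mixed_pg = subforum_levels(),
  pg_only = "problem_gambling", other = "other")

#' Generate a synthetic forum dataset
#'
#' Draws a complete [forum_dataset()] from a [generator_config()]:
#' registrations are Poisson draws at the configured weekly rates (days
#' uniform within the week); initial posts per period and subforum are
#' Poisson at the configured expectations with timestamps uniform within
#' the period; reply counts per 8-hour latency bin are Poisson around the
#' configured decay curve, attached to eligible initial posts (those at
#' least 7 days before the period end, so extracted histograms match the
#' curve exactly in expectation) and placed uniformly within their bin;
#' word counts are log-normal matched to the configured mean/SD; authors
#' are assigned to realise the configured user-type mix, with a configured
#' share of posts going to the pooled anonymous sentinel.
#'
#' All randomness flows from `config$seed` through named substreams
#' (registrations, threads, replies, lengths, authors), so regenerating
#' with the same config reproduces the dataset exactly.
#'
#' @param config a [generator_config()].
#' @return list with elements `dataset` (a validated `forum_dataset`) and
#'   `ledger` (expected and realised counts for every generation stage).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  periods <- config$periods
  seed <- config$seed

  ## -- substream 1: registrations ------------------------------------------
  set.seed(stream_seed(seed, 1L))
  regs <- config$registrations
  reg_rows <- vector("list", nrow(regs))
  for (i in seq_len(nrow(regs))) {
    n <- stats::rpois(1, regs$rate[i])
    if (n == 0) next
    start <- iso_week_start(regs$year[i], regs$week[i])
    reg_rows[[i]] <- data.frame(
      registration_date = start + sample(0:6, n, replace = TRUE),
      year = regs$year[i], week = regs$week[i])
  }
  reg_df <- do.call(rbind, reg_rows)
  n_users <- if (is.null(reg_df)) 0L else nrow(reg_df)
  users <- data.frame(
    user_id = if (n_users) sprintf("u%05d", seq_len(n_users)) else character(0),
    name = if (n_users) sprintf("user_%d", seq_len(n_users)) else character(0),
    status = if (n_users) sample(names(config$status_probs), n_users,
                                 replace = TRUE, prob = config$status_probs)
             else character(0),
    registration_date = if (n_users) reg_df$registration_date else
      as.Date(character(0)),
    stringsAsFactors = FALSE)
  ledger_reg <- regs
  ledger_reg$n <- vapply(seq_len(nrow(regs)), function(i) {
    if (is.null(reg_rows[[i]])) 0L else nrow(reg_rows[[i]])
  }, integer(1))

  ## -- substream 2: threads / initial posts --------------------------------
  set.seed(stream_seed(seed, 2L))
  act <- config$activity
  thread_rows <- list()
  ledger_posts <- act[, c("period", "subforum", "posts")]
  names(ledger_posts)[3] <- "expected_total"
  ledger_posts$expected_initial <- NA_real_
  ledger_posts$n_initial <- 0L
  for (p in unique(act$period)) {
    prow <- periods[periods$period == p, ]
    t_tot <- sum(act$posts[act$period == p])
    if (t_tot == 0) next
    r_tot <- expected_replies(config$decay, p)
    i_tot <- t_tot - r_tot
    sec0 <- as.numeric(as.POSIXct(paste(prow$start, "00:00:00"),
                                  tz = "Europe/Berlin"))
    sec1 <- as.numeric(as.POSIXct(paste(prow$end + 1, "00:00:00"),
                                  tz = "Europe/Berlin"))
    for (s in act$subforum[act$period == p]) {
      idx <- which(ledger_posts$period == p & ledger_posts$subforum == s)
      exp_init <- act$posts[act$period == p & act$subforum == s] *
        i_tot / t_tot
      ledger_posts$expected_initial[idx] <- exp_init
      n_init <- stats::rpois(1, exp_init)
      ledger_posts$n_initial[idx] <- n_init
      if (n_init == 0) next
      ts <- sort(stats::runif(n_init, sec0, sec1))
      thread_rows[[length(thread_rows) + 1L]] <- data.frame(
        period = p, subforum = s,
        timestamp = as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
        stringsAsFactors = FALSE)
    }
  }
  threads_df <- if (length(thread_rows)) do.call(rbind, thread_rows) else
    data.frame(period = character(0), subforum = character(0),
               timestamp = as.POSIXct(character(0), tz = "UTC"))
  n_threads <- nrow(threads_df)
  threads_df <- threads_df[order(as.numeric(threads_df$timestamp)), ,
                           drop = FALSE]
  threads_df$thread_id <- sprintf("t%06d", seq_len(n_threads))
  pend <- periods$end[match(threads_df$period, periods$period)]
  threads_df$eligible <- civil_date(threads_df$timestamp) <= pend - 7

  ## -- substream 3: replies ------------------------------------------------
  set.seed(stream_seed(seed, 3L))
  reply_rows <- list()
  ledger_bins <- list()
  for (p in unique(act$period)) {
    drow <- config$decay[config$decay$period == p, , drop = FALSE]
    if (nrow(drow) == 0) next
    curve <- decay_curve_vec(drow$y0[1], drow$a[1], drow$k[1])
    elig <- which(n_threads > 0 & threads_df$period == p & threads_df$eligible)
    n_b <- integer(LATENCY_N_BINS)
    if (length(elig) > 0 && sum(curve) > 0) {
      for (b in seq_len(LATENCY_N_BINS)) {
        n_b[b] <- stats::rpois(1, curve[b])
        if (n_b[b] == 0) next
        th <- elig[sample.int(length(elig), n_b[b], replace = TRUE)]
        lat_h <- (b - 1) * LATENCY_BIN_HOURS +
          stats::runif(n_b[b], 0, LATENCY_BIN_HOURS)
        reply_rows[[length(reply_rows) + 1L]] <- data.frame(
          thread_id = threads_df$thread_id[th],
          subforum = threads_df$subforum[th],
          period = p,
          timestamp = threads_df$timestamp[th] + lat_h * 3600,
          stringsAsFactors = FALSE)
      }
    }
    ledger_bins[[p]] <- data.frame(period = p,
                                   bin = seq_len(LATENCY_N_BINS) - 1L,
                                   expected = curve, n = n_b)
  }
  replies_df <- if (length(reply_rows)) do.call(rbind, reply_rows) else NULL

  ## assemble posts ---------------------------------------------------------
  posts <- data.frame(
    thread_id = c(threads_df$thread_id,
                  if (!is.null(replies_df)) replies_df$thread_id),
    subforum = c(threads_df$subforum,
                 if (!is.null(replies_df)) replies_df$subforum),
    period = c(threads_df$period,
               if (!is.null(replies_df)) replies_df$period),
    timestamp = c(threads_df$timestamp,
                  if (!is.null(replies_df)) replies_df$timestamp),
    is_initial = c(rep(TRUE, n_threads),
                   rep(FALSE, if (is.null(replies_df)) 0 else nrow(replies_df))),
    stringsAsFactors = FALSE)
  n_posts <- nrow(posts)
  if (n_posts) {
    posts <- posts[order(as.numeric(posts$timestamp), !posts$is_initial), ]
    posts$post_id <- sprintf("p%07d", seq_len(n_posts))
    ord <- order(posts$thread_id, as.numeric(posts$timestamp),
                 !posts$is_initial, posts$post_id)
    pos <- sequence(rle(posts$thread_id[ord])$lengths)
    posts$position <- NA_integer_
    posts$position[ord] <- pos
  } else {
    posts$post_id <- character(0)
    posts$position <- integer(0)
  }

  ## -- substream 4: word counts --------------------------------------------
  set.seed(stream_seed(seed, 4L))
  posts$word_count <- rep(0L, n_posts)
  if (n_posts) {
    for (i in seq_len(nrow(act))) {
      sel <- which(posts$period == act$period[i] &
                     posts$subforum == act$subforum[i])
      if (!length(sel)) next
      m <- act$word_mean[i]; s <- act$word_sd[i]
      if (is.na(m) || m <= 0) next
      if (is.na(s) || s == 0) {
        posts$word_count[sel] <- as.integer(round(m))
      } else {
        sig2 <- log(1 + (s / m)^2)
        mu <- log(m) - sig2 / 2
        posts$word_count[sel] <-
          as.integer(round(stats::rlnorm(length(sel), mu, sqrt(sig2))))
      }
    }
  }

  ## -- substream 5: authors ------------------------------------------------
  set.seed(stream_seed(seed, 5L))
  posts$user_id <- rep(NA_character_, n_posts)
  anon <- if (n_posts) stats::runif(n_posts) < config$anon_share else logical(0)
  posts$user_id[anon] <- "u_anon"
  if (n_users) {
    users$type <- sample(names(config$user_type_mix), n_users, replace = TRUE,
                         prob = config$user_type_mix)
    req <- type_required(); alw <- type_allowed()
    post_date <- civil_date(posts$timestamp)
    for (s in subforum_levels()) {
      open <- which(!anon & posts$subforum == s)
      open <- open[order(as.numeric(posts$timestamp[open]))]
      if (!length(open)) next
      taken <- logical(length(open))
      # one seed post per user whose type requires this subforum; users in
      # descending registration order take the latest free post dated at or
      # after their registration (a maximum matching for this structure)
      needers <- which(vapply(users$type, function(tp) s %in% req[[tp]],
                              logical(1)))
      needers <- needers[order(users$registration_date[needers],
                               decreasing = TRUE)]
      j <- length(open)
      for (u in needers) {
        while (j >= 1L && taken[j]) j <- j - 1L
        if (j < 1L) break
        if (post_date[open[j]] < users$registration_date[u]) next
        posts$user_id[open[j]] <- users$user_id[u]
        taken[j] <- TRUE
        j <- j - 1L
      }
      # remaining posts: any user whose type allows the subforum and who
      # had registered by the posting date
      allowers <- which(vapply(users$type, function(tp) s %in% alw[[tp]],
                               logical(1)))
      allowers <- allowers[order(users$registration_date[allowers])]
      if (length(allowers)) {
        reg_dates <- users$registration_date[allowers]
        k <- 0L
        for (ii in which(!taken)) {
          d <- post_date[open[ii]]
          while (k < length(allowers) && reg_dates[k + 1L] <= d) k <- k + 1L
          posts$user_id[open[ii]] <- if (k == 0L) "u_anon" else
            users$user_id[allowers[sample.int(k, 1L)]]
        }
      } else {
        posts$user_id[open[!taken]] <- "u_anon"
      }
    }
    users$type <- NULL
  } else if (n_posts) {
    posts$user_id <- "u_anon"
  }

  users <- rbind(users, data.frame(
    user_id = "u_anon", name = NA_character_, status = "anonymous",
    registration_date = as.Date(NA), stringsAsFactors = FALSE))

  threads_tbl <- threads_df[, intersect(c("thread_id", "subforum"),
                                        names(threads_df)), drop = FALSE]
  if (!"thread_id" %in% names(threads_tbl))
    threads_tbl <- data.frame(thread_id = character(0),
                              subforum = character(0))
  post_tbl <- posts[, c("post_id", "thread_id", "user_id", "timestamp",
                        "subforum", "word_count", "is_initial", "position")]
  rownames(post_tbl) <- NULL

  ds <- forum_dataset(users, threads_tbl, post_tbl,
                      metadata = list(source = "forumpulse synthetic generator",
                                      seed = seed,
                                      created = "generated at run time"))

  reply_count <- n_posts - n_threads
  ledger_posts$n_replies <- 0L
  if (reply_count > 0) {
    rc <- table(paste(posts$period[!posts$is_initial],
                      posts$subforum[!posts$is_initial]))
    key <- paste(ledger_posts$period, ledger_posts$subforum)
    ledger_posts$n_replies <- as.integer(ifelse(key %in% names(rc),
                                                rc[key], 0L))
  }
  ledger_posts$n_posts <- ledger_posts$n_initial + ledger_posts$n_replies

  ledger <- list(
    seed = seed,
    registrations = ledger_reg,
    posts = ledger_posts,
    reply_bins = if (length(ledger_bins)) do.call(rbind, ledger_bins) else NULL,
    totals = list(n_users = n_users, n_threads = n_threads,
                  n_posts = n_posts,
                  n_anonymous_posts = sum(post_tbl$user_id == "u_anon"))
  )
  list(dataset = ds, ledger = ledger)
}
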