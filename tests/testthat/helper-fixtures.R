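# small hand-built corpora used across test files

utc <- function(x) as.POSIXct(x, tz = "UTC")

# 3 registered users + anonymous sentinel; 2 threads in lockdown_1
make_mini_dataset <- function() {
  users <- data.frame(
    user_id = c("u1", "u2", "u3", "anon"),
    name = c("alice", "bob", "carol", NA),
    status = c("regular", "starter", "verified", "anonymous"),
    registration_date = c(as.Date("2020-01-05"), as.Date("2020-02-01"),
                          as.Date("2020-03-20"), NA),
    stringsAsFactors = FALSE)
  threads <- data.frame(thread_id = c("t1", "t2"),
                        subforum = c("online", "problem_gambling"),
                        stringsAsFactors = FALSE)
  posts <- data.frame(
    post_id = c("p1", "p2", "p3", "p4", "p5"),
    thread_id = c("t1", "t1", "t1", "t2", "t2"),
    user_id = c("u1", "u2", "anon", "u3", "anon"),
    timestamp = utc(c("2020-03-20 10:00:00", "2020-03-20 11:00:00",
                      "2020-03-21 10:00:00", "2020-04-01 08:00:00",
                      "2020-04-02 08:00:00")),
    subforum = c("online", "online", "online",
                 "problem_gambling", "problem_gambling"),
    word_count = c(10L, 20L, 0L, 30L, 15L),
    is_initial = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    position = c(1L, 2L, 3L, 1L, 2L),
    stringsAsFactors = FALSE)
  forum_dataset(users, threads, posts)
}

# single-thread corpus with configurable reply latencies (hours after the
# initial post, which sits at the start of lockdown_1)
make_latency_dataset <- function(latencies_h,
                                 initial_ts = "2020-03-16 00:00:00") {
  n <- length(latencies_h)
  users <- data.frame(user_id = "u1", name = "alice", status = "regular",
                      registration_date = as.Date("2020-01-01"),
                      stringsAsFactors = FALSE)
  threads <- data.frame(thread_id = "t1", subforum = "online",
                        stringsAsFactors = FALSE)
  t0 <- utc(initial_ts)
  posts <- data.frame(
    post_id = sprintf("p%03d", seq_len(n + 1)),
    thread_id = "t1",
    user_id = "u1",
    timestamp = c(t0, t0 + latencies_h * 3600),
    subforum = "online",
    word_count = 5L,
    is_initial = c(TRUE, rep(FALSE, n)),
    position = seq_len(n + 1),
    stringsAsFactors = FALSE)
  forum_dataset(users, threads, posts)
}

# minimal generator config: a single period's online subforum
make_tiny_config <- function(posts = 60, seed = 1, y0 = 0, a = 0, k = 1,
                             rate = 5) {
  act <- data.frame(period = "lockdown_1", subforum = "online",
                    posts = posts, word_mean = 30, word_sd = 40,
                    stringsAsFactors = FALSE)
  dec <- if (y0 > 0)
    data.frame(period = "lockdown_1", y0 = y0, a = a, k = k,
               stringsAsFactors = FALSE)
  else data.frame(period = character(0), y0 = numeric(0), a = numeric(0),
                  k = numeric(0))
  regs <- data.frame(year = 2020, week = 5:12, rate = rate)
  mix <- c(online_only = 0.7, terrestrial_only = 0, mixed = 0,
           online_only_pg = 0, terrestrial_only_pg = 0, mixed_pg = 0,
           pg_only = 0, other = 0.3)
  generator_config(regs, act, dec, mix, anon_share = 0.1, seed = seed)
}

# a decay_fit shell with fixed draws, for exercising posterior operations
make_constant_fit <- function(value, n = 500, params = c("y0", "a", "k")) {
  draws <- matrix(value, n, length(params),
                  dimnames = list(NULL, params))
  structure(list(draws = list(draws, draws), params = params,
                 rhat = stats::setNames(rep(1, length(params)), params),
                 converged = TRUE, accept = c(1, 1),
                 counts = rep(1, 21), bin_index = 0:20,
                 likelihood = "poisson",
                 config = list(chains = 2, iter = n, warmup = 0, thin = 1,
                               seed = 0)),
            class = "decay_fit")
}
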