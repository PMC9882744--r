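test_that("zero rates generate an empty corpus; invalid configs are rejected", {
  cfg <- make_tiny_config(posts = 0, rate = 0)
  g <- generate_dataset(cfg)
  expect_equal(nrow(g$dataset$posts), 0L)
  expect_equal(dataset_summary(g$dataset)$n_posts, 0L)

  act <- data.frame(period = "lockdown_1", subforum = "online", posts = 0,
                    word_mean = 30, word_sd = 40)
  dec <- data.frame(period = "lockdown_1", y0 = 50, a = 2, k = 1)
  regs <- data.frame(year = 2020, week = 10, rate = 1)
  mix <- c(online_only = 1, terrestrial_only = 0, mixed = 0,
           online_only_pg = 0, terrestrial_only_pg = 0, mixed_pg = 0,
           pg_only = 0, other = 0)
  # replies configured but no posts to attach them to
  expect_error(generator_config(regs, act, dec, mix),
               class = "fp_config_error")
  badmix <- mix; badmix["online_only"] <- 0.5
  act$posts <- 100
  expect_error(generator_config(regs, act, dec, badmix),
               "sum to 1", class = "fp_config_error")
  expect_error(generator_config(regs, act,
                                transform(dec, k = -1), mix),
               class = "fp_config_error")
})

test_that("generation is deterministic in the seed", {
  g1 <- generate_dataset(make_tiny_config(posts = 70, seed = 4, y0 = 20, a = 1))
  g2 <- generate_dataset(make_tiny_config(posts = 70, seed = 4, y0 = 20, a = 1))
  g3 <- generate_dataset(make_tiny_config(posts = 70, seed = 5, y0 = 20, a = 1))
  expect_identical(g1$dataset$posts, g2$dataset$posts)
  expect_identical(g1$dataset$users, g2$dataset$users)
  expect_false(identical(g1$dataset$posts, g3$dataset$posts))
})

test_that("realised post counts concentrate around configured expectations", {
  cfg <- make_tiny_config(posts = 500, seed = 8, y0 = 60, a = 3)
  g <- generate_dataset(cfg)
  n <- nrow(g$dataset$posts)
  expect_lt(abs(n - 500), 4 * sqrt(500))
  # ledger bookkeeping equals what the dataset contains
  s <- dataset_summary(g$dataset)
  expect_equal(s$n_posts, g$ledger$totals$n_posts)
  expect_equal(s$n_threads, g$ledger$totals$n_threads)
  expect_equal(sum(g$ledger$posts$n_posts), s$n_posts)
  expect_equal(sum(g$ledger$posts$n_initial), s$n_threads)
  expect_equal(s$n_anonymous_blocked_posts, g$ledger$totals$n_anonymous_posts)
})

test_that("generated corpora always satisfy the relational invariants", {
  for (seed in c(2, 13, 77)) {
    g <- generate_dataset(make_tiny_config(posts = 120, seed = seed,
                                           y0 = 35, a = 2))
    expect_s3_class(validate_forum_dataset(g$dataset), "forum_dataset")
    expect_length(attr(validate_forum_dataset(g$dataset), "quality_flags"), 0)
  }
})

test_that("the mean realised count over many seeds matches the expectation", {
  nseed <- 40
  counts <- vapply(seq_len(nseed), function(s) {
    nrow(generate_dataset(make_tiny_config(posts = 80, seed = 400 + s,
                                           y0 = 25, a = 1))$dataset$posts)
  }, numeric(1))
  se <- sqrt(80 / nseed)  # Poisson variance propagated to the mean
  expect_lt(abs(mean(counts) - 80), 3.5 * se)
})

test_that("the study-mirroring config encodes the observed conditions", {
  cfg <- lockdown_study_config()
  expect_s3_class(cfg, "generator_config")
  a <- cfg$activity
  expect_equal(a$posts[a$period == "lockdown_1" & a$subforum == "online"],
               6842)
  expect_equal(a$posts[a$period == "pre_lockdown_1" & a$subforum == "online"],
               4836)
  expect_equal(a$word_mean[a$period == "pre_lockdown_1" &
                             a$subforum == "problem_gambling"], 147.78)
  d <- cfg$decay
  expect_equal(unlist(d[d$period == "pre_lockdown_2", c("y0", "a", "k")]),
               c(y0 = 1639.89, a = 104.05, k = 1.25))
  # entire-forum totals reproduced by construction across subforums
  expect_equal(sum(a$posts[a$period == "pre_lockdown_1"]), 17628)
  expect_equal(sum(a$posts[a$period == "lockdown_2"]), 8737)
  # registration expectations per period
  regs <- cfg$registrations
  wk_start <- forumpulse:::iso_week_start(regs$year, regs$week)
  in_ld1 <- assign_period(wk_start) == "lockdown_1"
  expect_equal(sum(regs$rate[which(in_ld1)]), 281)
})

test_that("study-scale corpora reproduce the period-subforum cells", {
  g <- generate_dataset(lockdown_study_config(seed = 97))
  ds <- g$dataset
  n <- posts_in(ds, "lockdown_1", "online")
  expect_lt(abs(n - 6842), 4 * sqrt(6842))
  n2 <- posts_in(ds, "pre_lockdown_2", "terrestrial")
  expect_lt(abs(n2 - 194), 4 * sqrt(194))
  ls <- length_stats(ds, "pre_lockdown_1", "problem_gambling")
  se <- 147.78 * (127.78 / 100.73) / sqrt(ls$n)
  expect_lt(abs(ls$mean_words - 147.78), 3.5 * se)
  reg <- registrations_in(ds, "lockdown_1")
  expect_lt(abs(reg - 281), 4 * sqrt(281))
})
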