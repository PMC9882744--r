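test_that("percent_change reproduces hand-computed and printed values", {
  expect_equal(percent_change(4836, 6842), 41.48)
  expect_equal(percent_change(98, 36), -63.27)
  expect_equal(percent_change(175, 281), 60.57)
  expect_equal(percent_change(100, 100), 0)
  expect_error(percent_change(0, 5), class = "fp_undefined_change")
  # opposite inputs give opposite-signed changes
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 1, 1000); b <- runif(1, 1, 1000)
    if (abs(a - b) < 1e-6) next
    expect_equal(sign(percent_change(a, b)), -sign(percent_change(b, a)))
  }
})

test_that("length statistics use the sample (n-1) convention", {
  users <- data.frame(user_id = "u1", name = "a", status = "regular",
                      registration_date = as.Date("2020-01-01"),
                      stringsAsFactors = FALSE)
  threads <- data.frame(thread_id = "t1", subforum = "online",
                        stringsAsFactors = FALSE)
  posts <- data.frame(
    post_id = paste0("p", 1:3), thread_id = "t1", user_id = "u1",
    timestamp = utc("2020-03-20 10:00:00") + (0:2) * 60,
    subforum = "online", word_count = c(10L, 20L, 30L),
    is_initial = c(TRUE, FALSE, FALSE), position = 1:3,
    stringsAsFactors = FALSE)
  ds <- forum_dataset(users, threads, posts)
  ls <- length_stats(ds, "lockdown_1", "online")
  expect_equal(ls$mean_words, 20)
  expect_equal(ls$sd_words, 10)
  # single post: sd 0 by convention
  one <- posts[1, ]; one$word_count <- 7L
  ds1 <- forum_dataset(users, threads, one)
  ls1 <- length_stats(ds1, "lockdown_1", "online")
  expect_equal(ls1$mean_words, 7)
  expect_equal(ls1$sd_words, 0)
  expect_error(length_stats(ds, "lockdown_2", "online"),
               class = "fp_empty_selection")
})

test_that("period post counts partition across subforums", {
  g <- generate_dataset(make_tiny_config(posts = 120, seed = 11,
                                         y0 = 40, a = 2))
  ds <- g$dataset
  total <- posts_in(ds, "lockdown_1", "entire_forum")
  parts <- vapply(c("online", "terrestrial", "problem_gambling", "other"),
                  function(s) posts_in(ds, "lockdown_1", s), numeric(1))
  expect_equal(total, sum(parts))
  expect_equal(posts_in(ds, "pre_lockdown_2"), 0L)
})

test_that("registration series counts by ISO week and sums to period totals", {
  ds <- make_mini_dataset()
  rw <- registrations_per_week(ds)
  # u3 registered 2020-03-20 -> week 12 of 2020, inside lockdown 1
  expect_true(any(rw$year == 2020 & rw$week == 12 & rw$n == 1))
  expect_equal(sum(rw$n), 3L)  # sentinel has no registration date
  expect_equal(registrations_in(ds, "lockdown_1"), 1L)

  cfg <- make_tiny_config(posts = 0, seed = 9, rate = 25)
  cfg$decay <- cfg$decay[0, ]
  g <- generate_dataset(cfg)
  tot <- sum(registrations_per_week(g$dataset)$n)
  expect_lt(abs(tot - 8 * 25), 4 * sqrt(8 * 25))  # Poisson concentration
})

test_that("activity profiles measure spans and posting concentration", {
  users <- data.frame(
    user_id = c("u1", "u2"), name = c("a", "b"), status = "regular",
    registration_date = as.Date(c("2020-01-01", "2020-02-25")),
    stringsAsFactors = FALSE)
  threads <- data.frame(thread_id = "t1", subforum = "online",
                        stringsAsFactors = FALSE)
  n <- 10
  posts <- data.frame(
    post_id = sprintf("p%02d", 1:n), thread_id = "t1",
    user_id = c(rep("u1", 9), "u2"),
    timestamp = utc("2020-03-01 12:00:00") + c(0, 1:8 * 3600,
                                               365 * 86400),
    subforum = "online", word_count = 5L,
    is_initial = c(TRUE, rep(FALSE, n - 1)), position = 1:n,
    stringsAsFactors = FALSE)
  ds <- forum_dataset(users, threads, posts)
  ap <- activity_profile(ds)
  expect_equal(ap$n_posts[ap$user_id == "u1"], 9L)
  expect_equal(ap$span_days[ap$user_id == "u2"], 0)
  expect_equal(ap$days_to_first_post[ap$user_id == "u1"], 60)
  expect_equal(top_share(ap, 1), 0.9)
  expect_equal(top_share(ap, 2), 1)
  # concentration is non-decreasing in k on generated data
  g <- generate_dataset(make_tiny_config(posts = 100, seed = 21,
                                         y0 = 30, a = 2))
  shares <- top_share(activity_profile(g$dataset), 1:10)
  expect_true(all(diff(shares) >= 0))
})

test_that("subforum shares are percentages of the entire corpus", {
  g <- generate_dataset(make_tiny_config(posts = 90, seed = 2, y0 = 25, a = 1))
  sh <- subforum_shares(g$dataset)
  expect_equal(sum(sh$percent), 100)
  expect_equal(sh$percent[sh$subforum == "online"], 100)  # single-subforum
  expect_equal(sum(sh$n_posts), nrow(g$dataset$posts))
})
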