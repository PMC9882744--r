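test_that("a minimal corpus constructs and summarises correctly", {
  ds <- make_mini_dataset()
  expect_s3_class(ds, "forum_dataset")
  s <- dataset_summary(ds)
  expect_equal(s$n_posts, 5L)
  expect_equal(s$n_threads, 2L)
  expect_equal(s$n_registered_users, 3L)     # anonymous sentinel excluded
  expect_equal(s$n_anonymous_blocked_posts, 2L)
  ir <- s$initial_reply
  expect_equal(ir$n_posts[ir$subforum == "entire_forum"], 5L)
  # initial and reply fractions partition every non-empty subforum
  nz <- !is.na(ir$initial_fraction)
  expect_equal(ir$initial_fraction[nz] + ir$reply_fraction[nz],
               rep(1, sum(nz)))
})

test_that("integrity violations are rejected with row identifiers", {
  ds <- make_mini_dataset()
  bad <- ds$posts
  bad$timestamp[2] <- utc("2020-03-19 10:00:00")  # reply before initial
  expect_error(forum_dataset(ds$users, ds$threads, bad),
               "p2", class = "fp_integrity_error")
  bad <- ds$posts
  bad$user_id[4] <- "ghost"
  expect_error(forum_dataset(ds$users, ds$threads, bad),
               "p4", class = "fp_integrity_error")
  bad <- ds$posts
  bad$is_initial[2] <- TRUE                       # two initial posts in t1
  expect_error(forum_dataset(ds$users, ds$threads, bad),
               "t1", class = "fp_integrity_error")
  bad <- ds$posts
  bad$subforum[5] <- "online"                     # disagrees with thread t2
  expect_error(forum_dataset(ds$users, ds$threads, bad),
               class = "fp_integrity_error")
})

test_that("missing tables and columns give schema errors naming the element", {
  dir <- withr::local_tempdir()
  expect_error(load_dataset(dir), "users.csv", class = "fp_schema_error")
  ds <- make_mini_dataset()
  save_dataset(ds, dir)
  u <- utils::read.csv(file.path(dir, "users.csv"))
  u$status <- NULL
  utils::write.csv(u, file.path(dir, "users.csv"), row.names = FALSE)
  expect_error(load_dataset(dir), "status", class = "fp_schema_error")
})

test_that("save/load round-trips preserve all records, and resaving is byte-identical", {
  ds <- make_mini_dataset()
  dir1 <- withr::local_tempdir()
  save_dataset(ds, dir1)
  back <- load_dataset(dir1)
  expect_equal(nrow(back$posts), nrow(ds$posts))
  expect_equal(nrow(back$users), nrow(ds$users))
  ord <- order(ds$posts$post_id)
  expect_equal(back$posts$word_count, ds$posts$word_count[ord])
  expect_equal(back$posts$timestamp, ds$posts$timestamp[ord])
  expect_equal(back$users$registration_date,
               ds$users$registration_date[order(ds$users$user_id)])
  dir2 <- withr::local_tempdir()
  save_dataset(back, dir2)
  for (f in c("users.csv", "threads.csv", "posts.csv"))
    expect_identical(readLines(file.path(dir2, f)),
                     readLines(file.path(dir1, f)))
})

test_that("round-trip also holds for generated corpora and the empty corpus", {
  g <- generate_dataset(make_tiny_config(posts = 200, seed = 3,
                                         y0 = 30, a = 2))
  dir <- withr::local_tempdir()
  save_dataset(g$dataset, dir)
  back <- load_dataset(dir)
  expect_equal(nrow(back$posts), nrow(g$dataset$posts))
  expect_equal(nrow(back$threads), nrow(g$dataset$threads))
  expect_equal(nrow(back$users), nrow(g$dataset$users))
  expect_equal(sort(back$posts$post_id), sort(g$dataset$posts$post_id))

  empty <- forum_dataset(
    data.frame(user_id = character(0), name = character(0),
               status = character(0),
               registration_date = as.Date(character(0))),
    data.frame(thread_id = character(0), subforum = character(0)),
    data.frame(post_id = character(0), thread_id = character(0),
               user_id = character(0),
               timestamp = as.POSIXct(character(0), tz = "UTC"),
               subforum = character(0), word_count = integer(0),
               is_initial = logical(0), position = integer(0)))
  dire <- withr::local_tempdir()
  save_dataset(empty, dire)
  back <- load_dataset(dire)
  s <- dataset_summary(back)
  expect_equal(s$n_posts, 0L)
  expect_equal(s$n_registered_users, 0L)
})

test_that("summary totals are invariant under record permutation", {
  g <- generate_dataset(make_tiny_config(posts = 60, seed = 5, y0 = 20, a = 1))
  ds <- g$dataset
  set.seed(1)
  shuf <- forum_dataset(ds$users[sample(nrow(ds$users)), ],
                        ds$threads[sample(nrow(ds$threads)), ],
                        ds$posts[sample(nrow(ds$posts)), ])
  expect_equal(dataset_summary(shuf)[c("n_posts", "n_threads",
                                       "n_registered_users")],
               dataset_summary(ds)[c("n_posts", "n_threads",
                                     "n_registered_users")])
  expect_equal(type_distribution(shuf), type_distribution(ds))
})

test_that("sqlite format is reported as unsupported", {
  ds <- make_mini_dataset()
  expect_error(save_dataset(ds, tempfile(), format = "sqlite"),
               class = "fp_format_error")
  expect_error(load_dataset(tempfile(), format = "sqlite"),
               class = "fp_format_error")
})
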