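#' @keywords internal
subforum_levels <- function() c("online", "terrestrial", "problem_gambling", "other")

#' @keywords internal
user_status_levels <- function() {
  c("regular", "starter", "verified", "anonymous", "blocked", "deleted")
}

# statuses counted as registered profiles; anonymous/blocked/deleted users have
# no unique profile page and are pooled in post-level analyses only
registered_statuses <- function() c("regular", "starter", "verified")

#' Construct a forum dataset
#'
#' A `forum_dataset` bundles the three relational tables of a discussion
#' board corpus: `users` (one row per account, plus pooled sentinel rows for
#' anonymous/blocked authors), `threads` (one row per thread with its
#' subforum label) and `posts` (one row per post). Posts carry their own
#' subforum label, a word count (0 is legal: posts may be emptied by
#' moderators), an initial-post flag and their position in the thread.
#'
#' @param users data frame with columns `user_id`, `name`, `status`
#'   (one of regular/starter/verified/anonymous/blocked/deleted) and
#'   `registration_date` (`Date`, `NA` for users without a profile page).
#' @param threads data frame with columns `thread_id`, `subforum`.
#' @param posts data frame with columns `post_id`, `thread_id`, `user_id`,
#'   `timestamp` (`POSIXct`, stored as UTC), `subforum`, `word_count`,
#'   `is_initial`, `position`.
#' @param metadata list of free-form provenance fields (source, created).
#' @param validate check the referential-integrity invariants (default TRUE).
#' @return an object of class `forum_dataset`.
#' @seealso [load_dataset()], [save_dataset()], [dataset_summary()],
#'   [generate_dataset()]
#' @export
forum_dataset <- function(users, threads, posts, metadata = list(),
                          validate = TRUE) {
  users   <- as.data.frame(users,   stringsAsFactors = FALSE)
  threads <- as.data.frame(threads, stringsAsFactors = FALSE)
  posts   <- as.data.frame(posts,   stringsAsFactors = FALSE)
  if (!inherits(posts$timestamp, "POSIXct") && nrow(posts) > 0)
    stop("posts$timestamp must be POSIXct", call. = FALSE)
  if (nrow(posts) > 0) attr(posts$timestamp, "tzone") <- "UTC"
  ds <- structure(list(users = users, threads = threads, posts = posts,
                       metadata = metadata),
                  class = "forum_dataset")
  if (validate) ds <- validate_forum_dataset(ds)
  ds
}

fp_stop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = NULL)))
}

#' Validate a forum dataset
#'
#' Hard invariants (violations raise an `fp_integrity_error` naming the
#' offending rows): every post resolves to a user and a thread; each thread
#' has exactly one initial post at position 1; replies are not earlier than
#' their initial post; posts carry their thread's subforum label. Soft
#' data-quality checks (registration date after the user's first post;
#' anonymous/blocked/deleted users carrying a registration date) are recorded
#' in the `quality_flags` attribute, not rejected.
#'
#' @param ds a [forum_dataset()].
#' @return the dataset, invisibly usable, with a `quality_flags` attribute.
#' @export
validate_forum_dataset <- function(ds) {
  users <- ds$users; threads <- ds$threads; posts <- ds$posts
  need <- function(df, cols, tbl) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      fp_stop("fp_schema_error", "table '%s' is missing column(s): %s",
              tbl, paste(miss, collapse = ", "))
  }
  need(users, c("user_id", "name", "status", "registration_date"), "users")
  need(threads, c("thread_id", "subforum"), "threads")
  need(posts, c("post_id", "thread_id", "user_id", "timestamp", "subforum",
                "word_count", "is_initial", "position"), "posts")

  bad_status <- !users$status %in% user_status_levels()
  if (any(bad_status))
    fp_stop("fp_schema_error", "unknown user status for user(s): %s",
            paste(users$user_id[bad_status], collapse = ", "))
  bad_sf <- !posts$subforum %in% subforum_levels()
  if (any(bad_sf))
    fp_stop("fp_schema_error", "unknown subforum for post(s): %s",
            paste(posts$post_id[bad_sf], collapse = ", "))

  orphan_user <- !posts$user_id %in% users$user_id
  if (any(orphan_user))
    fp_stop("fp_integrity_error",
            "post(s) with unresolvable author reference: %s",
            paste(posts$post_id[orphan_user], collapse = ", "))
  orphan_thread <- !posts$thread_id %in% threads$thread_id
  if (any(orphan_thread))
    fp_stop("fp_integrity_error", "post(s) with unknown thread: %s",
            paste(posts$post_id[orphan_thread], collapse = ", "))

  if (nrow(posts) > 0) {
    if (any(posts$word_count < 0))
      fp_stop("fp_integrity_error", "negative word_count for post(s): %s",
              paste(posts$post_id[posts$word_count < 0], collapse = ", "))
    ini_per_thread <- tapply(posts$is_initial, posts$thread_id, sum)
    bad <- names(ini_per_thread)[ini_per_thread != 1L]
    if (length(bad))
      fp_stop("fp_integrity_error",
              "thread(s) without exactly one initial post: %s",
              paste(bad, collapse = ", "))
    if (any(posts$position[posts$is_initial] != 1L))
      fp_stop("fp_integrity_error",
              "initial post(s) not at position 1: %s",
              paste(posts$post_id[posts$is_initial & posts$position != 1L],
                    collapse = ", "))
    ini <- posts[posts$is_initial, c("thread_id", "timestamp", "subforum")]
    t0 <- ini$timestamp[match(posts$thread_id, ini$thread_id)]
    early <- !posts$is_initial & posts$timestamp < t0
    if (any(early))
      fp_stop("fp_integrity_error",
              "reply post(s) earlier than their initial post: %s",
              paste(posts$post_id[early], collapse = ", "))
    sf0 <- threads$subforum[match(posts$thread_id, threads$thread_id)]
    mism <- posts$subforum != sf0
    if (any(mism))
      fp_stop("fp_integrity_error",
              "post(s) whose subforum differs from their thread's: %s",
              paste(posts$post_id[mism], collapse = ", "))
  }

  flags <- character(0)
  reg <- users$status %in% registered_statuses()
  ghost_reg <- !reg & !is.na(users$registration_date)
  if (any(ghost_reg))
    flags <- c(flags, sprintf(
      "anonymous/blocked/deleted user(s) with a registration date: %s",
      paste(users$user_id[ghost_reg], collapse = ", ")))
  if (nrow(posts) > 0) {
    first_post <- tapply(as.numeric(posts$timestamp), posts$user_id, min)
    idx <- match(users$user_id, names(first_post))
    fp_date <- as.Date(as.POSIXct(unname(first_post[idx]),
                                  origin = "1970-01-01", tz = "UTC"),
                       tz = "Europe/Berlin")
    late <- reg & !is.na(users$registration_date) & !is.na(fp_date) &
      users$registration_date > fp_date
    if (any(late))
      flags <- c(flags, sprintf(
        "user(s) registered after their first post: %s",
        paste(users$user_id[late], collapse = ", ")))
  }
  attr(ds, "quality_flags") <- flags
  ds
}

csv_tables <- function() c("users", "threads", "posts")

#' Write a forum dataset to disk
#'
#' Writes the relational schema as one UTF-8 CSV file per table
#' (`users.csv`, `threads.csv`, `posts.csv`) under `path`. Rows are ordered
#' by primary key and timestamps serialised as ISO-8601 UTC, so saving a
#' reloaded dataset reproduces the files byte for byte.
#'
#' @param dataset a [forum_dataset()].
#' @param path directory to create/write into.
#' @param format only `"csv_dir"` is supported; `"sqlite"` (the schema's
#'   other on-disk form) raises an unsupported-format error.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path, format = c("csv_dir", "sqlite")) {
  format <- match.arg(format)
  if (format == "sqlite")
    fp_stop("fp_format_error",
            "sqlite output requires an SQLite driver; use format = 'csv_dir'")
  stopifnot(inherits(dataset, "forum_dataset"))
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    fp_stop("fp_io_error", "cannot create directory '%s'", path)

  u <- dataset$users[order(dataset$users$user_id), , drop = FALSE]
  u$registration_date <- ifelse(is.na(u$registration_date), "",
                                format(u$registration_date, "%Y-%m-%d"))
  u$name <- ifelse(is.na(u$name), "", u$name)
  th <- dataset$threads[order(dataset$threads$thread_id), , drop = FALSE]
  p <- dataset$posts[order(dataset$posts$post_id), , drop = FALSE]
  p$timestamp <- format(p$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  p$is_initial <- as.integer(p$is_initial)
  p$word_count <- as.integer(p$word_count)
  p$position <- as.integer(p$position)

  utils::write.csv(u[, c("user_id", "name", "status", "registration_date")],
                   file.path(path, "users.csv"), row.names = FALSE, na = "")
  utils::write.csv(th[, c("thread_id", "subforum")],
                   file.path(path, "threads.csv"), row.names = FALSE, na = "")
  utils::write.csv(p[, c("post_id", "thread_id", "user_id", "timestamp",
                         "subforum", "word_count", "is_initial", "position")],
                   file.path(path, "posts.csv"), row.names = FALSE, na = "")
  invisible(path)
}

#' Read a forum dataset from disk
#'
#' Reads the CSV directory layout written by [save_dataset()] and validates
#' all referential-integrity invariants. Missing files or columns raise an
#' `fp_schema_error` naming the missing element; invariant violations raise
#' an `fp_integrity_error` naming the offending rows.
#'
#' @inheritParams save_dataset
#' @param path directory containing `users.csv`, `threads.csv`, `posts.csv`.
#' @return a validated [forum_dataset()].
#' @export
load_dataset <- function(path, format = c("csv_dir", "sqlite")) {
  format <- match.arg(format)
  if (format == "sqlite")
    fp_stop("fp_format_error",
            "sqlite input requires an SQLite driver; use format = 'csv_dir'")
  files <- file.path(path, paste0(csv_tables(), ".csv"))
  miss <- !file.exists(files)
  if (any(miss))
    fp_stop("fp_schema_error", "missing table file(s): %s",
            paste(basename(files[miss]), collapse = ", "))
  rd <- function(f) utils::read.csv(f, colClasses = "character",
                                    stringsAsFactors = FALSE)
  u <- rd(files[1]); th <- rd(files[2]); p <- rd(files[3])

  u$name[!nzchar(u$name)] <- NA_character_
  u$registration_date <- as.Date(ifelse(nzchar(u$registration_date),
                                        u$registration_date, NA))
  p$timestamp <- as.POSIXct(sub("Z$", "", p$timestamp),
                            format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  p$word_count <- as.integer(p$word_count)
  p$is_initial <- as.integer(p$is_initial) == 1L
  p$position <- as.integer(p$position)
  forum_dataset(u, th, p,
                metadata = list(source = path, format = format))
}

#' Summarise a forum dataset
#'
#' Corpus-level counts following the board's counting rules: registered user
#' profiles exclude anonymous, blocked and deleted accounts (which have no
#' profile page), while their posts still count toward all post totals.
#'
#' @param dataset a [forum_dataset()].
#' @return a list of class `forum_summary` with elements `n_posts`,
#'   `n_threads`, `n_registered_users`, `n_anonymous_blocked_posts`, and
#'   `initial_reply`: a data frame of initial/reply proportions for the
#'   entire forum and each subforum.
#' @export
dataset_summary <- function(dataset) {
  stopifnot(inherits(dataset, "forum_dataset"))
  posts <- dataset$posts; users <- dataset$users
  reg_ids <- users$user_id[users$status %in% registered_statuses()]
  pooled <- posts$user_id %in%
    users$user_id[!users$status %in% registered_statuses()]
  sf <- c("entire_forum", subforum_levels())
  ir <- data.frame(subforum = sf, n_posts = 0L,
                   initial_fraction = NA_real_, reply_fraction = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_along(sf)) {
    sel <- if (sf[i] == "entire_forum") rep(TRUE, nrow(posts))
           else posts$subforum == sf[i]
    n <- sum(sel)
    ir$n_posts[i] <- n
    if (n > 0) {
      ir$initial_fraction[i] <- sum(posts$is_initial[sel]) / n
      ir$reply_fraction[i] <- 1 - ir$initial_fraction[i]
    }
  }
  structure(list(
    n_posts = nrow(posts),
    n_threads = nrow(dataset$threads),
    n_registered_users = length(reg_ids),
    n_anonymous_blocked_posts = sum(pooled),
    initial_reply = ir
  ), class = "forum_summary")
}

#' @export
print.forum_summary <- function(x, ...) {
  cat("Forum corpus summary\n")
  cat(sprintf("  posts: %d (%d by anonymous/blocked users)\n",
              x$n_posts, x$n_anonymous_blocked_posts))
  cat(sprintf("  threads: %d\n  registered user profiles: %d\n",
              x$n_threads, x$n_registered_users))
  ir <- x$initial_reply
  ir$initial_fraction <- round(100 * ir$initial_fraction, 2)
  ir$reply_fraction <- round(100 * ir$reply_fraction, 2)
  names(ir)[3:4] <- c("initial_pct", "reply_pct")
  print(ir, row.names = FALSE)
  invisible(x)
}

#' @export
print.forum_dataset <- function(x, ...) {
  cat(sprintf("<forum_dataset: %d users, %d threads, %d posts>\n",
              nrow(x$users), nrow(x$threads), nrow(x$posts)))
  fl <- attr(x, "quality_flags")
  if (length(fl)) cat("quality flags:\n", paste(" -", fl, collapse = "\n"), "\n")
  invisible(x)
}
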