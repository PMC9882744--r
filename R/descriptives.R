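#' Count posts in a period and subforum
#'
#' @param dataset a [forum_dataset()].
#' @param period one of the period names in `periods`.
#' @param subforum a subforum label or `"entire_forum"` (all posts,
#'   including the pooled "other" sections).
#' @param periods period table, see [default_periods()].
#' @return integer post count.
#' @export
posts_in <- function(dataset, period, subforum = "entire_forum",
                     periods = default_periods()) {
  stopifnot(inherits(dataset, "forum_dataset"),
            period %in% periods$period,
            subforum %in% c("entire_forum", subforum_levels()))
  posts <- dataset$posts
  if (nrow(posts) == 0) return(0L)
  sel <- assign_period(posts$timestamp, periods) == period
  sel[is.na(sel)] <- FALSE
  if (subforum != "entire_forum") sel <- sel & posts$subforum == subforum
  sum(sel)
}

#' Post-length statistics for a period and subforum
#'
#' Arithmetic mean and sample (n-1) standard deviation of post word counts.
#' A single post yields `sd = 0` by convention rather than `NA`.
#'
#' @inheritParams posts_in
#' @return list with `n`, `mean_words`, `sd_words`.
#' @export
length_stats <- function(dataset, period, subforum = "entire_forum",
                         periods = default_periods()) {
  stopifnot(inherits(dataset, "forum_dataset"))
  posts <- dataset$posts
  sel <- if (nrow(posts) == 0) logical(0)
         else assign_period(posts$timestamp, periods) == period
  sel[is.na(sel)] <- FALSE
  if (subforum != "entire_forum") sel <- sel & posts$subforum == subforum
  w <- posts$word_count[sel]
  if (length(w) == 0)
    fp_stop("fp_empty_selection",
            "no posts in period '%s', subforum '%s'", period, subforum)
  list(n = length(w), mean_words = mean(w),
       sd_words = if (length(w) == 1) 0 else stats::sd(w))
}

#' Signed percent change between two quantities
#'
#' `100 * (after - before) / before`, computed on unrounded inputs and
#' reported to two decimals.
#'
#' @param before baseline value, must be strictly positive.
#' @param after comparison value.
#' @param digits decimals for the reported value (default 2).
#' @return signed percent change.
#' @examples
#' percent_change(4836, 6842)  # +41.48
#' percent_change(98, 36)      # -63.27
#' @export
percent_change <- function(before, after, digits = 2) {
  if (any(before <= 0))
    fp_stop("fp_undefined_change",
            "percent change undefined for non-positive baseline")
  round(100 * (after - before) / before, digits)
}

#' Weekly series of new user registrations
#'
#' Counts registered users (status regular/starter/verified) by the ISO
#' calendar week of their registration date. Period totals are obtained by
#' summing member weeks.
#'
#' @param dataset a [forum_dataset()].
#' @return data frame `(year, week, n)`, one row per week with at least one
#'   registration, ordered chronologically; zero rows for an empty corpus.
#' @export
registrations_per_week <- function(dataset) {
  stopifnot(inherits(dataset, "forum_dataset"))
  users <- dataset$users
  keep <- users$status %in% registered_statuses() &
    !is.na(users$registration_date)
  d <- users$registration_date[keep]
  if (length(d) == 0)
    return(data.frame(year = integer(0), week = integer(0), n = integer(0)))
  cw <- calendar_week(d)
  agg <- stats::aggregate(list(n = rep(1L, nrow(cw))),
                          by = list(year = cw$year, week = cw$week), FUN = sum)
  agg <- agg[order(agg$year, agg$week), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Total registrations inside a period
#'
#' @inheritParams posts_in
#' @return integer count of users whose registration date lies in the period.
#' @export
registrations_in <- function(dataset, period, periods = default_periods()) {
  users <- dataset$users
  keep <- users$status %in% registered_statuses() &
    !is.na(users$registration_date)
  sum(assign_period(users$registration_date[keep], periods) == period,
      na.rm = TRUE)
}

#' User-level activity profile
#'
#' Per-user engagement summaries over the whole corpus: number of posts,
#' days between registration and first post, and the span in days between
#' first and last post.
#'
#' @param dataset a [forum_dataset()].
#' @return data frame with columns `user_id`, `n_posts`,
#'   `days_to_first_post` (`NA` without a registration date) and
#'   `span_days`, one row per registered user with at least one post.
#' @seealso [top_share()]
#' @export
activity_profile <- function(dataset) {
  stopifnot(inherits(dataset, "forum_dataset"))
  users <- dataset$users; posts <- dataset$posts
  reg <- users[users$status %in% registered_statuses(), , drop = FALSE]
  posts <- posts[posts$user_id %in% reg$user_id, , drop = FALSE]
  if (nrow(posts) == 0)
    return(data.frame(user_id = character(0), n_posts = integer(0),
                      days_to_first_post = numeric(0), span_days = numeric(0),
                      stringsAsFactors = FALSE))
  tnum <- as.numeric(posts$timestamp)
  first <- tapply(tnum, posts$user_id, min)
  last <- tapply(tnum, posts$user_id, max)
  n <- tapply(tnum, posts$user_id, length)
  ids <- names(n)
  reg_date <- reg$registration_date[match(ids, reg$user_id)]
  first_date <- civil_date(as.POSIXct(as.numeric(first), origin = "1970-01-01",
                                      tz = "UTC"))
  data.frame(
    user_id = ids,
    n_posts = as.integer(n),
    days_to_first_post = as.numeric(first_date - reg_date),
    span_days = as.numeric(last - first) / 86400,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Concentration of posting among the most active users
#'
#' Fraction of all registered-user posts written by the `k` most active
#' users; non-decreasing in `k`.
#'
#' @param profile output of [activity_profile()].
#' @param k number of top users (vectorised).
#' @return numeric shares in `[0, 1]`.
#' @export
top_share <- function(profile, k) {
  stopifnot(is.data.frame(profile), all(k >= 1))
  n <- sort(profile$n_posts, decreasing = TRUE)
  tot <- sum(n)
  if (tot == 0) return(rep(NA_real_, length(k)))
  vapply(pmin(k, length(n)), function(kk) sum(n[seq_len(kk)]) / tot,
         numeric(1))
}

#' Subforum shares of all posts
#'
#' @param dataset a [forum_dataset()].
#' @return data frame `(subforum, n_posts, percent)`; percentages are
#'   computed against the entire corpus and sum to 100 across the four
#'   labels.
#' @export
subforum_shares <- function(dataset) {
  stopifnot(inherits(dataset, "forum_dataset"))
  posts <- dataset$posts
  tab <- table(factor(posts$subforum, levels = subforum_levels()))
  tot <- sum(tab)
  data.frame(subforum = subforum_levels(), n_posts = as.integer(tab),
             percent = if (tot == 0) rep(NA_real_, 4)
                       else 100 * as.numeric(tab) / tot,
             stringsAsFactors = FALSE)
}

#' Phase-by-subforum descriptive table
#'
#' Post counts and post-length statistics for every analysis period crossed
#' with the entire forum and the three labelled subforums — the layout used
#' to compare lockdown and pre-lockdown posting activity.
#'
#' @param dataset a [forum_dataset()].
#' @param periods period table, see [default_periods()].
#' @return data frame with columns `period`, `subforum`, `n_posts`,
#'   `mean_words`, `sd_words` (length stats `NA` when a cell is empty).
#' @export
phase_table <- function(dataset, periods = default_periods()) {
  cells <- expand.grid(period = periods$period,
                       subforum = c("entire_forum", subforum_levels()),
                       stringsAsFactors = FALSE)
  cells$n_posts <- NA_integer_
  cells$mean_words <- NA_real_
  cells$sd_words <- NA_real_
  for (i in seq_len(nrow(cells))) {
    cells$n_posts[i] <- posts_in(dataset, cells$period[i], cells$subforum[i],
                                 periods)
    if (cells$n_posts[i] > 0) {
      ls <- length_stats(dataset, cells$period[i], cells$subforum[i], periods)
      cells$mean_words[i] <- ls$mean_words
      cells$sd_words[i] <- ls$sd_words
    }
  }
  cells
}
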