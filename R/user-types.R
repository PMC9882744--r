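#' The eight behavioural user types
#'
#' Registered users are classified by which subforums they ever posted in:
#' online-only, terrestrial-only, mixed (online and terrestrial, no
#' problem-gambling posts), the three "+PG" variants that add at least one
#' problem-gambling post, PG-only, and a residual `other` for profiles
#' matching none of the named patterns. The categories are mutually
#' exclusive and collectively exhaustive.
#'
#' @return character vector of the eight type names.
#' @export
user_type_levels <- function() {
  c("online_only", "terrestrial_only", "mixed",
    "online_only_pg", "terrestrial_only_pg", "mixed_pg",
    "pg_only", "other")
}

#' Classify a user from per-subforum post counts
#'
#' The named base categories require at least one post in their subforum and
#' zero posts in all other sections; their "+PG" variants additionally
#' require at least one problem-gambling post while keeping the base
#' category's zero-elsewhere constraint. `mixed` and `mixed_pg` require at
#' least one online and one terrestrial post (without/with problem-gambling
#' posts) and tolerate posts in other sections. Profiles matching no named
#' pattern are `other`.
#'
#' @param counts named non-negative counts with entries `online`,
#'   `terrestrial`, `problem_gambling`, `other`; missing entries count as 0.
#'   A matrix or data frame with those columns classifies each row.
#' @return a character vector of types (length 1 for a single profile).
#' @examples
#' classify_user(c(online = 5))                     # online_only
#' classify_user(c(online = 2, terrestrial = 1,
#'                 problem_gambling = 1))           # mixed_pg
#' @export
classify_user <- function(counts) {
  m <- profile_matrix(counts)
  if (any(m < 0)) fp_stop("fp_profile_error", "negative post counts")
  tot <- rowSums(m)
  if (any(tot == 0))
    fp_stop("fp_profile_error",
            "unclassifiable all-zero profile (user has no posts)")
  o <- m[, "online"] > 0; t <- m[, "terrestrial"] > 0
  p <- m[, "problem_gambling"] > 0; x <- m[, "other"] > 0
  out <- rep("other", nrow(m))
  out[o & !t & !p & !x] <- "online_only"
  out[t & !o & !p & !x] <- "terrestrial_only"
  out[o & t & !p]       <- "mixed"
  out[o & !t & p & !x]  <- "online_only_pg"
  out[t & !o & p & !x]  <- "terrestrial_only_pg"
  out[o & t & p]        <- "mixed_pg"
  out[p & !o & !t & !x] <- "pg_only"
  out
}

profile_matrix <- function(counts) {
  cols <- subforum_levels()
  if (is.data.frame(counts)) counts <- as.matrix(counts[, intersect(cols, names(counts))])
  if (is.matrix(counts)) {
    m <- matrix(0, nrow(counts), length(cols), dimnames = list(NULL, cols))
    m[, colnames(counts)] <- counts
    return(m)
  }
  if (is.null(names(counts)))
    fp_stop("fp_profile_error", "post-count profile must be named")
  bad <- setdiff(names(counts), cols)
  if (length(bad))
    fp_stop("fp_profile_error", "unknown subforum(s) in profile: %s",
            paste(bad, collapse = ", "))
  m <- matrix(0, 1, length(cols), dimnames = list(NULL, cols))
  m[1, names(counts)] <- counts
  m
}

#' Per-user post-count profiles
#'
#' @param dataset a [forum_dataset()].
#' @return data frame with one row per registered user who has at least one
#'   post, columns `user_id` and the four subforum counts.
#' @export
user_post_profiles <- function(dataset) {
  stopifnot(inherits(dataset, "forum_dataset"))
  users <- dataset$users; posts <- dataset$posts
  reg <- users$user_id[users$status %in% registered_statuses()]
  posts <- posts[posts$user_id %in% reg, , drop = FALSE]
  if (nrow(posts) == 0)
    return(data.frame(user_id = character(0),
                      online = integer(0), terrestrial = integer(0),
                      problem_gambling = integer(0), other = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(factor(posts$user_id), factor(posts$subforum,
                                             levels = subforum_levels()))
  out <- data.frame(user_id = rownames(tab), stringsAsFactors = FALSE)
  for (s in subforum_levels()) out[[s]] <- as.integer(tab[, s])
  out
}

#' User-type distribution of a corpus
#'
#' Classifies every registered user with at least one post and tabulates the
#' eight types. Anonymous, blocked and deleted authors are excluded, as are
#' registered users who never posted (their type is undefined).
#'
#' @param dataset a [forum_dataset()].
#' @return data frame with columns `type`, `n`, `proportion` (proportions
#'   over classifiable users, summing to 1; all zero for an empty user set).
#' @export
type_distribution <- function(dataset) {
  prof <- user_post_profiles(dataset)
  lv <- user_type_levels()
  if (nrow(prof) == 0)
    return(data.frame(type = lv, n = 0L, proportion = NA_real_,
                      stringsAsFactors = FALSE))
  ty <- classify_user(prof[, subforum_levels()])
  tab <- table(factor(ty, levels = lv))
  data.frame(type = lv, n = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE)
}
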