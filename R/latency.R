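LATENCY_WINDOW_HOURS <- 168
LATENCY_BIN_HOURS <- 8
LATENCY_N_BINS <- LATENCY_WINDOW_HOURS %/% LATENCY_BIN_HOURS  # 21

#' Extract reply latencies for one analysis period
#'
#' For every initial post whose civil date lies between the period start and
#' seven days before the period end (inclusive), emits the elapsed time in
#' hours between the initial post and each reply in its thread that arrives
#' within the first seven days (latency < 168 h). The eligibility cutoff
#' guarantees that every considered reply itself falls inside the period.
#' Latency is measured against the thread's initial post, not the preceding
#' reply.
#'
#' @param dataset a [forum_dataset()].
#' @param period a period name.
#' @param periods period table, see [default_periods()].
#' @return data frame `(thread_id, post_id, latency_hours)` with attribute
#'   `n_initial`, the number of eligible initial posts.
#' @export
extract_latencies <- function(dataset, period, periods = default_periods()) {
  stopifnot(inherits(dataset, "forum_dataset"), period %in% periods$period)
  row <- periods[periods$period == period, ]
  posts <- dataset$posts
  empty <- data.frame(thread_id = character(0), post_id = character(0),
                      latency_hours = numeric(0), stringsAsFactors = FALSE)
  if (nrow(posts) == 0) {
    attr(empty, "n_initial") <- 0L
    return(empty)
  }
  d <- civil_date(posts$timestamp)
  eligible <- posts$is_initial & d >= row$start & d <= row$end - 7
  ini <- posts[eligible, c("thread_id", "timestamp")]
  attr(empty, "n_initial") <- nrow(ini)
  if (nrow(ini) == 0) return(empty)

  rep_sel <- !posts$is_initial & posts$thread_id %in% ini$thread_id
  reps <- posts[rep_sel, c("thread_id", "post_id", "timestamp")]
  t0 <- ini$timestamp[match(reps$thread_id, ini$thread_id)]
  lat <- as.numeric(difftime(reps$timestamp, t0, units = "hours"))
  keep <- lat >= 0 & lat < LATENCY_WINDOW_HOURS
  out <- data.frame(thread_id = reps$thread_id[keep],
                    post_id = reps$post_id[keep],
                    latency_hours = lat[keep], stringsAsFactors = FALSE)
  out <- out[order(out$post_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_initial") <- nrow(ini)
  out
}

#' Bin reply latencies into the 21-bin 8-hour histogram
#'
#' Half-open bins `[8i, 8(i+1))` for `i = 0..20`, covering a full week
#' (0 to 167 h): a latency of exactly 8.0 h falls in the second bin.
#'
#' @param latencies numeric latencies in hours, all in `[0, 168)`, or the
#'   data frame returned by [extract_latencies()].
#' @param period optional period name recorded on the histogram.
#' @param n_initial number of eligible initial posts (taken from the
#'   `extract_latencies` attribute when available).
#' @return an object of class `latency_histogram`: list with `period`,
#'   `bin_width_hours` (8), `n_bins` (21), `bin_left_edges_hours`,
#'   integer `counts` summing to the number of latencies, and `n_initial`.
#' @export
bin_latencies <- function(latencies, period = NA_character_,
                          n_initial = NA_integer_) {
  if (is.data.frame(latencies)) {
    if (is.na(n_initial))
      n_initial <- attr(latencies, "n_initial") %||% NA_integer_
    latencies <- latencies$latency_hours
  }
  if (length(latencies) &&
      (any(latencies < 0) || any(latencies >= LATENCY_WINDOW_HOURS)))
    fp_stop("fp_latency_range",
            "latencies must lie in [0, %d) hours", LATENCY_WINDOW_HOURS)
  counts <- tabulate(floor(latencies / LATENCY_BIN_HOURS) + 1L,
                     nbins = LATENCY_N_BINS)
  structure(list(
    period = period,
    bin_width_hours = LATENCY_BIN_HOURS,
    n_bins = LATENCY_N_BINS,
    bin_left_edges_hours = seq(0L, LATENCY_WINDOW_HOURS - LATENCY_BIN_HOURS,
                               by = LATENCY_BIN_HOURS),
    counts = as.integer(counts),
    n_initial = as.integer(n_initial)
  ), class = "latency_histogram")
}

#' Latency histogram for a period of a dataset
#'
#' Convenience wrapper: [extract_latencies()] followed by [bin_latencies()].
#'
#' @inheritParams extract_latencies
#' @return a `latency_histogram`.
#' @export
latency_histogram <- function(dataset, period, periods = default_periods()) {
  lat <- extract_latencies(dataset, period, periods)
  bin_latencies(lat, period = period)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.latency_histogram <- function(x, ...) {
  cat(sprintf("<latency_histogram%s: %d replies in %d x %dh bins, %s eligible initial posts>\n",
              if (is.na(x$period)) "" else paste0(" [", x$period, "]"),
              sum(x$counts), x$n_bins, x$bin_width_hours,
              ifelse(is.na(x$n_initial), "?", x$n_initial)))
  print(stats::setNames(x$counts, paste0(x$bin_left_edges_hours, "h")))
  invisible(x)
}

#' Serialise a latency histogram to JSON
#'
#' @param hist a `latency_histogram`.
#' @param path optional file to write to.
#' @return the JSON string, invisibly when written to a file.
#' @export
histogram_to_json <- function(hist, path = NULL) {
  stopifnot(inherits(hist, "latency_histogram"))
  js <- jsonlite::toJSON(list(period = hist$period,
                              bin_width_hours = hist$bin_width_hours,
                              counts = hist$counts,
                              n_initial_posts = hist$n_initial),
                         auto_unbox = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
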