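#' Expected win probability under the Elo model
#'
#' @param r_a,r_b ratings of the focal individual and its opponent.
#' @param curve expectation curve: `"logistic"` uses
#'   `1 / (1 + 10^((r_b - r_a)/400))`; `"normal"` uses
#'   `pnorm((r_a - r_b) / (200 * sqrt(2)))`.
#' @return probability that `a` beats `b`.
#' @export
elo_expectation <- function(r_a, r_b, curve = c("normal", "logistic")) {
  curve <- match.arg(curve)
  if (curve == "logistic") 1 / (1 + 10^((r_b - r_a) / 400))
  else pnorm((r_a - r_b) / (200 * sqrt(2)))
}

#' Single Elo rating update
#'
#' Updates a winner/loser rating pair after one agonistic interaction.
#' The winner gains `k * (1 - E)` points and the loser loses the same
#' amount, where `E` is the winner's expected success probability, so the
#' total rating mass is conserved. Draws score 0.5 for both parties.
#'
#' @param r_winner,r_loser current ratings (for a draw, order is arbitrary).
#' @param k update step size, > 0.
#' @param curve see [elo_expectation()].
#' @param draw logical; was the interaction undecided?
#' @return numeric vector `c(winner, loser)` of updated ratings.
#' @examples
#' elo_update(1000, 1000, k = 100, curve = "logistic") # c(1050, 950)
#' @export
elo_update <- function(r_winner, r_loser, k = 100,
                       curve = c("normal", "logistic"), draw = FALSE) {
  curve <- match.arg(curve)
  if (!is.numeric(k) || length(k) != 1 || k <= 0)
    stop("'k' must be a positive number", call. = FALSE)
  e <- elo_expectation(r_winner, r_loser, curve)
  score <- if (draw) 0.5 else 1
  delta <- k * (score - e)
  c(r_winner + delta, r_loser - delta)
}

#' Sequential Elo ratings from an agonistic event table
#'
#' Applies [elo_update()] chronologically over a table of dyadic agonistic
#' interactions. Events with outcome `"unknown"` are skipped (and counted);
#' same-day events are applied in table order.
#'
#' @param events data frame with columns `date` (integer day index),
#'   `aggressor_id`, `victim_id`, and `outcome` in
#'   `c("win", "loss", "draw", "unknown")`, scored from the aggressor's
#'   perspective.
#' @param ids character vector of all individuals to track (events must only
#'   involve these ids). Defaults to the ids present in `events`.
#' @param entry_dates optional named integer vector giving the day each id
#'   entered the group (e.g. birth or study start); used by
#'   [rank_on_date()] to define who is present on a date.
#' @param k,start_value,curve Elo parameters; defaults follow the common
#'   reference implementation (k = 100, start 1000, normal curve).
#' @return an object of class `elo_series`.
#' @export
run_elo <- function(events, ids = NULL, entry_dates = NULL, k = 100,
                    start_value = 1000, curve = c("normal", "logistic")) {
  curve <- match.arg(curve)
  stopifnot(all(c("date", "aggressor_id", "victim_id", "outcome") %in% names(events)))
  bad <- setdiff(unique(events$outcome), c("win", "loss", "draw", "unknown"))
  if (length(bad))
    stop("unknown outcome values: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(ids)) ids <- sort(unique(c(events$aggressor_id, events$victim_id)))
  orphan <- setdiff(unique(c(events$aggressor_id, events$victim_id)), ids)
  if (length(orphan))
    stop("events involve unregistered ids: ", paste(head(orphan, 5), collapse = ", "),
         call. = FALSE)
  events <- events[order(events$date), , drop = FALSE]

  ratings <- setNames(rep(start_value, length(ids)), ids)
  n <- nrow(events)
  hist_date <- integer(2L * n); hist_id <- character(2L * n)
  hist_rating <- numeric(2L * n)
  hn <- 0L
  n_skipped <- 0L
  e_fun <- if (curve == "logistic") function(d) 1 / (1 + 10^(-d / 400))
           else function(d) pnorm(d / (200 * sqrt(2)))
  for (i in seq_len(n)) {
    out <- events$outcome[i]
    if (out == "unknown") { n_skipped <- n_skipped + 1L; next }
    a <- events$aggressor_id[i]; v <- events$victim_id[i]
    if (identical(a, v)) stop(sprintf("self-directed event at row %d", i), call. = FALSE)
    if (out == "loss") { w <- v; l <- a } else { w <- a; l <- v }
    rw <- ratings[[w]]; rl <- ratings[[l]]
    delta <- k * ((if (out == "draw") 0.5 else 1) - e_fun(rw - rl))
    ratings[[w]] <- rw + delta; ratings[[l]] <- rl - delta
    hist_date[hn + 1L] <- events$date[i]; hist_date[hn + 2L] <- events$date[i]
    hist_id[hn + 1L] <- w; hist_id[hn + 2L] <- l
    hist_rating[hn + 1L] <- rw + delta; hist_rating[hn + 2L] <- rl - delta
    hn <- hn + 2L
  }
  hist_date <- hist_date[seq_len(hn)]
  hist_id <- hist_id[seq_len(hn)]
  hist_rating <- hist_rating[seq_len(hn)]
  # per-id piecewise-constant trajectory
  traj <- lapply(setNames(ids, ids), function(id) {
    sel <- hist_id == id
    list(dates = hist_date[sel], ratings = hist_rating[sel])
  })
  structure(list(ids = ids, start_value = start_value, k = k, curve = curve,
                 entry_dates = entry_dates, trajectories = traj,
                 n_events = n - n_skipped, n_skipped = n_skipped),
            class = "elo_series")
}

#' @export
print.elo_series <- function(x, ...) {
  cat(sprintf("<elo_series> %d individuals, %d events applied (%d 'unknown' skipped), k=%g, start=%g, curve=%s\n",
              length(x$ids), x$n_events, x$n_skipped, x$k, x$start_value, x$curve))
  invisible(x)
}

# raw rating of one id at a date (last update at or before `date`)
elo_rating_at <- function(series, id, date) {
  tr <- series$trajectories[[id]]
  if (is.null(tr)) stop(sprintf("id '%s' not in Elo series", id), call. = FALSE)
  idx <- findInterval(date, tr$dates)
  if (idx == 0) series$start_value else tr$ratings[idx]
}

#' Rank (Elo rating) of an individual on a given date
#'
#' Returns the raw rating, or the rating standardized (mean 0, SD 1) across
#' all group members present on that date when `standardize = TRUE` — the
#' covariate form used for the IGC models.
#'
#' @param series an `elo_series` from [run_elo()].
#' @param id individual id.
#' @param date integer day index.
#' @param standardize standardize across members present on `date`?
#' @export
rank_on_date <- function(series, id, date, standardize = TRUE) {
  present <- series$ids
  if (!is.null(series$entry_dates))
    present <- present[series$entry_dates[present] <= date]
  if (!id %in% present)
    stop(sprintf("id '%s' not present on day %s", id, date), call. = FALSE)
  if (!standardize) return(elo_rating_at(series, id, date))
  r <- vapply(present, elo_rating_at, numeric(1), series = series, date = date)
  z <- zscore(r)
  z[[match(id, present)]]
}

# vectorized standardized ranks for several ids on one date
ranks_on_date <- function(series, ids, date) {
  present <- series$ids
  if (!is.null(series$entry_dates))
    present <- present[series$entry_dates[present] <= date]
  r <- vapply(present, elo_rating_at, numeric(1), series = series, date = date)
  z <- setNames(zscore(r), present)
  z[ids]
}
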