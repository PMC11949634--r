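# small shared fixtures, built in code

# a reduced study configuration: same rates and effect sizes as the default,
# shorter follow-up and lighter observation effort so generation stays fast
tiny_config <- function(seed = 11, n_days = 400, agonism_rate = 4,
                        igc_rate = 0.6, ...) {
  generator_config(
    cohort_sizes = matrix(c(4, 4, 4, 4, 3, 3, 4, 3, 3), nrow = 3, byrow = TRUE),
    adult_females = c(6, 5, 5), adult_males = c(3, 3, 2),
    n_days = n_days, agonism_rate = agonism_rate, igc_rate = igc_rate,
    seed = seed, ...)
}

# cached tiny cohort (generated once per test run)
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(tiny_config(), quiet = TRUE)
    cache
  }
})

tiny_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- tiny_cohort()
      dir <- file.path(tempdir(), "tiny_cohort_data")
      if (!dir.exists(dir)) write_cohort(co, dir)
      ds <- suppressMessages(load_tables(dir, quiet = TRUE))
      cache <<- suppressMessages(build_event_panel(ds))
    }
    cache
  }
})

# naive step-by-step Elo reference, independent of run_elo's implementation
naive_elo <- function(events, ids, k = 100, start = 1000,
                      curve = "normal") {
  r <- setNames(rep(start, length(ids)), ids)
  for (i in seq_len(nrow(events))) {
    o <- events$outcome[i]
    if (o == "unknown") next
    a <- events$aggressor_id[i]; v <- events$victim_id[i]
    w <- if (o == "loss") v else a
    l <- if (o == "loss") a else v
    e <- if (curve == "logistic") 1 / (1 + 10^((r[[l]] - r[[w]]) / 400))
         else pnorm((r[[w]] - r[[l]]) / (200 * sqrt(2)))
    sc <- if (o == "draw") 0.5 else 1
    r[[w]] <- r[[w]] + k * (sc - e)
    r[[l]] <- r[[l]] - k * (sc - e)
  }
  r
}

# random agonistic event table over `m` individuals
random_events <- function(n, m = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- sample(paste0("i", seq_len(m)), n, TRUE)
  v <- vapply(a, function(x) sample(setdiff(paste0("i", seq_len(m)), x), 1), "")
  data.frame(date = sort(sample(1:200, n, TRUE)), aggressor_id = a,
             victim_id = unname(v),
             outcome = sample(c("win", "loss", "draw", "unknown"), n, TRUE,
                              prob = c(0.6, 0.25, 0.1, 0.05)),
             stringsAsFactors = FALSE)
}

# dense-eigendecomposition eigenvector-centrality oracle (per component,
# max-normalized), mirroring the documented convention
dense_ec <- function(A) {
  n <- nrow(A)
  S <- (A + t(A)) > 0
  comp <- integer(n); cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1L; q <- s; comp[s] <- cid
    while (length(q)) {
      cur <- q[[1]]; q <- q[-1]
      nb <- which(S[cur, ] & comp == 0L); comp[nb] <- cid; q <- c(q, nb)
    }
  }
  out <- numeric(n)
  for (cc in seq_len(cid)) {
    idx <- which(comp == cc)
    if (length(idx) == 1 || sum(A[idx, idx]) == 0) next
    e <- eigen(A[idx, idx, drop = FALSE])
    v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
    out[idx] <- v / max(v)
  }
  out
}

# random non-negative weighted graph as a social_network object
random_network <- function(n_nodes, p_edge = 0.2, directed = FALSE,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("n", seq_len(n_nodes))
  pairs <- t(utils::combn(n_nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  e <- data.frame(from = nodes[pairs[keep, 1]], to = nodes[pairs[keep, 2]],
                  weight = sample(1:5, sum(keep), TRUE),
                  stringsAsFactors = FALSE)
  structure(list(year = 1, group_id = "G", mode = "spatial", nodes = nodes,
                 edges = e, directed = directed), class = "social_network")
}
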