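#' Build annual grooming and spatial association networks for one group
#'
#' Grooming networks are directed and weighted: the weight of edge A→B is
#' the number of scan records in which A was observed grooming B. Spatial
#' networks are undirected: the weight of A—B is the number of scan windows
#' in which the pair was recorded within 3 m (a pair observed in either
#' individual's neighbour list counts once per window).
#'
#' @param scans scan table (see [load_tables()] for the layout).
#' @param roster life-history table with columns `id`, `group_id`,
#'   `birth_date`.
#' @param year year index (day `d` falls in year `ceiling(d / year_length)`).
#' @param group_id group whose troop-level networks to build.
#' @param year_length days per year (default 365).
#' @return list with elements `grooming` and `spatial`, each a
#'   `social_network` object (fields `year`, `group_id`, `mode`, `nodes`,
#'   `edges` with columns from/to/weight, `directed`).
#' @export
build_networks <- function(scans, roster, year, group_id, year_length = 365) {
  yr_start <- (year - 1) * year_length + 1
  yr_end <- year * year_length
  members <- roster$id[roster$group_id == group_id & roster$birth_date <= yr_end]
  s <- scans[scans$group_id == group_id & scans$day >= yr_start & scans$day <= yr_end, ,
             drop = FALSE]
  if (nrow(s) == 0)
    warning(sprintf("no scans for group %s in year %d: networks are empty",
                    group_id, year))

  # grooming: one directed edge count per groomer row
  g <- s[!is.na(s$partner_id) & s$partner_role == "groomer", , drop = FALSE]
  if (nrow(g)) {
    key <- paste(g$individual_id, g$partner_id, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    groom_edges <- data.frame(
      from = vapply(parts, `[[`, "", 1),
      to = vapply(parts, `[[`, "", 2),
      weight = as.integer(tab), stringsAsFactors = FALSE, row.names = NULL)
  } else {
    groom_edges <- data.frame(from = character(0), to = character(0),
                              weight = integer(0))
  }

  # spatial: unordered pairs per scan window
  nb <- s[!is.na(s$neighbours) & nzchar(s$neighbours), , drop = FALSE]
  if (nrow(nb)) {
    nbl <- strsplit(nb$neighbours, ";", fixed = TRUE)
    len <- lengths(nbl)
    win <- paste(nb$day, nb$minute, sep = "_")
    a <- rep(nb$individual_id, len)
    b <- unlist(nbl, use.names = FALSE)
    w <- rep(win, len)
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(w, lo, hi, sep = "\r")
    uniq <- !duplicated(key)
    pair <- paste(lo[uniq], hi[uniq], sep = "\r")
    tab <- table(pair)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    sp_edges <- data.frame(
      from = vapply(parts, `[[`, "", 1),
      to = vapply(parts, `[[`, "", 2),
      weight = as.integer(tab), stringsAsFactors = FALSE, row.names = NULL)
  } else {
    sp_edges <- data.frame(from = character(0), to = character(0),
                           weight = integer(0))
  }

  mk <- function(mode, edges, directed) {
    structure(list(year = year, group_id = group_id, mode = mode,
                   nodes = members, edges = edges, directed = directed),
              class = "social_network")
  }
  list(grooming = mk("grooming", groom_edges, TRUE),
       spatial = mk("spatial", sp_edges, FALSE))
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("<social_network> %s, group %s, year %d: %d nodes, %d edges (%s)\n",
              x$mode, x$group_id, x$year, length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

# weighted adjacency matrix over the node set; undirected edge lists hold one
# row per unordered pair, directed lists one row per ordered pair
adjacency_matrix <- function(net, directed = c("sym", "in", "out")) {
  directed <- match.arg(directed)
  nodes <- net$nodes
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  e <- net$edges
  if (nrow(e)) {
    e <- e[e$from %in% nodes & e$to %in% nodes & e$from != e$to, , drop = FALSE]
    w <- tapply(e$weight, paste(match(e$from, nodes), match(e$to, nodes)), sum)
    ij <- do.call(rbind, lapply(strsplit(names(w), " "), as.integer))
    A[ij] <- as.numeric(w)
  }
  if (!net$directed) A <- A + t(A)
  else if (directed == "sym") A <- A + t(A)
  else if (directed == "in") A <- t(A)
  A
}

# leading-eigenvector scores of a non-negative matrix by shifted power
# iteration; returns vector normalized so the maximum equals 1
power_iteration_ec <- function(A, tol = 1e-10, max_iter = 20000) {
  n <- nrow(A)
  if (n == 1 || sum(A) == 0) return(rep(0, n))
  # diagonal shift makes the dominant eigenvalue unique for bipartite graphs
  shift <- max(rowSums(A))
  v <- rep(1 / sqrt(n), n)
  delta <- Inf
  for (i in seq_len(max_iter)) {
    w <- as.vector(A %*% v) + shift * v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(rep(0, n))
    w <- w / nw
    delta <- max(abs(w - v))
    v <- w
    if (delta < tol) return(v / max(v))
  }
  stop(sprintf(
    "eigenvector centrality did not converge in %d iterations (last delta %.3e); the spectral gap may be too small",
    max_iter, delta), call. = FALSE)
}

#' Eigenvector centrality of a social network
#'
#' Scores are the leading eigenvector of the weighted adjacency matrix,
#' computed by power iteration (tolerance 1e-10). Disconnected graphs are
#' handled per connected component, each component normalized so its
#' maximum score is 1; isolated nodes score 0. For directed grooming
#' networks the default symmetrizes (weight = in + out); `directed = "in"`
#' or `"out"` compute the left/right eigenvector variants.
#'
#' @param net a `social_network`.
#' @param directed `"sym"` (default), `"in"`, or `"out"`.
#' @param tol convergence tolerance of the power iteration.
#' @return data frame with columns `id`, `ec`.
#' @export
eigenvector_centrality <- function(net, directed = c("sym", "in", "out"),
                                   tol = 1e-10) {
  directed <- match.arg(directed)
  if (length(net$nodes) == 0)
    return(data.frame(id = character(0), ec = numeric(0)))
  A <- adjacency_matrix(net, directed)
  # components on the symmetrized support
  S <- (A + t(A)) > 0
  n <- nrow(A)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      nb <- which(S[cur, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  ec <- numeric(n)
  for (cc in seq_len(cid)) {
    idx <- which(comp == cc)
    if (length(idx) == 1 || sum(A[idx, idx]) == 0) { ec[idx] <- 0; next }
    ec[idx] <- power_iteration_ec(A[idx, idx, drop = FALSE], tol = tol)
  }
  data.frame(id = net$nodes, ec = ec, stringsAsFactors = FALSE)
}

#' Eigenvector centrality table across group-years
#'
#' Runs [build_networks()] and [eigenvector_centrality()] for every
#' group-year combination and assembles the year-matched centrality
#' covariates used by the IGC models.
#'
#' @inheritParams build_networks
#' @param years integer vector of year indices.
#' @param groups group ids (default: all in roster).
#' @return data frame `id`, `group_id`, `year`, `grooming_ec`, `spatial_ec`.
#' @export
centrality_table <- function(scans, roster, years, groups = NULL,
                             year_length = 365) {
  groups <- groups %||% sort(unique(roster$group_id))
  out <- list()
  for (g in groups) for (y in years) {
    nets <- suppressWarnings(build_networks(scans, roster, y, g, year_length))
    gec <- eigenvector_centrality(nets$grooming)
    sec <- eigenvector_centrality(nets$spatial)
    out[[paste(g, y)]] <- data.frame(
      id = gec$id, group_id = g, year = y,
      grooming_ec = gec$ec, spatial_ec = sec$ec[match(gec$id, sec$id)],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
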