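make_scans <- function(df) {
  defaults <- data.frame(day = 1, minute = 0, group_id = "G1",
                         individual_id = "a", activity = "resting",
                         partner_id = NA_character_, partner_role = "none",
                         neighbours = NA_character_, stringsAsFactors = FALSE)
  out <- defaults[rep(1, nrow(df)), ]
  out[names(df)] <- df
  rownames(out) <- NULL
  out
}

roster4 <- data.frame(id = c("a", "b", "c", "d"), sex = "F",
                      birth_date = 0L, mother_id = NA, group_id = "G1",
                      age_class = "adult", stringsAsFactors = FALSE)

test_that("grooming edges count directed groomer->groomee dyads", {
  sc <- make_scans(data.frame(
    day = c(1, 2, 3, 3), minute = c(0, 0, 0, 0),
    individual_id = c("a", "a", "a", "b"),
    activity = "grooming", partner_id = c("b", "b", "b", "a"),
    partner_role = c("groomer", "groomer", "groomer", "groomee")))
  nets <- build_networks(sc, roster4, year = 1, group_id = "G1")
  e <- nets$grooming$edges
  expect_equal(nrow(e), 1)
  expect_equal(e$from, "a"); expect_equal(e$to, "b"); expect_equal(e$weight, 3)
})

test_that("spatial pairs symmetrize and count once per scan window", {
  sc <- make_scans(data.frame(
    day = c(1, 1, 2), minute = c(0, 0, 0),
    individual_id = c("a", "b", "a"),
    neighbours = c("b", "a", "b")))
  nets <- build_networks(sc, roster4, year = 1, group_id = "G1")
  e <- nets$spatial$edges
  # day 1 recorded on both rows counts once; day 2 recorded once also counts
  expect_equal(nrow(e), 1)
  expect_equal(e$weight, 2)
  A <- vervetIGC:::adjacency_matrix(nets$spatial)
  expect_true(isSymmetric(A))
})

test_that("eigenvector centrality matches closed forms", {
  # star: centre 1.0, leaves 1/sqrt(3) ~ 0.5774
  star <- structure(list(year = 1, group_id = "G", mode = "spatial",
                         nodes = c("c", "l1", "l2", "l3"),
                         edges = data.frame(from = "c", to = c("l1", "l2", "l3"),
                                            weight = 1),
                         directed = FALSE), class = "social_network")
  ec <- eigenvector_centrality(star)
  expect_equal(ec$ec[ec$id == "c"], 1)
  expect_equal(ec$ec[ec$id != "c"], rep(1 / sqrt(3), 3), tolerance = 1e-8)
  # complete graph with equal weights: all scores 1
  comp <- structure(list(year = 1, group_id = "G", mode = "spatial",
                         nodes = c("a", "b", "c", "d"),
                         edges = data.frame(
                           from = c("a", "a", "a", "b", "b", "c"),
                           to = c("b", "c", "d", "c", "d", "d"), weight = 2),
                         directed = FALSE), class = "social_network")
  ec2 <- eigenvector_centrality(comp)
  expect_equal(ec2$ec, rep(1, 4), tolerance = 1e-8)
})

test_that("power iteration equals the dense eigendecomposition oracle", {
  for (s in 1:25) {
    net <- random_network(sample(5:50, 1), p_edge = runif(1, 0.05, 0.4), seed = s)
    A <- vervetIGC:::adjacency_matrix(net)
    expect_equal(eigenvector_centrality(net)$ec, dense_ec(A), tolerance = 1e-8)
  }
})

test_that("centrality is invariant to weight scaling and label permutation", {
  net <- random_network(20, p_edge = 0.25, seed = 42)
  ec1 <- eigenvector_centrality(net)
  net2 <- net; net2$edges$weight <- net2$edges$weight * 2
  expect_equal(eigenvector_centrality(net2)$ec, ec1$ec, tolerance = 1e-9)
  # permute node labels
  perm <- sample(seq_along(net$nodes))
  map <- setNames(net$nodes[perm], net$nodes)
  net3 <- net
  net3$nodes <- unname(map[net$nodes])
  net3$edges$from <- unname(map[net$edges$from])
  net3$edges$to <- unname(map[net$edges$to])
  ec3 <- eigenvector_centrality(net3)
  expect_equal(ec3$ec[match(unname(map[ec1$id]), ec3$id)], ec1$ec,
               tolerance = 1e-9)
})

test_that("never-observed individuals are isolated nodes with EC 0", {
  sc <- make_scans(data.frame(individual_id = "a", activity = "grooming",
                              partner_id = "b", partner_role = "groomer"))
  nets <- build_networks(sc, roster4, year = 1, group_id = "G1")
  ec <- eigenvector_centrality(nets$grooming)
  expect_equal(sort(ec$ec[ec$id %in% c("c", "d")]), c(0, 0))
  expect_true(all(ec$ec[ec$id %in% c("a", "b")] == 1)) # 2-node component
})

test_that("adding an edge to a node weakly increases its centrality", {
  net <- random_network(15, p_edge = 0.3, seed = 5)
  # ensure connectivity of the focal pair by operating within one component
  ec1 <- eigenvector_centrality(net)
  hub <- ec1$id[which.max(ec1$ec)]
  target <- ec1$id[ec1$ec > 0 & ec1$id != hub][1]
  net2 <- net
  net2$edges <- rbind(net2$edges,
                      data.frame(from = target, to = hub, weight = 5))
  ec2 <- eigenvector_centrality(net2)
  expect_gte(ec2$ec[ec2$id == target] + 1e-12, ec1$ec[ec1$id == target])
})

test_that("directed grooming centrality offers in/out variants", {
  # directed cycle with one doubled edge: in- and out-scores differ,
  # symmetrized scores treat weight as in + out
  net <- structure(list(year = 1, group_id = "G", mode = "grooming",
                        nodes = c("a", "b", "c"),
                        edges = data.frame(from = c("a", "b", "c", "a"),
                                           to = c("b", "c", "a", "c"),
                                           weight = c(2, 1, 1, 1)),
                        directed = TRUE), class = "social_network")
  ec_in <- eigenvector_centrality(net, directed = "in")
  ec_out <- eigenvector_centrality(net, directed = "out")
  expect_false(isTRUE(all.equal(ec_in$ec, ec_out$ec)))
  # the in-variant is the out-variant of the reversed graph
  rev <- net
  rev$edges[, c("from", "to")] <- rev$edges[, c("to", "from")]
  expect_equal(ec_in$ec, eigenvector_centrality(rev, directed = "out")$ec,
               tolerance = 1e-8)
})

test_that("empty years warn and yield empty networks", {
  sc <- make_scans(data.frame(individual_id = "a"))
  expect_warning(nets <- build_networks(sc, roster4, year = 7, group_id = "G1"),
                 "empty")
  expect_equal(nrow(nets$grooming$edges), 0)
  expect_equal(eigenvector_centrality(nets$grooming)$ec, rep(0, 4))
})
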