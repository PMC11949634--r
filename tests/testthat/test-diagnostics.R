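test_that("probability of direction reflects the dominant sign", {
  expect_equal(probability_of_direction(c(0.2, 1, 3)), 1)
  expect_equal(probability_of_direction(c(-1, 2, 3, 4)), 0.75)
  x <- c(-3, -1, 1, 3) # exactly symmetric
  expect_equal(probability_of_direction(x), 0.5)
  # zeros count towards the majority side
  expect_equal(probability_of_direction(c(0, 1, 1, -1)), 0.75)
  expect_error(probability_of_direction(numeric(0)), "2 draws")
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(2)
  good <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(abs(rhat(good) - 1), 0.01)
  bad <- cbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(rhat(bad), 1.1)
  expect_warning(r <- rhat(matrix(1, 100, 2)), "constant")
  expect_equal(r, 1)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("draw-wise Bayesian R2 follows its defining arithmetic", {
  # half the rows at p = 0.01, half at p = 0.99
  p <- rep(c(0.01, 0.99), each = 50)
  vfit <- var(p); vres <- mean(p * (1 - p))
  expect_equal(vfit / (vfit + vres), 0.9604, tolerance = 1e-3)
  set.seed(5)
  d <- data.frame(x = rnorm(400))
  d$y <- rbinom(400, 1, plogis(1.2 * d$x))
  f <- bglmm(y ~ x, d, chains = 2, iter = 1500, seed = 1, rhat_warn = FALSE)
  r2 <- bayes_r2(f, "conditional")
  # independent recomputation from the draws for one thinned subset
  dm <- draw_matrix(f)
  s <- nrow(dm)
  eta <- dm[s, "b_(Intercept)"] + dm[s, "b_x"] * d$x
  ps <- plogis(eta)
  expect_equal(unname(r2[length(r2)]),
               var(ps) / (var(ps) + mean(ps * (1 - ps))), tolerance = 1e-10)
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("conditional R2 includes random effects, marginal does not", {
  set.seed(9)
  n <- 800; L <- 40
  d <- data.frame(x = rnorm(n), g = factor(sample(L, n, TRUE)))
  d$y <- rbinom(n, 1, plogis(0.5 * d$x + rnorm(L, 0, 0.8)[d$g]))
  f <- bglmm(y ~ x + (1 | g), d, chains = 2, iter = 2000, seed = 2,
             rhat_warn = FALSE)
  r2c <- attr(bayes_r2(f, "conditional"), "summary")[["mean"]]
  r2m <- attr(bayes_r2(f, "marginal"), "summary")[["mean"]]
  expect_gt(r2c, r2m)
  # intercept-only model: constant fitted probabilities, R2 = 0 with warning
  f0 <- bglmm(y ~ 1, d, chains = 2, iter = 800, seed = 3, rhat_warn = FALSE)
  expect_warning(r0 <- bayes_r2(f0, "conditional"), "constant")
  expect_equal(max(r0), 0)
})

test_that("a 95% interval excluding zero implies pd above 0.975", {
  set.seed(11)
  d <- data.frame(x = rnorm(600))
  d$y <- rbinom(600, 1, plogis(0.8 * d$x))
  f <- bglmm(y ~ x, d, chains = 2, iter = 1500, seed = 4, rhat_warn = FALSE)
  s <- summary(f)
  excl <- s$q2.5 > 0 | s$q97.5 < 0
  expect_true(all(s$pd[excl] > 0.975))
})

test_that("residual autocorrelation is flat for exchangeable data and unit at duplicated lags", {
  set.seed(6)
  n <- 1500
  panel <- data.frame(id = rep(paste0("i", 1:15), each = n / 15),
                      date = rep(seq_len(n / 15), 15))
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.5 * d$x))
  d$id <- panel$id; d$date <- panel$date
  f <- bglmm(y ~ x, d, chains = 2, iter = 1200, seed = 2, rhat_warn = FALSE)
  tab <- residual_acf(f, d, max_lag = 4)
  expect_equal(nrow(tab), 4)
  # averaged over 15 individuals of length 100: well inside the noise band
  expect_true(all(abs(tab$acf) < 2 / sqrt(100 / 2)))
  expect_equal(nrow(residual_acf(f, d, max_lag = 0)), 0)
  # duplicated observations create dependent residuals: a series of iid
  # values each repeated twice has theoretical lag-1 autocorrelation 1/2
  d2 <- d[rep(seq(1, 200), each = 2), ]
  d2$date <- seq_len(nrow(d2)); d2$id <- "same"
  f2 <- bglmm(y ~ x, d2, chains = 2, iter = 1200, seed = 3, rhat_warn = FALSE)
  tab2 <- residual_acf(f2, d2, max_lag = 1)
  expect_equal(tab2$acf[1], 0.5, tolerance = 0.1)
})

test_that("posterior predictive tables bracket the observed statistics for a well-specified model", {
  set.seed(13)
  d <- data.frame(x = rnorm(700))
  d$y <- rbinom(700, 1, plogis(-0.4 + 0.7 * d$x))
  f <- bglmm(y ~ x, d, chains = 2, iter = 1500, seed = 5, rhat_warn = FALSE)
  tab <- ppc_table(f, n_rep = 200)
  expect_true(tab$rep_q2.5 <= tab$observed & tab$observed <= tab$rep_q97.5)
  # ordinal variant reports one share per category
  d$k <- draw_ordinal_oracle <- findInterval(rnorm(700), c(-0.5, 0.5)) + 1L
  fo <- bglmm(k ~ x, d, family = "ordinal", chains = 2, iter = 1500, seed = 6,
              rhat_warn = FALSE)
  tabo <- ppc_table(fo, n_rep = 100)
  expect_equal(nrow(tabo), 3)
  expect_equal(sum(tabo$observed), 1)
})
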