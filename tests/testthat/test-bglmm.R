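test_that("monotonic transform satisfies its endpoint and shape identities", {
  for (D in c(1, 2, 4, 6)) {
    zeta <- rexp(D); zeta <- zeta / sum(zeta)
    expect_equal(monotonic_transform(0, zeta), 0)
    expect_equal(monotonic_transform(D, zeta), D)
    expect_true(all(diff(monotonic_transform(0:D, zeta)) >= 0))
  }
  # all effect at the first step
  expect_equal(monotonic_transform(1:4, c(1, 0, 0, 0)), rep(4, 4))
  # uniform simplex: mo(x) = x
  expect_equal(monotonic_transform(0:4, rep(0.25, 4)), 0:4)
  expect_error(monotonic_transform(1, c(0.5, 0.4)), "sum to 1")
  expect_error(monotonic_transform(1, c(1.2, -0.2)), "non-negative")
})

test_that("ordinal category probabilities telescope to one", {
  # by construction: tau at logit(0.25/0.5/0.75), eta = 0 -> equal quarters
  tau <- qlogis(c(0.25, 0.5, 0.75))
  expect_equal(ordinal_likelihood(NULL, 0, tau), rep(0.25, 4))
  # extreme eta concentrates on the top category
  expect_gt(ordinal_likelihood(4, 30, tau), 1 - 1e-10)
  for (i in 1:20) {
    tau <- sort(rnorm(sample(2:6, 1), 0, 2))
    eta <- rnorm(1, 0, 3)
    expect_equal(sum(ordinal_likelihood(NULL, eta, tau)), 1, tolerance = 1e-12)
  }
  expect_error(ordinal_likelihood(1, 0, c(1, 0.5)), "increasing")
})

test_that("linear predictor assembles coefficients, interactions, monotonic terms and random intercepts", {
  expect_equal(linear_predictor(list(x = 5), beta = c(x = 0)), 0)
  expect_equal(linear_predictor(list(x1 = 2, x2 = 3), beta = c("x1:x2" = 1)), 6)
  # uniform simplex, D = 4, level 2, coefficient 0.5 -> 0.5 * 4 * 0.5 = 1
  expect_equal(
    linear_predictor(list(m = 2), mo = list(m = list(b = 0.5, zeta = rep(0.25, 4)))),
    1)
  expect_equal(
    linear_predictor(list(x = 2, m = 1), beta = c("(Intercept)" = 1, x = 0.5),
                     mo = list(m = list(b = 1, zeta = c(0.5, 0.5))),
                     re = c(id = 0.3, group = -0.1)),
    1 + 1 + 1 + 0.2)
  expect_error(linear_predictor(list(), beta = c(zz = 1)), "missing")
})

test_that("the model's Bernoulli log-likelihood matches a naive implementation", {
  set.seed(3)
  for (r in 1:5) {
    eta <- rnorm(100, 0, 2)
    y <- rbinom(100, 1, plogis(eta))
    naive <- sum(ifelse(y == 1, log(plogis(eta)), log(1 - plogis(eta))))
    expect_equal(vervetIGC:::loglik_bernoulli_cpp(eta, y), naive,
                 tolerance = 1e-10)
  }
})

test_that("intercept-only Bernoulli posterior matches the conjugate-scale oracle", {
  set.seed(10)
  d <- data.frame(y = rbinom(1000, 1, 0.6))
  f <- bglmm(y ~ 1, d, family = "bernoulli", chains = 2, iter = 2000, seed = 2)
  p_hat <- mean(plogis(draw_matrix(f)[, "b_(Intercept)"]))
  expect_lt(abs(p_hat - 0.6), 0.04)
})

test_that("ordinal model with K = 2 reproduces the Bernoulli fit", {
  set.seed(4)
  n <- 600
  d <- data.frame(x = rnorm(n), g = factor(sample(10, n, TRUE)))
  eta <- -0.3 + 0.8 * d$x + rnorm(10, 0, 0.4)[d$g]
  d$y <- rbinom(n, 1, plogis(eta))
  d$y2 <- d$y + 1L
  fb <- bglmm(y ~ x + (1 | g), d, family = "bernoulli", chains = 2,
              iter = 3000, seed = 5, rhat_warn = FALSE)
  fo <- bglmm(y2 ~ x + (1 | g), d, family = "ordinal", chains = 2,
              iter = 3000, seed = 6, rhat_warn = FALSE)
  sb <- summary(fb); so <- summary(fo)
  # slope agrees; the Bernoulli intercept is minus the single threshold
  expect_lt(abs(sb$mean[sb$parameter == "b_x"] -
                so$mean[so$parameter == "b_x"]), 0.1)
  expect_lt(abs(sb$mean[sb$parameter == "b_(Intercept)"] +
                so$mean[so$parameter == "tau[1]"]), 0.15)
})

test_that("a monotonic term with D = 1 degenerates to a binary dummy", {
  set.seed(8)
  n <- 800
  d <- data.frame(x = rbinom(n, 1, 0.5))
  d$y <- rbinom(n, 1, plogis(-0.5 + 0.9 * d$x))
  f1 <- bglmm(y ~ mo(x), d, family = "bernoulli", chains = 2, iter = 2500,
              seed = 1, rhat_warn = FALSE)
  f2 <- bglmm(y ~ x, d, family = "bernoulli", chains = 2, iter = 2500,
              seed = 1, rhat_warn = FALSE)
  s1 <- summary(f1); s2 <- summary(f2)
  # with D = 1 the simplex is degenerate at 1 and bmo is the dummy effect
  expect_equal(mean(draw_matrix(f1)[, "simo_x[1]"]), 1)
  expect_lt(abs(s1$mean[s1$parameter == "bmo_x"] -
                s2$mean[s2$parameter == "b_x"]), 0.12)
})

test_that("posterior means agree with a frequentist mixed-model fit at large n", {
  skip_if_not_installed("lme4")
  set.seed(12)
  n <- 1200; L <- 30
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5),
                  g = factor(sample(L, n, TRUE)))
  eta <- 0.4 + 0.7 * d$x1 - 0.5 * d$x2 + rnorm(L, 0, 0.5)[d$g]
  d$y <- rbinom(n, 1, plogis(eta))
  f <- bglmm(y ~ x1 + x2 + (1 | g), d, family = "bernoulli", chains = 2,
             iter = 3000, seed = 3, rhat_warn = FALSE)
  m <- lme4::glmer(y ~ x1 + x2 + (1 | g), d, family = binomial)
  fe <- lme4::fixef(m)
  s <- summary(f)
  for (nm in c("(Intercept)", "x1", "x2"))
    expect_lt(abs(s$mean[s$parameter == paste0("b_", nm)] - fe[[nm]]), 0.12)
  expect_lt(abs(s$mean[s$parameter == "sd_g"] -
                sqrt(unlist(lme4::VarCorr(m)))), 0.15)
})

test_that("the posterior agrees with an independent Gibbs sampler on a shared model", {
  skip_if_not_installed("rjags")
  set.seed(44)
  n <- 300; L <- 10
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5),
                  g = factor(sample(L, n, TRUE)))
  eta <- -0.2 + 0.9 * d$x1 + 0.5 * d$x2 + rnorm(L, 0, 0.5)[d$g]
  d$y <- rbinom(n, 1, plogis(eta))
  f <- bglmm(y ~ x1 + x2 + (1 | g), d, family = "bernoulli", chains = 2,
             iter = 6000, seed = 9, rhat_warn = FALSE)
  jm <- "model {
    for (i in 1:n) {
      logit(pr[i]) <- b0 + b1 * x1[i] + b2 * x2[i] + u[g[i]]
      y[i] ~ dbern(pr[i])
    }
    b0 ~ dnorm(0, 1); b1 ~ dnorm(0, 1); b2 ~ dnorm(0, 1)
    for (l in 1:L) { u[l] ~ dnorm(0, tau) }
    s ~ dnorm(0, 1) T(0,); tau <- 1 / (s * s)
  }"
  jmod <- rjags::jags.model(textConnection(jm),
                            data = list(n = n, y = d$y, x1 = d$x1, x2 = d$x2,
                                        g = as.integer(d$g), L = L),
                            n.chains = 2, n.adapt = 500, quiet = TRUE)
  sm <- rjags::coda.samples(jmod, c("b0", "b1", "b2", "s"), n.iter = 4000)
  js <- summary(sm)$statistics
  s <- summary(f)
  ours <- setNames(s$mean, s$parameter)
  oursd <- setNames((s$q97.5 - s$q2.5) / (2 * 1.96), s$parameter)
  map <- c(b0 = "b_(Intercept)", b1 = "b_x1", b2 = "b_x2", s = "sd_g")
  for (jp in names(map)) {
    expect_lt(abs(ours[[map[[jp]]]] - js[jp, "Mean"]), 0.12)
    expect_lt(abs(log(oursd[[map[[jp]]]] / js[jp, "SD"])), log(1.45))
  }
})

test_that("constant covariate columns are dropped with a warning", {
  d <- data.frame(y = rbinom(200, 1, 0.5), x = rnorm(200), z = 1)
  expect_warning(f <- bglmm(y ~ x + z, d, family = "bernoulli", chains = 2,
                            iter = 600, seed = 1, rhat_warn = FALSE),
                 "constant")
  expect_false("b_z" %in% f$par_names)
})

test_that("dropping a zero-variance random-effect factor leaves fitted probabilities unchanged", {
  set.seed(30)
  n <- 500
  d <- data.frame(x = rnorm(n), g = factor(sample(5, n, TRUE)),
                  h = factor(sample(4, n, TRUE)))
  d$y <- rbinom(n, 1, plogis(0.6 * d$x + rnorm(5, 0, 0.6)[d$g])) # h truly inert
  f1 <- bglmm(y ~ x + (1 | g) + (1 | h), d, chains = 2, iter = 3000, seed = 2,
              rhat_warn = FALSE)
  f2 <- bglmm(y ~ x + (1 | g), d, chains = 2, iter = 3000, seed = 2,
              rhat_warn = FALSE)
  p1 <- fitted_prob(f1, summary = TRUE)
  p2 <- fitted_prob(f2, summary = TRUE)
  expect_lt(mean(abs(p1 - p2)), 0.02)
})
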