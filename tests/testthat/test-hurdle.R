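test_that("hurdle log-likelihood matches the two-stage factorization", {
  expect_equal(hurdle_loglik(1, 1, 0.5, 0.5), log(0.25))
  # failing hurdle 1 short-circuits hurdle 2
  expect_equal(hurdle_loglik(0, NA, 0.5, 0.123), log(0.5))
  expect_equal(hurdle_loglik(0, NA, 0.5, 0.999), log(0.5))
  expect_error(hurdle_loglik(0, 1, 0.5, 0.5), "y1 = 0")
  expect_error(hurdle_loglik(1, NA, 0.5, 0.5), "undefined")
  expect_error(hurdle_loglik(1, 1, 1.2, 0.5), "in \\(0, 1\\)")
})

test_that("outcome probabilities sum to one over the three legal outcomes", {
  set.seed(1)
  for (r in 1:200) {
    p1 <- runif(1, 0.01, 0.99); p2 <- runif(1, 0.01, 0.99)
    tot <- exp(hurdle_loglik(0, NA, p1, p2)) +
      exp(hurdle_loglik(1, 0, p1, p2)) +
      exp(hurdle_loglik(1, 1, p1, p2))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("rank-statistic AUC matches hand-computed and degenerate cases", {
  # 4 scores, outcomes (0,0,1,1): 3 of 4 pos-neg pairs concordant
  expect_equal(auc_rank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_rank(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc_rank(1:10, c(rep(0, 5), rep(1, 5))), 1)
  expect_error(auc_rank(1:4, c(1, 1, 1, 1)), "single-class")
})

test_that("rank-statistic AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  for (r in 1:5) {
    sc <- round(runif(60), 2)          # rounded scores force ties
    y <- rbinom(60, 1, plogis(3 * (sc - 0.5)))
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_rank(sc, y), ref, tolerance = 1e-12)
  }
})

test_that("the double hurdle fits and its likelihood factorizes over hurdles", {
  sim <- simulate_panel("hurdle", n = 900, seed = 31)
  p <- sim$panel
  p$mother_id <- p$mother
  fit <- suppressWarnings(fit_double_hurdle(p, chains = 2, iter = 1200, seed = 7,
                                            rhat_warn = FALSE))
  expect_s3_class(fit$h1, "bglmm"); expect_s3_class(fit$h2, "bglmm")
  expect_equal(fit$h2$data_rows, sum(p$groomed))
  # factorization: hurdle-2 posterior equals an independent fit on the subset
  sub <- p[p$groomed == 1, ]
  ind <- bglmm(groomed_by_mother ~ sexM + age_z + rank_z + (1 | id) +
                 (1 | mother_id) + (1 | focal_group), sub,
               chains = 2, iter = 1200, seed = 7, rhat_warn = FALSE)
  s1 <- summary(fit$h2); s2 <- summary(ind)
  expect_lt(max(abs(s1$mean[grep("^b_", s1$parameter)] -
                    s2$mean[grep("^b_", s2$parameter)])), 0.12)
})

test_that("hurdle preconditions are enforced", {
  sim <- simulate_panel("hurdle", n = 60, seed = 5)
  p <- sim$panel; p$mother_id <- p$mother
  p0 <- p; p0$groomed <- 0; p0$groomed_by_mother <- NA_integer_
  expect_error(fit_double_hurdle(p0), "unidentifiable")
  p1 <- p; p1$groomed_by_mother[which(p1$groomed == 1)[1]] <- NA
  expect_error(fit_double_hurdle(p1), "groomed_by_mother")
})

test_that("AUC with random intercepts dominates the fixed-effect-only AUC in-sample", {
  sim <- simulate_panel("hurdle", n = 1200, seed = 17,
                        re_sds = c(id = 0.8, mother = 0.4, focal_group = 0.3))
  p <- sim$panel; p$mother_id <- p$mother
  fit <- suppressWarnings(fit_double_hurdle(p, chains = 2, iter = 1000, seed = 3,
                                            rhat_warn = FALSE))
  tab <- hurdle_auc_table(fit)
  expect_equal(names(tab), c("hurdle", "effects", "auc"))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  a_full <- tab$auc[tab$hurdle == 1 & tab$effects == "full"]
  a_main <- tab$auc[tab$hurdle == 1 & tab$effects == "main_only"]
  expect_gt(a_full, a_main)
})
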