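#' Probability of direction
#'
#' The posterior probability that a parameter is strictly on the side of
#' zero where most of its mass lies: `max(P(x > 0), P(x < 0))`, with exact
#' zeros counted towards the majority side. Ranges 0.5-1 for symmetric-ish
#' posteriors.
#'
#' @param draws numeric vector of posterior draws (>= 2).
#' @export
probability_of_direction <- function(draws) {
  if (length(draws) < 2) stop("need at least 2 draws", call. = FALSE)
  p_pos <- mean(draws > 0)
  p_neg <- mean(draws < 0)
  max(p_pos, p_neg) + mean(draws == 0)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Classic split-R-hat: each chain is halved, then the usual
#' between/within-variance ratio is computed over the split chains.
#' Constant draws define R-hat = 1 (with a warning).
#'
#' @param draws matrix of draws (iterations x chains); at least 2 chains
#'   and 4 draws per chain.
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("R-hat needs at least 2 chains", call. = FALSE)
  niter <- nrow(draws)
  if (niter < 4) stop("R-hat needs at least 4 draws per chain", call. = FALSE)
  half <- floor(niter / 2)
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(niter - half + 1):niter, , drop = FALSE])
  if (all(apply(split, 2, stats::var) == 0)) {
    if (stats::var(as.vector(split)) == 0) {
      warning("constant draws: R-hat defined as 1")
      return(1)
    }
    return(Inf)
  }
  m <- ncol(split); n <- nrow(split)
  means <- colMeans(split)
  B <- n * stats::var(means)
  W <- mean(apply(split, 2, stats::var))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via Geyer's initial positive sequence on the
# chain-averaged autocorrelations
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (n < 4) return(NA_real_)
  W <- mean(apply(draws, 2, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  max_lag <- min(n - 1, 500)
  rho <- rep(0, max_lag)
  acfs <- apply(draws, 2, function(x)
    as.vector(stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf))
  rho_hat <- rowMeans(acfs)[-1]
  s <- 0; t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho_hat[t] + rho_hat[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- n * m / (1 + 2 * s)
  min(ess, n * m)
}

#' Bayesian R-squared for a fitted mixed model
#'
#' Per posterior draw `s`: for Bernoulli models
#' `R2_s = Var_rows(p_s) / (Var_rows(p_s) + Mean_rows(p_s (1 - p_s)))`; for
#' ordinal models the latent-logit-scale variant
#' `Var_rows(eta_s) / (Var_rows(eta_s) + pi^2 / 3)` (labelled as such in
#' the pipeline outputs, since ordinal-model R-squared is convention-
#' dependent). `mode = "conditional"` includes random intercepts,
#' `"marginal"` sets them to zero (fixed effects only).
#'
#' @param fit a `bglmm` fit.
#' @param mode `"conditional"` or `"marginal"`.
#' @param max_draws cap on the number of draws used (thinned evenly).
#' @return numeric vector of draw-wise R-squared values, with a `summary`
#'   attribute (mean and central 95% interval).
#' @export
bayes_r2 <- function(fit, mode = c("conditional", "marginal"), max_draws = 1000) {
  mode <- match.arg(mode)
  S_all <- dim(fit$draws)[1] * dim(fit$draws)[2]
  idx <- if (S_all > max_draws) round(seq(1, S_all, length.out = max_draws)) else seq_len(S_all)
  r2 <- numeric(length(idx))
  chunk <- 200
  for (st in seq(1, length(idx), by = chunk)) {
    sel <- idx[st:min(st + chunk - 1, length(idx))]
    eta <- linpred_draws(fit, re = (mode == "conditional"), draw_idx = sel)
    if (fit$family == "bernoulli") {
      p <- plogis(eta)
      vfit <- apply(p, 1, stats::var)
      vres <- rowMeans(p * (1 - p))
      r2[st:(st + length(sel) - 1)] <- vfit / (vfit + vres)
    } else {
      vfit <- apply(eta, 1, stats::var)
      r2[st:(st + length(sel) - 1)] <- vfit / (vfit + pi^2 / 3)
    }
  }
  if (all(r2 == 0)) warning("constant fitted probabilities: R-squared is 0")
  attr(r2, "summary") <- c(mean = mean(r2),
                           q2.5 = unname(quantile(r2, 0.025)),
                           q97.5 = unname(quantile(r2, 0.975)))
  r2
}

#' Area under the ROC curve by the rank statistic
#'
#' Tie-corrected Mann-Whitney formulation: with midranks `r` of the scores,
#' `AUC = (sum of positive-class ranks - n1 (n1 + 1) / 2) / (n1 n0)`.
#'
#' @param scores numeric predicted scores.
#' @param labels 0/1 outcomes.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("AUC undefined: outcomes are single-class", call. = FALSE)
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Residual autocorrelation report
#'
#' Lag-1..max_lag autocorrelation of date-ordered posterior-mean Pearson
#' residuals, computed per individual and averaged across individuals
#' (lags an individual's series is too short for are dropped for that
#' individual).
#'
#' @param fit a Bernoulli `bglmm` fit.
#' @param panel the model frame the fit was run on.
#' @param max_lag maximum lag.
#' @param id_col,date_col panel columns identifying individual and date.
#' @return data frame `lag`, `acf`, `n_individuals`.
#' @export
residual_acf <- function(fit, panel, max_lag = 5, id_col = "id", date_col = "date") {
  if (max_lag < 1)
    return(data.frame(lag = integer(0), acf = numeric(0), n_individuals = integer(0)))
  p <- fitted_prob(fit, re = TRUE, summary = TRUE)
  res <- (fit$y - p) / sqrt(pmax(p * (1 - p), 1e-12))
  acc <- matrix(NA_real_, nrow = max_lag, ncol = 0)
  for (id in unique(panel[[id_col]])) {
    sel <- which(panel[[id_col]] == id)
    sel <- sel[order(panel[[date_col]][sel])]
    if (length(sel) < 2) next
    lmax <- min(max_lag, length(sel) - 1)
    a <- as.vector(stats::acf(res[sel], lag.max = lmax, plot = FALSE)$acf)[-1]
    acc <- cbind(acc, c(a, rep(NA_real_, max_lag - lmax)))
  }
  data.frame(lag = seq_len(max_lag),
             acf = rowMeans(acc, na.rm = TRUE),
             n_individuals = rowSums(!is.na(acc)))
}

#' Posterior predictive check table
#'
#' Compares observed outcome summaries with replicated data drawn from the
#' posterior predictive distribution: the overall positive rate for
#' Bernoulli models, and per-category shares for ordinal models.
#'
#' @param fit a `bglmm` fit.
#' @param n_rep number of posterior predictive replicates.
#' @return data frame `statistic`, `observed`, `rep_mean`, `rep_q2.5`,
#'   `rep_q97.5`.
#' @export
ppc_table <- function(fit, n_rep = 200) {
  S_all <- dim(fit$draws)[1] * dim(fit$draws)[2]
  idx <- round(seq(1, S_all, length.out = min(n_rep, S_all)))
  eta <- linpred_draws(fit, re = TRUE, draw_idx = idx)
  n <- length(fit$y)
  if (fit$family == "bernoulli") {
    p <- plogis(eta)
    rep_rate <- rowMeans(matrix(rbinom(length(p), 1, p), nrow = nrow(p)))
    data.frame(statistic = "positive_rate",
               observed = mean(fit$y),
               rep_mean = mean(rep_rate),
               rep_q2.5 = unname(quantile(rep_rate, 0.025)),
               rep_q97.5 = unname(quantile(rep_rate, 0.975)))
  } else {
    K <- fit$K
    tau_cols <- paste0("tau[", seq_len(K - 1), "]")
    dm <- draw_matrix(fit)[idx, tau_cols, drop = FALSE]
    shares <- matrix(NA_real_, nrow(eta), K)
    for (s in seq_len(nrow(eta))) {
      cum <- plogis(outer(dm[s, ], eta[s, ], "-"))  # (K-1) x n
      pr <- rbind(cum, 1) - rbind(0, cum)
      yrep <- apply(pr, 2, function(pp) sample.int(K, 1, prob = pmax(pp, 0)))
      shares[s, ] <- tabulate(yrep, K) / n
    }
    obs <- tabulate(fit$y, K) / n
    data.frame(statistic = paste0("share_level_", seq_len(K)),
               observed = obs,
               rep_mean = colMeans(shares),
               rep_q2.5 = apply(shares, 2, quantile, 0.025),
               rep_q97.5 = apply(shares, 2, quantile, 0.975))
  }
}

#' Full diagnostics report for a fitted model
#'
#' Bundles the per-parameter summaries with conditional and marginal
#' R-squared and the posterior predictive table.
#'
#' @param fit a `bglmm` fit.
#' @param r2_draws draws used for the R-squared vectors.
#' @export
diagnostics_report <- function(fit, r2_draws = 500) {
  r2c <- bayes_r2(fit, "conditional", max_draws = r2_draws)
  r2m <- bayes_r2(fit, "marginal", max_draws = r2_draws)
  list(parameters = summary(fit),
       r2 = rbind(
         data.frame(mode = "conditional", t(attr(r2c, "summary"))),
         data.frame(mode = "marginal", t(attr(r2m, "summary")))),
       ppc = ppc_table(fit))
}
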