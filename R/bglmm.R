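#' Monotonic transform of an ordinal predictor
#'
#' The monotonic construction for an ordinal covariate with levels `0..D`:
#' `mo(x) = D * sum(zeta[1:x])`, where `zeta` is a simplex of `D`
#' non-negative increments summing to 1. `mo(0) = 0`, `mo(D) = D`, and the
#' transform is nondecreasing, so the associated coefficient is the average
#' per-level effect.
#'
#' @param x integer level(s) in `0..D`.
#' @param zeta simplex of length `D` (sums to 1, tolerance 1e-10).
#' @return numeric vector in `[0, D]`.
#' @export
monotonic_transform <- function(x, zeta) {
  if (any(zeta < 0)) stop("simplex entries must be non-negative", call. = FALSE)
  if (abs(sum(zeta) - 1) > 1e-10) stop("'zeta' must sum to 1", call. = FALSE)
  D <- length(zeta)
  if (any(x < 0 | x > D | x != floor(x)))
    stop(sprintf("levels must be integers in 0..%d", D), call. = FALSE)
  cs <- c(0, cumsum(zeta))
  D * cs[x + 1]
}

#' Cumulative-logit ordinal category probabilities
#'
#' `P(Y = k) = plogis(tau[k] - eta) - plogis(tau[k-1] - eta)` with
#' `tau[0] = -Inf`, `tau[K] = +Inf`.
#'
#' @param k category (1..K), or `NULL` to return the full K-vector.
#' @param eta linear predictor (scalar).
#' @param tau strictly increasing thresholds, length K-1.
#' @export
ordinal_likelihood <- function(k = NULL, eta, tau) {
  if (any(diff(tau) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  p <- as.vector(ordinal_probs_cpp(eta, tau))
  if (is.null(k)) return(p)
  if (any(k < 1 | k > length(tau) + 1))
    stop("category out of range", call. = FALSE)
  p[k]
}

#' Evaluate the linear predictor of a mixed model for one observation
#'
#' `eta = sum_j beta_j x_j + sum interactions + sum monotonic contributions
#' + sum random intercepts`. Interaction coefficients are named `"a:b"` and
#' evaluated as the product of the named covariates.
#'
#' @param row named list/vector of covariate values (use `"(Intercept)" = 1`
#'   implicitly: an `"(Intercept)"` coefficient needs no covariate).
#' @param beta named coefficient vector.
#' @param mo named list of monotonic terms, each
#'   `list(b = coefficient, zeta = simplex)`, with `row[[name]]` the level.
#' @param re numeric vector of random-intercept values for the row's levels
#'   (already looked up); unknown levels should be passed as 0.
#' @export
linear_predictor <- function(row, beta = numeric(0), mo = list(), re = numeric(0)) {
  eta <- 0
  for (nm in names(beta)) {
    if (nm == "(Intercept)") { eta <- eta + beta[[nm]]; next }
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    val <- prod(vapply(parts, function(p) {
      if (is.null(row[[p]])) stop(sprintf("covariate '%s' missing", p), call. = FALSE)
      as.numeric(row[[p]])
    }, numeric(1)))
    eta <- eta + beta[[nm]] * val
  }
  for (nm in names(mo)) {
    if (is.null(row[[nm]])) stop(sprintf("covariate '%s' missing", nm), call. = FALSE)
    eta <- eta + mo[[nm]]$b * monotonic_transform(as.numeric(row[[nm]]), mo[[nm]]$zeta)
  }
  eta + sum(re)
}

# ---- formula parsing -------------------------------------------------------

# splits y ~ a + b + mo(x) + (1 | g) into fixed / monotonic / random pieces
parse_bglmm_formula <- function(formula, data) {
  tt <- terms(formula, keep.order = TRUE)
  labels <- attr(tt, "term.labels")
  resp <- as.character(attr(tt, "variables"))[[attr(tt, "response") + 1]]
  re_labels <- grep("\\|", labels, value = TRUE)
  mo_labels <- grep("^mo\\(", labels, value = TRUE)
  fixed_labels <- setdiff(labels, c(re_labels, mo_labels))
  re_vars <- vapply(re_labels, function(l) {
    m <- regmatches(l, regexec("^1 *\\| *(.+)$", l))[[1]]
    if (length(m) < 2) stop(sprintf("unsupported random term '%s'; only (1 | g) intercepts are supported", l),
                            call. = FALSE)
    trimws(m[2])
  }, character(1), USE.NAMES = FALSE)
  mo_vars <- vapply(mo_labels, function(l) {
    trimws(sub("^mo\\((.+)\\)$", "\\1", l))
  }, character(1), USE.NAMES = FALSE)
  list(response = resp, fixed = fixed_labels, mo = mo_vars, re = re_vars)
}

#' Fit a Bayesian mixed model by adaptive MCMC
#'
#' Bernoulli (logit) or cumulative-ordinal (logit) regression with crossed /
#' nested random intercepts and optional monotonic ordinal predictors,
#' sampled by an adaptive blockwise random-walk Metropolis algorithm
#' (covariance-adapted joint block for the regression coefficients; scalar
#' updates for random intercepts and variance components; adaptation during
#' warmup only). Priors: normal(0, 1) on standardized fixed effects,
#' half-normal(0, 1) on random-effect SDs, Dirichlet(1, ..., 1) on
#' monotonic simplexes, normal(0, 5) on ordinal thresholds.
#'
#' @param formula model formula, e.g.
#'   `y ~ age_z + sexM + mo(mat_level) + (1 | id) + (1 | focal_group)`.
#'   Only `(1 | g)` random intercepts are supported; nested intercepts are
#'   expressed by coding the nested factor's levels uniquely (as
#'   [build_event_panel()] does).
#' @param data model frame. Continuous covariates are expected to be scaled
#'   and mean-centred already (the `_z` panel columns).
#' @param family `"bernoulli"` or `"ordinal"`.
#' @param chains,iter MCMC chains and total iterations per chain (first
#'   half is warmup/adaptation and discarded).
#' @param seed integer seed making the fit reproducible.
#' @param prior_sd_beta,prior_sd_tau prior scales for coefficients and
#'   ordinal thresholds.
#' @param drop_constant drop constant covariate columns (with a warning)
#'   instead of failing.
#' @param rhat_warn warn when any parameter's split R-hat exceeds 1.01.
#' @return an object of class `bglmm` with posterior `draws`
#'   (iterations x chains x parameters) and the model frame needed by
#'   [fitted_prob()], [bayes_r2()] and [summary.bglmm()].
#' @export
bglmm <- function(formula, data, family = c("bernoulli", "ordinal"),
                  chains = 4, iter = 2000, seed = NULL,
                  prior_sd_beta = 1, prior_sd_tau = 5,
                  drop_constant = TRUE, rhat_warn = TRUE) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  pf <- parse_bglmm_formula(formula, data)

  y_raw <- data[[pf$response]]
  if (is.null(y_raw)) stop(sprintf("response '%s' not found", pf$response), call. = FALSE)
  if (family == "bernoulli") {
    y <- as.integer(y_raw)
    if (!all(y %in% c(0L, 1L))) stop("Bernoulli response must be 0/1", call. = FALSE)
    K <- 2L
  } else {
    y <- if (is.ordered(y_raw) || is.factor(y_raw)) as.integer(y_raw) else as.integer(y_raw)
    if (min(y) < 1) stop("ordinal response must take values 1..K", call. = FALSE)
    K <- max(y)
    if (K < 2) stop("ordinal response needs at least 2 observed categories", call. = FALSE)
  }
  n <- length(y)

  # fixed-effect design
  fixed_form <- if (length(pf$fixed))
    reformulate(pf$fixed, intercept = (family == "bernoulli"))
  else if (family == "bernoulli") ~1 else ~0
  X <- model.matrix(fixed_form, data)
  if (drop_constant && ncol(X)) {
    const <- apply(X, 2, function(col) length(unique(col)) == 1) &
      colnames(X) != "(Intercept)"
    if (any(const)) {
      warning("dropping constant covariate column(s): ",
              paste(colnames(X)[const], collapse = ", "))
      X <- X[, !const, drop = FALSE]
    }
  }
  p <- ncol(X)

  # monotonic terms
  M <- length(pf$mo)
  mo_x <- list(); mo_D <- list()
  for (v in pf$mo) {
    xv <- as.integer(data[[v]])
    if (any(is.na(xv)) || any(xv < 0)) stop(sprintf("monotonic term '%s' must be non-negative integers", v), call. = FALSE)
    D <- max(xv)
    if (D < 1) stop(sprintf("monotonic term '%s' is constant at 0", v), call. = FALSE)
    mo_x[[v]] <- xv
    mo_D[[v]] <- D
  }

  # random intercepts
  Fn <- length(pf$re)
  re_index <- list(); re_levels <- list()
  for (g in pf$re) {
    f <- factor(data[[g]])
    re_index[[g]] <- as.integer(f) - 1L
    re_levels[[g]] <- levels(f)
  }
  re_nlev <- vapply(re_levels, length, integer(1))

  warmup <- floor(iter / 2)
  keep <- iter - warmup

  # covariates (near-)constant within a factor's levels ride a likelihood
  # ridge with that factor's intercepts; register an aligned-shift move for
  # each such pair (within-level SD under half the overall SD is the mixing
  # heuristic - any choice gives a valid kernel, this one targets the
  # ridges that actually stall blockwise updates)
  shift_factor <- integer(0); shift_col <- integer(0); shift_xlev <- list()
  if (p && Fn) {
    for (fi in seq_len(Fn)) {
      idx <- re_index[[fi]] + 1L
      for (j in seq_len(p)) {
        if (colnames(X)[j] == "(Intercept)") next
        tot_sd <- stats::sd(X[, j])
        if (!is.finite(tot_sd) || tot_sd == 0) next
        lev_mean <- tapply(X[, j], idx, mean)
        within_sd <- sqrt(mean((X[, j] - lev_mean[idx])^2))
        if (within_sd <= 0.5 * tot_sd && stats::var(as.numeric(lev_mean)) > 0) {
          xl <- numeric(re_nlev[fi])
          xl[as.integer(names(lev_mean))] <- as.numeric(lev_mean)
          shift_factor <- c(shift_factor, fi - 1L)
          shift_col <- c(shift_col, j - 1L)
          shift_xlev[[length(shift_xlev) + 1]] <- xl
        }
      }
    }
  }

  # empirical threshold starting values
  tau0 <- if (family == "ordinal") {
    cp <- cumsum(tabulate(y, K))[-K] / n
    cp <- pmin(pmax(cp, 1 / (n + 1)), 1 - 1 / (n + 1))
    qlogis(cp)
  } else numeric(0)

  par_names <- c(
    if (p) paste0("b_", colnames(X)),
    if (M) paste0("bmo_", names(mo_x)),
    unlist(lapply(names(mo_x), function(v) paste0("simo_", v, "[", seq_len(mo_D[[v]]), "]"))),
    unlist(lapply(names(re_levels), function(g) paste0("r_", g, "[", re_levels[[g]], "]"))),
    if (Fn) paste0("sd_", names(re_levels)),
    if (family == "ordinal") paste0("tau[", seq_len(K - 1), "]"))

  # mode and curvature of the (random-effect-free) penalized likelihood:
  # chains start at the ridge-IRLS mode, and the fixed-effect proposal
  # starts from the inverse curvature, which encodes collinear geometry the
  # sample-covariance adaptation would otherwise have to learn slowly
  Z <- X
  for (v in names(mo_x)) Z <- cbind(Z, mo_x[[v]])  # uniform-simplex mo column
  beta_hat <- rep(0, ncol(Z))
  if (family == "bernoulli" && ncol(Z)) {
    for (it_irls in 1:12) {
      pr <- plogis(as.vector(Z %*% beta_hat))
      W <- pmax(pr * (1 - pr), 1e-6)
      zres <- as.vector(Z %*% beta_hat) + (y - pr) / W
      beta_new <- tryCatch(
        solve(crossprod(Z, Z * W) + diag(1 / prior_sd_beta^2, ncol(Z)),
              crossprod(Z, W * zres)),
        error = function(e) beta_hat)
      if (max(abs(beta_new - beta_hat)) < 1e-8) { beta_hat <- beta_new; break }
      beta_hat <- as.vector(beta_new)
    }
    pr <- plogis(as.vector(Z %*% beta_hat))
    W <- pmax(pr * (1 - pr), 1e-6)
    beta_prop_cov <- tryCatch(
      solve(crossprod(Z, Z * W) + diag(1 / prior_sd_beta^2, ncol(Z))),
      error = function(e) diag(1e-4, ncol(Z)))
  } else {
    beta_prop_cov <- tryCatch(
      solve(crossprod(Z) / 4 + diag(1 / prior_sd_beta^2, ncol(Z))),
      error = function(e) diag(1e-4, ncol(Z)))
  }
  prop_sd <- sqrt(pmax(diag(beta_prop_cov), 1e-12))

  draws <- array(NA_real_, dim = c(keep, chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  acc <- numeric(chains)
  for (ch in seq_len(chains)) {
    inits <- list(
      beta = beta_hat[seq_len(p)] + rnorm(p, 0, 2 * prop_sd[seq_len(p)]),
      bmo = if (M) beta_hat[p + seq_len(M)] +
        rnorm(M, 0, 2 * prop_sd[p + seq_len(M)]) else numeric(0),
      gamma = lapply(names(mo_x), function(v) rnorm(mo_D[[v]] - 1, 0, 0.1)),
      u = lapply(seq_len(Fn), function(f) rep(0, re_nlev[f])),
      log_sd = log(0.5) + rnorm(Fn, 0, 0.2),
      tau = if (family == "ordinal") sort(tau0 + rnorm(K - 1, 0, 0.05)) else numeric(0))
    res <- mcmc_glmm_chain(
      family = if (family == "bernoulli") 0L else 1L,
      y_ = y, X = X, mo_x_ = unname(mo_x), mo_D_ = unname(mo_D),
      re_index_ = unname(re_index), re_nlev = unname(re_nlev),
      K = K, iter = iter, warmup = warmup,
      beta_prior_sd = prior_sd_beta, tau_prior_sd = prior_sd_tau,
      inits = inits,
      intercept_col = {
        ic <- match("(Intercept)", colnames(X)); if (is.na(ic)) -1L else ic - 1L
      },
      shift_factor = shift_factor, shift_col = shift_col,
      shift_xlev = shift_xlev, beta_prop_cov = beta_prop_cov)
    draws[, ch, ] <- res$draws
    acc[ch] <- res$accept_rate_fixed
  }

  fit <- structure(list(
    formula = formula, family = family, K = K,
    draws = draws, par_names = par_names,
    X = X, y = y, mo_x = mo_x, mo_D = mo_D,
    re_index = re_index, re_levels = re_levels,
    data_rows = nrow(data),
    chains = chains, iter = iter, warmup = warmup,
    accept_rate_fixed = acc), class = "bglmm")

  if (rhat_warn) {
    rh <- apply_rhat(fit)
    bad <- names(rh)[is.finite(rh) & rh > 1.01]
    if (length(bad))
      warning("split R-hat > 1.01 for: ", paste(head(bad, 8), collapse = ", "),
              if (length(bad) > 8) sprintf(" (+%d more)", length(bad) - 8) else "",
              "; consider more iterations")
  }
  fit
}

# flattened draw matrix (chains stacked) for a parameter subset
draw_matrix <- function(fit, pars = NULL) {
  d <- fit$draws
  m <- matrix(aperm(d, c(1, 2, 3)), nrow = dim(d)[1] * dim(d)[2],
              dimnames = list(NULL, fit$par_names))
  if (!is.null(pars)) m[, pars, drop = FALSE] else m
}

apply_rhat <- function(fit) {
  vapply(seq_along(fit$par_names), function(j) rhat(fit$draws[, , j, drop = TRUE]),
         numeric(1), USE.NAMES = FALSE) |> setNames(fit$par_names)
}

# population-level parameters (everything except per-level intercepts)
population_pars <- function(fit) {
  grep("^r_", fit$par_names, value = TRUE, invert = TRUE)
}

#' Posterior summary of a fitted model
#'
#' Mean, median, central 95% credible interval, probability of direction,
#' split R-hat and effective sample size for each population-level
#' parameter.
#'
#' @param object a `bglmm` fit.
#' @param pars parameters to summarize (default: population-level).
#' @param ... unused.
#' @export
summary.bglmm <- function(object, pars = population_pars(object), ...) {
  out <- do.call(rbind, lapply(pars, function(pn) {
    j <- match(pn, object$par_names)
    x <- as.vector(object$draws[, , j])
    data.frame(parameter = pn, mean = mean(x), median = median(x),
               q2.5 = unname(quantile(x, 0.025)), q97.5 = unname(quantile(x, 0.975)),
               pd = probability_of_direction(x),
               rhat = rhat(object$draws[, , j, drop = TRUE]),
               ess = ess_basic(object$draws[, , j, drop = TRUE]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.bglmm <- function(x, ...) {
  cat(sprintf("<bglmm> %s model, %d rows, %d chains x %d iter (%d warmup)\n",
              x$family, x$data_rows, x$chains, x$iter, x$warmup))
  print(summary(x), digits = 3)
  invisible(x)
}

# linear predictor draws (S x n). re = TRUE adds random intercepts
# ("conditional"); re = FALSE sets them to zero ("marginal").
linpred_draws <- function(fit, re = TRUE, draw_idx = NULL) {
  dm <- draw_matrix(fit)
  if (!is.null(draw_idx)) dm <- dm[draw_idx, , drop = FALSE]
  S <- nrow(dm)
  n <- length(fit$y)
  beta_cols <- paste0("b_", colnames(fit$X))
  eta <- if (length(beta_cols)) dm[, beta_cols, drop = FALSE] %*% t(fit$X)
         else matrix(0, S, n)
  for (v in names(fit$mo_x)) {
    D <- fit$mo_D[[v]]
    zs <- dm[, paste0("simo_", v, "[", seq_len(D), "]"), drop = FALSE]
    cz <- cbind(0, t(apply(zs, 1, cumsum)))      # S x (D+1)
    mo_val <- D * cz[, fit$mo_x[[v]] + 1, drop = FALSE]  # S x n
    eta <- eta + dm[, paste0("bmo_", v)] * mo_val
  }
  if (re) {
    for (g in names(fit$re_levels)) {
      uc <- dm[, paste0("r_", g, "[", fit$re_levels[[g]], "]"), drop = FALSE]
      eta <- eta + uc[, fit$re_index[[g]] + 1L, drop = FALSE]
    }
  }
  eta
}

#' Posterior fitted probabilities
#'
#' For Bernoulli models, draws (or posterior means) of per-row success
#' probabilities; for ordinal models, the latent-scale linear predictor
#' draws (used by the latent-scale R-squared) or category probabilities.
#'
#' @param fit a `bglmm` fit.
#' @param re include random intercepts (conditional) or zero them
#'   (marginal)?
#' @param summary return the posterior mean per row instead of draws?
#' @param draw_idx optional draw subset (row indices of the stacked draws).
#' @export
fitted_prob <- function(fit, re = TRUE, summary = FALSE, draw_idx = NULL) {
  if (!summary) {
    eta <- linpred_draws(fit, re = re, draw_idx = draw_idx)
    return(if (fit$family == "bernoulli") plogis(eta) else eta)
  }
  # posterior mean per row, accumulated in draw chunks to bound memory
  idx <- draw_idx %||% seq_len(dim(fit$draws)[1] * dim(fit$draws)[2])
  acc <- numeric(length(fit$y))
  chunk <- 200
  for (st in seq(1, length(idx), by = chunk)) {
    sel <- idx[st:min(st + chunk - 1, length(idx))]
    eta <- linpred_draws(fit, re = re, draw_idx = sel)
    acc <- acc + colSums(if (fit$family == "bernoulli") plogis(eta) else eta)
  }
  acc / length(idx)
}
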