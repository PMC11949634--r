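# Ground-truth generating parameters for the four IGC models, on the
# scaled-and-centred covariate scale. Signs and rough magnitudes emulate the
# study system: participation rises with age, maternal participation and
# focal participant numbers; aggression intensity tracks maternal intensity;
# grooming receipt tracks participation; mothers preferentially groom
# younger offspring. Sex and neophilia are null effects for participation.

#' Default ground-truth coefficients of the synthetic cohort
#'
#' Named lists of generating fixed-effect coefficients for the
#' participation model (`m1`, Bernoulli), the aggression-intensity model
#' (`m2`, cumulative ordinal with monotonic maternal level), the
#' grooming-receipt model (`m3`, Bernoulli, all non-adults), and the
#' maternal-groomer hurdle (`m4b`, Bernoulli on groomed rows), plus the
#' `m2` thresholds/simplex and the random-effect SDs.
#'
#' @return nested list with elements `m1`, `m2`, `m3`, `m4b`, `re_sds`.
#' @export
default_truth <- function() {
  list(
    m1 = c("(Intercept)" = -2.3, age_z = 0.65, sexM = 0, rank_z = 0.15,
           neophilia_z = 0, grooming_ec_z = 0.15, spatial_ec_z = -0.15,
           mother_part = 1.1, n_focal_z = 0.7, n_opp_z = 0.2,
           focal_size_z = -0.15, opp_size_z = 0,
           "n_focal_z:n_opp_z" = -0.1),
    m2 = list(
      beta = c(age_z = 0.5, sexM = 0, rank_z = 0, neophilia_z = 0.2,
               grooming_ec_z = 0.2, spatial_ec_z = -0.2,
               n_focal_z = -0.3, n_opp_z = 0.3, focal_size_z = 0,
               "n_focal_z:n_opp_z" = 0),
      b_mo = 0.35,
      zeta = c(0.4, 0.3, 0.2, 0.1),
      tau = c(1.9, 2.5, 5.1)),
    m3 = c("(Intercept)" = -3.2, participation = 1.6, sexM = -0.25,
           age_z = 0, rank_z = 0.25, neophilia_z = 0,
           grooming_ec_z = 0.2, spatial_ec_z = -0.15,
           focal_size_z = 0.25, n_focal_z = 0.2, n_opp_z = 0.2),
    m4b = c("(Intercept)" = 0, sexM = 0, age_z = -0.6, rank_z = 0),
    re_sds = list(
      m1 = c(id = 0.5, focal_group = 0.3, opp_group = 0.3),
      m2 = c(id = 0.3, focal_group = 0.2, opp_group = 0.2),
      m3 = c(id = 0.3, focal_group = 0.2),
      m4 = c(id = 0.3, mother = 0.2, focal_group = 0.2)))
}

# draw one ordinal response per row given latent eta and thresholds
draw_ordinal <- function(eta, tau) {
  K <- length(tau) + 1
  cum <- plogis(outer(tau, eta, "-"))      # (K-1) x n
  pr <- rbind(cum, 1) - rbind(0, cum)
  vapply(seq_along(eta), function(i) sample.int(K, 1, prob = pmax(pr[, i], 0)),
         integer(1))
}

#' Simulate a model-ready panel directly from one of the IGC models
#'
#' Draws covariates, random intercepts and responses from the exact
#' generative model that [bglmm()] / [fit_double_hurdle()] later fit, for
#' parameter-recovery and calibration experiments. Continuous covariates
#' are iid standard normal (already on the scaled-and-centred model
#' scale); sex is Bernoulli(0.5); maternal participation Bernoulli(0.4);
#' maternal aggression level an ordinal 0-4 draw.
#'
#' @param model `"participation"` (Bernoulli, full Model-1 structure),
#'   `"aggression"` (cumulative ordinal with monotonic maternal level), or
#'   `"hurdle"` (groomed / groomed-by-mother with id-in-mother-in-group
#'   intercepts).
#' @param n panel rows.
#' @param truth generating parameters; defaults to [default_truth()]
#'   entries. For `"hurdle"` a list with `b1` (groomed; names
#'   `"(Intercept)"`, `sexM`, `age_z`, `rank_z`) and `b2`
#'   (groomed-by-mother, same names).
#' @param re_sds named random-effect SDs (defaults per model from
#'   [default_truth()]).
#' @param n_id,n_group,n_opp numbers of individuals, focal groups and
#'   opposing groups (ids nest in groups; each id has one mother).
#' @param seed RNG seed.
#' @return list with `panel` (data frame) and `truth` (generating
#'   parameters, including the drawn random intercepts).
#' @export
simulate_panel <- function(model = c("participation", "aggression", "hurdle"),
                           n = 2000, truth = NULL, re_sds = NULL,
                           n_id = 68, n_group = 3, n_opp = 3, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  tr0 <- default_truth()

  id <- factor(sample(n_id, n, TRUE), levels = seq_len(n_id))
  id_group <- sample(n_group, n_id, TRUE)            # id nested in group
  fg <- factor(id_group[as.integer(id)], levels = seq_len(n_group))
  og <- factor(sample(n_opp, n, TRUE), levels = seq_len(n_opp))
  panel <- data.frame(
    id = paste0("id", id), focal_group = paste0("G", fg),
    opp_group = paste0("O", og),
    age_z = rnorm(n), sexM = rbinom(n_id, 1, 0.5)[as.integer(id)],
    rank_z = rnorm(n), neophilia_z = rnorm(n),
    grooming_ec_z = rnorm(n), spatial_ec_z = rnorm(n),
    n_focal_z = rnorm(n), n_opp_z = rnorm(n),
    focal_size_z = rnorm(n), opp_size_z = rnorm(n),
    date = sample(1500, n, TRUE),
    stringsAsFactors = FALSE)

  if (model == "participation") {
    truth <- truth %||% tr0$m1
    re_sds <- re_sds %||% tr0$re_sds$m1
    panel$mother_part <- rbinom(n, 1, 0.4)
    u_id <- rnorm(n_id, 0, re_sds[["id"]])
    u_fg <- rnorm(n_group, 0, re_sds[["focal_group"]])
    u_og <- rnorm(n_opp, 0, re_sds[["opp_group"]])
    Xf <- model.matrix(~ age_z + sexM + rank_z + neophilia_z + grooming_ec_z +
                         spatial_ec_z + mother_part + focal_size_z + opp_size_z +
                         n_focal_z * n_opp_z, panel)
    stopifnot(all(colnames(Xf) %in% names(truth)))
    eta <- as.vector(Xf %*% truth[colnames(Xf)]) +
      u_id[as.integer(id)] + u_fg[as.integer(fg)] + u_og[as.integer(og)]
    panel$participation <- rbinom(n, 1, plogis(eta))
    return(list(panel = panel,
                truth = list(beta = truth, re_sds = re_sds,
                             u = list(id = u_id, focal_group = u_fg, opp_group = u_og))))
  }

  if (model == "aggression") {
    truth <- truth %||% tr0$m2
    re_sds <- re_sds %||% tr0$re_sds$m2
    panel$mat_level <- sample(0:4, n, TRUE, prob = c(0.45, 0.3, 0.1, 0.11, 0.04))
    u_id <- rnorm(n_id, 0, re_sds[["id"]])
    u_fg <- rnorm(n_group, 0, re_sds[["focal_group"]])
    u_og <- rnorm(n_opp, 0, re_sds[["opp_group"]])
    Xf <- model.matrix(~ 0 + age_z + sexM + rank_z + neophilia_z + grooming_ec_z +
                         spatial_ec_z + focal_size_z + n_focal_z + n_opp_z +
                         n_focal_z:n_opp_z, panel)
    stopifnot(all(colnames(Xf) %in% names(truth$beta)))
    eta <- as.vector(Xf %*% truth$beta[colnames(Xf)]) +
      truth$b_mo * monotonic_transform(panel$mat_level, truth$zeta) +
      u_id[as.integer(id)] + u_fg[as.integer(fg)] + u_og[as.integer(og)]
    panel$level <- draw_ordinal(eta, truth$tau)
    return(list(panel = panel,
                truth = list(beta = truth$beta, b_mo = truth$b_mo,
                             zeta = truth$zeta, tau = truth$tau, re_sds = re_sds,
                             u = list(id = u_id, focal_group = u_fg, opp_group = u_og))))
  }

  # hurdle: groomed, then groomed-by-mother, id in mother in focal group
  truth <- truth %||% list(
    b1 = c("(Intercept)" = -0.5, sexM = -0.25, age_z = 0.4, rank_z = 0.25),
    b2 = tr0$m4b)
  re_sds <- re_sds %||% tr0$re_sds$m4
  n_mother <- max(2, floor(n_id / 2))
  id_mother <- sample(n_mother, n_id, TRUE)
  panel$mother <- paste0("M", id_mother[as.integer(id)])
  u1 <- list(id = rnorm(n_id, 0, re_sds[["id"]]),
             mother = rnorm(n_mother, 0, re_sds[["mother"]]),
             focal_group = rnorm(n_group, 0, re_sds[["focal_group"]]))
  u2 <- list(id = rnorm(n_id, 0, re_sds[["id"]]),
             mother = rnorm(n_mother, 0, re_sds[["mother"]]),
             focal_group = rnorm(n_group, 0, re_sds[["focal_group"]]))
  Xf <- model.matrix(~ sexM + age_z + rank_z, panel)
  mid <- id_mother[as.integer(id)]
  eta1 <- as.vector(Xf %*% truth$b1[colnames(Xf)]) +
    u1$id[as.integer(id)] + u1$mother[mid] + u1$focal_group[as.integer(fg)]
  panel$groomed <- rbinom(n, 1, plogis(eta1))
  eta2 <- as.vector(Xf %*% truth$b2[colnames(Xf)]) +
    u2$id[as.integer(id)] + u2$mother[mid] + u2$focal_group[as.integer(fg)]
  panel$groomed_by_mother <- ifelse(panel$groomed == 1,
                                    rbinom(n, 1, plogis(eta2)), NA_integer_)
  list(panel = panel,
       truth = list(b1 = truth$b1, b2 = truth$b2, re_sds = re_sds,
                    u1 = u1, u2 = u2))
}
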