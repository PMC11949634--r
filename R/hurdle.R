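#' Log-likelihood of one nested double-hurdle outcome
#'
#' Hurdle 1: was the non-adult groomed during the IGC (`y1`); hurdle 2,
#' defined only when `y1 = 1`: was the groomer its mother (`y2`).
#' `log L = (1 - y1) log(1 - p1) + y1 [log p1 + y2 log p2 +
#' (1 - y2) log(1 - p2)]`.
#'
#' @param y1 0/1 groomed.
#' @param y2 0/1 groomed-by-mother, or `NA` when `y1 = 0`.
#' @param p1,p2 hurdle probabilities in (0, 1).
#' @export
hurdle_loglik <- function(y1, y2, p1, p2) {
  if (any(p1 <= 0 | p1 >= 1 | p2 <= 0 | p2 >= 1))
    stop("hurdle probabilities must lie in (0, 1)", call. = FALSE)
  if (any(y1 == 0 & !is.na(y2)))
    stop("y2 is defined for a row with y1 = 0", call. = FALSE)
  if (any(y1 == 1 & is.na(y2)))
    stop("y2 is undefined for a row with y1 = 1", call. = FALSE)
  y2f <- ifelse(is.na(y2), 0, y2)
  (1 - y1) * log(1 - p1) +
    y1 * (log(p1) + y2f * log(p2) + (1 - y2f) * log(1 - p2))
}

#' Fit the nested double-hurdle grooming model
#'
#' Two Bernoulli mixed submodels sharing the covariates sex, age and rank,
#' with non-adult id nested in maternal id nested in focal-group id as
#' random intercepts: hurdle 1 models grooming receipt on all participant
#' rows; hurdle 2 models groomer-is-mother on the rows that cleared
#' hurdle 1. The joint likelihood factorizes over the two hurdles (no
#' shared parameters), so the submodels are sampled as independent blocks.
#'
#' @param panel participant-row model frame (see [model_frame()] with
#'   `"m4"`), with columns `groomed`, `groomed_by_mother`, `sexM`,
#'   `age_z`, `rank_z`, `id`, `mother_id`, `focal_group`.
#' @param chains,iter sampler settings per hurdle (default: eight chains,
#'   500 iterations).
#' @param seed RNG seed.
#' @param ... passed to [bglmm()].
#' @return object of class `hurdle_fit`: list with elements `h1`, `h2`
#'   (both `bglmm` fits) and the row indices of hurdle 2.
#' @export
fit_double_hurdle <- function(panel, chains = 8, iter = 500, seed = NULL, ...) {
  need <- c("groomed", "groomed_by_mother", "sexM", "age_z", "rank_z",
            "id", "mother_id", "focal_group")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  bad <- which(panel$groomed == 1 & is.na(panel$groomed_by_mother))
  if (length(bad))
    stop("groomed rows must carry a groomed_by_mother outcome (row ",
         bad[1], ")", call. = FALSE)
  if (sum(panel$groomed) == 0)
    stop("no hurdle-1 successes: the maternal hurdle is unidentifiable",
         call. = FALSE)
  form1 <- groomed ~ sexM + age_z + rank_z +
    (1 | id) + (1 | mother_id) + (1 | focal_group)
  h1 <- bglmm(form1, panel, family = "bernoulli", chains = chains,
              iter = iter, seed = seed, ...)
  sub <- panel[panel$groomed == 1, , drop = FALSE]
  if (length(unique(sub$groomed_by_mother)) < 2)
    warning("hurdle-2 outcome is single-class; its intercept is only weakly identified")
  form2 <- groomed_by_mother ~ sexM + age_z + rank_z +
    (1 | id) + (1 | mother_id) + (1 | focal_group)
  h2 <- bglmm(form2, sub, family = "bernoulli", chains = chains,
              iter = iter, seed = if (is.null(seed)) NULL else seed + 1L, ...)
  structure(list(h1 = h1, h2 = h2, h2_rows = which(panel$groomed == 1),
                 n = nrow(panel)), class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf("<hurdle_fit> %d participant rows, %d cleared hurdle 1\n",
              x$n, length(x$h2_rows)))
  cat("-- hurdle 1: groomed --\n"); print(summary(x$h1), digits = 3)
  cat("-- hurdle 2: groomed by mother --\n"); print(summary(x$h2), digits = 3)
  invisible(x)
}

#' In-sample AUC of a hurdle submodel
#'
#' Area under the ROC curve of the posterior-mean predicted probability
#' against the observed outcome, by the tie-corrected rank statistic
#' ([auc_rank()]). `effects = "full"` includes the random intercepts;
#' `"main_only"` uses the fixed effects alone.
#'
#' @param fit a `hurdle_fit`.
#' @param which_hurdle 1 (groomed) or 2 (groomed by mother).
#' @param effects `"full"` or `"main_only"`.
#' @export
hurdle_auc <- function(fit, which_hurdle = 1, effects = c("full", "main_only")) {
  effects <- match.arg(effects)
  m <- if (which_hurdle == 1) fit$h1 else fit$h2
  p <- fitted_prob(m, re = (effects == "full"), summary = TRUE)
  auc_rank(p, m$y)
}

#' AUC table for both hurdles and both effect sets
#'
#' @param fit a `hurdle_fit`.
#' @return data frame `hurdle`, `effects`, `auc`.
#' @export
hurdle_auc_table <- function(fit) {
  grid <- expand.grid(hurdle = 1:2, effects = c("full", "main_only"),
                      stringsAsFactors = FALSE)
  grid$auc <- mapply(function(h, e) hurdle_auc(fit, h, e),
                     grid$hurdle, grid$effects)
  grid[order(grid$hurdle), ]
}
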