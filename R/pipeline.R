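MODEL_FORMULAS <- list(
  m1 = participation ~ age_z + sexM + rank_z + neophilia_z + grooming_ec_z +
    spatial_ec_z + mother_part + focal_size_z + opp_size_z +
    n_focal_z * n_opp_z + (1 | id) + (1 | focal_group) + (1 | opp_group),
  m2 = level ~ age_z + sexM + rank_z + neophilia_z + grooming_ec_z +
    spatial_ec_z + focal_size_z + n_focal_z * n_opp_z + mo(mat_level) +
    (1 | id) + (1 | focal_group) + (1 | opp_group),
  m3 = groomed ~ participation + age_z + sexM + rank_z + neophilia_z +
    grooming_ec_z + spatial_ec_z + focal_size_z + n_focal_z + n_opp_z +
    (1 | id) + (1 | focal_group))

MODEL_SETTINGS <- list(
  m1 = list(family = "bernoulli", chains = 4, iter = 2500),
  m2 = list(family = "ordinal", chains = 4, iter = 4000),
  m3 = list(family = "bernoulli", chains = 4, iter = 3500),
  m4 = list(chains = 8, iter = 500))

#' Fit one of the four IGC models on an event panel
#'
#' Applies the model's formula and reference sampler settings (Model 1:
#' Bernoulli participation, 4 chains x 2500 iterations; Model 2:
#' cumulative-ordinal aggression level with monotonic maternal level,
#' 4 x 4000; Model 3: Bernoulli grooming receipt, 4 x 3500; Model 4:
#' double hurdle, 8 x 500). Settings can be overridden for reduced-scale
#' runs.
#'
#' @param panel from [build_event_panel()].
#' @param model `"m1"`, `"m2"`, `"m3"` or `"m4"`.
#' @param chains,iter override the reference sampler settings.
#' @param seed RNG seed.
#' @param ... passed on to [bglmm()] / [fit_double_hurdle()].
#' @return a `bglmm` fit (m1-m3) or `hurdle_fit` (m4).
#' @export
fit_igc_model <- function(panel, model = c("m1", "m2", "m3", "m4"),
                          chains = NULL, iter = NULL, seed = NULL, ...) {
  model <- match.arg(model)
  st <- MODEL_SETTINGS[[model]]
  chains <- chains %||% st$chains
  iter <- iter %||% st$iter
  frame <- model_frame(panel, model)
  if (model == "m4")
    return(fit_double_hurdle(frame, chains = chains, iter = iter, seed = seed, ...))
  if (model == "m2") frame$level <- as.integer(frame$level)
  bglmm(MODEL_FORMULAS[[model]], frame, family = st$family,
        chains = chains, iter = iter, seed = seed, ...)
}

#' Descriptive summary of an event panel
#'
#' The headline descriptive statistics of the IGC data set: number of
#' IGCs, share of IGCs with at least one non-adult participant, the
#' distribution of participant aggression levels, maternal
#' co-participation among participant rows, the participant sex split and
#' the mean participant age in years.
#'
#' @param panel from [build_event_panel()].
#' @param year_length days per year (for age conversion).
#' @return named list of summaries.
#' @export
describe_dataset <- function(panel, year_length = 365) {
  if (!nrow(panel)) stop("empty panel", call. = FALSE)
  n_igc <- length(unique(panel$event_id))
  by_ev <- tapply(panel$participation, panel$event_id, max)
  part <- panel[panel$participation == 1, , drop = FALSE]
  lv <- if (nrow(part)) table(factor(part$level, levels = 1:4)) else
    table(factor(integer(0), levels = 1:4))
  lv_share <- if (nrow(part)) 100 * as.numeric(lv) / nrow(part) else rep(NA_real_, 4)
  sex <- if (nrow(part)) 100 * c(M = mean(part$sexM), F = mean(1 - part$sexM)) else
    c(M = NA_real_, F = NA_real_)
  list(
    n_igc = n_igc,
    pct_igc_with_nonadult = 100 * mean(by_ev > 0),
    n_participant_rows = nrow(part),
    pct_level = setNames(lv_share,
                         c("non-aggressive", "stationary", "active", "physical")),
    pct_mother_coparticipation = if (nrow(part)) 100 * mean(part$mother_part) else NA_real_,
    pct_sex = sex,
    mean_participant_age_years = if (nrow(part)) mean(part$age) / year_length else NA_real_)
}

#' Run the full pipeline end to end
#'
#' generate (or load) -> validate -> networks/centrality -> Elo -> panel ->
#' fit the requested models -> diagnostics, writing outputs and a run
#' manifest under `out_dir`.
#'
#' @param data_dir directory with the five input tables, or `NULL` to
#'   generate a synthetic cohort from `config`.
#' @param config a [generator_config()] (used when `data_dir` is `NULL`).
#' @param models subset of `c("m1", "m2", "m3", "m4")`.
#' @param reference `"all_nonadults"` or `"juveniles"`.
#' @param out_dir output directory.
#' @param sampler optional named list of per-model overrides, e.g.
#'   `list(m1 = list(chains = 2, iter = 1000))`.
#' @param seed seed for the model fits (data generation uses the config
#'   seed).
#' @param quiet suppress progress messages.
#' @return the manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(data_dir = NULL, config = generator_config(),
                         models = c("m1", "m2", "m3", "m4"),
                         reference = "all_nonadults",
                         out_dir = "igc_run", sampler = list(),
                         seed = 1, quiet = FALSE) {
  bad <- setdiff(models, c("m1", "m2", "m3", "m4"))
  if (length(bad)) stop("unknown model id(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(started = format(Sys.time()), seed = seed,
                   reference = reference, models = models, stages = list())

  if (is.null(data_dir)) {
    say("generating synthetic cohort ...")
    cohort <- generate_cohort(config, quiet = quiet)
    data_dir <- file.path(out_dir, "data")
    write_cohort(cohort, data_dir)
    manifest$stages$generate <- list(seed = config$seed, dir = data_dir)
  }
  dataset <- load_tables(data_dir, quiet = quiet)
  manifest$stages$load <- list(
    rows = lapply(dataset[c("roster", "scans", "agonism", "igc")], nrow))

  say("building panel ...")
  panel <- build_event_panel(dataset, reference = reference)
  data.table::fwrite(panel, file.path(out_dir, "panel.csv"))
  manifest$stages$panel <- list(rows = nrow(panel),
                                dropped = attr(panel, "n_dropped"),
                                path = file.path(out_dir, "panel.csv"))

  desc <- describe_dataset(panel)
  jsonlite::write_json(desc, file.path(out_dir, "descriptives.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$describe <- list(path = file.path(out_dir, "descriptives.json"))

  fits <- list()
  for (m in models) {
    say("fitting ", m, " ...")
    ov <- sampler[[m]] %||% list()
    fit <- fit_igc_model(panel, m, chains = ov$chains, iter = ov$iter,
                         seed = seed + match(m, c("m1", "m2", "m3", "m4")))
    fits[[m]] <- fit
    if (inherits(fit, "hurdle_fit")) {
      s <- rbind(cbind(hurdle = 1, summary(fit$h1)),
                 cbind(hurdle = 2, summary(fit$h2)))
      data.table::fwrite(hurdle_auc_table(fit), file.path(out_dir, "m4_auc.csv"))
    } else {
      s <- summary(fit)
      r2 <- rbind(
        data.frame(mode = "conditional",
                   t(attr(bayes_r2(fit, "conditional"), "summary"))),
        data.frame(mode = "marginal",
                   t(attr(bayes_r2(fit, "marginal"), "summary"))))
      data.table::fwrite(r2, file.path(out_dir, paste0(m, "_r2.csv")))
    }
    data.table::fwrite(s, file.path(out_dir, paste0(m, "_summary.csv")))
    manifest$stages[[m]] <- list(rows = if (inherits(fit, "hurdle_fit")) fit$n
                                 else fit$data_rows,
                                 seed = seed + match(m, c("m1", "m2", "m3", "m4")),
                                 path = file.path(out_dir, paste0(m, "_summary.csv")))
  }
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, panel = panel, fits = fits,
                 descriptives = desc))
}
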