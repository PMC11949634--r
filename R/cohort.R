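#' Configuration of the synthetic vervet cohort generator
#'
#' Builds and validates the generative settings for [generate_cohort()].
#' Defaults emulate the study system: three habituated groups followed for
#' five years (observation five days per week, 10 h per day, scan windows
#' of 10 min every 30 min), three seasonal birth cohorts of non-adults
#' (68 in total) each with a resident mother, roughly 3350 aggressive
#' intergroup conflicts and ~50,000 agonistic interactions overall, and
#' IGC outcome models whose generating coefficients are [default_truth()].
#'
#' @param n_groups number of groups (>= 2; IGC needs an opponent).
#' @param cohort_sizes matrix (groups x birth cohorts) of non-adult counts.
#' @param adult_females,adult_males adults per group.
#' @param start_day,n_days observation window: calendar days
#'   `start_day .. start_day + n_days - 1`; days with
#'   `((day - 1) %% 7) < 5` are observed. Day 1 opens the first birth-cohort
#'   year, so birth dates may precede `start_day`.
#' @param year_length days per year.
#' @param scan_interval,scan_window,obs_hours scan design (minutes between
#'   window starts, window length, daily observation hours).
#' @param igc_rate expected IGC events per group per observed day.
#' @param agonism_rate expected agonistic events per group per observed day.
#' @param draw_prob,unknown_prob probability that an agonistic outcome is a
#'   draw, or recorded as unknown.
#' @param latent_strength_sd SD of individual latent fighting strength
#'   (win probability is logistic in the strength difference).
#' @param grooming_kernel list: `rate` (expected grooming bouts per
#'   individual per scan), `mother_multiplier` (mother-offspring dyad
#'   weight factor), `sociality_sd` (log-normal SD of individual grooming
#'   gregariousness).
#' @param spatial_kernel list: `rate`, `nonadult_affinity` (weight factor
#'   for non-adult/non-adult proximity), `mother_affinity`, `sociality_sd`.
#' @param p_adult_participation per-adult probability of joining an IGC.
#' @param adult_level_probs distribution of adult participation levels 1-4.
#' @param opp_participants_mean mean number of opposing-group participants.
#' @param true_coefficients generating coefficients (see [default_truth()]).
#' @param random_effect_sds generating random-effect SDs per model.
#' @param missingness probability that a scan record is missed.
#' @param seed integer; fully determines the generated tables.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(
    n_groups = 3,
    cohort_sizes = matrix(c(8, 8, 8, 8, 8, 7, 8, 7, 6), nrow = 3, byrow = TRUE,
                          dimnames = list(NULL, NULL)),
    adult_females = c(14, 12, 10),
    adult_males = c(9, 8, 7),
    start_day = 366, n_days = 1825, year_length = 365,
    scan_interval = 30, scan_window = 10, obs_hours = 10,
    igc_rate = 0.86, agonism_rate = 13,
    draw_prob = 0.05, unknown_prob = 0.02,
    latent_strength_sd = 0.8,
    grooming_kernel = list(rate = 0.08, mother_multiplier = 8, sociality_sd = 0.5),
    spatial_kernel = list(rate = 0.6, nonadult_affinity = 3, mother_affinity = 4,
                          sociality_sd = 0.5),
    p_adult_participation = 0.19,
    adult_level_probs = c(0.55, 0.15, 0.22, 0.08),
    opp_participants_mean = 5,
    true_coefficients = default_truth(),
    random_effect_sds = default_truth()$re_sds,
    missingness = 0,
    seed = 1) {
  if (!is.numeric(n_groups) || n_groups < 2) stop_config("n_groups", "need >= 2 groups")
  cohort_sizes <- as.matrix(cohort_sizes)
  if (nrow(cohort_sizes) != n_groups) stop_config("cohort_sizes", "need one row per group")
  if (any(cohort_sizes < 1)) stop_config("cohort_sizes", "cohort sizes must be >= 1")
  if (length(adult_females) != n_groups) stop_config("adult_females", "need one count per group")
  if (length(adult_males) != n_groups) stop_config("adult_males", "need one count per group")
  if (any(adult_females < apply(cohort_sizes, 1, max)))
    stop_config("adult_females", "need at least as many adult females as the largest birth cohort (one infant per mother per season)")
  for (fld in c("igc_rate", "agonism_rate", "latent_strength_sd", "missingness"))
    if (get(fld) < 0) stop_config(fld, "must be non-negative")
  if (scan_window < 1 || scan_interval <= scan_window)
    stop_config("scan_interval", "must exceed scan_window >= 1")
  if (n_days < 1) stop_config("n_days", "must be positive")
  if (draw_prob + unknown_prob > 1) stop_config("draw_prob", "draw_prob + unknown_prob > 1")
  if (abs(sum(adult_level_probs) - 1) > 1e-8 || length(adult_level_probs) != 4)
    stop_config("adult_level_probs", "must be 4 probabilities summing to 1")
  if (missingness >= 1) stop_config("missingness", "must be < 1")
  if (!is.numeric(seed) || length(seed) != 1) stop_config("seed", "must be a single integer")
  fields <- names(formals(generator_config))
  structure(mget(fields), class = "generator_config")
}

obs_days <- function(cfg) {
  days <- seq(cfg$start_day, cfg$start_day + cfg$n_days - 1L)
  days[((days - 1L) %% 7L) < 5L]
}

day_to_year <- function(day, year_length = 365) as.integer(ceiling(day / year_length))

#' Generate the study population roster
#'
#' Adults (with per-group counts) plus non-adult birth cohorts; every
#' non-adult is assigned a distinct adult-female mother within its group
#' and birth cohort (one infant per mother per season). Individual latent
#' fighting strengths, grooming/spatial gregariousness and neophilia
#' scores are drawn here and carried as extra roster columns used by the
#' downstream generators (they are not written to roster.csv).
#'
#' @param cfg a [generator_config()].
#' @return data frame roster; attribute `"neophilia"` holds the neophilia
#'   table.
#' @export
generate_population <- function(cfg) {
  set.seed(cfg$seed)
  rows <- list()
  for (g in seq_len(cfg$n_groups)) {
    gid <- paste0("G", g)
    af <- sprintf("%s_AF%02d", gid, seq_len(cfg$adult_females[g]))
    am <- sprintf("%s_AM%02d", gid, seq_len(cfg$adult_males[g]))
    rows[[length(rows) + 1]] <- data.frame(
      id = c(af, am), sex = rep(c("F", "M"), c(length(af), length(am))),
      birth_date = -3000L, mother_id = NA_character_, group_id = gid,
      age_class = "adult", stringsAsFactors = FALSE)
    for (cy in seq_len(ncol(cfg$cohort_sizes))) {
      k <- cfg$cohort_sizes[g, cy]
      mothers <- sample(af, k)           # distinct mothers within a season
      births <- (cy - 1L) * cfg$year_length +
        sample(280:340, k, replace = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        id = sprintf("%s_C%d%02d", gid, cy, seq_len(k)),
        sex = sample(c("F", "M"), k, replace = TRUE),
        birth_date = as.integer(births), mother_id = mothers, group_id = gid,
        age_class = "nonadult", stringsAsFactors = FALSE)
    }
  }
  roster <- do.call(rbind, rows)
  n <- nrow(roster)
  # latent individual traits (generator internals)
  roster$strength <- rnorm(n, 0, cfg$latent_strength_sd) +
    ifelse(roster$age_class == "adult", 1.2, -0.8) +
    ifelse(roster$sex == "M" & roster$age_class == "adult", 0.5, 0)
  roster$groom_soc <- exp(rnorm(n, 0, cfg$grooming_kernel$sociality_sd))
  roster$spat_soc <- exp(rnorm(n, 0, cfg$spatial_kernel$sociality_sd))
  roster$neophilia <- round(rbeta(n, 2, 2), 4)
  attr(roster, "neophilia") <- data.frame(id = roster$id,
                                          neophilia = roster$neophilia,
                                          stringsAsFactors = FALSE)
  roster
}

# group membership eras: periods with constant member sets (changing at
# non-adult births inside the observation window)
membership_eras <- function(roster, cfg) {
  days <- obs_days(cfg)
  out <- list()
  for (gid in unique(roster$group_id)) {
    rg <- roster[roster$group_id == gid, ]
    cuts <- sort(unique(rg$birth_date[rg$birth_date > min(days)]))
    bounds <- c(min(days), cuts[cuts <= max(days)], max(days) + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      dd <- days[days >= bounds[b] & days < bounds[b + 1L]]
      if (!length(dd)) next
      members <- rg[rg$birth_date <= dd[1], ]
      out[[length(out) + 1]] <- list(group = gid, days = dd, members = members)
    }
  }
  out
}

#' Generate the scan-sampling table
#'
#' One record per (visible) group member per scan window. Grooming bouts
#' are drawn per window from a dyadic kernel (individual gregariousness
#' products, mother-offspring dyads up-weighted by
#' `grooming_kernel$mother_multiplier`); proximity (<= 3 m) pairs come
#' from a spatial kernel concentrated within the non-adult age class.
#'
#' @param roster from [generate_population()].
#' @param cfg the same [generator_config()].
#' @return data frame with columns `day`, `minute`, `group_id`,
#'   `individual_id`, `activity`, `partner_id`, `partner_role`,
#'   `neighbours` (`;`-separated ids).
#' @export
generate_scans <- function(roster, cfg) {
  set.seed(cfg$seed + 1L)
  W <- floor(cfg$obs_hours * 60 / cfg$scan_interval)
  minutes <- (seq_len(W) - 1L) * cfg$scan_interval
  act_base <- c(foraging = 0.42, resting = 0.25, moving = 0.2, playing = 0.13)
  eras <- membership_eras(roster, cfg)
  res <- vector("list", length(eras))
  for (e in seq_along(eras)) {
    er <- eras[[e]]
    mem <- er$members
    nm <- nrow(mem)
    wins <- data.table::CJ(day = er$days, minute = minutes, sorted = FALSE)
    nw <- nrow(wins)
    dy <- if (nm >= 2) t(utils::combn(nm, 2)) else matrix(numeric(0), 0, 2)
    mo_pair <- !is.na(mem$mother_id[dy[, 1]]) & mem$mother_id[dy[, 1]] == mem$id[dy[, 2]] |
      !is.na(mem$mother_id[dy[, 2]]) & mem$mother_id[dy[, 2]] == mem$id[dy[, 1]]
    both_na <- mem$age_class[dy[, 1]] == "nonadult" & mem$age_class[dy[, 2]] == "nonadult"
    gw <- mem$groom_soc[dy[, 1]] * mem$groom_soc[dy[, 2]] *
      ifelse(mo_pair, cfg$grooming_kernel$mother_multiplier, 1)
    sw <- mem$spat_soc[dy[, 1]] * mem$spat_soc[dy[, 2]] *
      ifelse(both_na, cfg$spatial_kernel$nonadult_affinity, 1) *
      ifelse(mo_pair, cfg$spatial_kernel$mother_affinity, 1)

    # grooming bouts
    nb <- rpois(nw, nm * cfg$grooming_kernel$rate / 2)
    B <- sum(nb)
    bouts <- NULL
    if (B > 0 && nrow(dy) > 0) {
      bw <- rep.int(seq_len(nw), nb)
      bd <- sample.int(nrow(dy), B, replace = TRUE, prob = gw)
      i1 <- dy[bd, 1]; i2 <- dy[bd, 2]
      # groomer: mothers groom offspring more often than the reverse
      mo1 <- !is.na(mem$mother_id[i2]) & mem$mother_id[i2] == mem$id[i1]
      mo2 <- !is.na(mem$mother_id[i1]) & mem$mother_id[i1] == mem$id[i2]
      p1 <- ifelse(mo1, 0.7, ifelse(mo2, 0.3, 0.5))
      g1 <- runif(B) < p1
      groomer <- ifelse(g1, i1, i2); groomee <- ifelse(g1, i2, i1)
      # at most one bout per individual per window
      long <- data.table::data.table(win = rep(bw, 2), ind = c(groomer, groomee),
                                     bout = rep(seq_len(B), 2))
      long[, dup := duplicated(paste(win, ind))]
      bad <- unique(long$bout[long$dup])
      keep <- setdiff(seq_len(B), bad)
      if (length(keep))
        bouts <- data.table::data.table(win = bw[keep], groomer = groomer[keep],
                                        groomee = groomee[keep])
    }

    # proximity pairs
    np <- rpois(nw, nm * cfg$spatial_kernel$rate / 2)
    P <- sum(np)
    nbrs <- NULL
    if (P > 0 && nrow(dy) > 0) {
      pw <- rep.int(seq_len(nw), np)
      pd <- sample.int(nrow(dy), P, replace = TRUE, prob = sw)
      nbrs <- data.table::data.table(
        win = c(pw, pw), ind = c(dy[pd, 1], dy[pd, 2]),
        nb = c(dy[pd, 2], dy[pd, 1]))
      nbrs <- nbrs[, .(neighbours = paste(unique(mem$id[nb]), collapse = ";")),
                   by = .(win, ind)]
    }

    rows <- data.table::CJ(win = seq_len(nw), ind = seq_len(nm), sorted = FALSE)
    rows[, `:=`(day = wins$day[win], minute = wins$minute[win],
                group_id = er$group, individual_id = mem$id[ind])]
    rows[, `:=`(activity = sample(names(act_base), .N, replace = TRUE, prob = act_base),
                partner_id = NA_character_, partner_role = "none")]
    if (!is.null(bouts)) {
      bl <- data.table::rbindlist(list(
        bouts[, .(win, ind = groomer, partner = groomee, role = "groomer")],
        bouts[, .(win, ind = groomee, partner = groomer, role = "groomee")]))
      rows[bl, on = c("win", "ind"),
           `:=`(activity = "grooming", partner_id = mem$id[i.partner],
                partner_role = i.role)]
    }
    if (!is.null(nbrs)) {
      rows[nbrs, on = c("win", "ind"), neighbours := i.neighbours]
    } else rows[, neighbours := NA_character_]
    if (cfg$missingness > 0)
      rows <- rows[runif(.N) >= cfg$missingness]
    res[[e]] <- rows[, .(day, minute, group_id, individual_id, activity,
                         partner_id, partner_role, neighbours)]
  }
  out <- data.table::rbindlist(res)
  data.table::setorder(out, group_id, day, minute, individual_id)
  as.data.frame(out)
}

#' Generate the agonistic interaction table
#'
#' Dyadic events among same-group members present on the event day; the
#' aggressor wins with probability `plogis(strength_aggressor -
#' strength_victim)`; configured fractions of draws and unknown outcomes.
#'
#' @inheritParams generate_scans
#' @export
generate_agonism <- function(roster, cfg) {
  set.seed(cfg$seed + 2L)
  if (any(!is.finite(roster$strength)))
    stop("latent strengths undefined for some individuals", call. = FALSE)
  eras <- membership_eras(roster, cfg)
  res <- list()
  for (er in eras) {
    nm <- nrow(er$members)
    if (nm < 2) next
    n_ev <- rpois(1, length(er$days) * cfg$agonism_rate)
    if (n_ev == 0) next
    d <- sample(er$days, n_ev, replace = TRUE)
    i <- sample.int(nm, n_ev, replace = TRUE)
    j <- sample.int(nm - 1L, n_ev, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    pwin <- plogis(er$members$strength[i] - er$members$strength[j])
    u <- runif(n_ev)
    outcome <- ifelse(u < cfg$unknown_prob, "unknown",
               ifelse(u < cfg$unknown_prob + cfg$draw_prob, "draw",
               ifelse(runif(n_ev) < pwin, "win", "loss")))
    res[[length(res) + 1]] <- data.frame(
      date = d, aggressor_id = er$members$id[i], victim_id = er$members$id[j],
      outcome = outcome, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$date), ]
  rownames(out) <- NULL
  out
}

# standardized Elo rank lookup table for (group, date) combinations
rank_lookup <- function(elo_list, roster, needs) {
  needs <- unique(needs[, c("group_id", "date")])
  out <- list()
  for (r in seq_len(nrow(needs))) {
    g <- needs$group_id[r]; d <- needs$date[r]
    s <- elo_list[[g]]
    present <- s$ids[s$entry_dates[s$ids] <= d]
    z <- ranks_on_date(s, present, d)
    out[[r]] <- data.frame(group_id = g, date = d, id = present,
                           rank = unname(z), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate the IGC event table from pipeline-derived covariates
#'
#' For each event: the opposing group is sampled, adult participants (and
#' their aggression levels) drawn, then non-adult participation from the
#' Model-1 logistic with the configured true coefficients and random
#' effects; participant aggression levels from the Model-2 cumulative
#' ordinal generative model (maternal level entering through the monotonic
#' transform); within-IGC grooming receipt from the grooming model and the
#' groomer-is-mother outcome from the maternal hurdle. Covariates (age,
#' rank, centralities) are the ones computed by the real pipeline stages
#' on the synthetic streams.
#'
#' @param roster from [generate_population()].
#' @param centrality year-matched EC table from [centrality_table()].
#' @param elo_list named list (by group) of [run_elo()] series.
#' @param cfg the [generator_config()].
#' @return list: `igc` (event table), `frame` (the internal truth frame,
#'   one row per non-adult x event, with outcomes), `re` (drawn random
#'   intercepts).
#' @export
generate_igc <- function(roster, centrality, elo_list, cfg) {
  set.seed(cfg$seed + 3L)
  tc <- cfg$true_coefficients
  sds <- cfg$random_effect_sds
  groups <- sort(unique(roster$group_id))
  days <- obs_days(cfg)

  # events
  ev <- list()
  for (g in groups) {
    n_ev <- rpois(1, length(days) * cfg$igc_rate)
    d <- sort(sample(days, n_ev, replace = TRUE))
    opp <- sample(setdiff(groups, g), n_ev, replace = TRUE)
    ev[[g]] <- data.frame(date = d, focal_group = g, opposing_group = opp,
                          stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$date, ev$focal_group), ]
  ev$event_id <- sprintf("IGC%05d", seq_len(nrow(ev)))
  rownames(ev) <- NULL
  nE <- nrow(ev)

  sizes_on <- function(g, d) sum(roster$group_id == g & roster$birth_date <= d)
  ev$focal_group_size <- mapply(sizes_on, ev$focal_group, ev$date)
  ev$opposing_group_size <- mapply(sizes_on, ev$opposing_group, ev$date)
  ev$n_opposing_participants <- 1L + rpois(nE, cfg$opp_participants_mean - 1)

  # adult participation (mothers' participation feeds the non-adult models)
  adult_part <- vector("list", nE)
  for (i in seq_len(nE)) {
    ad <- roster[roster$group_id == ev$focal_group[i] & roster$age_class == "adult", "id"]
    take <- ad[runif(length(ad)) < cfg$p_adult_participation]
    lv <- sample(1:4, length(take), replace = TRUE, prob = cfg$adult_level_probs)
    adult_part[[i]] <- setNames(lv, take)
  }
  ev$n_focal_participants <- vapply(adult_part, length, integer(1))

  # eligibility frame: non-adults of the focal group born by the event date
  na_ros <- roster[roster$age_class == "nonadult", ]
  fr <- do.call(rbind, lapply(seq_len(nE), function(i) {
    el <- na_ros[na_ros$group_id == ev$focal_group[i] &
                   na_ros$birth_date <= ev$date[i], ]
    if (!nrow(el)) return(NULL)
    data.frame(event_id = ev$event_id[i], date = ev$date[i],
               focal_group = ev$focal_group[i], opp_group = ev$opposing_group[i],
               id = el$id, sex = el$sex, mother_id = el$mother_id,
               birth_date = el$birth_date, neophilia = el$neophilia,
               stringsAsFactors = FALSE)
  }))
  fr$age <- fr$date - fr$birth_date
  fr$sexM <- as.integer(fr$sex == "M")
  fr$year <- day_to_year(fr$date, cfg$year_length)

  # pipeline covariates
  fr <- merge(fr, centrality[, c("id", "year", "grooming_ec", "spatial_ec")],
              by = c("id", "year"), all.x = TRUE, sort = FALSE)
  fr$grooming_ec[is.na(fr$grooming_ec)] <- 0
  fr$spatial_ec[is.na(fr$spatial_ec)] <- 0
  rl <- rank_lookup(elo_list, roster,
                    data.frame(group_id = fr$focal_group, date = fr$date))
  fr <- merge(fr, rl, by.x = c("focal_group", "date", "id"),
              by.y = c("group_id", "date", "id"), all.x = TRUE, sort = FALSE)
  eix <- match(fr$event_id, ev$event_id)
  fr$n_focal <- ev$n_focal_participants[eix]
  fr$n_opp <- ev$n_opposing_participants[eix]
  fr$focal_size <- ev$focal_group_size[eix]
  fr$opp_size <- ev$opposing_group_size[eix]
  fr$mother_part <- as.integer(mapply(
    function(i, m) m %in% names(adult_part[[i]]), eix, fr$mother_id))
  fr$mat_level <- as.integer(mapply(
    function(i, m) if (m %in% names(adult_part[[i]])) adult_part[[i]][[m]] else 0L,
    eix, fr$mother_id))

  # random intercepts
  na_ids <- sort(unique(na_ros$id))
  re <- list(
    m1 = list(id = setNames(rnorm(length(na_ids), 0, sds$m1[["id"]]), na_ids),
              focal = setNames(rnorm(length(groups), 0, sds$m1[["focal_group"]]), groups),
              opp = setNames(rnorm(length(groups), 0, sds$m1[["opp_group"]]), groups)),
    m2 = list(id = setNames(rnorm(length(na_ids), 0, sds$m2[["id"]]), na_ids),
              focal = setNames(rnorm(length(groups), 0, sds$m2[["focal_group"]]), groups),
              opp = setNames(rnorm(length(groups), 0, sds$m2[["opp_group"]]), groups)),
    m3 = list(id = setNames(rnorm(length(na_ids), 0, sds$m3[["id"]]), na_ids),
              focal = setNames(rnorm(length(groups), 0, sds$m3[["focal_group"]]), groups)),
    m4b = list(id = setNames(rnorm(length(na_ids), 0, sds$m4[["id"]]), na_ids),
               mother = setNames(rnorm(nrow(roster), 0, sds$m4[["mother"]]), roster$id),
               focal = setNames(rnorm(length(groups), 0, sds$m4[["focal_group"]]), groups)))

  # ---- Model 1: participation ----
  fr <- scale_continuous(fr, c("age", "rank", "neophilia", "grooming_ec",
                               "spatial_ec", "n_focal", "n_opp", "focal_size",
                               "opp_size"))
  b1 <- tc$m1
  eta1 <- b1[["(Intercept)"]] + b1[["age_z"]] * fr$age_z +
    b1[["sexM"]] * fr$sexM + b1[["rank_z"]] * fr$rank_z +
    b1[["neophilia_z"]] * fr$neophilia_z +
    b1[["grooming_ec_z"]] * fr$grooming_ec_z +
    b1[["spatial_ec_z"]] * fr$spatial_ec_z +
    b1[["mother_part"]] * fr$mother_part +
    b1[["n_focal_z"]] * fr$n_focal_z + b1[["n_opp_z"]] * fr$n_opp_z +
    b1[["focal_size_z"]] * fr$focal_size_z + b1[["opp_size_z"]] * fr$opp_size_z +
    b1[["n_focal_z:n_opp_z"]] * fr$n_focal_z * fr$n_opp_z +
    re$m1$id[fr$id] + re$m1$focal[fr$focal_group] + re$m1$opp[fr$opp_group]
  fr$participation <- rbinom(nrow(fr), 1, plogis(eta1))

  # ---- Model 2: aggression level of participants ----
  fr$level <- 0L
  part <- which(fr$participation == 1)
  if (length(part)) {
    sub <- scale_continuous(fr[part, c("age", "rank", "neophilia",
                                       "grooming_ec", "spatial_ec", "n_focal",
                                       "n_opp", "focal_size")],
                            c("age", "rank", "neophilia", "grooming_ec",
                              "spatial_ec", "n_focal", "n_opp", "focal_size"))
    b2 <- tc$m2$beta
    eta2 <- b2[["age_z"]] * sub$age_z + b2[["sexM"]] * fr$sexM[part] +
      b2[["rank_z"]] * sub$rank_z + b2[["neophilia_z"]] * sub$neophilia_z +
      b2[["grooming_ec_z"]] * sub$grooming_ec_z +
      b2[["spatial_ec_z"]] * sub$spatial_ec_z +
      b2[["n_focal_z"]] * sub$n_focal_z + b2[["n_opp_z"]] * sub$n_opp_z +
      b2[["focal_size_z"]] * sub$focal_size_z +
      b2[["n_focal_z:n_opp_z"]] * sub$n_focal_z * sub$n_opp_z +
      tc$m2$b_mo * monotonic_transform(fr$mat_level[part], tc$m2$zeta) +
      re$m2$id[fr$id[part]] + re$m2$focal[fr$focal_group[part]] +
      re$m2$opp[fr$opp_group[part]]
    fr$level[part] <- draw_ordinal(eta2, tc$m2$tau)
  }

  # ---- grooming receipt (Model 3 structure, all non-adults) ----
  b3 <- tc$m3
  eta3 <- b3[["(Intercept)"]] + b3[["participation"]] * fr$participation +
    b3[["sexM"]] * fr$sexM + b3[["age_z"]] * fr$age_z +
    b3[["rank_z"]] * fr$rank_z + b3[["neophilia_z"]] * fr$neophilia_z +
    b3[["grooming_ec_z"]] * fr$grooming_ec_z +
    b3[["spatial_ec_z"]] * fr$spatial_ec_z +
    b3[["focal_size_z"]] * fr$focal_size_z +
    b3[["n_focal_z"]] * fr$n_focal_z + b3[["n_opp_z"]] * fr$n_opp_z +
    re$m3$id[fr$id] + re$m3$focal[fr$focal_group]
  fr$groomed <- rbinom(nrow(fr), 1, plogis(eta3))

  # ---- groomer-is-mother hurdle ----
  fr$groomed_by_mother <- NA_integer_
  gsel <- which(fr$groomed == 1)
  if (length(gsel)) {
    sub <- scale_continuous(fr[gsel, c("age", "rank"), drop = FALSE],
                            c("age", "rank"))
    b4 <- tc$m4b
    eta4 <- b4[["(Intercept)"]] + b4[["sexM"]] * fr$sexM[gsel] +
      b4[["age_z"]] * sub$age_z + b4[["rank_z"]] * sub$rank_z +
      re$m4b$id[fr$id[gsel]] + re$m4b$mother[fr$mother_id[gsel]] +
      re$m4b$focal[fr$focal_group[gsel]]
    fr$groomed_by_mother[gsel] <- rbinom(length(gsel), 1, plogis(eta4))
  }

  # groomer identities
  fr$groomer <- NA_character_
  if (length(gsel)) {
    fr$groomer[gsel] <- vapply(gsel, function(r) {
      if (fr$groomed_by_mother[r] == 1) return(fr$mother_id[r])
      af <- roster$id[roster$group_id == fr$focal_group[r] &
                        roster$age_class == "adult" & roster$sex == "F"]
      sample(setdiff(af, fr$mother_id[r]), 1)
    }, character(1))
  }

  # serialize participants and grooming per event
  fr_by_ev <- split(seq_len(nrow(fr)), fr$event_id)
  ev$participants <- vapply(seq_len(nE), function(i) {
    ad <- adult_part[[i]]
    rws <- fr_by_ev[[ev$event_id[i]]]
    nap <- rws[fr$participation[rws] == 1]
    paste(c(sprintf("%s:%d", names(ad), ad),
            sprintf("%s:%d", fr$id[nap], fr$level[nap])), collapse = ";")
  }, character(1))
  ev$igc_grooming <- vapply(seq_len(nE), function(i) {
    rws <- fr_by_ev[[ev$event_id[i]]]
    gr <- rws[fr$groomed[rws] == 1]
    if (!length(gr)) return("")
    paste(sprintf("%s>%s", fr$groomer[gr], fr$id[gr]), collapse = ";")
  }, character(1))

  list(igc = ev, frame = fr, re = re)
}

#' Generate a full synthetic cohort
#'
#' Orchestrates [generate_population()], [generate_scans()],
#' [generate_agonism()], the pipeline covariate stages
#' ([centrality_table()], [run_elo()]) and [generate_igc()], so the IGC
#' outcome covariates are the ones the real pipeline computes from the
#' synthetic observation streams.
#'
#' @param cfg a [generator_config()].
#' @param quiet suppress progress messages.
#' @return list of class `igc_cohort` with the five tables (`roster`,
#'   `neophilia`, `scans`, `agonism`, `igc`), the truth bundle (`truth`:
#'   generating coefficients, random intercepts, config) and the internal
#'   outcome `frame`.
#' @export
generate_cohort <- function(cfg = generator_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  say("generating population ...")
  roster <- generate_population(cfg)
  say("generating scans ...")
  scans <- generate_scans(roster, cfg)
  say("generating agonism ...")
  agonism <- generate_agonism(roster, cfg)
  say("social networks / centrality ...")
  yrs <- sort(unique(day_to_year(obs_days(cfg), cfg$year_length)))
  centrality <- centrality_table(scans, roster, yrs, year_length = cfg$year_length)
  say("Elo ratings ...")
  elo_list <- list()
  for (g in sort(unique(roster$group_id))) {
    rg <- roster[roster$group_id == g, ]
    evg <- agonism[agonism$aggressor_id %in% rg$id, ]
    elo_list[[g]] <- run_elo(evg, ids = rg$id,
                             entry_dates = setNames(pmax(rg$birth_date, 0L), rg$id))
  }
  say("IGC events and outcomes ...")
  igc <- generate_igc(roster, centrality, elo_list, cfg)
  structure(list(
    roster = roster[, c("id", "sex", "birth_date", "mother_id", "group_id", "age_class")],
    neophilia = attr(roster, "neophilia"),
    scans = scans, agonism = agonism, igc = igc$igc,
    frame = igc$frame,
    centrality = centrality, elo = elo_list,
    truth = list(coefficients = cfg$true_coefficients,
                 random_effect_sds = cfg$random_effect_sds,
                 random_intercepts = igc$re,
                 strengths = setNames(roster$strength, roster$id),
                 seed = cfg$seed, config = cfg)), class = "igc_cohort")
}

#' Write the five cohort tables plus the ground-truth bundle
#'
#' UTF-8 comma-delimited files with header rows (`roster.csv`,
#' `neophilia.csv`, `scans.csv`, `agonism.csv`, `igc.csv`) and
#' `truth.json` (generating parameters).
#'
#' @param cohort an `igc_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(cohort$roster, file.path(dir, "roster.csv"))
  data.table::fwrite(cohort$neophilia, file.path(dir, "neophilia.csv"))
  data.table::fwrite(cohort$scans, file.path(dir, "scans.csv"))
  data.table::fwrite(cohort$agonism, file.path(dir, "agonism.csv"))
  data.table::fwrite(cohort$igc, file.path(dir, "igc.csv"))
  tr <- cohort$truth
  tr$config <- tr$config[setdiff(names(tr$config), c("true_coefficients",
                                                     "random_effect_sds"))]
  # JSON arrays drop R names; serialize named vectors as objects instead
  named_to_list <- function(x) {
    if (is.list(x)) lapply(x, named_to_list)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(named_to_list(tr), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
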