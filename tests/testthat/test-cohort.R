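test_that("population generation matches the configuration and is deterministic", {
  cfg <- tiny_config(seed = 5)
  ros <- generate_population(cfg)
  expect_equal(sum(ros$age_class == "nonadult"), sum(cfg$cohort_sizes))
  expect_equal(length(unique(ros$group_id)), 3)
  # every non-adult has a same-group adult-female mother
  na <- ros[ros$age_class == "nonadult", ]
  expect_true(all(!is.na(na$mother_id)))
  mg <- ros$group_id[match(na$mother_id, ros$id)]
  expect_equal(mg, na$group_id)
  # one infant per mother per birth season
  season <- vervetIGC:::day_to_year(na$birth_date + 85, cfg$year_length)
  expect_false(any(duplicated(paste(na$mother_id, season))))
  # same seed, same roster; different seed differs
  expect_identical(ros, generate_population(tiny_config(seed = 5)))
  expect_false(identical(ros$id[1:5] == ros$id[1:5],
                         identical(ros, generate_population(tiny_config(seed = 6)))))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(tiny_config(igc_rate = -1), "igc_rate")
  expect_error(generator_config(cohort_sizes = matrix(0, 3, 3)), "cohort_sizes")
  expect_error(tiny_config(scan_interval = 5, scan_window = 10), "scan_interval")
  expect_error(generator_config(n_groups = 1), "n_groups")
  expect_error(tiny_config(draw_prob = 0.9, unknown_prob = 0.2), "draw_prob")
})

test_that("scan windows follow the 10-min-window-every-30-min design", {
  # 10 h of observation at 30-min intervals: 20 windows per observed day
  cfg <- tiny_config(n_days = 7)
  ros <- generate_population(cfg)
  sc <- generate_scans(ros, cfg)
  per_day <- tapply(sc$minute, paste(sc$group_id, sc$day),
                    function(m) length(unique(m)))
  expect_true(all(per_day == 20))
  expect_true(all(sc$minute %% 30 == 0))
  # one record per member per window (no missingness by default)
  n_members <- table(ros$group_id)
  cnt <- table(sc$group_id, sc$day, sc$minute)
  for (g in names(n_members)) {
    born <- sum(ros$group_id == g & ros$birth_date <= min(sc$day))
    expect_true(all(cnt[g, , ] %in% c(0, born:max(n_members))))
  }
  expect_true(all(sc$activity %in% c("foraging", "resting", "grooming",
                                     "moving", "playing")))
})

test_that("the grooming kernel concentrates bouts on mother-offspring dyads", {
  base <- tiny_config(seed = 9, n_days = 60)
  ros <- generate_population(base)
  mother_share <- function(mult) {
    cfg <- tiny_config(seed = 9, n_days = 60,
                       grooming_kernel = list(rate = 0.2, mother_multiplier = mult,
                                              sociality_sd = 0.5))
    sc <- generate_scans(ros, cfg)
    g <- sc[sc$partner_role == "groomer", ]
    nonad <- ros$id[ros$age_class == "nonadult"]
    g <- g[g$individual_id %in% nonad | g$partner_id %in% nonad, ]
    mom1 <- ros$mother_id[match(g$partner_id, ros$id)] == g$individual_id
    mom2 <- ros$mother_id[match(g$individual_id, ros$id)] == g$partner_id
    mean((!is.na(mom1) & mom1) | (!is.na(mom2) & mom2))
  }
  s1 <- mother_share(1)
  s10 <- mother_share(10)
  expect_gt(s10, 3 * s1)
  # with multiplier 10, mothers are the modal grooming partner of non-adults
  expect_gt(s10, 0.4)
})

test_that("agonistic outcomes follow the logistic strength model", {
  cfg <- tiny_config(seed = 2, n_days = 300, agonism_rate = 10,
                     draw_prob = 0, unknown_prob = 0)
  ros <- generate_population(cfg)
  # equal strengths: aggressor win rate converges to 0.5
  ros0 <- ros; ros0$strength <- 0
  ag0 <- generate_agonism(ros0, cfg)
  expect_lt(abs(mean(ag0$outcome == "win") - 0.5), 0.02)
  # strength difference +4: win rate ~ plogis(4) = 0.982
  ros4 <- ros
  ros4$strength <- ifelse(ros4$sex == "F", 4, 0)
  ag4 <- generate_agonism(ros4, cfg)
  ff <- ros4$strength[match(ag4$aggressor_id, ros4$id)] == 4 &
    ros4$strength[match(ag4$victim_id, ros4$id)] == 0
  expect_lt(abs(mean(ag4$outcome[ff] == "win") - plogis(4)), 0.012)
  # all draws when draw_prob = 1
  cfgd <- tiny_config(seed = 2, n_days = 30, draw_prob = 1, unknown_prob = 0)
  expect_true(all(generate_agonism(ros, cfgd)$outcome == "draw"))
})

test_that("a null participation model yields a 50% participation rate", {
  tc <- default_truth()
  tc$m1[] <- 0
  sds0 <- lapply(default_truth()$re_sds, function(x) { x[] <- 1e-8; x })
  cfg <- tiny_config(seed = 7, n_days = 150, true_coefficients = tc,
                     random_effect_sds = sds0)
  co <- generate_cohort(cfg, quiet = TRUE)
  expect_lt(abs(mean(co$frame$participation) - 0.5), 0.03)
})

test_that("a strong age effect makes participation rise across age quintiles", {
  tc <- default_truth()
  tc$m1["age_z"] <- 2
  cfg <- tiny_config(seed = 8, n_days = 250, true_coefficients = tc)
  co <- generate_cohort(cfg, quiet = TRUE)
  fr <- co$frame
  q <- cut(fr$age, quantile(fr$age, 0:5 / 5), include.lowest = TRUE)
  rate <- tapply(fr$participation, q, mean)
  expect_true(all(diff(rate) > 0))
})

test_that("a degenerate grooming intercept produces zero grooming records", {
  tc <- default_truth()
  tc$m3["(Intercept)"] <- -40
  cfg <- tiny_config(seed = 3, n_days = 100, true_coefficients = tc)
  co <- generate_cohort(cfg, quiet = TRUE)
  expect_equal(sum(co$frame$groomed), 0)
  expect_true(all(co$igc$igc_grooming == ""))
})

test_that("generated tables use only the legal categorical alphabets and emit the truth", {
  co <- tiny_cohort()
  expect_true(all(co$agonism$outcome %in% c("win", "loss", "draw", "unknown")))
  expect_true(all(co$frame$level %in% 0:4))
  expect_true(all(co$frame$level[co$frame$participation == 1] %in% 1:4))
  expect_true(all(co$frame$mat_level %in% 0:4))
  expect_named(co$truth$coefficients, c("m1", "m2", "m3", "m4b", "re_sds"))
  expect_true(all(c("id", "focal", "opp") %in% names(co$truth$random_intercepts$m1)))
})

test_that("cohort generation is byte-identical under the seed", {
  cfg <- tiny_config(seed = 4, n_days = 40)
  c1 <- generate_cohort(cfg, quiet = TRUE)
  c2 <- generate_cohort(cfg, quiet = TRUE)
  for (tb in c("roster", "scans", "agonism", "igc", "neophilia"))
    expect_identical(c1[[tb]], c2[[tb]])
})
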