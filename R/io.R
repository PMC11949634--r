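ACTIVITIES <- c("foraging", "resting", "grooming", "moving", "playing")
OUTCOMES <- c("win", "loss", "draw", "unknown")

#' Aggression level labels of the 0-4 participation scale
#'
#' 0 non-participant, 1 non-aggressive (at the site), 2 stationary (facial
#' or vocal threats), 3 active (lunge/charge/chase), 4 physical
#' (slap/grab/bite).
#' @export
aggression_levels <- function() {
  c("0" = "non-participant", "1" = "non-aggressive", "2" = "stationary",
    "3" = "active", "4" = "physical")
}

io_error <- function(file, row, msg) {
  stop(sprintf("%s, line %d: %s", file, row + 1L, msg), call. = FALSE)
}

# "id:level;id:level" -> named integer vector
parse_participants <- function(s) {
  if (is.na(s) || !nzchar(s)) return(setNames(integer(0), character(0)))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  setNames(as.integer(vapply(parts, `[[`, "", 2)),
           vapply(parts, `[[`, "", 1))
}

# "groomer>groomee;..." -> 2-column character matrix
parse_grooming <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(matrix(character(0), 0, 2, dimnames = list(NULL, c("groomer", "groomee"))))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ">", fixed = TRUE)
  m <- cbind(groomer = vapply(parts, `[[`, "", 1),
             groomee = vapply(parts, `[[`, "", 2))
  m
}

#' Load and validate the five observation tables
#'
#' Reads `roster.csv`, `neophilia.csv`, `scans.csv`, `agonism.csv` and
#' `igc.csv` from a directory, checks the schema invariants (categorical
#' alphabets, grooming records with partners, no self-partners, aggressor
#' distinct from victim, participation levels 1-4, focal group distinct
#' from opposing group) and referential integrity against the roster, and
#' returns a typed dataset bundle.
#'
#' @param dir directory containing the five CSV files.
#' @param quiet suppress the row-count summary message.
#' @return list of class `igc_dataset`.
#' @export
load_tables <- function(dir, quiet = FALSE) {
  need <- c("roster.csv", "neophilia.csv", "scans.csv", "agonism.csv", "igc.csv")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  rd <- function(f) as.data.frame(data.table::fread(file.path(dir, f),
                                                    na.strings = c("NA", "")))
  roster <- rd("roster.csv"); neophilia <- rd("neophilia.csv")
  scans <- rd("scans.csv"); agonism <- rd("agonism.csv"); igc <- rd("igc.csv")

  # roster
  for (cl in c("id", "sex", "birth_date", "mother_id", "group_id", "age_class"))
    if (!cl %in% names(roster)) io_error("roster.csv", 0, paste("missing column", cl))
  if (anyDuplicated(roster$id))
    io_error("roster.csv", anyDuplicated(roster$id), "duplicate id")
  ids <- roster$id
  bad <- which(!is.na(roster$mother_id) &
                 roster$group_id != roster$group_id[match(roster$mother_id, ids)])
  if (length(bad)) io_error("roster.csv", bad[1], "mother in a different group")
  bad <- which(roster$age_class == "nonadult" & is.na(roster$mother_id))
  if (length(bad)) io_error("roster.csv", bad[1], "non-adult without a mother")

  # neophilia
  if (!all(c("id", "neophilia") %in% names(neophilia)))
    io_error("neophilia.csv", 0, "needs columns id, neophilia")
  bad <- which(!is.na(neophilia$neophilia) &
                 (neophilia$neophilia < 0 | neophilia$neophilia > 1))
  if (length(bad)) io_error("neophilia.csv", bad[1], "neophilia outside [0, 1]")

  # scans
  bad <- which(!scans$activity %in% ACTIVITIES)
  if (length(bad))
    io_error("scans.csv", bad[1], sprintf("unknown activity '%s'", scans$activity[bad[1]]))
  bad <- which(scans$activity == "grooming" &
                 (is.na(scans$partner_id) | !scans$partner_role %in% c("groomer", "groomee")))
  if (length(bad)) io_error("scans.csv", bad[1], "grooming record without partner/role")
  bad <- which(!is.na(scans$partner_id) & scans$partner_id == scans$individual_id)
  if (length(bad)) io_error("scans.csv", bad[1], "individual recorded as own partner")
  bad <- which(!scans$individual_id %in% ids)
  if (length(bad)) io_error("scans.csv", bad[1],
                            sprintf("unknown id '%s'", scans$individual_id[bad[1]]))

  # agonism
  bad <- which(!agonism$outcome %in% OUTCOMES)
  if (length(bad)) io_error("agonism.csv", bad[1],
                            sprintf("unknown outcome '%s'", agonism$outcome[bad[1]]))
  bad <- which(agonism$aggressor_id == agonism$victim_id)
  if (length(bad)) io_error("agonism.csv", bad[1], "aggressor equals victim")
  bad <- which(!agonism$aggressor_id %in% ids | !agonism$victim_id %in% ids)
  if (length(bad)) io_error("agonism.csv", bad[1], "unknown id in agonistic event")

  # igc
  bad <- which(igc$focal_group == igc$opposing_group)
  if (length(bad)) io_error("igc.csv", bad[1], "focal group equals opposing group")
  group_of <- setNames(roster$group_id, ids)
  for (r in seq_len(nrow(igc))) {
    pm <- parse_participants(igc$participants[r])
    if (length(pm)) {
      if (any(is.na(pm) | pm < 1 | pm > 4))
        io_error("igc.csv", r, "participation level outside 1..4")
      unk <- setdiff(names(pm), ids)
      if (length(unk)) io_error("igc.csv", r, sprintf("unknown participant '%s'", unk[1]))
    }
    gm <- parse_grooming(igc$igc_grooming[r])
    if (nrow(gm)) {
      unk <- setdiff(c(gm), ids)
      if (length(unk)) io_error("igc.csv", r, sprintf("unknown groomer/groomee '%s'", unk[1]))
      out_grp <- which(group_of[gm[, "groomee"]] != igc$focal_group[r])
      if (length(out_grp))
        io_error("igc.csv", r, "grooming dyad outside the focal group")
    }
  }

  if (!quiet)
    message(sprintf(
      "loaded %d roster rows, %d scans, %d agonistic events, %d IGC events",
      nrow(roster), nrow(scans), nrow(agonism), nrow(igc)))
  structure(list(roster = roster, neophilia = neophilia, scans = scans,
                 agonism = agonism, igc = igc), class = "igc_dataset")
}

# covariate stages computed from a dataset bundle
covariate_stages <- function(dataset, year_length = 365, elo_params = list()) {
  days <- c(dataset$scans$day, dataset$agonism$date, dataset$igc$date)
  yrs <- sort(unique(day_to_year(days, year_length)))
  centrality <- centrality_table(dataset$scans, dataset$roster, yrs,
                                 year_length = year_length)
  elo_list <- list()
  for (g in sort(unique(dataset$roster$group_id))) {
    rg <- dataset$roster[dataset$roster$group_id == g, ]
    evg <- dataset$agonism[dataset$agonism$aggressor_id %in% rg$id, ]
    elo_list[[g]] <- do.call(run_elo, c(
      list(events = evg, ids = rg$id,
           entry_dates = setNames(pmax(rg$birth_date, 0L), rg$id)),
      elo_params))
  }
  list(centrality = centrality, elo = elo_list)
}

#' Build the model-ready event panel
#'
#' One row per non-adult per IGC of its group, with the covariates the
#' models use: age (days), sex, standardized Elo rank on the event date,
#' neophilia, year-matched grooming and spatial eigenvector centrality,
#' maternal participation (0/1) and maternal aggression level (0-4),
#' participant counts and group sizes, plus the response fields
#' (participation 0/1, aggression level 0-4, groomed 0/1,
#' groomed-by-mother 0/1 where defined). Continuous predictors are scaled
#' and mean-centred into `_z` companions.
#'
#' Rows whose individual has no network coverage for the event year are
#' dropped and counted in the `n_dropped` attribute; missing neophilia
#' scores are imputed at the population mean and flagged
#' (`neophilia_imputed`).
#'
#' @param dataset an `igc_dataset` from [load_tables()].
#' @param reference `"all_nonadults"` or `"juveniles"` (independent
#'   juveniles only: age at the event at least `weaning_days`).
#' @param stages optional precomputed list with `centrality` and `elo`
#'   (from the internal covariate stages); computed from the bundle when
#'   omitted.
#' @param weaning_days independence threshold for the juvenile subset.
#' @param year_length days per year.
#' @return data frame panel; attributes `n_dropped` and `reference`.
#' @export
build_event_panel <- function(dataset,
                              reference = c("all_nonadults", "juveniles"),
                              stages = NULL, weaning_days = 365,
                              year_length = 365) {
  reference <- match.arg(reference)
  stages <- stages %||% covariate_stages(dataset, year_length)
  roster <- dataset$roster
  igc <- dataset$igc
  na_ros <- roster[roster$age_class == "nonadult", ]

  rows <- do.call(rbind, lapply(seq_len(nrow(igc)), function(i) {
    el <- na_ros[na_ros$group_id == igc$focal_group[i] &
                   na_ros$birth_date <= igc$date[i], ]
    if (!nrow(el)) return(NULL)
    data.frame(event_id = igc$event_id[i], date = igc$date[i],
               focal_group = igc$focal_group[i],
               opp_group = igc$opposing_group[i],
               focal_size = igc$focal_group_size[i],
               opp_size = igc$opposing_group_size[i],
               n_focal = igc$n_focal_participants[i],
               n_opp = igc$n_opposing_participants[i],
               id = el$id, sex = el$sex, mother_id = el$mother_id,
               birth_date = el$birth_date, stringsAsFactors = FALSE)
  }))
  rows$age <- rows$date - rows$birth_date
  if (reference == "juveniles") rows <- rows[rows$age >= weaning_days, ]
  rows$sexM <- as.integer(rows$sex == "M")
  rows$year <- day_to_year(rows$date, year_length)

  # responses from the participants / grooming maps
  pmap <- lapply(igc$participants, parse_participants)
  gmap <- lapply(igc$igc_grooming, parse_grooming)
  names(pmap) <- names(gmap) <- igc$event_id
  eix <- match(rows$event_id, igc$event_id)
  rows$level <- mapply(function(i, id) {
    lv <- pmap[[i]][id]; if (is.na(lv)) 0L else as.integer(lv)
  }, eix, rows$id)
  rows$participation <- as.integer(rows$level > 0)
  rows$mat_level <- mapply(function(i, m) {
    lv <- pmap[[i]][m]; if (is.na(lv)) 0L else as.integer(lv)
  }, eix, rows$mother_id)
  rows$mother_part <- as.integer(rows$mat_level > 0)
  rows$groomed <- as.integer(mapply(function(i, id)
    id %in% gmap[[i]][, "groomee"], eix, rows$id))
  rows$groomed_by_mother <- ifelse(rows$groomed == 1L, mapply(function(i, id, m) {
    g <- gmap[[i]]
    as.integer(m %in% g[g[, "groomee"] == id, "groomer"])
  }, eix, rows$id, rows$mother_id), NA_integer_)

  # covariates from the pipeline stages
  cen <- stages$centrality
  rows <- merge(rows, cen[, c("id", "year", "grooming_ec", "spatial_ec")],
                by = c("id", "year"), all.x = TRUE, sort = FALSE)
  n_before <- nrow(rows)
  drop <- is.na(rows$grooming_ec) | is.na(rows$spatial_ec)
  if (any(drop)) {
    message(sprintf("dropping %d row(s) without network coverage for the event year",
                    sum(drop)))
    rows <- rows[!drop, ]
  }
  rl <- rank_lookup(stages$elo, roster,
                    data.frame(group_id = rows$focal_group, date = rows$date))
  rows <- merge(rows, rl, by.x = c("focal_group", "date", "id"),
                by.y = c("group_id", "date", "id"), all.x = TRUE, sort = FALSE)
  neo <- setNames(dataset$neophilia$neophilia, dataset$neophilia$id)
  rows$neophilia <- unname(neo[rows$id])
  rows$neophilia_imputed <- is.na(rows$neophilia)
  if (any(rows$neophilia_imputed))
    rows$neophilia[rows$neophilia_imputed] <- mean(rows$neophilia, na.rm = TRUE)

  rows <- scale_continuous(rows, c("age", "rank", "neophilia", "grooming_ec",
                                   "spatial_ec", "n_focal", "n_opp",
                                   "focal_size", "opp_size"))
  rows <- rows[order(rows$event_id, rows$id), ]
  rownames(rows) <- NULL
  attr(rows, "n_dropped") <- n_before - nrow(rows)
  attr(rows, "reference") <- reference
  rows
}

#' Prepare the model frame for one of the four IGC models
#'
#' `m1` uses the full panel; `m2` and `m4` restrict to participant rows
#' and re-scale the continuous covariates within the restricted frame
#' (each model's data set is scaled before fitting); `m3` uses the full
#' panel with grooming receipt as the response.
#'
#' @param panel from [build_event_panel()].
#' @param model `"m1"`, `"m2"`, `"m3"` or `"m4"`.
#' @export
model_frame <- function(panel, model = c("m1", "m2", "m3", "m4")) {
  model <- match.arg(model)
  cont <- c("age", "rank", "neophilia", "grooming_ec", "spatial_ec",
            "n_focal", "n_opp", "focal_size", "opp_size")
  if (model %in% c("m1", "m3")) return(panel)
  sub <- panel[panel$participation == 1, , drop = FALSE]
  sub <- scale_continuous(sub, cont)
  rownames(sub) <- NULL
  sub
}
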