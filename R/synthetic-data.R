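# Seeded synthetic inputs with the statistical structure the analysis
# assumes: logger-style temperature series (seasonal cycle + daily tidal
# fluctuation + multi-month low-amplitude heatwave + noise) and survey data
# whose bleaching severity follows an ordered dose-response in accumulated
# DHW, attenuated in intertidal habitats.

#' Define a synthetic climate scenario for one site
#'
#' The generated water temperature is
#' `T(t) = mean_annual + seasonal + tidal + heatwave + noise`: a seasonal
#' cosine peaking at `season_phase` (day of year), a daily tidal sinusoid of
#' amplitude `tidal_amplitude` (3.5 degC gives the 7 degC daily range of an
#' extreme intertidal pool), an optional heatwave (linear ramps of
#' `ramp_days` around a plateau of `magnitude` degC lasting `duration_days`),
#' and Gaussian logger noise.
#'
#' @param site_id Site label.
#' @param mmm Site maximum monthly mean SST (degC), the anomaly baseline.
#' @param mean_annual Annual mean temperature (degC).
#' @param seasonal_amplitude Half-range of the seasonal cycle (degC).
#' @param season_phase Day of year at which the seasonal cycle peaks.
#' @param tidal_amplitude Half-range of the daily tidal component (degC).
#' @param heatwave `NULL` or a list with `start` (date), `duration_days`,
#'   `magnitude` (degC), `ramp_days`.
#' @param noise_sd Gaussian noise standard deviation (degC).
#' @param habitat Habitat label carried onto the series.
#' @param interval_minutes Logger cadence (default 15).
#' @param seed Integer seed used by [gen_temperature()].
#' @return A `climate_scenario` list.
#' @export
climate_scenario <- function(site_id, mmm, mean_annual,
                             seasonal_amplitude = 0, season_phase = 32,
                             tidal_amplitude = 0, heatwave = NULL,
                             noise_sd = 0, habitat = "unspecified",
                             interval_minutes = 15, seed = NULL) {
  if (seasonal_amplitude < 0 || tidal_amplitude < 0 || noise_sd < 0) {
    stop_input("amplitudes and noise_sd must be non-negative")
  }
  if (!is.null(heatwave)) {
    need <- c("start", "duration_days", "magnitude", "ramp_days")
    if (!all(need %in% names(heatwave))) {
      stop_input("heatwave needs fields ", paste(need, collapse = ", "))
    }
    if (heatwave$duration_days < 0) stop_input("heatwave duration must be >= 0")
    heatwave$start <- as.Date(heatwave$start)
  }
  structure(list(site_id = as.character(site_id), mmm = mmm,
                 mean_annual = mean_annual,
                 seasonal_amplitude = seasonal_amplitude,
                 season_phase = season_phase,
                 tidal_amplitude = tidal_amplitude,
                 heatwave = heatwave, noise_sd = noise_sd,
                 habitat = habitat, interval_minutes = interval_minutes,
                 seed = seed),
            class = "climate_scenario")
}

heatwave_term <- function(day_num, hw) {
  if (is.null(hw)) return(rep(0, length(day_num)))
  s <- as.numeric(hw$start)
  e <- s + hw$duration_days
  r <- hw$ramp_days
  up <- if (r > 0) pmin(pmax((day_num - (s - r)) / r, 0), 1) else as.numeric(day_num >= s)
  down <- if (r > 0) pmin(pmax(((e + r) - day_num) / r, 0), 1) else as.numeric(day_num <= e)
  hw$magnitude * pmin(up, down)
}

#' Generate a logger-style temperature series from a scenario
#'
#' Samples the scenario's temperature model every `interval_minutes` from
#' `start` 00:00 through `end` 23:45 (local clock). Deterministic given the
#' scenario seed.
#'
#' @param scenario A [climate_scenario()].
#' @param start,end Dates (inclusive); `start` must precede `end`.
#' @return A [temperature_series()].
#' @export
gen_temperature <- function(scenario, start, end) {
  if (!inherits(scenario, "climate_scenario")) {
    stop_input("scenario must be a climate_scenario")
  }
  start <- as.Date(start); end <- as.Date(end)
  if (start >= end) stop_input("start date must precede end date")
  step <- scenario$interval_minutes * 60
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(end, "23:59:59"), tz = "UTC")
  times <- seq(t0, t1, by = step)
  doy <- as.POSIXlt(times)$yday + 1
  frac_day <- (as.numeric(times) %% 86400) / 86400
  day_num <- as.numeric(as.Date(times))
  temp <- scenario$mean_annual +
    scenario$seasonal_amplitude *
      cos(2 * pi * (doy - scenario$season_phase) / 365.25) +
    scenario$tidal_amplitude * sin(2 * pi * frac_day) +
    heatwave_term(day_num, scenario$heatwave)
  if (scenario$noise_sd > 0) {
    temp <- temp + with_seed(scenario$seed,
                             stats::rnorm(length(times), 0, scenario$noise_sd))
  }
  temperature_series(times, temp, site_id = scenario$site_id,
                     habitat = scenario$habitat,
                     nominal_interval = scenario$interval_minutes)
}

#' Define a synthetic community profile
#'
#' @param site_id Site label.
#' @param genera Named fractions of coral cover per genus, summing to 1.
#' @param morphology Named character, morphology per genus (defaults to
#'   `"branching"` for every genus).
#' @param coral_fraction Fraction of the substrate occupied by hard coral.
#' @param substrate_mix Named fractions of the non-coral substrate over
#'   `soft_coral`, `algae_turf`, `sand_rubble`, `rock`, `unknown`
#'   (normalised).
#' @param colonies_per_quadrat Mean number of coral colonies (regions) per
#'   quadrat map.
#' @return A `community_profile` list.
#' @export
community_profile <- function(site_id, genera,
                              morphology = NULL,
                              coral_fraction = 0.5,
                              substrate_mix = c(algae_turf = 0.4,
                                                sand_rubble = 0.3,
                                                rock = 0.3),
                              colonies_per_quadrat = 8) {
  if (is.null(names(genera)) || any(genera < 0)) {
    stop_input("genera must be a named vector of non-negative fractions")
  }
  if (abs(sum(genera) - 1) > 1e-9) stop_input("genus fractions must sum to 1")
  if (coral_fraction < 0 || coral_fraction > 1) {
    stop_input("coral_fraction must lie in [0, 1]")
  }
  if (is.null(morphology)) {
    morphology <- stats::setNames(rep("branching", length(genera)), names(genera))
  }
  if (!all(names(genera) %in% names(morphology))) {
    stop_input("morphology must name every genus")
  }
  if (!all(morphology %in% MORPHOLOGIES)) {
    stop_input("morphology values must be one of ", paste(MORPHOLOGIES, collapse = ", "))
  }
  if (!all(names(substrate_mix) %in% setdiff(SUBSTRATE_CATEGORIES, "hard_coral"))) {
    stop_input("substrate_mix names must be non-coral categories")
  }
  structure(list(site_id = as.character(site_id), genera = genera,
                 morphology = morphology, coral_fraction = coral_fraction,
                 substrate_mix = substrate_mix / sum(substrate_mix),
                 colonies_per_quadrat = colonies_per_quadrat),
            class = "community_profile")
}

#' Ordered dose-response of coral health to accumulated heat stress
#'
#' Cumulative-logit model on the ordered health scale UB < M < S < D:
#' `P(state >= k) = logistic((dhw - (theta_k + shift)) / scale)`. The
#' per-habitat `tolerance_shift` (DHW added to every threshold) encodes the
#' higher thermal tolerance of corals from fluctuating intertidal
#' environments.
#'
#' Defaults (theta_M = 2, theta_S = 3.5, theta_D = 7 DHW, scale = 1,
#' intertidal shift +1) put the majority of a subtidal community in the
#' severe category near 4.5 DHW while the matching intertidal community
#' stays near 50% severe.
#'
#' @param theta Named thresholds `c(M=, S=, D=)` in DHW, non-decreasing.
#' @param scale Logistic scale in DHW (> 0).
#' @param tolerance_shift Named per-habitat threshold shifts in DHW.
#' @return A `bleaching_response` list.
#' @export
bleaching_response <- function(theta = c(M = 2, S = 3.5, D = 7), scale = 1,
                               tolerance_shift = c(intertidal = 1,
                                                   subtidal = 0)) {
  if (!all(c("M", "S", "D") %in% names(theta))) {
    stop_input("theta must name M, S and D")
  }
  theta <- theta[c("M", "S", "D")]
  if (is.unsorted(theta)) stop_input("thresholds must satisfy theta_M <= theta_S <= theta_D")
  if (scale <= 0) stop_input("scale must be positive")
  structure(list(theta = theta, scale = scale,
                 tolerance_shift = tolerance_shift),
            class = "bleaching_response")
}

#' Health-category probabilities at a given heat stress
#'
#' @param dhw Non-negative DHW value(s).
#' @param response A [bleaching_response()].
#' @param habitat Habitat label; habitats absent from `tolerance_shift` get
#'   shift 0.
#' @return For scalar `dhw` a named probability vector over
#'   `c("UB","M","S","D")`; for vector input a matrix with one row per value.
#'   Probabilities are non-negative and sum to 1.
#' @export
bleaching_probabilities <- function(dhw, response, habitat = "subtidal") {
  if (!inherits(response, "bleaching_response")) {
    stop_input("response must be a bleaching_response")
  }
  if (any(dhw < 0)) stop_input("dhw must be non-negative")
  shift <- response$tolerance_shift[habitat]
  shift <- if (is.na(shift)) 0 else unname(shift)
  p_ge <- vapply(response$theta, function(th)
    stats::plogis((dhw - (th + shift)) / response$scale), numeric(length(dhw)))
  p_ge <- matrix(p_ge, nrow = length(dhw))
  out <- cbind(UB = 1 - p_ge[, 1], M = p_ge[, 1] - p_ge[, 2],
               S = p_ge[, 2] - p_ge[, 3], D = p_ge[, 3])
  if (length(dhw) == 1L) out[1, ] else out
}

# one synthetic quadrat map: abiotic strips plus coral colonies whose health
# states are drawn per colony (points within a colony share its state,
# reproducing the overdispersion of real quadrats)
sim_quadrat_map <- function(profile, probs, quadrat_id, transect_id) {
  if (profile$coral_fraction == 0) {
    warning("coral_fraction is 0: generating an all-abiotic map", call. = FALSE)
  }
  widths <- numeric(0)
  labels <- data.frame(category = character(), genus = character(),
                       morphology = character(), health = character(),
                       stringsAsFactors = FALSE)
  if (length(profile$substrate_mix) && profile$coral_fraction < 1) {
    ab_w <- profile$substrate_mix * (1 - profile$coral_fraction)
    labels <- rbind(labels, data.frame(
      category = names(ab_w), genus = NA_character_,
      morphology = NA_character_, health = NA_character_))
    widths <- c(widths, unname(ab_w))
  }
  if (profile$coral_fraction > 0) {
    k <- max(1L, stats::rpois(1, profile$colonies_per_quadrat))
    w <- stats::rexp(k)
    w <- w / sum(w) * profile$coral_fraction
    genus <- sample(names(profile$genera), k, replace = TRUE,
                    prob = profile$genera)
    health <- sample(colnames(probs) %||% names(probs), k, replace = TRUE,
                     prob = probs)
    labels <- rbind(labels, data.frame(
      category = "hard_coral", genus = genus,
      morphology = unname(profile$morphology[genus]), health = health))
    widths <- c(widths, w)
  }
  quadrat_map_strips(labels, widths, quadrat_id = quadrat_id,
                     transect_id = transect_id)
}

#' Simulate a photoquadrat survey driven by accumulated heat stress
#'
#' Builds quadrat maps whose region areas follow the community profile,
#' assigns each coral colony a health state drawn from
#' [bleaching_probabilities()] at the supplied DHW, then runs the
#' point-count scoring end to end. Fully reproducible given `seed`.
#'
#' @param profile A [community_profile()].
#' @param response A [bleaching_response()].
#' @param dhw Accumulated heat stress (DHW) at survey time.
#' @param n_transects Number of transects (>= 1).
#' @param quadrats_per_transect Quadrats scored per transect.
#' @param points_per_quadrat Points per quadrat (default 100).
#' @param habitat Habitat label (selects the tolerance shift).
#' @param site,time Labels written into the point records.
#' @param seed Integer seed.
#' @return A `survey_sim` list: `maps` (list of [quadrat_map()]), `scores`
#'   (list of [score_points()] tallies), and `points` (long point-record
#'   data frame: `quadrat_id, transect_id, site, time, point_index,
#'   category, genus, morphology, health`).
#' @export
gen_survey <- function(profile, response, dhw, n_transects,
                       quadrats_per_transect, points_per_quadrat = 100,
                       habitat = "subtidal", site = profile$site_id,
                       time = "t1", seed = NULL) {
  if (!inherits(profile, "community_profile")) {
    stop_input("profile must be a community_profile")
  }
  if (n_transects < 1) stop_input("n_transects must be >= 1")
  probs <- bleaching_probabilities(dhw, response, habitat)
  probs <- matrix(probs, nrow = 1, dimnames = list(NULL, HEALTH_LEVELS))
  with_seed(seed, {
    maps <- list(); scores <- list(); points <- list()
    for (tr in seq_len(n_transects)) {
      tid <- sprintf("%s_T%02d", site, tr)
      for (q in seq_len(quadrats_per_transect)) {
        qid <- sprintf("%s_Q%02d", tid, q)
        map <- sim_quadrat_map(profile, probs, qid, tid)
        smp <- spawn_stratified_points(points_per_quadrat, seed = draw_seed())
        sc <- score_points(map, smp)
        idx <- mapply(locate_region, x = smp$x, y = smp$y,
                      MoreArgs = list(map = map))
        points[[qid]] <- data.frame(
          quadrat_id = qid, transect_id = tid, site = site, time = time,
          point_index = seq_len(nrow(smp)),
          category = ifelse(is.na(idx), "unknown", map$category[idx]),
          genus = map$genus[idx], morphology = map$morphology[idx],
          health = map$health[idx], stringsAsFactors = FALSE)
        maps[[qid]] <- map
        scores[[qid]] <- sc
      }
    }
    structure(list(maps = maps, scores = scores,
                   points = do.call(rbind, c(points, make.row.names = FALSE))),
              site = site, time = time, habitat = habitat, dhw = dhw,
              seed = seed, class = "survey_sim")
  })
}

#' Simulate a roving-diver survey
#'
#' Colony list for a single-genus stand (the sparse-cover survey mode):
#' diameters uniform over `diameter_range`, health states drawn from the
#' dose-response at the supplied DHW (or from `baseline` probabilities when
#' `response` is `NULL`).
#'
#' @param response A [bleaching_response()] or `NULL`.
#' @param dhw Accumulated heat stress at survey time.
#' @param n_colonies Number of colonies scored (>= 1).
#' @param genus Genus label (default `"Turbinaria"`).
#' @param baseline Named health probabilities used when `response` is `NULL`.
#' @param diameter_range Colony diameter range in cm (default 2-150).
#' @param site,location,date Labels written into the records.
#' @param habitat Habitat label.
#' @param seed Integer seed.
#' @return Data frame `site, location, date, colony_id, genus, diameter_cm,
#'   health`.
#' @export
gen_roving <- function(response, dhw, n_colonies, genus = "Turbinaria",
                       baseline = c(UB = 1, M = 0, S = 0, D = 0),
                       diameter_range = c(2, 150), site = "site",
                       location = "loc", date = NA, habitat = "subtidal",
                       seed = NULL) {
  if (n_colonies < 1) stop_input("n_colonies must be >= 1")
  probs <- if (is.null(response)) {
    baseline[HEALTH_LEVELS] / sum(baseline)
  } else {
    bleaching_probabilities(dhw, response, habitat)
  }
  with_seed(seed, data.frame(
    site = site, location = location, date = date,
    colony_id = sprintf("C%04d", seq_len(n_colonies)),
    genus = genus,
    diameter_cm = stats::runif(n_colonies, diameter_range[1], diameter_range[2]),
    health = sample(HEALTH_LEVELS, n_colonies, replace = TRUE, prob = probs),
    stringsAsFactors = FALSE
  ))
}
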