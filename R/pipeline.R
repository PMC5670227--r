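# Config-driven orchestration: simulate -> heat -> survey -> stats, each
# stage writing plain CSV/TSV plus a JSON manifest with seeds and file
# hashes for the audit trail.

#' Read a pipeline run configuration (JSON)
#'
#' The configuration holds global `options` (accumulation rule, window_days,
#' n_perm, seed, chi2_correction, cover_basis), a `climatology` map
#' (site -> mmm/source) and a `sites` array. Each site names its habitat and
#' either file inputs (`logger_csv`, per-time `points_csv` / `roving_csv`)
#' or a synthetic `scenario` + `survey` block for [run_simulate()]. All
#' referenced paths are checked before any stage executes.
#'
#' @param path JSON config path.
#' @param base_dir Directory against which relative paths resolve (defaults
#'   to the config's directory).
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop_input("config not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg$base_dir <- base_dir
  validate_run_config(cfg)
}

#' Validate an in-memory run configuration
#'
#' @param cfg A config list (same shape as [read_run_config()] output).
#' @return The validated `run_config`, with defaults filled in.
#' @export
validate_run_config <- function(cfg) {
  cfg$options <- utils::modifyList(
    list(rule = "all_positive", window_days = 84, n_perm = 9999,
         min_coverage = 0.75, chi2_correction = "none",
         cover_basis = "hard_coral_points"),
    cfg$options %||% list())
  if (!cfg$options$rule %in% DHD_RULES) {
    stop_input("options$rule must be one of ", paste(DHD_RULES, collapse = ", "))
  }
  if (is.null(cfg$sites) || !length(cfg$sites)) stop_input("config has no sites")
  base <- cfg$base_dir %||% "."
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  for (i in seq_along(cfg$sites)) {
    s <- cfg$sites[[i]]
    if (is.null(s$site_id)) stop_input("site ", i, " has no site_id")
    for (f in c("logger_csv")) {
      if (!is.null(s[[f]])) {
        s[[f]] <- resolve(s[[f]])
        if (!file.exists(s[[f]])) stop_input("site '", s$site_id, "': ", f,
                                             " not found: ", s[[f]])
      }
    }
    for (f in c("points_csv", "roving_csv")) {
      if (!is.null(s[[f]])) {
        s[[f]] <- lapply(s[[f]], resolve)
        miss <- !vapply(s[[f]], file.exists, logical(1))
        if (any(miss)) stop_input("site '", s$site_id, "': ", f, " not found: ",
                                  s[[f]][[which(miss)[1]]])
      }
    }
    s$habitat <- s$habitat %||% "unspecified"
    cfg$sites[[i]] <- s
  }
  # the stats stage always permutes, so a seed is mandatory
  if (is.null(cfg$seed)) stop_input("config must carry a seed")
  class(cfg) <- "run_config"
  cfg
}

site_clim <- function(cfg, site_id) {
  entry <- cfg$climatology[[site_id]]
  if (is.null(entry)) stop_input("no climatology entry for site '", site_id, "'")
  climatology(site_id, entry$mmm, entry$source %||% "config")
}

write_manifest <- function(out_dir, stage, cfg, files, seed = NULL) {
  files <- files[file.exists(files)]
  manifest <- list(
    stage = stage, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = seed %||% cfg$seed, options = cfg$options,
    files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the heat-stress stage
#'
#' For every site with a logger series, computes the heat-stress profile
#' under both accumulation rules and writes a per-site profile CSV
#' (`heat_<site>.csv`, configured rule) plus a one-row-per-site summary
#' (`heat_summary.csv`) with days above MMM/threshold and final DHD/DHW
#' under both rules, DHW at 1-decimal reporting precision alongside the raw
#' values.
#'
#' @param cfg A `run_config`.
#' @param out_dir Output directory (created if missing).
#' @return The summary data frame, invisibly.
#' @export
run_heat_stress <- function(cfg, out_dir = cfg$out_dir %||% ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); written <- character(0)
  for (s in cfg$sites) {
    if (is.null(s$logger_csv)) next
    series <- read_logger_csv(s$logger_csv, site_id = s$site_id,
                              habitat = s$habitat)
    clim <- site_clim(cfg, s$site_id)
    prof <- lapply(DHD_RULES, function(r)
      heat_stress_profile(series, clim, rule = r,
                          window_days = cfg$options$window_days,
                          min_coverage = cfg$options$min_coverage))
    names(prof) <- DHD_RULES
    main <- prof[[cfg$options$rule]]
    f <- file.path(out_dir, paste0("heat_", s$site_id, ".csv"))
    utils::write.csv(as.data.frame(main), f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
    sums <- lapply(prof, exceedance_summary)
    rows[[s$site_id]] <- data.frame(
      site = s$site_id, habitat = s$habitat, mmm = clim$mmm,
      n_days = sums[[1]]$n_days,
      days_above_mmm = sums[[1]]$days_above_mmm,
      days_above_threshold = sums[[1]]$days_above_threshold,
      max_anomaly = sums[[1]]$max_anomaly,
      dhd_all_positive = sums$all_positive$final_dhd,
      dhw_all_positive = report_dhw(sums$all_positive$final_dhd),
      dhd_noaa_ge1 = sums$noaa_ge1$final_dhd,
      dhw_noaa_ge1 = report_dhw(sums$noaa_ge1$final_dhd),
      n_gap_days = sums[[1]]$n_gap_days)
  }
  if (!length(rows)) stop_input("no site in the config has a logger series")
  summary <- do.call(rbind, c(rows, make.row.names = FALSE))
  f <- file.path(out_dir, "heat_summary.csv")
  utils::write.csv(summary, f, row.names = FALSE, quote = FALSE)
  write_manifest(out_dir, "heat", cfg, c(written, f))
  invisible(summary)
}

#' Run the survey-analysis stage
#'
#' Photoquadrat sites: per site x time, health percent cover of hard-coral
#' points summarised across transects (mean +/- SE, transects as replicates)
#' and the dominant genus; also writes the combined wide abundance matrix
#' (`abundance.csv`) that feeds [run_stats()]. Roving sites: per-time health
#' tallies. Outputs: `survey_health.tsv`, `survey_dominant.tsv`,
#' `roving_tallies.tsv`, `abundance.csv`.
#'
#' @inheritParams run_heat_stress
#' @return List with elements `health`, `dominant`, `roving`, invisibly.
#' @export
run_survey_analysis <- function(cfg, out_dir = cfg$out_dir %||% ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  health_rows <- list(); dom_rows <- list(); rov_rows <- list()
  all_points <- list()
  for (s in cfg$sites) {
    for (tm in names(s$points_csv %||% list())) {
      pts <- read_points_csv(s$points_csv[[tm]])
      pts$site <- s$site_id; pts$time <- tm
      all_points[[paste(s$site_id, tm)]] <- pts
      covers <- per_quadrat_health(pts)
      if (nrow(covers)) {
        ts <- transect_summary(covers, class_cols = "health")
        health_rows[[paste(s$site_id, tm)]] <-
          cbind(site = s$site_id, time = tm, ts)
      }
      dom_rows[[paste(s$site_id, tm)]] <-
        cbind(site = s$site_id, time = tm, dominant_genus(pts))
    }
    for (tm in names(s$roving_csv %||% list())) {
      rec <- read_roving_csv(s$roving_csv[[tm]])
      tally <- roving_tally(rec, survey_id = paste(s$site_id, tm))
      rov_rows[[paste(s$site_id, tm)]] <-
        cbind(site = s$site_id, time = tm,
              n_colonies = attr(tally, "n_colonies"), as.data.frame(tally))
    }
  }
  written <- character(0)
  out <- list()
  if (length(health_rows)) {
    out$health <- do.call(rbind, c(health_rows, make.row.names = FALSE))
    f <- file.path(out_dir, "survey_health.tsv")
    utils::write.table(out$health, f, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, f)
    out$dominant <- do.call(rbind, c(dom_rows, make.row.names = FALSE))
    f <- file.path(out_dir, "survey_dominant.tsv")
    utils::write.table(out$dominant, f, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, f)
    ab <- abundance_from_points(do.call(rbind, c(all_points, make.row.names = FALSE)))
    f <- file.path(out_dir, "abundance.csv")
    write_abundance_csv(ab, f)
    written <- c(written, f)
  }
  if (length(rov_rows)) {
    out$roving <- do.call(rbind, c(rov_rows, make.row.names = FALSE))
    f <- file.path(out_dir, "roving_tallies.tsv")
    utils::write.table(out$roving, f, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  if (!length(written)) stop_input("no survey inputs in the config")
  write_manifest(out_dir, "survey", cfg, written)
  invisible(out)
}

# per-quadrat health percent cover (of hard-coral points) in the long form
# transect_summary() expects
per_quadrat_health <- function(pts) {
  hc <- pts[pts$category == "hard_coral" & !is.na(pts$health), , drop = FALSE]
  quads <- unique(pts[c("transect_id", "quadrat_id")])
  rows <- lapply(seq_len(nrow(quads)), function(i) {
    sel <- hc$quadrat_id == quads$quadrat_id[i]
    if (!any(sel)) return(NULL)
    tab <- table(hc$health[sel])
    data.frame(transect_id = quads$transect_id[i],
               quadrat_id = quads$quadrat_id[i],
               health = names(tab),
               percent = 100 * as.numeric(tab) / sum(tab))
  })
  do.call(rbind, c(rows, make.row.names = FALSE)) %||%
    data.frame(transect_id = character(), quadrat_id = character(),
               health = character(), percent = numeric())
}

dominant_genus <- function(pts) {
  hc <- pts[pts$category == "hard_coral" & !is.na(pts$genus), , drop = FALSE]
  if (!nrow(hc)) {
    return(data.frame(dominant_genus = NA_character_, percent_of_coral = NA_real_))
  }
  tab <- sort(table(hc$genus), decreasing = TRUE)
  data.frame(dominant_genus = names(tab)[1],
             percent_of_coral = 100 * as.numeric(tab)[1] / sum(tab))
}

#' Run the statistics stage
#'
#' From the abundance matrix written by [run_survey_analysis()]: square-root
#' transform, Bray-Curtis dissimilarities, a two-way PERMANOVA (time x site,
#' restricted to sites surveyed at both time points), a one-way PERMANOVA
#' across sites at the final time point with Holm-adjusted pairwise
#' comparisons, and a covariance PCA. Roving sites get a Pearson chi-square
#' comparing health (unbleached vs bleached) between time points. Every test
#' is stamped with its seed and permutation count; outputs:
#' `stats_permanova.tsv`, `stats_pairwise.tsv`, `stats_chisq.tsv`,
#' `pca_scores.csv`, `pca_loadings.csv`, `stats_manifest.json`.
#'
#' @inheritParams run_heat_stress
#' @param seed Seed for the permutation streams (defaults to the config's).
#' @return List of result objects, invisibly.
#' @export
run_stats <- function(cfg, out_dir = cfg$out_dir %||% ".", seed = cfg$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_perm <- cfg$options$n_perm
  out <- list(); written <- character(0)
  perm_rows <- list()
  ab_path <- file.path(out_dir, "abundance.csv")
  seeds <- with_seed(seed, replicate(4, draw_seed()))
  if (file.exists(ab_path)) {
    ab <- sqrt_transform(read_abundance_csv(ab_path))
    meta <- ab$meta
    times <- sort(unique(meta$time))
    # two-way time x site over sites present at every time point
    if (length(times) >= 2) {
      per_site <- tapply(meta$time, meta$site, function(t) length(unique(t)))
      both <- names(per_site)[per_site == length(times)]
      sel <- meta$site %in% both
      if (length(both) >= 2 && sum(sel) >= 8) {
        d2 <- bray_curtis(abundance_matrix(ab$values[sel, , drop = FALSE],
                                           meta[sel, , drop = FALSE], "sqrt"))
        out$twoway <- permanova_twoway(d2, meta$time[sel], meta$site[sel],
                                       n_perm = n_perm, seed = seeds[1],
                                       term_names = c("Time", "Site", "Time:Site"))
        perm_rows$twoway <- cbind(test = "twoway_time_site",
                                  as.data.frame(out$twoway))
      }
    }
    # one-way site effect at the final time point + pairwise post hoc
    tlast <- times[length(times)]
    sel <- meta$time == tlast
    gr <- droplevels(factor(meta$site[sel]))
    if (nlevels(gr) >= 2 && all(table(gr) >= 2)) {
      d1 <- bray_curtis(abundance_matrix(ab$values[sel, , drop = FALSE],
                                         meta[sel, , drop = FALSE], "sqrt"))
      out$oneway <- permanova_oneway(d1, gr, n_perm = n_perm, seed = seeds[2])
      perm_rows$oneway <- cbind(test = paste0("oneway_site_", tlast),
                                as.data.frame(out$oneway))
      if (nlevels(gr) >= 3) {
        out$pairwise <- pairwise_posthoc(d1, gr, n_perm = n_perm, seed = seeds[3])
        f <- file.path(out_dir, "stats_pairwise.tsv")
        utils::write.table(as.data.frame(out$pairwise), f, sep = "\t",
                           row.names = FALSE, quote = FALSE)
        written <- c(written, f)
      }
    }
    out$pca <- pca(ab)
    f <- file.path(out_dir, "pca_scores.csv")
    utils::write.csv(cbind(meta, as.data.frame(out$pca$scores)), f,
                     row.names = FALSE, quote = FALSE)
    written <- c(written, f)
    f <- file.path(out_dir, "pca_loadings.csv")
    utils::write.csv(data.frame(class = rownames(out$pca$loadings),
                                as.data.frame(out$pca$loadings),
                                check.names = FALSE),
                     f, row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  if (length(perm_rows)) {
    tab <- do.call(rbind, c(perm_rows, make.row.names = FALSE))
    tab$n_perm <- n_perm; tab$seed <- seed
    f <- file.path(out_dir, "stats_permanova.tsv")
    utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  # chi-square per roving site: time x (UB vs bleached)
  chi_rows <- list()
  for (s in cfg$sites) {
    tms <- names(s$roving_csv %||% list())
    if (length(tms) < 2) next
    counts <- t(vapply(tms, function(tm) {
      h <- read_roving_csv(s$roving_csv[[tm]])$health
      c(UB = sum(h == "UB"), bleached = sum(h != "UB"))
    }, numeric(2)))
    res <- chi_square(counts, correction = cfg$options$chi2_correction)
    chi_rows[[s$site_id]] <- data.frame(
      site = s$site_id, comparison = paste(tms, collapse = " vs "),
      statistic = res$statistic, df = res$df, p = res$p_value,
      correction = res$correction)
    out$chisq[[s$site_id]] <- res
  }
  if (length(chi_rows)) {
    f <- file.path(out_dir, "stats_chisq.tsv")
    utils::write.table(do.call(rbind, c(chi_rows, make.row.names = FALSE)),
                       f, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  if (!length(written)) stop_input("nothing to analyse: run the survey stage first")
  write_manifest(out_dir, "stats", cfg, written, seed = seed)
  invisible(out)
}

#' Run the simulation stage
#'
#' For every site carrying a `scenario`, generates the logger CSV; for every
#' site carrying a `survey` block, computes the DHW accrued at each survey
#' date from its own generated series (configured rule and window) and
#' generates the survey files (point-score CSVs, or a roving CSV when
#' `survey$mode == "roving"`). The config is returned with the generated
#' paths filled in, ready for the analysis stages.
#'
#' @inheritParams run_heat_stress
#' @param seed Master seed (defaults to the config's).
#' @return The updated `run_config`, invisibly.
#' @export
run_simulate <- function(cfg, out_dir = cfg$out_dir %||% ".", seed = cfg$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  with_seed(seed, {
    for (i in seq_along(cfg$sites)) {
      s <- cfg$sites[[i]]
      if (is.null(s$scenario)) next
      sc <- s$scenario
      if (!inherits(sc, "climate_scenario")) {
        hw <- sc$heatwave
        sc <- climate_scenario(s$site_id, mmm = sc$mmm,
                               mean_annual = sc$mean_annual,
                               seasonal_amplitude = sc$seasonal_amplitude %||% 0,
                               season_phase = sc$season_phase %||% 32,
                               tidal_amplitude = sc$tidal_amplitude %||% 0,
                               heatwave = hw, noise_sd = sc$noise_sd %||% 0,
                               habitat = s$habitat,
                               seed = sc$seed %||% draw_seed())
      }
      series <- gen_temperature(sc, s$start, s$end)
      lf <- file.path(out_dir, paste0("logger_", s$site_id, ".csv"))
      write_logger_csv(series, lf)
      written <- c(written, lf)
      s$logger_csv <- lf
      if (is.null(cfg$climatology[[s$site_id]])) {
        cfg$climatology[[s$site_id]] <- list(mmm = sc$mmm, source = "scenario")
      }
      if (!is.null(s$survey)) {
        sv <- s$survey
        clim <- site_clim(cfg, s$site_id)
        prof <- heat_stress_profile(series, clim, rule = cfg$options$rule,
                                    window_days = cfg$options$window_days)
        resp <- if (inherits(sv$response, "bleaching_response")) sv$response
                else do.call(bleaching_response, sv$response %||% list())
        for (tm in names(sv$times)) {
          date <- as.Date(sv$times[[tm]])
          row <- match(date, prof$date)
          if (is.na(row)) stop_input("site '", s$site_id, "': survey date ",
                                     date, " outside the generated series")
          dhw <- prof$dhw[row]
          if ((sv$mode %||% "photoquadrat") == "roving") {
            rec <- gen_roving(resp, dhw, n_colonies = sv$n_colonies[[tm]],
                              genus = sv$genus %||% "Turbinaria",
                              site = s$site_id, location = s$site_id,
                              date = as.character(date), habitat = s$habitat,
                              seed = draw_seed())
            f <- file.path(out_dir, sprintf("roving_%s_%s.csv", s$site_id, tm))
            write_roving_csv(rec, f)
            s$roving_csv[[tm]] <- f
          } else {
            prof_cfg <- if (inherits(sv$profile, "community_profile")) {
              sv$profile
            } else {
              pl <- sv$profile
              # JSON objects arrive as named lists; the constructors want vectors
              for (f in c("genera", "morphology", "substrate_mix")) {
                if (!is.null(pl[[f]])) pl[[f]] <- unlist(pl[[f]])
              }
              do.call(community_profile, c(list(site_id = s$site_id), pl))
            }
            sim <- gen_survey(prof_cfg, resp, dhw,
                              n_transects = sv$n_transects,
                              quadrats_per_transect = sv$quadrats_per_transect,
                              points_per_quadrat = sv$points_per_quadrat %||% 100,
                              habitat = s$habitat, site = s$site_id,
                              time = tm, seed = draw_seed())
            f <- file.path(out_dir, sprintf("points_%s_%s.csv", s$site_id, tm))
            write_points_csv(sim$points, f)
            s$points_csv[[tm]] <- f
          }
          written <- c(written, f)
        }
      }
      cfg$sites[[i]] <- s
    }
  })
  if (!length(written)) stop_input("no site in the config has a scenario")
  write_manifest(out_dir, "simulate", cfg, written, seed = seed)
  invisible(cfg)
}

#' Build the five-site demonstration configuration
#'
#' A synthetic regional survey emulating a latitudinal study design: a
#' remote tropical reef under strong heat stress surveyed only at the second
#' time point; a macrotidal site with intertidal (daily range 7 degC,
#' tolerance-shifted) and subtidal environments under a moderate multi-month
#' heatwave; a fringing reef and a high-latitude island with little or no
#' heat stress; and a temperate site surveyed by roving diver. Temperatures
#' run from late October to mid April with surveys in mid January and early
#' April.
#'
#' @param seed Master seed.
#' @param n_perm Permutations for the statistics stage (default 999, the
#'   CI-speed setting; raise to 9999 for final runs).
#' @param n_transects,quadrats_per_transect Survey effort per site/time.
#' @return A `run_config`.
#' @export
demo_config <- function(seed = 1, n_perm = 999, n_transects = 6,
                        quadrats_per_transect = 5) {
  # heatwave magnitudes sized so the all_positive rule accrues roughly 9, 4.5
  # and 2.4 DHW by the second survey: a multi-month, low-amplitude event
  # whose daily anomalies stay below 1 degC (so the noaa_ge1 rule sees none)
  hw_strong <- list(start = "2015-11-20", duration_days = 145,
                    magnitude = 0.78, ramp_days = 10)
  hw_moderate <- list(start = "2015-11-20", duration_days = 150,
                      magnitude = 0.36, ramp_days = 15)
  hw_weak <- list(start = "2016-01-10", duration_days = 60,
                  magnitude = 0.55, ramp_days = 10)
  genera_acropora <- list(genera = c(Acropora = 0.75, Porites = 0.12,
                                     Goniopora = 0.08, Galaxea = 0.05),
                          coral_fraction = 0.55)
  genera_montipora <- list(genera = c(Montipora = 0.45, Acropora = 0.25,
                                      Galaxea = 0.18, Platygyra = 0.12),
                           coral_fraction = 0.4)
  genera_pocillopora <- list(genera = c(Pocillopora = 0.55, Acropora = 0.3,
                                        Platygyra = 0.15),
                             coral_fraction = 0.35)
  survey_block <- function(times, profile, mode = "photoquadrat",
                           n_colonies = NULL) {
    c(list(times = times, profile = profile,
           n_transects = n_transects,
           quadrats_per_transect = quadrats_per_transect,
           response = list(), mode = mode),
      if (!is.null(n_colonies)) list(n_colonies = n_colonies))
  }
  t1 <- "2016-01-15"; t2 <- "2016-04-06"
  cfg <- list(
    seed = seed,
    options = list(rule = "all_positive", window_days = 84, n_perm = n_perm),
    climatology = list(),
    sites = list(
      list(site_id = "TropicalRemote", habitat = "subtidal",
           start = "2015-11-01", end = "2016-04-23",
           scenario = list(mmm = 30.827, mean_annual = 30.827,
                           seasonal_amplitude = 0, heatwave = hw_strong,
                           noise_sd = 0.15),
           survey = survey_block(list(t2 = "2016-04-23"), genera_montipora)),
      list(site_id = "MacrotidalIntertidal", habitat = "intertidal",
           start = "2015-10-22", end = "2016-04-06",
           scenario = list(mmm = 30.827, mean_annual = 30.5,
                           seasonal_amplitude = 0.4, season_phase = 60,
                           tidal_amplitude = 3.5, heatwave = hw_moderate,
                           noise_sd = 0.2),
           survey = survey_block(list(t1 = t1, t2 = t2), genera_acropora)),
      list(site_id = "MacrotidalSubtidal", habitat = "subtidal",
           start = "2015-10-22", end = "2016-04-06",
           scenario = list(mmm = 30.827, mean_annual = 30.5,
                           seasonal_amplitude = 0.4, season_phase = 60,
                           tidal_amplitude = 0.5,
                           heatwave = utils::modifyList(hw_moderate,
                                                        list(magnitude = 0.34)),
                           noise_sd = 0.2),
           survey = survey_block(list(t1 = t1, t2 = t2), genera_acropora)),
      list(site_id = "FringingReef", habitat = "reef_flat",
           start = "2015-11-24", end = "2016-05-17",
           scenario = list(mmm = 27.399, mean_annual = 26.0,
                           seasonal_amplitude = 1.2, season_phase = 60,
                           noise_sd = 0.2),
           survey = survey_block(list(t1 = "2016-02-15", t2 = "2016-05-17"),
                                 genera_acropora)),
      list(site_id = "HighLatitudeIsland", habitat = "subtidal",
           start = "2015-11-14", end = "2016-04-01",
           scenario = list(mmm = 22.323, mean_annual = 20.9,
                           seasonal_amplitude = 1.3, season_phase = 60,
                           heatwave = hw_weak, noise_sd = 0.2),
           survey = survey_block(list(t1 = "2016-02-05", t2 = "2016-04-01"),
                                 genera_pocillopora)),
      list(site_id = "TemperateBay", habitat = "subtidal",
           start = "2015-09-16", end = "2016-03-01",
           scenario = list(mmm = 21.3, mean_annual = 19.5,
                           seasonal_amplitude = 1.6, season_phase = 45,
                           noise_sd = 0.2),
           survey = survey_block(list(t1 = "2015-12-08", t2 = "2016-03-01"),
                                 NULL, mode = "roving",
                                 n_colonies = list(t1 = 45, t2 = 78)))
    ))
  validate_run_config(cfg)
}

#' Run the full demonstration pipeline
#'
#' Chains simulate -> heat -> survey -> stats over the [demo_config()]
#' design and returns the stage results.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_perm Permutations for the statistics stage.
#' @return List with `config`, `heat`, `survey`, `stats`.
#' @export
run_demo <- function(out_dir, seed = 1, n_perm = 999) {
  cfg <- demo_config(seed = seed, n_perm = n_perm)
  cfg$out_dir <- out_dir
  cfg <- run_simulate(cfg, out_dir)
  heat <- run_heat_stress(cfg, out_dir)
  survey <- run_survey_analysis(cfg, out_dir)
  stats <- run_stats(cfg, out_dir)
  invisible(list(config = cfg, heat = heat, survey = survey, stats = stats))
}
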