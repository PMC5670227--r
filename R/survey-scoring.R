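# Benthic composition and coral health scoring: stratified random point
# counts over labelled quadrat maps (photoquadrat workflow) and roving-diver
# colony tallies.

SUBSTRATE_CATEGORIES <- c("hard_coral", "soft_coral", "algae_turf",
                          "sand_rubble", "rock", "unknown")
MORPHOLOGIES <- c("branching", "plating", "encrusting", "massive")
HEALTH_LEVELS <- c("UB", "M", "S", "D")

#' Coral health categories
#'
#' The categorical bleaching score used throughout: `UB` unbleached, `M`
#' moderately bleached (<50% of the colony bleached, or pale), `S` severely
#' bleached (>50%), `D` dead.
#'
#' @return Character vector `c("UB", "M", "S", "D")`.
#' @export
health_levels <- function() HEALTH_LEVELS

#' Substrate categories scored in photoquadrats
#'
#' @return Character vector of the six substrate categories.
#' @export
substrate_categories <- function() SUBSTRATE_CATEGORIES

#' Construct a labelled quadrat map
#'
#' An abstract stand-in for a survey photograph: the 50 x 50 cm quadrat is a
#' unit square partitioned into labelled axis-aligned rectangles. Hard-coral
#' regions (colonies) carry genus, morphology and health; other substrate
#' regions carry only their category.
#'
#' @param regions Data frame with columns `category`, `genus`, `morphology`,
#'   `health`, `x0`, `x1`, `y0`, `y1`. Coordinates in `[0, 1]`. Non-coral
#'   regions must have `NA` genus/morphology/health.
#' @param quadrat_id,transect_id Labels.
#' @return A `quadrat_map` data frame.
#' @export
quadrat_map <- function(regions, quadrat_id = "Q1", transect_id = "T1") {
  need <- c("category", "genus", "morphology", "health",
            "x0", "x1", "y0", "y1")
  if (!all(need %in% names(regions))) {
    stop_input("regions must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(regions) == 0L) stop_input("quadrat map has no regions")
  if (!all(regions$category %in% SUBSTRATE_CATEGORIES)) {
    stop_input("unknown substrate category: ",
               paste(setdiff(regions$category, SUBSTRATE_CATEGORIES), collapse = ", "))
  }
  hc <- regions$category == "hard_coral"
  if (any(hc & (is.na(regions$genus) | is.na(regions$morphology) |
                  is.na(regions$health)))) {
    stop_input("hard_coral regions require genus, morphology and health")
  }
  if (any(!hc & (!is.na(regions$genus) | !is.na(regions$morphology) |
                   !is.na(regions$health)))) {
    stop_input("non-coral regions must not carry genus/morphology/health")
  }
  if (any(hc & !regions$morphology %in% MORPHOLOGIES)) {
    stop_input("morphology must be one of ", paste(MORPHOLOGIES, collapse = ", "))
  }
  if (any(hc & !regions$health %in% HEALTH_LEVELS)) {
    stop_input("health must be one of ", paste(HEALTH_LEVELS, collapse = ", "))
  }
  with(regions, {
    if (any(x0 < 0 | x1 > 1 | y0 < 0 | y1 > 1 | x1 <= x0 | y1 <= y0)) {
      stop_input("region rectangles must be non-degenerate and within the unit square")
    }
  })
  area <- with(regions, (x1 - x0) * (y1 - y0))
  if (abs(sum(area) - 1) > 1e-6) {
    warning("region areas sum to ", signif(sum(area), 6),
            ", not 1: the map does not tile the canvas", call. = FALSE)
  }
  structure(as.data.frame(regions), quadrat_id = quadrat_id,
            transect_id = transect_id,
            class = c("quadrat_map", "data.frame"))
}

#' Build a quadrat map from vertical strips
#'
#' Convenience constructor: full-height strips with widths proportional to
#' the requested areas, in the given order. The synthetic survey generator
#' emits maps in this form.
#'
#' @param labels Data frame with columns `category`, `genus`, `morphology`,
#'   `health` (one row per region).
#' @param widths Positive areas, recycled to `nrow(labels)`; normalised to 1.
#' @inheritParams quadrat_map
#' @return A `quadrat_map`.
#' @export
quadrat_map_strips <- function(labels, widths, quadrat_id = "Q1",
                               transect_id = "T1") {
  widths <- rep_len(widths, nrow(labels))
  if (any(widths <= 0)) stop_input("strip widths must be positive")
  w <- widths / sum(widths)
  x1 <- cumsum(w)
  x0 <- c(0, x1[-length(x1)])
  x1[length(x1)] <- 1
  quadrat_map(cbind(labels, data.frame(x0 = x0, x1 = x1, y0 = 0, y1 = 1)),
              quadrat_id = quadrat_id, transect_id = transect_id)
}

#' Spawn stratified random points over the unit square
#'
#' Divides the canvas into a g x g grid with `g = floor(sqrt(n))`, places one
#' uniform point in each sub-cell, and scatters the remaining `n - g^2`
#' points uniformly over the whole canvas. Every sub-cell is therefore
#' guaranteed at least one point, which is what keeps point-count cover
#' estimates low-variance relative to simple random placement.
#'
#' @param n Number of points (>= 1); photoquadrat scoring uses 100.
#' @param seed Integer seed; identical seeds give identical samples.
#' @return A `point_sample` data frame with columns `x`, `y`, `subcell`
#'   (1-based row-major index into the g x g grid).
#' @export
spawn_stratified_points <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop_input("n must be an integer >= 1")
  }
  n <- as.integer(n)
  g <- floor(sqrt(n))
  with_seed(seed, {
    cell <- expand.grid(col = seq_len(g), row = seq_len(g))
    x <- (cell$col - 1 + stats::runif(g * g)) / g
    y <- (cell$row - 1 + stats::runif(g * g)) / g
    extra <- n - g * g
    if (extra > 0) {
      x <- c(x, stats::runif(extra))
      y <- c(y, stats::runif(extra))
    }
    subcell <- pmin(floor(x * g), g - 1) + g * pmin(floor(y * g), g - 1) + 1
    structure(data.frame(x = x, y = y, subcell = as.integer(subcell)),
              n = n, grid = g, seed = seed,
              class = c("point_sample", "data.frame"))
  })
}

# index of the first region (file order) containing (x, y); NA if none
locate_region <- function(map, x, y) {
  hit <- which(x >= map$x0 & x <= map$x1 & y >= map$y0 & y <= map$y1)
  if (length(hit)) hit[1] else NA_integer_
}

#' Score sample points against a quadrat map
#'
#' Each point receives the label of its containing region; a point lying on a
#' shared boundary goes to the first matching region in file order
#' (deterministic tie-break). Points covered by no region -- impossible for a
#' map that tiles the canvas -- are scored `unknown` with a warning.
#'
#' @param map A [quadrat_map()].
#' @param sample A [spawn_stratified_points()] sample.
#' @return A `quadrat_score` data frame: one row per scored label class with
#'   columns `category`, `genus`, `morphology`, `health`, `count`.
#' @export
score_points <- function(map, sample) {
  if (!inherits(map, "quadrat_map")) stop_input("map must be a quadrat_map")
  if (!all(c("x", "y") %in% names(sample))) stop_input("sample needs x and y")
  idx <- mapply(locate_region, x = sample$x, y = sample$y,
                MoreArgs = list(map = map))
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " point(s) outside all regions scored as 'unknown'",
            call. = FALSE)
  }
  lab <- data.frame(
    category = ifelse(is.na(idx), "unknown", map$category[idx]),
    genus = map$genus[idx], morphology = map$morphology[idx],
    health = map$health[idx], stringsAsFactors = FALSE
  )
  key <- paste(lab$category, lab$genus, lab$morphology, lab$health, sep = "\r")
  tab <- table(key)
  first <- match(names(tab), key)
  tally <- data.frame(lab[first, , drop = FALSE],
                      count = as.integer(tab), row.names = NULL)
  tally <- tally[order(tally$category, tally$genus, tally$health), , drop = FALSE]
  rownames(tally) <- NULL
  structure(tally,
            quadrat_id = attr(map, "quadrat_id"),
            transect_id = attr(map, "transect_id"),
            n_points = nrow(sample),
            class = c("quadrat_score", "data.frame"))
}

#' Percent cover from a point-count tally
#'
#' With `basis = "all_points"` returns the substrate composition (percent of
#' all points per category). With `basis = "hard_coral_points"` returns the
#' composition of coral cover only (percent of hard-coral points), grouped by
#' `genus` x `health` or by `health` alone -- the denominators used for
#' bleaching summaries.
#'
#' @param score A [score_points()] tally.
#' @param basis `"all_points"` or `"hard_coral_points"`.
#' @param drop_unknown Drop `unknown` points and renormalise (substrate basis
#'   only; `unknown` never enters coral-health denominators).
#' @param grouping For the coral basis: `"genus_health"` (default) or
#'   `"health"`.
#' @return A data frame of grouping columns plus `count` and `percent`
#'   (0-100, summing to 100 over included classes). When the coral basis is
#'   requested but the quadrat holds no hard-coral points, a zero-row frame
#'   with attribute `no_coral = TRUE` is returned rather than an error.
#' @export
percent_cover <- function(score, basis = c("all_points", "hard_coral_points"),
                          drop_unknown = FALSE,
                          grouping = c("genus_health", "health")) {
  basis <- match.arg(basis)
  grouping <- match.arg(grouping)
  n <- attr(score, "n_points")
  if (is.null(n) || n == 0L) stop_input("score has no points")
  if (basis == "all_points") {
    df <- score
    if (drop_unknown) df <- df[df$category != "unknown", , drop = FALSE]
    agg <- stats::aggregate(count ~ category, data = df, sum)
    denom <- sum(agg$count)
    if (denom == 0L) stop_input("no points left after dropping 'unknown'")
    agg$percent <- 100 * agg$count / denom
    return(agg)
  }
  hc <- score[score$category == "hard_coral", , drop = FALSE]
  if (nrow(hc) == 0L || sum(hc$count) == 0L) {
    out <- if (grouping == "genus_health") {
      data.frame(genus = character(), health = character(),
                 count = integer(), percent = numeric())
    } else {
      data.frame(health = character(), count = integer(), percent = numeric())
    }
    attr(out, "no_coral") <- TRUE
    return(out)
  }
  agg <- if (grouping == "genus_health") {
    stats::aggregate(count ~ genus + health, data = hc, sum)
  } else {
    stats::aggregate(count ~ health, data = hc, sum)
  }
  agg$percent <- 100 * agg$count / sum(agg$count)
  agg
}

#' Transect-level mean and standard error of percent cover
#'
#' Aggregates quadrat-level percent-cover tables to the site level with
#' transects as the replicate unit: class percentages are first averaged
#' across the quadrats of each transect (classes absent from a quadrat count
#' as 0%), then the mean and standard error across transects are reported
#' (SE = sd / sqrt(number of transects)).
#'
#' @param covers A data frame stacking per-quadrat [percent_cover()] output
#'   with added columns `transect_id` and `quadrat_id`.
#' @param class_cols Character vector naming the class columns (e.g.
#'   `c("genus", "health")` or `"health"`).
#' @return A data frame of class columns plus `mean`, `se`, `n_transects`.
#'   With a single transect the SE is reported as `NA`.
#' @export
transect_summary <- function(covers, class_cols = "health") {
  need <- c(class_cols, "transect_id", "quadrat_id", "percent")
  if (!all(need %in% names(covers))) {
    stop_input("covers needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(covers) == 0L) stop_input("no cover rows supplied")
  covers$class <- do.call(paste, c(covers[class_cols], sep = "\r"))
  quads <- unique(covers[c("transect_id", "quadrat_id")])
  classes <- unique(covers[c(class_cols, "class")])
  # complete the class x quadrat grid: absent class = 0 percent
  grid <- merge(quads, classes["class"], by = NULL)
  grid <- merge(grid, covers[c("transect_id", "quadrat_id", "class", "percent")],
                by = c("transect_id", "quadrat_id", "class"), all.x = TRUE)
  grid$percent[is.na(grid$percent)] <- 0
  per_tr <- stats::aggregate(percent ~ transect_id + class, data = grid, mean)
  out <- stats::aggregate(percent ~ class, data = per_tr, function(p) {
    c(mean = mean(p), se = if (length(p) > 1) stats::sd(p) / sqrt(length(p)) else NA_real_,
      n = length(p))
  })
  stats_mat <- out$percent
  res <- merge(classes, data.frame(class = out$class,
                                   mean = stats_mat[, "mean"],
                                   se = stats_mat[, "se"],
                                   n_transects = as.integer(stats_mat[, "n"])),
               by = "class")
  res$class <- NULL
  res[do.call(order, res[class_cols]), , drop = FALSE] -> res
  rownames(res) <- NULL
  res
}

#' Tally colony health from a roving-diver survey
#'
#' Roving surveys score every colony a diver encounters in a timed swim;
#' they are used where coral cover is too sparse for transects.
#'
#' @param records Data frame with a `health` column (codes `UB`, `M`, `S`,
#'   `D`), one row per colony.
#' @param survey_id Label carried on the result.
#' @return A `health_tally` data frame with columns `health`, `count`,
#'   `percent` (all four categories always present, zeros kept).
#' @export
roving_tally <- function(records, survey_id = "roving") {
  if (!"health" %in% names(records)) stop_input("records need a 'health' column")
  n <- nrow(records)
  if (n == 0L) stop_input("no colony records")
  bad <- which(!records$health %in% HEALTH_LEVELS)
  if (length(bad)) {
    stop_input("unrecognised health code '", records$health[bad[1]],
               "' in record ", bad[1])
  }
  count <- vapply(HEALTH_LEVELS, function(h) sum(records$health == h), integer(1))
  structure(
    data.frame(health = HEALTH_LEVELS, count = count,
               percent = 100 * count / n, row.names = NULL),
    survey_id = survey_id, n_colonies = n,
    class = c("health_tally", "data.frame")
  )
}
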