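test_that("stratified sampler fills every sub-cell for all n and seeds", {
  s100 <- spawn_stratified_points(100, seed = 1)
  expect_equal(nrow(s100), 100)
  expect_equal(sort(unique(s100$subcell)), 1:100)  # 10x10, one per cell

  s5 <- spawn_stratified_points(5, seed = 2)
  expect_equal(nrow(s5), 5)
  expect_true(all(1:4 %in% s5$subcell))  # 2x2 grid occupied + 1 free point

  for (seed in 1:15) {
    n <- sample(1:60, 1)
    s <- spawn_stratified_points(n, seed = seed)
    g <- attr(s, "grid")
    expect_equal(nrow(s), n)
    expect_true(all(seq_len(g * g) %in% s$subcell))
    expect_true(all(s$x >= 0 & s$x <= 1 & s$y >= 0 & s$y <= 1))
  }
  expect_error(spawn_stratified_points(0), "n must be")
})

test_that("sampler and scoring are reproducible given the seed", {
  a <- spawn_stratified_points(100, seed = 99)
  b <- spawn_stratified_points(100, seed = 99)
  expect_identical(a, b)
  m <- two_strip_map(0.6)
  expect_identical(score_points(m, a), score_points(m, b))
})

test_that("score_points assigns labels, conserves tallies, breaks ties by file order", {
  m <- coral_map()
  s <- spawn_stratified_points(100, seed = 5)
  sc <- score_points(m, s)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$count, 100)
  expect_equal(sc$genus, "Acropora")
  expect_equal(sum(sc$count), attr(sc, "n_points"))

  # boundary point: both strips contain x = 0.6; first region in file order wins
  m2 <- two_strip_map(0.6, "rock", "sand_rubble")
  pt <- data.frame(x = 0.6, y = 0.5)
  sc2 <- score_points(m2, structure(pt, n = 1L, class = c("point_sample", "data.frame")))
  expect_equal(sc2$category, "rock")

  # point outside all regions: unknown with a warning
  m3 <- suppressWarnings(  # deliberately non-tiling map
    quadrat_map(data.frame(category = "rock", genus = NA, morphology = NA,
                           health = NA, x0 = 0, x1 = 0.5, y0 = 0, y1 = 1)))
  expect_warning(
    sc3 <- score_points(m3, data.frame(x = c(0.2, 0.9), y = 0.5)),
    "outside")
  expect_equal(sum(sc3$count[sc3$category == "unknown"]), 1)
})

test_that("cover estimates converge to true area shares (Monte-Carlo)", {
  # boundary off the stratification grid so the estimator has variance
  m <- two_strip_map(0.57)
  est <- vapply(1:400, function(seed) {
    sc <- score_points(m, spawn_stratified_points(100, seed = seed))
    pc <- percent_cover(sc, basis = "all_points")
    pc$percent[pc$category == "rock"]
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 57), 3 * se)

  # grid-aligned boundary: stratification removes the variance entirely
  m60 <- two_strip_map(0.6)
  est60 <- vapply(1:25, function(seed) {
    sc <- score_points(m60, spawn_stratified_points(100, seed = seed))
    pc <- percent_cover(sc, basis = "all_points")
    pc$percent[pc$category == "rock"]
  }, numeric(1))
  expect_equal(est60, rep(60, 25))
})

test_that("percent_cover handles both bases, renormalisation and no-coral", {
  mk_score <- function(df, n) structure(df, n_points = n,
                                        class = c("quadrat_score", "data.frame"))
  sc <- mk_score(data.frame(category = "hard_coral", genus = "Acropora",
                            morphology = "branching", health = c("UB", "D"),
                            count = c(50L, 50L)), 100L)
  pc <- percent_cover(sc, basis = "hard_coral_points")
  expect_equal(pc$percent[pc$health == "UB"], 50)
  expect_equal(pc$percent[pc$health == "D"], 50)

  sc2 <- mk_score(data.frame(category = c("hard_coral", "rock", "unknown"),
                             genus = c("Acropora", NA, NA),
                             morphology = c("branching", NA, NA),
                             health = c("UB", NA, NA),
                             count = c(40L, 40L, 20L)), 100L)
  pc2 <- percent_cover(sc2, basis = "all_points", drop_unknown = TRUE)
  expect_equal(sort(pc2$percent), c(50, 50))
  pc2b <- percent_cover(sc2, basis = "all_points")
  expect_equal(sum(pc2b$percent), 100)

  # random tallies equal the independent ratio oracle; sums are exact
  set.seed(7)
  for (k in 1:5) {
    counts <- as.integer(rmultinom(1, 100, runif(4)))
    sc3 <- mk_score(data.frame(category = "hard_coral", genus = "G",
                               morphology = "massive",
                               health = c("UB", "M", "S", "D"),
                               count = counts), 100L)
    pc3 <- percent_cover(sc3, basis = "hard_coral_points", grouping = "health")
    expect_equal(pc3$percent[match(c("UB", "M", "S", "D"), pc3$health)],
                 100 * counts / sum(counts))
    expect_equal(sum(pc3$percent), 100, tolerance = 1e-9)
  }

  # no hard coral at all: explicit empty result, not an error
  sc4 <- mk_score(data.frame(category = "rock", genus = NA, morphology = NA,
                             health = NA, count = 100L), 100L)
  pc4 <- percent_cover(sc4, basis = "hard_coral_points")
  expect_equal(nrow(pc4), 0)
  expect_true(attr(pc4, "no_coral"))
})

test_that("transect_summary computes mean and SE with transects as replicates", {
  covers <- data.frame(
    transect_id = c("T1", "T2"), quadrat_id = c("Q1", "Q2"),
    health = "UB", percent = c(80, 90))
  ts <- transect_summary(covers)
  expect_equal(ts$mean, 85)
  expect_equal(ts$se, 5)
  expect_equal(ts$n_transects, 2L)

  same <- data.frame(transect_id = c("T1", "T2", "T3"),
                     quadrat_id = paste0("Q", 1:3),
                     health = "S", percent = 40)
  expect_equal(transect_summary(same)$se, 0)

  one <- covers[1, ]
  expect_true(is.na(transect_summary(one)$se))

  # textbook mean/SE oracle over 6 random transects
  set.seed(21)
  p <- runif(6, 0, 100)
  covers6 <- data.frame(transect_id = paste0("T", 1:6),
                        quadrat_id = paste0("Q", 1:6),
                        health = "M", percent = p)
  ts6 <- transect_summary(covers6)
  expect_equal(ts6$mean, mean(p))
  expect_equal(ts6$se, sd(p) / sqrt(6))
})

test_that("absent classes count as zero within a transect", {
  covers <- data.frame(
    transect_id = c("T1", "T1", "T2"),
    quadrat_id = c("Q1", "Q1", "Q2"),
    health = c("UB", "S", "UB"),
    percent = c(50, 50, 100))
  ts <- transect_summary(covers)
  # transect T2 has 0% S, so S averages (50 + 0) / 2
  expect_equal(ts$mean[ts$health == "S"], 25)
})

test_that("roving_tally reproduces printed-count percentages and rejects bad codes", {
  dec <- data.frame(health = c(rep("UB", 41), rep("M", 4)))
  td <- roving_tally(dec)
  expect_equal(td$percent[td$health == "UB"], 100 * 41 / 45, tolerance = 1e-9)
  expect_equal(attr(td, "n_colonies"), 45L)

  mar <- data.frame(health = c(rep("UB", 72), rep("M", 6)))
  tm <- roving_tally(mar)
  expect_equal(round(tm$percent[tm$health == "UB"], 1), 92.3)

  alld <- roving_tally(data.frame(health = rep("D", 7)))
  expect_equal(alld$percent[alld$health == "D"], 100)
  expect_equal(sum(alld$count), 7L)

  expect_error(roving_tally(data.frame(health = c("UB", "X"))), "record 2")
})
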