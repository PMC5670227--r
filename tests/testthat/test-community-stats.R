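meta_for <- function(n) data.frame(site = "S", time = "t1",
                                   transect_id = paste0("T", seq_len(n)))

test_that("sqrt_transform is the element-wise root with state tracking", {
  m <- abundance_matrix(matrix(c(0, 100, 25, 49), 2), meta_for(2))
  s <- sqrt_transform(m)
  expect_equal(s$values, matrix(c(0, 10, 5, 7), 2))
  expect_equal(s$values^2, m$values)
  expect_error(sqrt_transform(s), "already transformed")
  expect_error(abundance_matrix(matrix(-1), meta_for(1)), "non-negative")

  set.seed(4)
  r <- matrix(runif(20, 0, 100), 4)
  expect_equal(sqrt_transform(abundance_matrix(r, meta_for(4)))$values, sqrt(r))
})

test_that("bray_curtis matches hand computation and metric properties", {
  x <- rbind(a = c(1, 2, 3), b = c(2, 1, 3))
  d <- bray_curtis(x)
  expect_equal(d["a", "b"], 2 / 12)

  same <- rbind(c(3, 1, 0), c(3, 1, 0))
  expect_equal(bray_curtis(same)[1, 2], 0)

  disjoint <- rbind(c(5, 0, 2, 0), c(0, 1, 0, 4))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)

  expect_warning(dz <- bray_curtis(rbind(c(0, 0), c(0, 0), c(1, 1))),
                 "all-zero")
  expect_equal(dz[1, 2], 0)

  set.seed(8)
  r <- matrix(rexp(30), 6)
  dr <- bray_curtis(r)
  expect_equal(unclass(dr), unclass(t(dr)))
  expect_true(all(dr >= 0 & dr <= 1))
  expect_equal(diag(dr), rep(0, 6), ignore_attr = TRUE)
  skip_if_not_installed("vegan")
  expect_equal(unclass(dr), as.matrix(vegan::vegdist(r, "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("one-way PERMANOVA reproduces the reference implementation", {
  skip_if_not_installed("vegan")
  for (seed in 1:5) {
    x <- rand_abundance(12, 6, seed)
    g <- factor(rep(c("a", "b", "c"), each = 4))
    d <- bray_curtis(x)
    mine <- permanova_oneway(d, g, n_perm = 99, seed = 1)
    ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
    expect_equal(mine$F[1], ref$F[1], tolerance = 1e-10)
    expect_equal(mine$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-10)
    expect_equal(mine$df[1:2], ref$Df[1:2])
  }
})

test_that("one-way SS partition is conserved and invariant to relabelling", {
  x <- rand_abundance(10, 5, 3)
  d <- bray_curtis(x)
  g <- factor(rep(1:2, each = 5))
  r <- permanova_oneway(d, g, n_perm = 49, seed = 1)
  expect_equal(r$SS[1] + r$SS[2], r$SS[3], tolerance = 1e-8)
  # relabelled groups, permuted rows: same F
  perm <- c(6:10, 1:5)
  r2 <- permanova_oneway(d[perm, perm], factor(c(rep("B", 5), rep("A", 5))),
                         n_perm = 49, seed = 1)
  expect_equal(r2$F[1], r$F[1], tolerance = 1e-10)
  # reproducibility
  expect_identical(permanova_oneway(d, g, n_perm = 99, seed = 7)$p[1],
                   permanova_oneway(d, g, n_perm = 99, seed = 7)$p[1])
})

test_that("exact enumeration equals the brute-force oracle at N = 6", {
  for (seed in 1:3) {
    x <- rand_abundance(6, 4, seed + 30)
    d <- bray_curtis(x)
    g <- factor(rep(1:2, each = 3))
    mine <- permanova_oneway(d, g, method = "exact")
    expect_equal(mine$p[1], oracle_exact_p(unclass(d), g), tolerance = 1e-12)
  }
})

test_that("perfectly separated clouds reach the permutation floor", {
  # groups of 10: the chance a random permutation reproduces the exact
  # partition (and ties the observed F) is ~1e-5, so the floor is attainable
  set.seed(12)
  x <- rbind(matrix(rnorm(40, 0, 0.05), 10), matrix(rnorm(40, 50, 0.05), 10))
  x <- abs(x)
  d <- bray_curtis(x)
  r <- permanova_oneway(d, factor(rep(1:2, each = 10)), n_perm = 199, seed = 2)
  expect_equal(r$p[1], 1 / 200)
})

test_that("Euclidean one-way PERMANOVA equals classical ANOVA F", {
  set.seed(5)
  y <- rnorm(15)
  g <- factor(rep(1:3, each = 5))
  d <- as.matrix(dist(y))
  r <- permanova_oneway(d, g, n_perm = 49, seed = 1)
  ref <- summary(aov(y ~ g))[[1]]
  expect_equal(r$F[1], ref$`F value`[1], tolerance = 1e-10)
  expect_equal(r$SS[1:2], ref$`Sum Sq`, tolerance = 1e-10)
})

test_that("single-member groups and degenerate designs are rejected", {
  d <- bray_curtis(rand_abundance(5, 4, 2))
  expect_error(permanova_oneway(d, factor(c(1, 1, 1, 1, 2)), n_perm = 9),
               "single member.*2")
  expect_error(permanova_oneway(d, factor(rep(1, 5)), n_perm = 9),
               "at least 2 groups")
})

test_that("two-way SS partition matches classical sequential ANOVA (Euclidean)", {
  set.seed(6)
  a <- factor(rep(1:2, each = 9))
  b <- factor(rep(rep(1:3, each = 3), 2))
  y <- rnorm(18) + as.numeric(a) + 0.5 * as.numeric(b)
  d <- as.matrix(dist(y))
  r <- permanova_twoway(d, a, b, n_perm = 49, seed = 1)
  ref <- anova(lm(y ~ a * b))
  expect_equal(r$SS[1:3], ref$`Sum Sq`[1:3], tolerance = 1e-8)
  expect_equal(r$SS[4], ref$`Sum Sq`[4], tolerance = 1e-8)
  expect_equal(r$F[1:3], ref$`F value`[1:3], tolerance = 1e-8)
  expect_equal(r$df[1:4], ref$Df)
  # SS conservation
  expect_equal(sum(r$SS[1:4]), r$SS[5], tolerance = 1e-8)
})

test_that("a single-level second factor reduces to the one-way analysis", {
  x <- rand_abundance(10, 5, 9)
  d <- bray_curtis(x)
  a <- factor(rep(1:2, each = 5))
  b <- factor(rep("only", 10))
  r2 <- permanova_twoway(d, a, b, n_perm = 99, seed = 3)
  r1 <- permanova_oneway(d, a, n_perm = 99, seed = 3)
  expect_equal(r2$SS[r2$term == "B"], 0, tolerance = 1e-10)
  expect_equal(r2$df[r2$term == "B"], 0)
  expect_equal(r2$SS[1], r1$SS[1], tolerance = 1e-10)
  expect_equal(r2$F[1], r1$F[1], tolerance = 1e-10)
})

test_that("two-way design validation catches empty cells and aliasing", {
  x <- rand_abundance(8, 4, 13)
  d <- bray_curtis(x)
  a <- factor(rep(1:2, each = 4))
  b_empty <- factor(c(1, 1, 2, 2, 1, 1, 1, 1))
  expect_error(permanova_twoway(d, a, b_empty, n_perm = 9), "empty design cell")
  expect_error(permanova_twoway(d, a, a, n_perm = 9), "aliased")
})

test_that("interaction test holds its size under an additive null", {
  # balanced 2x2, moderate additive shifts, no interaction: rejection ~ alpha.
  # Unrestricted permutation of raw observations (the implemented scheme) is
  # only approximately exact for interactions and turns conservative when
  # main effects dominate the residual scale, so the null here uses shifts
  # comparable to the noise.
  n_sim <- 200
  rej <- 0
  set.seed(2024)
  for (k in seq_len(n_sim)) {
    a <- factor(rep(1:2, each = 6))
    b <- factor(rep(rep(1:2, each = 3), 2))
    y <- matrix(rexp(12 * 4), 12) + 0.5 * as.numeric(a) + 0.3 * as.numeric(b)
    d <- bray_curtis(y)
    r <- permanova_twoway(d, a, b, n_perm = 199, seed = sample.int(1e6, 1))
    if (r$p[r$term == "A:B"] <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_sim, 0.03 - 1e-9)
  expect_lte(rej / n_sim, 0.07 + 1e-9)
})

test_that("Holm adjustment follows the sequential-Bonferroni ladder", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)                  # m = 1: no correction
  expect_equal(min(holm_adjust(rep(0.02, 4))), 0.08)   # first step m * p0
  set.seed(31)
  for (k in 1:5) {
    p <- runif(sample(2:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, p.adjust(p, "holm"))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("pairwise post hoc runs all pairs and adjusts", {
  x <- rand_abundance(12, 5, 17)
  d <- bray_curtis(x)
  g <- factor(rep(c("a", "b", "c"), each = 4))
  pw <- pairwise_posthoc(d, g, n_perm = 99, seed = 5)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adj, holm_adjust(pw$p_raw))
  # each pair's F agrees with a direct one-way on the subset
  sel <- g %in% c("a", "b")
  r_ab <- permanova_oneway(d[sel, sel], droplevels(g[sel]), n_perm = 9, seed = 1)
  expect_equal(pw$F[pw$group1 == "a" & pw$group2 == "b"], r_ab$F[1],
               tolerance = 1e-10)
})

test_that("PCA on the covariance matrix behaves like the reference", {
  # collinear data: one component carries all variance
  line <- cbind(1:6, 2 * (1:6))
  p1 <- pca(line * 1.0)
  expect_equal(p1$proportion[1], 1)

  set.seed(41)
  x <- matrix(runif(40, 0, 10), 8)
  p <- pca(x)
  expect_true(all(p$eigenvalues >= 0))
  expect_equal(sum(p$proportion), 1)
  # full-rank reconstruction of the centred data
  xc <- scale(x, center = TRUE, scale = FALSE)
  expect_equal(p$scores %*% t(p$loadings), unclass(xc), tolerance = 1e-8,
               ignore_attr = TRUE)
  # eigenvalue spectrum matches prcomp and survives orthogonal rotation
  expect_equal(p$eigenvalues, unname(prcomp(x)$sdev^2), tolerance = 1e-9)
  qr_q <- qr.Q(qr(matrix(rnorm(25), 5)))
  p_rot <- pca(x %*% qr_q)
  expect_equal(p_rot$eigenvalues, p$eigenvalues, tolerance = 1e-8)
  # sign convention: dominant loading positive
  expect_true(all(apply(p$loadings, 2, function(v) v[which.max(abs(v))] > 0)))

  expect_error(pca(matrix(1, 4, 3)), "zero variance")
})

test_that("chi_square matches the textbook computation and the reference", {
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chi_square(prop)$statistic, 0, tolerance = 1e-12)

  set.seed(19)
  for (k in 1:5) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    mine <- chi_square(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(mine$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter))
  }

  t22 <- matrix(c(12, 5, 9, 14), 2)
  yates <- chi_square(t22, correction = "yates")
  refy <- suppressWarnings(chisq.test(t22, correct = TRUE))
  expect_equal(yates$statistic, unname(refy$statistic), tolerance = 1e-12)

  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
})
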