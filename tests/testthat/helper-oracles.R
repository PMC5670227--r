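# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / direct formulas, without touching the package
# code paths they check.

# windowed-sum DHD: loop over dates, filter the trailing window explicitly
oracle_dhd <- function(dates, anomaly, rule, window_days) {
  full <- seq(min(dates), max(dates), by = "day")
  a <- rep(NA_real_, length(full))
  a[match(dates, full)] <- anomaly
  vapply(seq_along(full), function(i) {
    win <- full > full[i] - window_days & full <= full[i]
    v <- a[win]
    v[is.na(v)] <- 0
    keep <- if (rule == "all_positive") v > 0 else v >= 1
    sum(v[keep])
  }, numeric(1))
}

# one-way pseudo-F straight from the defining sums, double loops and all
oracle_oneway_f <- function(D, groups) {
  groups <- as.factor(groups)
  n <- nrow(D)
  a <- nlevels(groups)
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + D[i, j]^2
  sst <- sst / n
  ssw <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    acc <- 0
    for (i in idx) for (j in idx) if (i < j) acc <- acc + D[i, j]^2
    ssw <- ssw + acc / length(idx)
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

# all permutations of 1..n, independent of the package's generator
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  do.call(rbind, lapply(seq_len(n), function(k) {
    sub <- oracle_perms(n - 1)
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# exact permutation p for a one-way design by full enumeration
oracle_exact_p <- function(D, groups) {
  f_obs <- oracle_oneway_f(D, groups)
  perms <- oracle_perms(length(groups))
  f_all <- apply(perms, 1, function(p) oracle_oneway_f(D, groups[p]))
  mean(f_all >= f_obs - 1e-12)
}

# small random abundance-style matrix (non-negative, sparse-ish)
rand_abundance <- function(n, k, seed) {
  reefbleach:::with_seed(seed, {
    m <- matrix(stats::rexp(n * k), n, k)
    m[m < 0.4] <- 0
    m
  })
}

# a flat 15-minute temperature series with prescribed daily anomalies
series_from_daily <- function(daily_anomaly, mmm, site = "S",
                              start = as.Date("2016-01-01"), habitat = "unspecified") {
  days <- start + seq_along(daily_anomaly) - 1
  stamps <- rep(as.POSIXct(paste(days, "00:00:00"), tz = "UTC"), each = 96) +
    rep(seq(0, by = 900, length.out = 96), times = length(days))
  temperature_series(stamps, rep(mmm + daily_anomaly, each = 96),
                     site_id = site, habitat = habitat)
}

# two-strip map: fraction p of category a, rest category b
two_strip_map <- function(p, cat_a = "rock", cat_b = "sand_rubble",
                          quadrat_id = "Q1", transect_id = "T1") {
  quadrat_map(data.frame(
    category = c(cat_a, cat_b), genus = NA_character_,
    morphology = NA_character_, health = NA_character_,
    x0 = c(0, p), x1 = c(p, 1), y0 = 0, y1 = 1
  ), quadrat_id = quadrat_id, transect_id = transect_id)
}

# single-class coral map
coral_map <- function(genus = "Acropora", morphology = "branching",
                      health = "UB", quadrat_id = "Q1") {
  quadrat_map(data.frame(
    category = "hard_coral", genus = genus, morphology = morphology,
    health = health, x0 = 0, x1 = 1, y0 = 0, y1 = 1
  ), quadrat_id = quadrat_id)
}
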