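# Multivariate and categorical statistics for community comparisons:
# square-root transform, Bray-Curtis dissimilarity, one- and two-way
# PERMANOVA with permutation p-values, Holm (sequential Bonferroni) pairwise
# tests, covariance PCA and Pearson chi-square. All test statistics are
# computed from first principles here; no external multivariate package is
# used at run time.

#' Construct an abundance matrix with row metadata
#'
#' Rows are transects (the replicate unit), columns are community classes
#' (typically genus x health), values are percent abundance on the 0-100
#' scale.
#'
#' @param values Non-negative numeric matrix, transects x classes.
#' @param meta Data frame of row metadata (e.g. `site`, `habitat`, `time`,
#'   `transect_id`), one row per transect.
#' @param transform `"raw"` or `"sqrt"` (state flag; see [sqrt_transform()]).
#' @return An `abundance_matrix` object.
#' @export
abundance_matrix <- function(values, meta, transform = "raw") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_input("values must be numeric")
  if (anyNA(values)) stop_input("values contain NA")
  if (any(values < 0)) stop_input("abundances must be non-negative")
  if (!is.data.frame(meta) || nrow(meta) != nrow(values)) {
    stop_input("meta must be a data frame with one row per matrix row")
  }
  transform <- match.arg(transform, c("raw", "sqrt"))
  structure(list(values = values, meta = meta, transform = transform),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix:", nrow(x$values), "rows x", ncol(x$values),
      "classes, transform =", x$transform, "\n")
  invisible(x)
}

#' Square-root transform an abundance matrix
#'
#' The standard variance-stabilising transform applied to percent-abundance
#' data before Bray-Curtis/PERMANOVA, down-weighting dominant classes.
#'
#' @param m An `abundance_matrix` in state `"raw"`.
#' @return The matrix with element-wise square roots, state `"sqrt"`.
#' @export
sqrt_transform <- function(m) {
  if (!inherits(m, "abundance_matrix")) stop_input("m must be an abundance_matrix")
  if (m$transform != "raw") stop_input("matrix is already transformed")
  abundance_matrix(sqrt(m$values), m$meta, transform = "sqrt")
}

as_values <- function(m, warn_raw = FALSE, what = "input") {
  if (inherits(m, "abundance_matrix")) {
    if (warn_raw && m$transform == "raw") {
      warning(what, " is untransformed (state 'raw'); the conventional ",
              "workflow square-root transforms first", call. = FALSE)
    }
    m$values
  } else {
    as.matrix(m)
  }
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(i, j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk), bounded in `[0, 1]`
#' (0 identical composition, 1 disjoint support). Bray-Curtis is a
#' semimetric: the triangle inequality is not guaranteed. A pair of all-zero
#' rows has an undefined ratio and is defined as 0 with a warning.
#'
#' @param m An `abundance_matrix` (warns if state `"raw"`) or plain matrix
#'   with at least 2 rows.
#' @return A symmetric `dissimilarity` matrix with zero diagonal.
#' @export
bray_curtis <- function(m) {
  x <- as_values(m, warn_raw = TRUE, what = "abundance matrix")
  if (nrow(x) < 2L) stop_input("need at least 2 rows to form dissimilarities")
  num <- as.matrix(stats::dist(x, method = "manhattan"))
  rs <- rowSums(x)
  den <- outer(rs, rs, "+")
  if (any(den == 0 & upper.tri(den))) {
    warning("pair(s) of all-zero rows: dissimilarity defined as 0", call. = FALSE)
  }
  d <- ifelse(den > 0, num / den, 0)
  diag(d) <- 0
  lab <- rownames(x) %||% as.character(seq_len(nrow(x)))
  dimnames(d) <- list(lab, lab)
  structure(d, class = c("dissimilarity", "matrix"))
}

as_dist_matrix <- function(d) {
  d <- if (inherits(d, "dist")) as.matrix(d) else unclass(as.matrix(d))
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12) {
    stop_input("d must be a symmetric distance matrix")
  }
  d
}

# within-group sum of squared distances: sum over groups of
# (1/n_g) * sum_{i<j in g} d_ij^2
ss_within <- function(D2, groups) {
  s <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  }
  s
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.integer(block)
    r <- r + nrow(sub)
  }
  out
}

permanova_table <- function(terms, df, ss, df_res, ss_res, n, p) {
  ms <- ifelse(df > 0, ss / df, NA_real_)
  ms_res <- ss_res / df_res
  data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df, df_res, n - 1L),
    SS = c(ss, ss_res, sum(ss) + ss_res),
    MS = c(ms, ms_res, NA_real_),
    F = c(ms / ms_res, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_),
    row.names = NULL
  )
}

#' One-way PERMANOVA
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components and tests the pseudo-F statistic
#' `F = (SS_A / (a-1)) / (SS_W / (N-a))` by unrestricted permutation of the
#' group labels. The p-value estimator includes the observed statistic,
#' `p = (b + 1) / (n_perm + 1)`, so p > 0 always; ties (permuted F equal to
#' observed) count towards b (conservative). `method = "exact"` enumerates
#' all N! label permutations instead (small N only) and returns the exact
#' permutation p-value.
#'
#' @param d Dissimilarity matrix (`dissimilarity`, `dist`, or plain
#'   symmetric matrix).
#' @param groups Factor (or coercible) of group labels, >= 2 groups with
#'   >= 2 members each.
#' @param n_perm Number of random permutations (default 9999).
#' @param seed Integer seed for the permutation stream.
#' @param method `"sampled"` (default) or `"exact"`.
#' @return A `permanova` object: the ANOVA-style table plus attributes
#'   `n_perm`, `seed`, `method`.
#' @export
permanova_oneway <- function(d, groups, n_perm = 9999, seed = NULL,
                             method = c("sampled", "exact")) {
  method <- match.arg(method)
  D2 <- as_dist_matrix(d)^2
  groups <- droplevels(as.factor(groups))
  n <- nrow(D2)
  if (length(groups) != n) stop_input("groups length must match d")
  a <- nlevels(groups)
  if (a < 2L) stop_input("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2L)) {
    stop_input("group(s) with a single member: ",
               paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  ss_t <- sum(D2) / (2 * n)
  f_stat <- function(g) {
    ssw <- ss_within(D2, g)
    ((ss_t - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_stat(groups)
  if (method == "exact") {
    if (n > 9L) stop_input("exact enumeration limited to n <= 9")
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1, function(p) f_stat(groups[p]))
    p_val <- mean(f_perm >= f_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    p_val <- with_seed(seed, {
      b <- 0L
      for (k in seq_len(n_perm)) {
        if (f_stat(groups[sample.int(n)]) >= f_obs - 1e-12) b <- b + 1L
      }
      (b + 1) / (n_perm + 1)
    })
  }
  ssw_obs <- ss_within(D2, groups)
  tab <- permanova_table("groups", a - 1L, ss_t - ssw_obs,
                         n - a, ssw_obs, n, p_val)
  structure(tab, n_perm = n_perm, seed = seed, method = method,
            class = c("permanova", "data.frame"))
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Two-way crossed PERMANOVA
#'
#' Distance-based linear-model partition: the Gower-centred matrix
#' `G = C (-1/2 D^2) C` (with `C = I - 11'/n`) is projected onto sequential
#' design subspaces -- factor A, then B adjusted for A, then the A:B
#' interaction adjusted for both (Type I sums of squares in the order given).
#' Each term's pseudo-F uses the residual mean square; p-values come from
#' unrestricted permutation of the observations, recomputing every term per
#' permutation. On Euclidean distances of univariate data the partition
#' reproduces classical sequential two-way ANOVA exactly.
#'
#' @inheritParams permanova_oneway
#' @param a,b Crossed factors (every A x B cell must be non-empty).
#' @param term_names Length-3 labels for the A, B and interaction rows.
#' @return A `permanova` object with one row per term plus residual/total.
#' @export
permanova_twoway <- function(d, a, b, n_perm = 9999, seed = NULL,
                             term_names = c("A", "B", "A:B")) {
  D2 <- as_dist_matrix(d)^2
  n <- nrow(D2)
  a <- droplevels(as.factor(a)); b <- droplevels(as.factor(b))
  if (length(a) != n || length(b) != n) stop_input("factor lengths must match d")
  if (nlevels(a) < 2L) stop_input("factor A needs at least 2 levels")
  if (nlevels(b) > 1L && nlevels(interaction(a, b, drop = TRUE)) == nlevels(a)) {
    stop_input("factors A and B are aliased (B is a relabelling of A)")
  }
  cells <- table(a, b)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1, ]
    stop_input("empty design cell: A = ", levels(a)[empty[1]],
               ", B = ", levels(b)[empty[2]])
  }
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% (-0.5 * D2) %*% C
  X1 <- matrix(1, n, 1)
  XA <- stats::model.matrix(~a)
  # a single-level B degenerates gracefully: its (and the interaction's)
  # design subspace collapses onto A's, giving SS = 0 with 0 df
  XB <- if (nlevels(b) > 1L) stats::model.matrix(~ a + b) else XA
  XF <- if (nlevels(b) > 1L) stats::model.matrix(~ a * b) else XA
  H1 <- hat_matrix(X1); HA <- hat_matrix(XA)
  HB <- hat_matrix(XB); HF <- hat_matrix(XF)
  inc <- list(HA - H1, HB - HA, HF - HB)
  df <- c(qr(XA)$rank - 1L, qr(XB)$rank - qr(XA)$rank,
          qr(XF)$rank - qr(XB)$rank)
  df_res <- n - qr(XF)$rank
  if (df_res < 1L) stop_input("no residual degrees of freedom (need replication within cells)")
  ss_terms <- function(Gm) vapply(inc, function(H) sum(H * Gm), numeric(1))
  tot <- sum(diag(G))
  ss_obs <- ss_terms(G)
  ss_res_obs <- tot - sum(ss_obs)
  active <- df > 0L
  f_of <- function(ss, ss_res) ifelse(df > 0, (ss / pmax(df, 1)) / (ss_res / df_res), NA_real_)
  f_obs <- f_of(ss_obs, ss_res_obs)
  counts <- rep(0L, 3L)
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      p <- sample.int(n)
      Gp <- G[p, p]
      ssp <- ss_terms(Gp)
      fp <- f_of(ssp, tot - sum(ssp))
      counts <- counts + as.integer(active & !is.na(fp) & fp >= f_obs - 1e-12)
    }
  })
  p_val <- ifelse(active, (counts + 1) / (n_perm + 1), NA_real_)
  tab <- permanova_table(term_names, df, ss_obs, df_res, ss_res_obs, n, p_val)
  structure(tab, n_perm = n_perm, seed = seed, method = "sampled",
            class = c("permanova", "data.frame"))
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", attr(x, "method"), ", n_perm = ", attr(x, "n_perm"),
      ", seed = ", attr(x, "seed") %||% "NULL", ")\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Holm sequential Bonferroni adjustment
#'
#' Step-down family-wise error control: sort the m raw p-values ascending and
#' set `p_adj(i) = max_{j <= i} min(1, (m - j + 1) * p_raw(j))`; adjusted
#' values are monotone non-decreasing in the raw ordering.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  if (any(is.na(p) | p < 0 | p > 1)) stop_input("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  stepped <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(stepped)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pairwise one-way PERMANOVAs with sequential Bonferroni correction
#'
#' Runs a one-way PERMANOVA for every pair of groups and adjusts the raw
#' permutation p-values with [holm_adjust()].
#'
#' @inheritParams permanova_oneway
#' @return A data frame with columns `group1`, `group2`, `F`, `p_raw`,
#'   `p_adj`; attributes `n_perm`, `seed`.
#' @export
pairwise_posthoc <- function(d, groups, n_perm = 9999, seed = NULL) {
  D <- as_dist_matrix(d)
  groups <- droplevels(as.factor(groups))
  lev <- levels(groups)
  if (length(lev) < 2L) stop_input("need at least 2 groups")
  pairs <- utils::combn(lev, 2)
  seeds <- with_seed(seed, replicate(ncol(pairs), draw_seed()))
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    sel <- groups %in% pairs[, k]
    res <- permanova_oneway(D[sel, sel, drop = FALSE], groups[sel],
                            n_perm = n_perm, seed = seeds[k])
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               F = res$F[1], p_raw = res$p[1])
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holm_adjust(out$p_raw)
  structure(out, n_perm = n_perm, seed = seed,
            class = c("pairwise_permanova", "data.frame"))
}

#' Principal component analysis on the covariance matrix
#'
#' Eigen-decomposition of the column variance-covariance matrix of the
#' (typically square-root transformed) abundance data; scores are the
#' centred data projected on the eigenvectors. Sign convention: within each
#' component the largest-magnitude loading is positive. Eigenvalues below
#' numerical zero are clamped to 0.
#'
#' @param m An `abundance_matrix` (warns if raw) or plain matrix, >= 3 rows.
#' @return A `reef_pca` list: `eigenvalues`, `loadings`, `scores`,
#'   `proportion` (variance proportions summing to 1).
#' @export
pca <- function(m) {
  x <- as_values(m, warn_raw = TRUE, what = "abundance matrix")
  if (nrow(x) < 3L) stop_input("PCA needs at least 3 rows")
  xc <- scale(x, center = TRUE, scale = FALSE)
  cv <- stats::cov(xc)
  e <- eigen(cv, symmetric = TRUE)
  ev <- e$values
  if (any(ev < -1e-9 * max(abs(ev), 1))) stop_input("covariance matrix not PSD")
  ev <- pmax(ev, 0)
  if (sum(ev) <= 1e-12) stop_input("zero variance: all rows identical")
  V <- e$vectors
  flip <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  V <- sweep(V, 2, flip, `*`)
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  rownames(V) <- colnames(x)
  scores <- xc %*% V
  structure(list(eigenvalues = ev, loadings = V, scores = scores,
                 proportion = ev / sum(ev)),
            class = "reef_pca")
}

#' @export
print.reef_pca <- function(x, ...) {
  cat("PCA:", length(x$eigenvalues), "components; variance proportions:",
      paste(signif(x$proportion[seq_len(min(4, length(x$proportion)))], 3),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts
#' `E = row_total x col_total / grand_total`, df `(r-1)(c-1)`, and upper-tail
#' p from the chi-square distribution. No continuity correction by default;
#' `correction = "yates"` subtracts 0.5 from each `|O - E|`.
#'
#' @param tab Matrix (or table) of non-negative counts, >= 2 rows and
#'   columns, no zero row/column margin.
#' @param correction `"none"` (default) or `"yates"`.
#' @return A `chisq_result` list: `statistic`, `df`, `p_value`, `expected`,
#'   `correction`.
#' @export
chi_square <- function(tab, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  O <- as.matrix(tab)
  if (any(O < 0) || anyNA(O)) stop_input("counts must be non-negative")
  if (nrow(O) < 2L || ncol(O) < 2L) stop_input("need at least a 2 x 2 table")
  N <- sum(O)
  if (N <= 0) stop_input("grand total must be positive")
  rt <- rowSums(O); ct <- colSums(O)
  if (any(rt == 0)) stop_input("zero row margin: row ", which(rt == 0)[1])
  if (any(ct == 0)) stop_input("zero column margin: column ", which(ct == 0)[1])
  E <- outer(rt, ct) / N
  dev <- abs(O - E)
  if (correction == "yates") dev <- pmax(dev - 0.5, 0)
  x2 <- sum(dev^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  structure(list(statistic = x2, df = df,
                 p_value = stats::pchisq(x2, df, lower.tail = FALSE),
                 expected = E, correction = correction),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X^2 = %.4g, df = %d, p = %.4g (%s)\n",
              x$statistic, x$df, x$p_value, x$correction))
  invisible(x)
}
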