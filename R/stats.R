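# Shared statistical primitives: quantile normalization, the T / log2
# median-ratio (LMR) feature statistic, permutation empirical nulls,
# empirical p-values, Stouffer combination, and the Z-score transform.

#' Quantile normalization
#'
#' Forces every column to share one value distribution: the vector of
#' row-wise means of the column-sorted matrix, placed back by within-column
#' rank.  Tied values within a column receive the mean of the reference
#' values their ranks span, so the result is deterministic.
#'
#' @param x Numeric matrix (features x samples), no missing values.
#' @param na_ok If `TRUE`, missing cells are tolerated: each column's
#'   non-missing values are mapped onto the reference distribution by
#'   interpolation at their rank quantiles. Off by default because the
#'   strict contract is no-missing.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x, na_ok = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop_value("quantile_normalize: need at least one column")
  if (anyNA(x)) {
    if (!na_ok) stop_value("quantile_normalize: missing values are not allowed")
    return(quantile_normalize_na(x))
  }
  sorted <- apply(x, 2L, sort)
  if (is.null(dim(sorted))) sorted <- matrix(sorted, ncol = ncol(x))
  ref <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    xs <- x[ord, j]
    # tied values share the mean of the reference values their ranks span
    out[ord, j] <- stats::ave(ref, match(xs, xs))
  }
  out
}

# NA-tolerant variant: reference distribution from row means of the sorted
# complete columns' quantile curves, evaluated at each column's own rank grid.
quantile_normalize_na <- function(x) {
  n <- nrow(x)
  probs <- (seq_len(n) - 0.5) / n
  qcols <- apply(x, 2L, function(col) {
    stats::quantile(col, probs = probs, na.rm = TRUE, names = FALSE, type = 7)
  })
  ref <- rowMeans(qcols)
  out <- x
  for (j in seq_len(ncol(x))) {
    ok <- !is.na(x[, j])
    m <- sum(ok)
    if (m == 0L) next
    r <- rank(x[ok, j], ties.method = "average")
    out[ok, j] <- stats::approx(probs, ref, xout = (r - 0.5) / m, rule = 2)$y
  }
  out
}

#' Per-feature T and log2-median-ratio
#'
#' The two-statistic pair used throughout: a pooled-variance two-sample
#' Student t computed on the analysis (log2) scale, and the log2 ratio of
#' group medians computed on the intensity scale.  For odd group sizes the
#' median commutes with `2^x`, so the LMR equals the difference of log2
#' medians; for even sizes the intensity-scale median is used as stated.
#'
#' @param values_a,values_b Numeric vectors for the two groups.
#' @param scale `"log2"` (default; values are log2 intensities) or
#'   `"intensity"` (raw scale; T is computed on `log2(values)`).
#' @return A list of class `"feature_statistic"` with elements `T`, `LMR`,
#'   `direction` (`"up"`, `"down"`, `"none"`), and flags `t_defined`,
#'   `lmr_defined`.
#' @export
feature_statistic <- function(values_a, values_b, scale = c("log2", "intensity")) {
  scale <- match.arg(scale)
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (scale == "intensity") {
    a <- a[a > 0]; b <- b[b > 0]
    la <- log2(a); lb <- log2(b)
    ia <- a; ib <- b
  } else {
    la <- a; lb <- b
    ia <- 2^a; ib <- 2^b
  }
  t_defined <- length(la) >= 2L && length(lb) >= 2L
  Tstat <- NA_real_
  if (t_defined) {
    na <- length(la); nb <- length(lb)
    sp2 <- ((na - 1) * stats::var(la) + (nb - 1) * stats::var(lb)) / (na + nb - 2)
    if (sp2 <= 0) {
      if (mean(la) == mean(lb)) {
        Tstat <- 0
      } else {
        t_defined <- FALSE
      }
    } else {
      Tstat <- (mean(la) - mean(lb)) / sqrt(sp2 * (1 / na + 1 / nb))
    }
  }
  lmr_defined <- length(ia) >= 1L && length(ib) >= 1L
  LMR <- NA_real_
  if (lmr_defined) {
    ma <- stats::median(ia); mb <- stats::median(ib)
    if (ma <= 0 || mb <= 0) lmr_defined <- FALSE else LMR <- log2(ma / mb)
  }
  direction <- if (!lmr_defined || LMR == 0) "none" else if (LMR > 0) "up" else "down"
  structure(list(T = Tstat, LMR = LMR, direction = direction,
                 t_defined = t_defined, lmr_defined = lmr_defined),
            class = "feature_statistic")
}

# Vectorized T/LMR over the rows of a log2 matrix for two column index sets.
# NA cells are treated as unquantified.  Returns a data.frame with columns
# T and LMR (NA where undefined: <2 finite per group for T, <1 for LMR).
row_feature_stats <- function(log2_mat, idx_a, idx_b) {
  A <- log2_mat[, idx_a, drop = FALSE]
  B <- log2_mat[, idx_b, drop = FALSE]
  na_cnt <- rowSums(is.finite(A))
  nb_cnt <- rowSums(is.finite(B))
  if (!anyNA(A) && !anyNA(B)) {
    na <- ncol(A); nb <- ncol(B)
    ma <- rowMeans(A); mb <- rowMeans(B)
    va <- (rowSums(A * A) - na * ma * ma) / (na - 1)
    vb <- (rowSums(B * B) - nb * mb * mb) / (nb - 1)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    Tv <- ifelse(sp2 > 0, (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb)),
                 ifelse(ma == mb, 0, NA_real_))
    LMR <- log2(row_medians(2^A) / row_medians(2^B))
  } else {
    n <- nrow(log2_mat)
    Tv <- rep(NA_real_, n); LMR <- rep(NA_real_, n)
    ok_t <- na_cnt >= 2L & nb_cnt >= 2L
    ok_l <- na_cnt >= 1L & nb_cnt >= 1L
    for (i in which(ok_t | ok_l)) {
      fs <- feature_statistic(A[i, ], B[i, ], scale = "log2")
      if (fs$t_defined) Tv[i] <- fs$T
      if (fs$lmr_defined) LMR[i] <- fs$LMR
    }
  }
  Tv[na_cnt < 2L | nb_cnt < 2L] <- NA_real_
  data.frame(T = Tv, LMR = LMR)
}

# All distinct assignments of n_a "A" labels over n samples, as a matrix of
# column-index sets for group A (one row per relabeling, identity included).
all_relabelings <- function(n, n_a) {
  t(utils::combn(n, n_a))
}

#' Build a permutation empirical null
#'
#' Shuffles group labels over the sample axis (or matrix elements), recomputes
#' the T and LMR statistics for every feature, and pools all permuted values
#' into one null per comparison.  When the number of distinct relabelings does
#' not exceed `n_perm` (e.g. 20 for a 3-vs-3 design), all are enumerated with
#' a warning; otherwise `n_perm` distinct relabelings are sampled.  The LMR
#' cutoff is the mean of the absolute values of the configured lower/upper
#' percentiles of the pooled null LMR distribution.
#'
#' @param data Numeric log2 matrix, features x samples. `NA` = unquantified.
#' @param labels Factor/character of length `ncol(data)` with two levels; the
#'   first level of `factor(labels)` is group A.
#' @param scheme `"channel_permutation"` (proteome), `"sample_resampling"`
#'   (bootstrap within the pooled samples), or `"element_permutation"`.
#' @param n_perm Number of permutations requested.
#' @param seed Integer seed; identical seeds give identical nulls.
#' @param lmr_percentiles Length-2 percent pair for the cutoff.
#' @return An object of class `"empirical_null"`: `null_T`, `null_LMR`
#'   (pooled, NA dropped), `lmr_cutoff`, `scheme`, `n_perm` (performed),
#'   `seed`, `lmr_percentiles`.
#' @export
build_empirical_null <- function(data, labels,
                                 scheme = c("channel_permutation",
                                            "sample_resampling",
                                            "element_permutation"),
                                 n_perm = 100L, seed = 1L,
                                 lmr_percentiles = c(5, 95)) {
  scheme <- match.arg(scheme)
  data <- as.matrix(data)
  if (n_perm < 1L) stop_config("n_perm must be >= 1")
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop_config("labels must define exactly two groups")
  n <- ncol(data)
  n_a <- sum(labels == levels(labels)[1L])
  if (n_a < 2L || n - n_a < 2L)
    stop_config("each group needs at least 2 samples")

  null_T <- vector("list", 0L)
  null_LMR <- vector("list", 0L)
  if (scheme == "channel_permutation") {
    total <- choose(n, n_a)
    if (total < 2) stop_config("fewer than 2 distinct label arrangements")
    if (total <= n_perm) {
      if (total < n_perm)
        warning(sprintf(paste0("only %d distinct relabelings exist for this ",
                               "design; enumerating all instead of %d draws"),
                        total, n_perm), call. = FALSE)
      sets <- all_relabelings(n, n_a)
    } else {
      sets <- with_seed(derive_seed(seed, "relabelings"), {
        if (total <= 5e4) {
          allsets <- all_relabelings(n, n_a)
          allsets[sample.int(nrow(allsets), n_perm), , drop = FALSE]
        } else {
          # collision probability negligible for large designs
          t(replicate(n_perm, sort(sample.int(n, n_a))))
        }
      })
    }
    for (i in seq_len(nrow(sets))) {
      idx_a <- sets[i, ]
      st <- row_feature_stats(data, idx_a, setdiff(seq_len(n), idx_a))
      null_T[[i]] <- st$T
      null_LMR[[i]] <- st$LMR
    }
    n_done <- nrow(sets)
  } else if (scheme == "sample_resampling") {
    for (i in seq_len(n_perm)) {
      s <- derive_seed(seed, paste0("boot:", i))
      idx <- with_seed(s, list(a = sample.int(n, n_a, replace = TRUE),
                               b = sample.int(n, n - n_a, replace = TRUE)))
      # columns resampled with replacement from the pooled samples
      st <- row_feature_stats(cbind(data[, idx$a, drop = FALSE],
                                    data[, idx$b, drop = FALSE]),
                              seq_len(n_a), n_a + seq_len(n - n_a))
      null_T[[i]] <- st$T
      null_LMR[[i]] <- st$LMR
    }
    n_done <- n_perm
  } else { # element_permutation
    idx_a <- which(labels == levels(labels)[1L])
    idx_b <- which(labels == levels(labels)[2L])
    for (i in seq_len(n_perm)) {
      s <- derive_seed(seed, paste0("elem:", i))
      shuf <- with_seed(s, matrix(sample(as.vector(data)), nrow(data), ncol(data)))
      st <- row_feature_stats(shuf, idx_a, idx_b)
      null_T[[i]] <- st$T
      null_LMR[[i]] <- st$LMR
    }
    n_done <- n_perm
  }

  null_T <- unlist(null_T, use.names = FALSE)
  null_LMR <- unlist(null_LMR, use.names = FALSE)
  keep <- is.finite(null_T) & is.finite(null_LMR)
  null_T <- null_T[keep]
  null_LMR <- null_LMR[keep]
  if (!length(null_T)) stop_value("empirical null is empty after dropping undefined statistics")
  structure(list(null_T = null_T,
                 null_LMR = null_LMR,
                 lmr_cutoff = lmr_cutoff(null_LMR, lmr_percentiles),
                 scheme = scheme,
                 n_perm = n_done,
                 seed = as.integer(seed),
                 lmr_percentiles = lmr_percentiles),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf("empirical null (%s): %d permutations, %d pooled values\n",
              x$scheme, x$n_perm, length(x$null_T)))
  cat(sprintf("  LMR cutoff (%.1f/%.1f pct): %.4f\n",
              x$lmr_percentiles[1], x$lmr_percentiles[2], x$lmr_cutoff))
  invisible(x)
}

#' Fold-change cutoff from a null LMR distribution
#'
#' Mean of the absolute values of the lower and upper percentiles of the
#' pooled null log2-median-ratio distribution.
#'
#' @param null_lmr Numeric vector of null LMR values.
#' @param percentiles Percent pair, e.g. `c(5, 95)`.
#' @return Non-negative scalar cutoff.
#' @export
lmr_cutoff <- function(null_lmr, percentiles = c(5, 95)) {
  q <- stats::quantile(null_lmr, probs = percentiles / 100, names = FALSE)
  mean(abs(q))
}

#' Empirical p-value against a pooled null
#'
#' Add-one estimator, never zero: two-tailed
#' `p = (1 + #\{|x| >= |obs|\}) / (1 + n)`; right-sided
#' `p = (1 + #\{x >= obs\}) / (1 + n)`.
#'
#' @param observed Numeric vector of observed statistics.
#' @param null Numeric vector of pooled null values (non-empty).
#' @param tail `"two"` or `"right"`.
#' @return Vector of p-values in `(0, 1]`.
#' @export
empirical_p <- function(observed, null, tail = c("two", "right")) {
  tail <- match.arg(tail)
  null <- null[is.finite(null)]
  if (!length(null)) stop_value("empirical_p: null distribution is empty")
  if (tail == "two") {
    s <- sort(abs(null))
    x <- abs(observed)
  } else {
    s <- sort(null)
    x <- observed
  }
  n <- length(s)
  # findInterval with left.open counts null values strictly below x
  cnt_ge <- n - findInterval(x, s, left.open = TRUE)
  p <- (1 + cnt_ge) / (1 + n)
  p[!is.finite(observed)] <- NA_real_
  p
}

#' Stouffer combination of the T and LMR p-values
#'
#' Each two-tailed component p is converted to a one-sided z signed by its
#' effect direction (`z = qnorm(1 - p/2) * sign`), the z's are combined as
#' `(z_T + z_LMR)/sqrt(2)`, and the overall p is the two-sided normal tail
#' of the combined z.  Opposite directions therefore cancel.
#'
#' @param p_T,p_LMR Two-tailed component p-values in `(0, 1]`.
#' @param direction_T,direction_LMR `"up"`/`"down"`/`"none"` or numeric sign.
#' @param p_floor Optional floor applied to zero p-values (e.g.
#'   `1/(1 + n_perm)`); a zero p without a floor is an error.
#' @return A list of class `"combined_p"`: `p_T`, `p_LMR`, `z_T`, `z_LMR`,
#'   `overall_p`.  Vectorized over its arguments.
#' @export
stouffer_combine <- function(p_T, p_LMR, direction_T, direction_LMR,
                             p_floor = NULL) {
  as_sign <- function(d) {
    if (is.numeric(d)) return(sign(d))
    ifelse(d == "up", 1, ifelse(d == "down", -1, 0))
  }
  fix_p <- function(p) {
    if (any(p <= 0, na.rm = TRUE)) {
      if (is.null(p_floor))
        stop_value("component p-value of 0; supply p_floor = 1/(1 + n_perm)")
      warning("p-value of 0 clipped to p_floor", call. = FALSE)
      p[p <= 0] <- p_floor
    }
    if (any(p > 1, na.rm = TRUE)) stop_value("p-values must lie in (0, 1]")
    p
  }
  p_T <- fix_p(p_T); p_LMR <- fix_p(p_LMR)
  z_T <- stats::qnorm(1 - p_T / 2) * as_sign(direction_T)
  z_LMR <- stats::qnorm(1 - p_LMR / 2) * as_sign(direction_LMR)
  z_comb <- (z_T + z_LMR) / sqrt(2)
  overall <- 2 * stats::pnorm(-abs(z_comb))
  overall <- pmin(overall, 1)
  structure(list(p_T = p_T, p_LMR = p_LMR, z_T = z_T, z_LMR = z_LMR,
                 overall_p = overall),
            class = "combined_p")
}

#' Z-score transform of an enrichment p-value
#'
#' `Z = -qnorm(P)`: the negated inverse standard-normal CDF, strictly
#' decreasing in P; P = 0.5 maps to 0, P = 0.05 to 1.645.
#'
#' @param P Probability strictly inside `(0, 1)`; vectorized.
#' @return Numeric vector of Z-scores.
#' @export
z_from_p <- function(P) {
  if (any(P <= 0 | P >= 1, na.rm = TRUE))
    stop_value("z_from_p: P must lie strictly in (0, 1)")
  -stats::qnorm(P)
}
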