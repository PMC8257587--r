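# Model-similarity statistics: consistent-sibling-peptide fold-change
# correlation with a sample-permutation null, DEP-set overlap significance,
# and hierarchical clustering of models.

#' Select DE sibling peptides consistent with their protein call
#'
#' Returns the DE peptides whose protein group is a DEP and whose direction
#' matches the DEP's direction.
#'
#' @param de_peptides Output of [call_de_peptides()].
#' @param deps Output of [rollup_proteins()].
#' @return Character vector of peptide ids.
#' @export
consistent_sibling_peptides <- function(de_peptides, deps) {
  de <- de_peptides[de_peptides$is_de, , drop = FALSE]
  m <- match(de$protein_group, deps$protein_group)
  keep <- !is.na(m) & de$direction == deps$direction[m]
  sort(de$peptide_id[keep])
}

#' Fold-change correlation between two experiments with permutation p
#'
#' Pearson correlation of the two experiments' log2-median-ratios on a
#' common peptide/gene set.  The null permutes the condition labels
#' independently within each experiment, recomputes both LMR vectors and
#' their correlation, and pools; p is right-sided with the add-one rule.
#' When the joint number of distinct relabeling pairs is at most `n_perm`
#' (e.g. 20 x 20 = 400 for two 3-vs-3 designs) all pairs are enumerated
#' with a warning.
#'
#' @param set Character vector of feature ids (length >= 3) present in both
#'   experiments.
#' @param exp_a,exp_b Lists `list(mat = log2 matrix, labels = 2-level
#'   factor over columns)`; rows must cover `set`.  The first factor level
#'   is the "case" group of the LMR.
#' @param n_perm Permutation count (default 5000).
#' @param seed Integer seed.
#' @return List of class `"similarity_result"`: `rho`, `m` (set size),
#'   `p_perm`, `regression` (`slope`, `intercept`, `r_squared`),
#'   `null_rho`.
#' @export
fc_correlation <- function(set, exp_a, exp_b, n_perm = 5000L, seed = 1L) {
  if (length(set) < 3L)
    stop_value("need at least 3 consistent sibling features for a correlation")
  lmr_vec <- function(ex, idx_a, idx_b) {
    m <- ex$mat[set, , drop = FALSE]
    log2(row_medians(2^m[, idx_a, drop = FALSE]) /
           row_medians(2^m[, idx_b, drop = FALSE]))
  }
  grp_idx <- function(ex) {
    l <- factor(ex$labels)
    list(a = which(l == levels(l)[1]), b = which(l == levels(l)[2]))
  }
  ia <- grp_idx(exp_a); ib <- grp_idx(exp_b)
  va <- lmr_vec(exp_a, ia$a, ia$b)
  vb <- lmr_vec(exp_b, ib$a, ib$b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop_value("zero-variance fold-change vector; correlation undefined")
  rho <- stats::cor(va, vb)
  fit <- stats::lm.fit(cbind(1, va), vb)
  r2 <- 1 - sum(fit$residuals^2) / sum((vb - mean(vb))^2)

  na <- ncol(exp_a$mat); nb <- ncol(exp_b$mat)
  sets_a <- all_relabelings(na, length(ia$a))
  sets_b <- all_relabelings(nb, length(ib$a))
  total <- nrow(sets_a) * nrow(sets_b)
  if (total <= n_perm) {
    if (total < n_perm)
      warning(sprintf("only %d distinct joint relabelings; enumerating all",
                      total), call. = FALSE)
    pairs <- cbind(rep(seq_len(nrow(sets_a)), each = nrow(sets_b)),
                   rep(seq_len(nrow(sets_b)), times = nrow(sets_a)))
  } else {
    pairs <- with_seed(derive_seed(seed, "corr_perm"),
                       cbind(sample.int(nrow(sets_a), n_perm, replace = TRUE),
                             sample.int(nrow(sets_b), n_perm, replace = TRUE)))
  }
  null_rho <- vapply(seq_len(nrow(pairs)), function(i) {
    pa <- sets_a[pairs[i, 1], ]
    pb <- sets_b[pairs[i, 2], ]
    x <- lmr_vec(exp_a, pa, setdiff(seq_len(na), pa))
    y <- lmr_vec(exp_b, pb, setdiff(seq_len(nb), pb))
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  null_rho <- null_rho[is.finite(null_rho)]
  p <- empirical_p(rho, null_rho, tail = "right")
  structure(list(rho = rho, m = length(set), p_perm = p,
                 regression = list(slope = unname(fit$coefficients[2]),
                                   intercept = unname(fit$coefficients[1]),
                                   r_squared = r2),
                 null_rho = null_rho),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("fold-change correlation: rho = %.3f (m = %d), right-sided permutation p = %.3g\n",
              x$rho, x$m, x$p_perm))
  invisible(x)
}

#' Hypergeometric overlap test between two feature sets
#'
#' Right-tail probability of observing at least the seen overlap when both
#' sets are drawn from a universe of the stated size.
#'
#' @param set_a,set_b Character vectors (subsets of the universe).
#' @param universe_size Integer universe size (>= both set sizes).
#' @return List: `overlap` (count), `p`.
#' @export
dep_overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) > universe_size || length(set_b) > universe_size)
    stop_value("set larger than the stated universe")
  ov <- length(intersect(set_a, set_b))
  p <- stats::phyper(ov - 1, length(set_a), universe_size - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(overlap = ov, p = p)
}

#' Hierarchical clustering of model fold-change profiles
#'
#' Average-linkage agglomeration on pairwise Euclidean distances between
#' model columns.  Columns are ordered by name first so the tree is
#' invariant to input column order (ties in merge heights then resolve
#' identically).
#'
#' @param fc Fold-change matrix (genes x models).
#' @return An [stats::hclust] tree over the models.
#' @export
cluster_models <- function(fc) {
  fc <- as.matrix(fc)
  if (ncol(fc) < 2L) stop_config("need at least two model columns")
  fc <- fc[, order(colnames(fc)), drop = FALSE]
  stats::hclust(stats::dist(t(fc), method = "euclidean"), method = "average")
}

#' Per-sample Pearson correlation matrix
#'
#' Convenience view of sample-level agreement: Pearson correlations between
#' quantile-normalized sample columns.
#'
#' @param mat Numeric matrix (features x samples).
#' @return Symmetric correlation matrix (samples x samples).
#' @export
sample_correlation <- function(mat) {
  stats::cor(quantile_normalize(as.matrix(mat)))
}
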