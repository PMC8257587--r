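# Microarray differential-expression stage (human and yeast variants) and
# the multi-model log2-fold-change matrix over the DEG union.

#' Collapse probes to genes
#'
#' Keeps, for each gene, the probe with the highest mean log2 intensity
#' across samples (ties broken by probe order).
#'
#' @param x An `"expr_matrix"` whose rows are probes.
#' @param probe_to_gene Named character vector, `names = probe id`,
#'   values = gene id.
#' @return An `"expr_matrix"` with one row per gene.
#' @export
collapse_probes <- function(x, probe_to_gene) {
  g <- probe_to_gene[rownames(x)]
  if (anyNA(g)) stop_schema("probe(s) without a gene mapping: ",
                            paste(rownames(x)[is.na(g)][1], "..."))
  mu <- rowMeans(unclass(x))
  ord <- order(g, -mu)
  keep <- ord[!duplicated(g[ord])]
  keep <- sort(keep)
  out <- unclass(x)[keep, , drop = FALSE]
  rownames(out) <- unname(g[keep])
  new_expr_matrix(out, groups(x), attr(x, "organism"))
}

#' Sample-permutation null for an expression matrix
#'
#' @param x An `"expr_matrix"` (log2 intensities, two groups).
#' @param contrast Length-2 character `c(group_a, group_b)`; statistics are
#'   A vs B.
#' @param n_perm Permutation count (default 1000; 3-vs-3 designs enumerate
#'   all 20 distinct relabelings).
#' @param seed Integer seed.
#' @param lmr_percentiles Cutoff percentile pair (human default
#'   `c(2.5, 97.5)`, yeast `c(5, 95)`).
#' @param scheme Permutation (default) or bootstrap resampling.
#' @return An `"empirical_null"`.
#' @export
expression_null <- function(x, contrast = levels(groups(x)), n_perm = 1000L,
                            seed = 1L, lmr_percentiles = c(2.5, 97.5),
                            scheme = c("channel_permutation",
                                       "sample_resampling")) {
  scheme <- match.arg(scheme)
  grp <- groups(x)
  sel <- grp %in% contrast
  labels <- factor(grp[sel], levels = contrast)
  build_empirical_null(unclass(x)[, sel, drop = FALSE], labels,
                       scheme = scheme, n_perm = n_perm, seed = seed,
                       lmr_percentiles = lmr_percentiles)
}

#' Call differentially expressed genes
#'
#' Integrative rule: per gene, a pooled-variance T and a log2-median-ratio
#' are computed, each gets a two-tailed empirical p against the pooled
#' sample-permutation null, and the two are Stouffer-combined.
#' Human variant: DEG iff overall p < `alpha` and `|LMR|` strictly exceeds
#' the 2.5/97.5-percentile null cutoff.  Yeast variant (guarding against
#' high-variance data): DEG iff `p_T <= alpha_strict` and `|LMR| >=` the
#' 5/95-percentile cutoff.
#'
#' @inheritParams expression_null
#' @param null An `"empirical_null"` from [expression_null()] on the same
#'   matrix/contrast.
#' @param variant `"human"` or `"yeast"`.
#' @param alpha Human overall-p threshold (default 0.05).
#' @param alpha_strict Yeast T-p threshold (default 0.01).
#' @return Data frame: `gene_id`, `T`, `LMR`, `p_T`, `p_LMR`, `overall_p`,
#'   `direction`, `is_deg`; the LMR cutoff in `attr(, "lmr_cutoff")`.
#' @export
call_degs <- function(x, contrast = levels(groups(x)), null,
                      variant = c("human", "yeast"),
                      alpha = 0.05, alpha_strict = 0.01) {
  variant <- match.arg(variant)
  stopifnot(inherits(null, "empirical_null"))
  grp <- groups(x)
  idx_a <- which(grp == contrast[1])
  idx_b <- which(grp == contrast[2])
  st <- row_feature_stats(unclass(x), idx_a, idx_b)
  A <- unclass(x)[, idx_a, drop = FALSE]
  B <- unclass(x)[, idx_b, drop = FALSE]
  va <- rowSums((A - rowMeans(A))^2)
  vb <- rowSums((B - rowMeans(B))^2)
  zero_var <- (va + vb) < 1e-12
  st$T[zero_var] <- NA_real_
  n_excluded <- sum(is.na(st$T))
  if (n_excluded > 0)
    log_msg(n_excluded, " gene(s) with undefined T (zero variance or too few samples) excluded from calling")
  p_T <- empirical_p(st$T, null$null_T, tail = "two")
  p_LMR <- empirical_p(st$LMR, null$null_LMR, tail = "two")
  dir_T <- sign(st$T)
  dir_LMR <- sign(st$LMR)
  comb <- stouffer_combine(p_T, p_LMR, dir_T, dir_LMR)
  direction <- ifelse(is.na(st$LMR) | st$LMR == 0, "none",
                      ifelse(st$LMR > 0, "up", "down"))
  is_deg <- if (variant == "human") {
    !is.na(comb$overall_p) & comb$overall_p < alpha &
      !is.na(st$LMR) & abs(st$LMR) > null$lmr_cutoff
  } else {
    !is.na(p_T) & p_T <= alpha_strict &
      !is.na(st$LMR) & abs(st$LMR) >= null$lmr_cutoff
  }
  is_deg[is.na(st$T)] <- FALSE
  out <- data.frame(gene_id = rownames(x), T = st$T, LMR = st$LMR,
                    p_T = p_T, p_LMR = p_LMR, overall_p = comb$overall_p,
                    direction = direction, is_deg = is_deg,
                    stringsAsFactors = FALSE)
  attr(out, "lmr_cutoff") <- null$lmr_cutoff
  attr(out, "variant") <- variant
  out
}

#' Full DEG stage on one expression matrix
#'
#' @inheritParams call_degs
#' @param config An [analysis_config()].
#' @return List: `null`, `degs`.
#' @export
deg_pipeline <- function(x, contrast = levels(groups(x)),
                         variant = c("human", "yeast"),
                         config = analysis_config()) {
  variant <- match.arg(variant)
  pct <- if (variant == "human") config$lmr_percentiles_deg else c(5, 95)
  null <- expression_null(x, contrast, n_perm = config$n_perm_transcriptome,
                          seed = derive_seed(config$seed, "deg_null"),
                          lmr_percentiles = pct)
  degs <- call_degs(x, contrast, null, variant = variant,
                    alpha = config$alpha_deg,
                    alpha_strict = config$alpha_deg_strict)
  list(null = null, degs = degs)
}

#' Build the multi-model fold-change matrix
#'
#' Rows are the union of DEGs across models; entries are each gene's LMR in
#' each model (graded values, not zeros, for non-DEG models); columns are
#' quantile-normalized by default.
#'
#' @param deg_results Named list (>= 2) of [call_degs()] outputs sharing one
#'   gene universe.
#' @param normalize Quantile-normalize the columns (default `TRUE`).
#' @return Numeric matrix (genes x models) of class `"fc_matrix"`.
#' @export
build_fc_matrix <- function(deg_results, normalize = TRUE) {
  if (length(deg_results) < 2L)
    stop_config("need at least two models to build a fold-change matrix")
  if (is.null(names(deg_results)) || any(!nzchar(names(deg_results))))
    names(deg_results) <- paste0("model", seq_along(deg_results))
  union_genes <- sort(unique(unlist(lapply(deg_results, function(d)
    d$gene_id[d$is_deg]))))
  if (!length(union_genes))
    stop_value("no DEGs in any model; fold-change matrix would be empty")
  m <- sapply(deg_results, function(d) {
    if (!all(union_genes %in% d$gene_id))
      stop_schema("gene universes differ across models")
    d$LMR[match(union_genes, d$gene_id)]
  })
  m <- matrix(m, nrow = length(union_genes),
              dimnames = list(union_genes, names(deg_results)))
  if (normalize) m <- quantile_normalize(m)
  class(m) <- c("fc_matrix", class(m))
  m
}
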