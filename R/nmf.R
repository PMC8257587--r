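# NMF clustering of the fold-change matrix with permutation-based
# activation significance, membership assignment, and cluster ranking.

#' Lossless non-negative embedding of a signed matrix
#'
#' Each model column `c` is split into `max(c, 0)` and `max(-c, 0)`
#' (suffixes `_up` / `_down`), preserving up/down semantics; the original
#' column is recoverable as their difference.
#'
#' @param fc Real-valued matrix (genes x models).
#' @return Non-negative matrix with `2 * ncol(fc)` columns.
#' @export
nonneg_embed <- function(fc) {
  fc <- as.matrix(fc)
  cn <- colnames(fc)
  if (is.null(cn)) cn <- paste0("m", seq_len(ncol(fc)))
  pos <- pmax(fc, 0)
  neg <- pmax(-fc, 0)
  out <- matrix(0, nrow(fc), 2L * ncol(fc),
                dimnames = list(rownames(fc),
                                as.vector(rbind(paste0(cn, "_up"),
                                                paste0(cn, "_down")))))
  out[, seq(1L, ncol(out), by = 2L)] <- pos
  out[, seq(2L, ncol(out), by = 2L)] <- neg
  out
}

#' Fit an NMF by multiplicative updates
#'
#' Frobenius-loss NMF `V ~ W H` with Lee-Seung multiplicative updates.  The
#' default initialization is NNDSVD-a (non-negative double SVD with zeros
#' filled by the matrix mean): deterministic, and far better at aligning
#' components with planted block structure than random starts, which tend
#' to fragment blocks when k exceeds the true rank.  A seeded uniform
#' random initialization is available via `init = "random"`.  The loss is
#' non-increasing across iterations; fitting stops at `max_iter` or when
#' the relative loss change drops below `tol`.
#'
#' @param v Non-negative matrix (genes x columns).
#' @param k Rank (number of clusters); must not exceed `min(dim(v))`.
#' @param seed Integer seed (consumed only by `init = "random"`).
#' @param max_iter,tol Stopping rule (defaults 500, 1e-5).
#' @param init `"nndsvda"` (default), `"nndsvd"`, or `"random"`.
#' @return List of class `"nmf_fit"`: `basis` (genes x k activation
#'   values), `pattern` (k x columns), `loss` (trace, one value per
#'   iteration), `iterations`, `k`, `seed`.
#' @export
fit_nmf <- function(v, k, seed = 1L, max_iter = 500L, tol = 1e-5,
                    init = c("nndsvda", "nndsvd", "random")) {
  init <- match.arg(init)
  v <- as.matrix(v)
  if (any(v < 0)) stop_value("fit_nmf: input must be non-negative")
  if (k > min(dim(v)))
    stop_config("k (", k, ") exceeds min(dim) = ", min(dim(v)))
  eps <- 1e-10
  n <- nrow(v); m <- ncol(v)
  if (init == "random") {
    sc <- sqrt(mean(v) / k)
    st <- with_seed(seed, list(W = matrix(stats::runif(n * k), n, k) * sc,
                               H = matrix(stats::runif(k * m), k, m) * sc))
  } else {
    st <- nndsvd_init(v, k, fill_mean = init == "nndsvda")
  }
  W <- st$W; H <- st$H
  loss <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, v)) / (crossprod(W) %*% H + eps)
    W <- W * (v %*% t(H)) / (W %*% tcrossprod(H) + eps)
    cur <- sum((v - W %*% H)^2)
    loss <- c(loss, cur)
    if (is.finite(prev) && prev > 0 && abs(prev - cur) / prev < tol) break
    prev <- cur
  }
  # resolve the W/H scale ambiguity: unit-norm pattern rows, data-scale
  # activations -- makes activation values comparable across fits (the
  # permutation null depends on this)
  hn <- sqrt(rowSums(H^2))
  hn[hn == 0] <- 1
  W <- W * rep(hn, each = n)
  H <- H / hn
  dimnames(W) <- list(rownames(v), paste0("C", seq_len(k)))
  dimnames(H) <- list(paste0("C", seq_len(k)), colnames(v))
  structure(list(basis = W, pattern = H, loss = loss,
                 iterations = length(loss), k = k, seed = as.integer(seed)),
            class = "nmf_fit")
}

# NNDSVD initialization (Boutsidis & Gallopoulos 2008): take the leading k
# singular triplets, keep the dominant non-negative section of each, scale
# by the singular values.  fill_mean replaces exact zeros by mean(v)
# ("nndsvda"), which multiplicative updates cannot escape from zero.
nndsvd_init <- function(v, k, fill_mean = TRUE) {
  s <- svd(v, nu = k, nv = k)
  n <- nrow(v); m <- ncol(v)
  W <- matrix(0, n, k); H <- matrix(0, k, m)
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  for (j in seq_len(k)[-1]) {
    u <- s$u[, j]; x <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    xp <- pmax(x, 0); xn <- pmax(-x, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nxp <- sqrt(sum(xp^2)); nxn <- sqrt(sum(xn^2))
    if (nup * nxp >= nun * nxn) {
      sig <- nup * nxp
      wj <- up / max(nup, 1e-12); hj <- xp / max(nxp, 1e-12)
    } else {
      sig <- nun * nxn
      wj <- un / max(nun, 1e-12); hj <- xn / max(nxn, 1e-12)
    }
    W[, j] <- sqrt(s$d[j] * sig) * wj
    H[j, ] <- sqrt(s$d[j] * sig) * hj
  }
  if (fill_mean) {
    mu <- mean(v)
    W[W == 0] <- mu
    H[H == 0] <- mu
  }
  list(W = W, H = H)
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF fit: k = %d, %d iterations, final loss %.6g\n",
              x$k, x$iterations, x$loss[length(x$loss)]))
  invisible(x)
}

#' Permutation significance of NMF activation values
#'
#' For each of `n_perm` permutations all elements of the matrix are globally
#' shuffled, the NMF is refit (same k, seed-derived initializations), and
#' every gene-side activation value is pooled into a single null.  Each
#' observed activation value receives a right-sided add-one empirical p
#' against that pooled null.
#'
#' @inheritParams fit_nmf
#' @param fit Optional pre-computed `"nmf_fit"` of `v` (fitted internally
#'   when absent).
#' @param n_perm Number of element permutations.
#' @return Matrix (genes x k) of adjusted p-values, with the pooled null in
#'   `attr(, "null")` and the fit in `attr(, "fit")`.
#' @export
activation_significance <- function(v, k, n_perm = 100L, seed = 1L,
                                    fit = NULL, max_iter = 500L, tol = 1e-5,
                                    init = "nndsvda") {
  v <- as.matrix(v)
  if (is.null(fit))
    fit <- fit_nmf(v, k, seed = derive_seed(seed, "obs"),
                   max_iter = max_iter, tol = tol, init = init)
  null_vals <- vector("list", n_perm)
  for (b in seq_len(n_perm)) {
    vp <- with_seed(derive_seed(seed, paste0("shuffle:", b)),
                    matrix(sample(as.vector(v)), nrow(v), ncol(v)))
    pf <- fit_nmf(vp, k, seed = derive_seed(seed, paste0("init:", b)),
                  max_iter = max_iter, tol = tol, init = init)
    null_vals[[b]] <- as.vector(pf$basis)
  }
  null <- unlist(null_vals, use.names = FALSE)
  p <- matrix(empirical_p(as.vector(fit$basis), null, tail = "right"),
              nrow(v), k, dimnames = dimnames(fit$basis))
  attr(p, "null") <- null
  attr(p, "fit") <- fit
  p
}

#' NMF clustering with membership and ranking
#'
#' End-to-end: non-negative embedding, NMF fit, activation significance,
#' membership assignment (`activation_p < cluster_p`), and cluster ranking
#' by descending Euclidean norm of the activation (basis) columns, ties
#' broken by cluster index.
#'
#' @param fc Signed fold-change matrix (genes x models), e.g. from
#'   [build_fc_matrix()].
#' @param k Number of clusters.
#' @param n_perm Element permutations for the activation null.
#' @param seed Integer seed.
#' @param cluster_p Membership threshold on the adjusted activation p
#'   (default 0.01).
#' @param max_iter,tol Passed to [fit_nmf()].
#' @return List of class `"nmf_clustering"`: `fit`, `activation_p`,
#'   `memberships` (named list cluster -> gene ids), `ranking` (cluster
#'   indices by descending norm), `norms`, `k`, `cluster_p`.
#' @export
nmf_cluster <- function(fc, k, n_perm = 100L, seed = 1L, cluster_p = 0.01,
                        max_iter = 500L, tol = 1e-5, init = "nndsvda") {
  v <- nonneg_embed(fc)
  p <- activation_significance(v, k, n_perm = n_perm, seed = seed,
                               max_iter = max_iter, tol = tol, init = init)
  fit <- attr(p, "fit")
  norms <- sqrt(colSums(fit$basis^2))
  ranking <- order(-norms, seq_len(k))
  memberships <- lapply(seq_len(k), function(i)
    rownames(v)[p[, i] < cluster_p])
  names(memberships) <- colnames(fit$basis)
  structure(list(fit = fit, activation_p = p, memberships = memberships,
                 ranking = ranking, norms = norms, k = k,
                 cluster_p = cluster_p),
            class = "nmf_clustering")
}

#' @export
print.nmf_clustering <- function(x, ...) {
  cat(sprintf("NMF clustering: k = %d, %d genes with >= 1 membership\n",
              x$k, length(unique(unlist(x$memberships)))))
  invisible(x)
}

#' Rank clusters and select the top m
#'
#' Clusters ordered by descending Euclidean norm of their activation
#' columns (ties by cluster index); the first `m` are returned with their
#' member gene lists.
#'
#' @param clustering An `"nmf_clustering"`.
#' @param m Number of clusters to keep (default 10).
#' @return Data frame: `rank`, `cluster`, `norm`, `n_members`, plus the
#'   member lists in `attr(, "members")`.
#' @export
rank_and_select <- function(clustering, m = 10L) {
  stopifnot(inherits(clustering, "nmf_clustering"))
  if (m > clustering$k)
    stop_config("m (", m, ") exceeds the number of clusters k = ", clustering$k)
  sel <- clustering$ranking[seq_len(m)]
  out <- data.frame(rank = seq_len(m),
                    cluster = colnames(clustering$fit$basis)[sel],
                    norm = clustering$norms[sel],
                    n_members = lengths(clustering$memberships[sel]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "members") <- clustering$memberships[sel]
  out
}

# Hard labels: each gene's argmax-activation cluster (used for ARI scoring
# of planted structure).
#' Assign each gene to its maximum-activation cluster
#' @param clustering An `"nmf_clustering"` or `"nmf_fit"`.
#' @return Named integer vector of cluster indices per gene.
#' @export
hard_clusters <- function(clustering) {
  basis <- if (inherits(clustering, "nmf_clustering"))
    clustering$fit$basis else clustering$basis
  lab <- max.col(basis, ties.method = "first")
  names(lab) <- rownames(basis)
  lab
}
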