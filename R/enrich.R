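# In-repo gene-set enrichment (hypergeometric; stand-in for a web-service
# annotation tool) and the Sorensen-Dice process network over enriched terms.

#' Hypergeometric gene-set enrichment
#'
#' One-sided (over-representation) hypergeometric p per term, with the
#' published-style pass rule: p below `p_max` AND at least `min_genes` genes of
#' the list in the term.  `z = -qnorm(p)`.  An EASE-style conservative
#' variant (overlap reduced by one) is available behind `ease`.
#'
#' @param gene_list Character vector of query genes; ids outside the
#'   universe are dropped with a warning.
#' @param collection A `"gene_set_collection"` (named list term -> members).
#' @param universe Character vector of background genes (default: union of
#'   all collection members).
#' @param p_max Pass threshold on p (default 0.1).
#' @param min_genes Minimum overlap for a pass (default 5).
#' @param ease If `TRUE`, subtract 1 from the overlap before computing p.
#' @return Data frame: `term`, `n_term`, `overlap`, `p`, `z`, `passes`,
#'   sorted by p.
#' @export
enrich <- function(gene_list, collection, universe = NULL, p_max = 0.1,
                   min_genes = 5L, ease = FALSE) {
  if (!length(gene_list)) stop_value("enrich: empty gene list")
  if (is.null(universe)) universe <- unique(unlist(collection))
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    gene_list <- intersect(gene_list, universe)
  }
  if (!length(gene_list)) stop_value("enrich: no query genes inside the universe")
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(collection), function(term) {
    members <- intersect(collection[[term]], universe)
    K <- length(members)
    ov <- length(intersect(gene_list, members))
    q <- if (ease) max(ov - 1L, 0L) else ov
    p <- stats::phyper(q - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, n_term = K, overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$z <- ifelse(out$p > 0 & out$p < 1, -stats::qnorm(out$p),
                  ifelse(out$p >= 1, -Inf, Inf))
  out$passes <- out$p < p_max & out$overlap >= min_genes
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sorensen-Dice coefficient of two sets
#'
#' `2|A intersect B| / (|A| + |B|)`.
#'
#' @param a,b Vectors (treated as sets).
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) return(0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Build the process network over enriched terms
#'
#' Nodes are the terms passing enrichment in at least one cluster, labeled
#' by their contributing clusters and carrying the term's annotated gene
#' set.  Every node pair is a candidate edge; an edge is kept iff the
#' number of shared genes is at least `min_shared` AND the Dice coefficient
#' strictly exceeds `cutoff`.  With `cutoff = "auto"`, the cutoff is the
#' 95th percentile of the Dice distribution over all node pairs.
#'
#' @param enrichments Named list (cluster -> [enrich()] output).
#' @param collection The `"gene_set_collection"` supplying node gene sets.
#' @param universe Optional background restriction of the node gene sets.
#' @param min_shared Minimum shared genes per edge (default 3).
#' @param cutoff Numeric Dice cutoff (default 0.4, strict `>`) or `"auto"`.
#' @return List of class `"process_network"`: `nodes` (data frame `term`,
#'   `clusters`, `n_genes`), `edges` (data frame `from`, `to`, `shared`,
#'   `dice`), `gene_sets`, `cutoff` (the numeric cutoff used).
#' @export
build_process_network <- function(enrichments, collection, universe = NULL,
                                  min_shared = 3L, cutoff = 0.4) {
  if (is.data.frame(enrichments)) enrichments <- list(cluster1 = enrichments)
  if (is.null(names(enrichments)))
    names(enrichments) <- paste0("cluster", seq_along(enrichments))
  passing <- lapply(enrichments, function(e) e$term[e$passes])
  terms <- sort(unique(unlist(passing)))
  if (!length(terms)) {
    warning("no term passes enrichment; returning an empty network",
            call. = FALSE)
    return(structure(list(nodes = data.frame(term = character(0),
                                             clusters = character(0),
                                             n_genes = integer(0),
                                             stringsAsFactors = FALSE),
                          edges = empty_edges(), gene_sets = list(),
                          cutoff = if (identical(cutoff, "auto")) NA_real_ else cutoff),
                     class = "process_network"))
  }
  gene_sets <- lapply(terms, function(t) {
    g <- unique(collection[[t]])
    if (!is.null(universe)) g <- intersect(g, universe)
    g
  })
  names(gene_sets) <- terms
  cluster_label <- vapply(terms, function(t) {
    paste(names(passing)[vapply(passing, function(p) t %in% p, logical(1))],
          collapse = ",")
  }, character(1))
  nodes <- data.frame(term = terms, clusters = unname(cluster_label),
                      n_genes = lengths(gene_sets), stringsAsFactors = FALSE)
  rownames(nodes) <- NULL

  if (length(terms) < 2L) {
    return(structure(list(nodes = nodes, edges = empty_edges(),
                          gene_sets = gene_sets,
                          cutoff = if (identical(cutoff, "auto")) NA_real_ else cutoff),
                     class = "process_network"))
  }
  pairs <- utils::combn(terms, 2L)
  shared <- integer(ncol(pairs)); dice <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    gi <- gene_sets[[pairs[1, i]]]; gj <- gene_sets[[pairs[2, i]]]
    shared[i] <- length(intersect(gi, gj))
    dice[i] <- dice_coefficient(gi, gj)
  }
  if (identical(cutoff, "auto")) {
    cutoff <- stats::quantile(dice, probs = 0.95, names = FALSE)
    log_msg("auto Dice cutoff (95th percentile of all node pairs): ",
            format(cutoff, digits = 4))
  }
  keep <- shared >= min_shared & dice > cutoff
  edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                      shared = shared[keep], dice = dice[keep],
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, gene_sets = gene_sets,
                 cutoff = cutoff),
            class = "process_network")
}

empty_edges <- function() {
  data.frame(from = character(0), to = character(0), shared = integer(0),
             dice = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.process_network <- function(x, ...) {
  cat(sprintf("process network: %d nodes, %d edges (Dice cutoff %s)\n",
              nrow(x$nodes), nrow(x$edges),
              if (is.na(x$cutoff)) "NA" else format(x$cutoff, digits = 4)))
  invisible(x)
}
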