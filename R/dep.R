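# TMT differential-expression stage: peptide filtering, DE-peptide calling
# against the channel-permutation null, and rollup to proteins.

#' Filter peptides before differential testing
#'
#' Retains peptides that (i) are unique to one protein group, (ii) have
#' precursor isolation purity strictly above `purity_min`, and (iii) whose
#' maximum log2 intensity across channels strictly exceeds the given
#' percentile of the distribution of all peptides' max log2 intensities.
#' Zero intensities are treated as unquantified throughout.
#'
#' @param table A `"peptide_table"`.
#' @param purity_min Purity floor (default 0.75, strict `>`).
#' @param intensity_percentile Percentile (percent) of the max-log2-intensity
#'   distribution (default 5, strict `>`).
#' @return The filtered `"peptide_table"`.
#' @export
filter_peptides <- function(table, purity_min = 0.75, intensity_percentile = 5) {
  stopifnot(inherits(table, "peptide_table"))
  m <- peptide_intensities(table)
  m[m <= 0] <- NA
  maxlog <- apply(log2(m), 1L, max, na.rm = TRUE)
  maxlog[!is.finite(maxlog)] <- NA
  thr <- stats::quantile(maxlog, probs = intensity_percentile / 100,
                         na.rm = TRUE, names = FALSE)
  keep <- table$is_unique &
    table$isolation_purity > purity_min &
    !is.na(maxlog) & maxlog > thr
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop_value("no peptides survive filtering; review purity/intensity thresholds")
  new_peptide_table(as.data.frame(out), channels(table), attr(table, "fraction"))
}

# log2 intensity matrix restricted to a contrast's channels, quantile
# normalized; zeros enter as NA.  Returns list(mat, idx_a, idx_b).
contrast_matrix <- function(table, contrast, normalize = TRUE) {
  ch <- channels(table)
  cond_a <- contrast[1]; cond_b <- contrast[2]
  missing <- setdiff(c(cond_a, cond_b), unique(ch$condition))
  if (length(missing))
    stop_config("condition(s) not in channel map: ", paste(missing, collapse = ", "))
  sel <- ch$condition %in% c(cond_a, cond_b)
  m <- peptide_intensities(table)[, ch$channel[sel], drop = FALSE]
  m[m <= 0] <- NA
  lm <- log2(m)
  if (normalize) lm <- quantile_normalize(lm, na_ok = TRUE)
  cond <- ch$condition[sel]
  list(mat = lm,
       idx_a = which(cond == cond_a),
       idx_b = which(cond == cond_b),
       labels = factor(cond, levels = c(cond_a, cond_b)))
}

#' Build the channel-permutation null for a peptide table
#'
#' Convenience wrapper: restricts the (quantile-normalized log2) intensity
#' matrix to the contrast's channels and permutes the channel labels.
#'
#' @param table Filtered `"peptide_table"`.
#' @param contrast Length-2 character vector `c(condition_a, condition_b)`;
#'   statistics are A vs B (positive = up in A).
#' @param n_perm Number of channel permutations (default 100; with a 3-vs-3
#'   contrast only 20 distinct relabelings exist and all are enumerated).
#' @param seed Integer seed.
#' @param lmr_percentiles Cutoff percentile pair (default `c(5, 95)`).
#' @return An `"empirical_null"`.
#' @export
peptide_null <- function(table, contrast, n_perm = 100L, seed = 1L,
                         lmr_percentiles = c(5, 95)) {
  cm <- contrast_matrix(table, contrast)
  build_empirical_null(cm$mat, cm$labels, scheme = "channel_permutation",
                       n_perm = n_perm, seed = seed,
                       lmr_percentiles = lmr_percentiles)
}

#' Call differentially expressed peptides
#'
#' A peptide is DE iff its two-tailed empirical p (observed T against the
#' pooled channel-permutation null) is below `alpha`, its absolute log2
#' median-ratio exceeds the null-derived cutoff, and it is quantified in
#' more than two replicates of at least one condition.
#'
#' @inheritParams peptide_null
#' @param null An `"empirical_null"` built on the same filtered table.
#' @param alpha Peptide-level threshold (default 0.05).
#' @return Data frame: `peptide_id`, `protein_group`, `T`, `LMR`, `p`,
#'   `direction`, `is_de`.
#' @export
call_de_peptides <- function(table, contrast, null, alpha = 0.05) {
  stopifnot(inherits(null, "empirical_null"))
  cm <- contrast_matrix(table, contrast)
  st <- row_feature_stats(cm$mat, cm$idx_a, cm$idx_b)
  p <- empirical_p(st$T, null$null_T, tail = "two")
  # "identified under only one condition (> more than two replicates)":
  # quantified (nonzero) in more than two replicates of >= 1 condition
  quant_a <- rowSums(is.finite(cm$mat[, cm$idx_a, drop = FALSE]))
  quant_b <- rowSums(is.finite(cm$mat[, cm$idx_b, drop = FALSE]))
  replicate_ok <- quant_a > 2L | quant_b > 2L
  direction <- ifelse(is.na(st$LMR) | st$LMR == 0, "none",
                      ifelse(st$LMR > 0, "up", "down"))
  is_de <- !is.na(p) & p < alpha &
    !is.na(st$LMR) & abs(st$LMR) > null$lmr_cutoff &
    replicate_ok
  data.frame(peptide_id = table$peptide_id,
             protein_group = table$protein_group,
             T = st$T, LMR = st$LMR, p = p,
             direction = direction, is_de = is_de,
             stringsAsFactors = FALSE)
}

#' Roll DE peptides up to differentially expressed proteins
#'
#' A protein group is a DEP iff at least two unique DE peptides support it
#' and all of its DE peptides share one direction; groups with mixed
#' directions are excluded.
#'
#' @param de_peptides Output of [call_de_peptides()].
#' @return Data frame sorted by `protein_group`: `protein_group`,
#'   `direction`, `n_de_peptides`, `supporting_peptides`
#'   (comma-collapsed ids).
#' @export
rollup_proteins <- function(de_peptides) {
  de <- de_peptides[de_peptides$is_de & de_peptides$direction != "none", ,
                    drop = FALSE]
  if (nrow(de) == 0L)
    return(data.frame(protein_group = character(0), direction = character(0),
                      n_de_peptides = integer(0),
                      supporting_peptides = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(de, de$protein_group), function(g) {
    dirs <- unique(g$direction)
    if (length(dirs) != 1L || nrow(g) < 2L) return(NULL)
    data.frame(protein_group = g$protein_group[1], direction = dirs,
               n_de_peptides = nrow(g),
               supporting_peptides = paste(sort(g$peptide_id), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(protein_group = character(0), direction = character(0),
                      n_de_peptides = integer(0),
                      supporting_peptides = character(0),
                      stringsAsFactors = FALSE))
  out <- out[order(out$protein_group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-compartment DEP overlap
#'
#' Intersects two DEP lists (e.g. nucleus vs cytoplasm of the same contrast)
#' within each direction.
#'
#' @param dep_a,dep_b DEP data frames from [rollup_proteins()].
#' @return List with `common_up`, `common_down` (character vectors) and
#'   `counts` (named integer vector `up`, `down`).
#' @export
cross_fraction_overlap <- function(dep_a, dep_b) {
  up_a <- dep_a$protein_group[dep_a$direction == "up"]
  up_b <- dep_b$protein_group[dep_b$direction == "up"]
  dn_a <- dep_a$protein_group[dep_a$direction == "down"]
  dn_b <- dep_b$protein_group[dep_b$direction == "down"]
  common_up <- sort(intersect(up_a, up_b))
  common_down <- sort(intersect(dn_a, dn_b))
  list(common_up = common_up, common_down = common_down,
       counts = c(up = length(common_up), down = length(common_down)))
}

#' Run the full DEP stage on one peptide table
#'
#' filter -> channel-permutation null -> DE-peptide calls -> protein rollup.
#'
#' @inheritParams peptide_null
#' @param config An [analysis_config()].
#' @return List: `filtered`, `null`, `de_peptides`, `deps`.
#' @export
dep_pipeline <- function(table, contrast, config = analysis_config()) {
  filtered <- filter_peptides(table, config$purity_min,
                              config$intensity_percentile)
  null <- peptide_null(filtered, contrast,
                       n_perm = config$n_perm_proteome,
                       seed = derive_seed(config$seed, "dep_null"),
                       lmr_percentiles = config$lmr_percentiles_dep)
  de_peptides <- call_de_peptides(filtered, contrast, null,
                                  alpha = config$alpha_dep)
  deps <- rollup_proteins(de_peptides)
  list(filtered = filtered, null = null, de_peptides = de_peptides,
       deps = deps)
}
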