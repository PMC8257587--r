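#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults are the published analysis settings: 100 channel permutations
#' for the proteome null, 1,000 resamplings for the transcriptome, 5,000 for
#' the fold-change correlation null; DE-peptide alpha 0.05 with the log2
#' median-ratio (LMR) cutoff from the 5th/95th null percentiles; DEG alpha
#' 0.05 with the 2.5th/97.5th percentiles (yeast variant: p <= 0.01 with
#' 5th/95th); NMF with k = 100 clusters, top 10 retained, membership at
#' p < 0.01; enrichment pass at p < 0.1 with >= 5 genes; network edges at
#' >= 3 shared genes and Dice > 0.4 (or the "auto" 95th-percentile rule).
#'
#' @param seed Integer run seed.
#' @param n_perm_proteome,n_perm_transcriptome,n_perm_correlation Permutation
#'   counts for the three empirical nulls.
#' @param alpha_dep,alpha_deg,alpha_deg_strict Calling thresholds.
#' @param purity_min Minimum precursor isolation purity (strict `>`).
#' @param intensity_percentile Max-log2-intensity floor, as a percentile of
#'   the per-peptide max-intensity distribution (strict `>`).
#' @param lmr_percentiles_dep,lmr_percentiles_deg Percentile pairs defining
#'   the LMR cutoff for peptides and genes respectively.
#' @param nmf_k,nmf_top,cluster_p NMF rank, number of top clusters, and the
#'   activation-significance membership threshold.
#' @param enrich_p,enrich_min_genes Enrichment pass rules.
#' @param dice_min_shared,dice_cutoff Process-network edge rules;
#'   `dice_cutoff` may be the string `"auto"`.
#' @return A validated list of class `"sennet_config"`.
#' @export
analysis_config <- function(seed = 1L,
                            n_perm_proteome = 100L,
                            n_perm_transcriptome = 1000L,
                            n_perm_correlation = 5000L,
                            alpha_dep = 0.05,
                            alpha_deg = 0.05,
                            alpha_deg_strict = 0.01,
                            purity_min = 0.75,
                            intensity_percentile = 5,
                            lmr_percentiles_dep = c(5, 95),
                            lmr_percentiles_deg = c(2.5, 97.5),
                            nmf_k = 100L,
                            nmf_top = 10L,
                            cluster_p = 0.01,
                            enrich_p = 0.1,
                            enrich_min_genes = 5L,
                            dice_min_shared = 3L,
                            dice_cutoff = 0.4) {
  cfg <- list(
    seed = as.integer(seed),
    n_perm_proteome = as.integer(n_perm_proteome),
    n_perm_transcriptome = as.integer(n_perm_transcriptome),
    n_perm_correlation = as.integer(n_perm_correlation),
    alpha_dep = alpha_dep,
    alpha_deg = alpha_deg,
    alpha_deg_strict = alpha_deg_strict,
    purity_min = purity_min,
    intensity_percentile = intensity_percentile,
    lmr_percentiles_dep = as.numeric(lmr_percentiles_dep),
    lmr_percentiles_deg = as.numeric(lmr_percentiles_deg),
    nmf_k = as.integer(nmf_k),
    nmf_top = as.integer(nmf_top),
    cluster_p = cluster_p,
    enrich_p = enrich_p,
    enrich_min_genes = as.integer(enrich_min_genes),
    dice_min_shared = as.integer(dice_min_shared),
    dice_cutoff = dice_cutoff
  )
  class(cfg) <- "sennet_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  prob_fields <- c("alpha_dep", "alpha_deg", "alpha_deg_strict",
                   "cluster_p", "enrich_p")
  for (f in prob_fields) {
    p <- cfg[[f]]
    if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
      stop_config("config field '", f, "' must be a probability in (0,1)")
  }
  for (f in c("lmr_percentiles_dep", "lmr_percentiles_deg")) {
    pr <- cfg[[f]]
    if (length(pr) != 2L || !all(pr > 0 & pr < 100) || pr[1] >= pr[2])
      stop_config("config field '", f, "' must be a strictly ordered pair of percents")
  }
  counts <- c("n_perm_proteome", "n_perm_transcriptome", "n_perm_correlation",
              "nmf_k", "nmf_top", "enrich_min_genes", "dice_min_shared")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1)
      stop_config("config field '", f, "' must be a count >= 1")
  }
  if (!(is.numeric(cfg$purity_min) && cfg$purity_min > 0 && cfg$purity_min < 1))
    stop_config("config field 'purity_min' must be a fraction in (0,1)")
  dc <- cfg$dice_cutoff
  if (!(identical(dc, "auto") || (is.numeric(dc) && dc >= 0 && dc < 1)))
    stop_config("config field 'dice_cutoff' must be a fraction in [0,1) or \"auto\"")
  invisible(cfg)
}

#' Write / read a configuration file
#'
#' Flat `key: value` text format (UTF-8, "." decimal, vectors
#' comma-separated).  `read_config` round-trips the output of
#' `write_config` exactly.
#'
#' @param cfg A `"sennet_config"` object.
#' @param path File path.
#' @return `read_config` returns a validated `"sennet_config"`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sennet_config"))
  lines <- vapply(names(cfg), function(nm) {
    v <- cfg[[nm]]
    val <- if (is.character(v)) v else
      paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
            collapse = ",")
    paste0(nm, ": ", val)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad))
    stop_config("malformed config line ", bad[1], ": ", lines[bad[1]])
  defaults <- analysis_config()
  out <- defaults
  for (m in kv) {
    key <- m[2]; val <- m[3]
    if (!key %in% names(defaults))
      stop_config("unknown config key '", key, "'")
    if (key == "dice_cutoff" && identical(val, "auto")) {
      out[[key]] <- "auto"
    } else {
      num <- suppressWarnings(as.numeric(strsplit(val, ",", fixed = TRUE)[[1]]))
      if (anyNA(num)) stop_config("non-numeric value for config key '", key, "'")
      out[[key]] <- if (is.integer(defaults[[key]])) as.integer(num) else num
    }
  }
  validate_config(out)
  out
}

#' @export
print.sennet_config <- function(x, ...) {
  cat("sennet analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}
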