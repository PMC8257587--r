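# Seeded generators for every pipeline input, with planted truth carried
# alongside.  All generators are pure functions of (parameters, seed).

#' Simulate a TMT peptide reporter-intensity table
#'
#' Emulates one labeling set of a two-condition, n-replicate TMT design:
#' protein base abundances are lognormal, each peptide carries a
#' multiplicative ionization factor, reporter intensities are abundance x
#' factor x lognormal noise with the given coefficient of variation, a
#' fraction of proteins is planted as differentially expressed (half up,
#' half down, scaled by `fold` in the case condition), isolation purities
#' are Beta-distributed with mass near 1 and a sub-0.75 tail, and ~5% of
#' peptides are flagged non-unique.
#'
#' @param n_proteins Number of protein groups (default 1000).
#' @param peptides_per_protein Unique peptides per protein (default 2).
#' @param frac_de Fraction of proteins planted DE (default 0.05).
#' @param fold Linear fold change of planted proteins (default 4).
#' @param cv Coefficient of variation of the reporter noise (default 0.1).
#' @param n_rep Replicates per condition (default 3).
#' @param seed Integer seed.
#' @param conditions Length-2 condition names, case first
#'   (default `c("senescent", "young")`).
#' @param fraction Compartment tag (default `"nucleus"`).
#' @param frac_nonunique Fraction of peptides flagged non-unique (0.05).
#' @param purity_beta Beta shape pair for purities (default `c(8, 1)`).
#' @return List: `table` (a `"peptide_table"`), `truth` (data frame
#'   `protein_group`, `is_de`, `direction`, `fold`).
#' @export
simulate_tmt <- function(n_proteins = 1000L, peptides_per_protein = 2L,
                         frac_de = 0.05, fold = 4, cv = 0.1, n_rep = 3L,
                         seed = 1L,
                         conditions = c("senescent", "young"),
                         fraction = "nucleus", frac_nonunique = 0.05,
                         purity_beta = c(8, 1)) {
  if (frac_de < 0 || frac_de >= 1) stop_config("frac_de must lie in [0, 1)")
  if (fold <= 1) stop_config("fold must exceed 1")
  if (n_rep < 2L) stop_config("n_rep must be >= 2")
  if (cv <= 0) stop_config("cv must be positive")
  with_seed(seed, {
    n_pep <- n_proteins * peptides_per_protein
    protein <- rep(sprintf("P%04d", seq_len(n_proteins)),
                   each = peptides_per_protein)
    peptide <- sprintf("%s_pep%d", protein,
                       rep(seq_len(peptides_per_protein), times = n_proteins))
    n_de <- round(frac_de * n_proteins)
    de_idx <- if (n_de > 0) sample.int(n_proteins, n_de) else integer(0)
    dir_prot <- rep("none", n_proteins)
    if (n_de > 0)
      dir_prot[de_idx] <- rep(c("up", "down"), length.out = n_de)
    # abundances ~ lognormal around 2^17 with sd 1.5 on log2 (typical TMT
    # reporter dynamic range); peptide ionization spans ~2 log2 units
    abundance <- 2^stats::rnorm(n_proteins, mean = 17, sd = 1.5)
    ion <- 2^stats::rnorm(n_pep, mean = 0, sd = 1)
    sdlog <- sqrt(log(1 + cv^2))
    cond_vec <- rep(conditions, each = n_rep)
    m <- matrix(0, n_pep, 2L * n_rep)
    base <- abundance[rep(seq_len(n_proteins), each = peptides_per_protein)] * ion
    scale_de <- ifelse(dir_prot == "up", fold,
                       ifelse(dir_prot == "down", 1 / fold, 1))
    scale_pep <- scale_de[rep(seq_len(n_proteins), each = peptides_per_protein)]
    for (j in seq_len(ncol(m))) {
      mu <- if (cond_vec[j] == conditions[1]) base * scale_pep else base
      m[, j] <- mu * exp(stats::rnorm(n_pep, 0, sdlog))
    }
    channel_names <- tmt_channel_names(2L * n_rep)
    colnames(m) <- channel_names
    channel_map <- data.frame(channel = channel_names,
                              condition = cond_vec,
                              replicate = rep(seq_len(n_rep), times = 2L),
                              stringsAsFactors = FALSE)
    purity <- stats::rbeta(n_pep, purity_beta[1], purity_beta[2])
    is_unique <- stats::runif(n_pep) >= frac_nonunique
    df <- data.frame(peptide_id = peptide, protein_group = protein,
                     is_unique = is_unique, isolation_purity = purity,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(m, check.names = FALSE))
    table <- new_peptide_table(df, channel_map, fraction)
    truth <- data.frame(protein_group = sprintf("P%04d", seq_len(n_proteins)),
                        is_de = dir_prot != "none", direction = dir_prot,
                        fold = ifelse(dir_prot == "none", 1, fold),
                        stringsAsFactors = FALSE)
    list(table = table, truth = truth)
  })
}

# Standard 10-plex reporter channel names, truncated to n.
tmt_channel_names <- function(n) {
  all <- c("126", "127N", "127C", "128N", "128C", "129N", "129C", "130N",
           "130C", "131")
  if (n > length(all)) c(all, paste0("ch", seq_len(n - length(all)))) else all[seq_len(n)]
}

#' Simulate a microarray log2-intensity matrix
#'
#' Gene baselines Normal(8, 2) on the log2 scale, i.i.d. Normal(0, sigma)
#' measurement noise, and a planted fraction of genes shifted by
#' +/- `effect_log2` in the case group (half up, half down).
#'
#' @param n_genes Number of genes (default 2000).
#' @param frac_de Fraction planted DE (default 0.1).
#' @param effect_log2 Planted shift in log2 units (default 1 = 2-fold).
#' @param sigma Noise SD on the log2 scale (default 0.25).
#' @param n_per_group Samples per group (default 3).
#' @param seed Integer seed.
#' @param groups Length-2 group names, case first
#'   (default `c("senescent", "young")`).
#' @param organism Organism tag (default `"human"`).
#' @return List: `matrix` (an `"expr_matrix"`), `truth` (data frame
#'   `gene_id`, `is_de`, `direction`, `effect_log2`).
#' @export
simulate_microarray <- function(n_genes = 2000L, frac_de = 0.1,
                                effect_log2 = 1, sigma = 0.25,
                                n_per_group = 3L, seed = 1L,
                                groups = c("senescent", "young"),
                                organism = "human") {
  if (frac_de < 0 || frac_de >= 1) stop_config("frac_de must lie in [0, 1)")
  if (sigma <= 0) stop_config("sigma must be positive")
  if (n_per_group < 2L) stop_config("n_per_group must be >= 2")
  with_seed(seed, {
    gene <- sprintf("G%05d", seq_len(n_genes))
    n_de <- round(frac_de * n_genes)
    de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
    dirs <- rep("none", n_genes)
    if (n_de > 0) dirs[de_idx] <- rep(c("up", "down"), length.out = n_de)
    baseline <- stats::rnorm(n_genes, 8, 2)
    shift <- ifelse(dirs == "up", effect_log2,
                    ifelse(dirs == "down", -effect_log2, 0))
    n_s <- 2L * n_per_group
    cond <- rep(groups, each = n_per_group)
    m <- matrix(stats::rnorm(n_genes * n_s, 0, sigma), n_genes, n_s)
    m <- m + baseline
    m[, cond == groups[1]] <- m[, cond == groups[1]] + shift
    colnames(m) <- paste0(cond, "_", rep(seq_len(n_per_group), 2))
    rownames(m) <- gene
    grp <- stats::setNames(cond, colnames(m))
    truth <- data.frame(gene_id = gene, is_de = dirs != "none",
                        direction = dirs,
                        effect_log2 = abs(shift), stringsAsFactors = FALSE)
    list(matrix = new_expr_matrix(m, factor(grp, levels = groups), organism),
         truth = truth)
  })
}

#' Simulate a multi-model fold-change matrix with planted blocks
#'
#' Background entries are ~0 plus Gaussian noise; each block assigns a
#' signed mean fold change to a set of genes in its active models,
#' emulating shared-vs-model-specific expression programs.
#'
#' @param n_genes Total genes (default 200).
#' @param n_models Model columns (default 6).
#' @param block_spec List of blocks, each
#'   `list(n = genes, models = column indices, sign = +1/-1, fc = mean
#'   |log2 FC|)`.  Blocks partition a leading subset of genes (no overlap).
#'   Default: four 40-gene blocks (all-shared up, models 1-2 up, models 3-4
#'   down, models 5-6 down) at |FC| 2.
#' @param noise_sigma Gaussian noise SD (default 0.1).
#' @param seed Integer seed.
#' @return List: `matrix` (genes x models, class `"fc_matrix"`), `truth`
#'   (data frame `gene_id`, `block` with 0 = background).
#' @export
simulate_model_fc <- function(n_genes = 200L, n_models = 6L,
                              block_spec = NULL, noise_sigma = 0.1,
                              seed = 1L) {
  if (is.null(block_spec)) {
    block_spec <- list(
      list(n = 40L, models = seq_len(n_models), sign = +1, fc = 2),
      list(n = 40L, models = c(1L, 2L), sign = +1, fc = 2),
      list(n = 40L, models = c(3L, 4L), sign = -1, fc = 2),
      list(n = 40L, models = c(5L, min(6L, n_models)), sign = -1, fc = 2)
    )
  }
  block_spec <- lapply(block_spec, function(b) {
    b$n <- as.integer(b$n); b$models <- as.integer(b$models); b
  })
  total_block <- sum(vapply(block_spec, `[[`, integer(1), "n"))
  if (total_block > n_genes)
    stop_config("block genes (", total_block, ") exceed n_genes (", n_genes, ")")
  for (b in block_spec) {
    if (any(b$models < 1L | b$models > n_models))
      stop_config("block references a model outside 1..n_models")
  }
  with_seed(seed, {
    gene <- sprintf("G%05d", seq_len(n_genes))
    m <- matrix(stats::rnorm(n_genes * n_models, 0, noise_sigma),
                n_genes, n_models,
                dimnames = list(gene, sprintf("model%d", seq_len(n_models))))
    labels <- integer(n_genes)
    at <- 1L
    for (bi in seq_along(block_spec)) {
      b <- block_spec[[bi]]
      rows <- at:(at + b$n - 1L)
      m[rows, b$models] <- m[rows, b$models] + b$sign * b$fc
      labels[rows] <- bi
      at <- at + b$n
    }
    class(m) <- c("fc_matrix", class(m))
    list(matrix = m,
         truth = data.frame(gene_id = gene, block = labels,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a gene-set collection (GMT)
#'
#' Random term memberships from a universe, plus optional planted term
#' pairs with exact shared-gene counts so that downstream Dice thresholds
#' are exercised at known values.
#'
#' @param n_terms Number of random terms (default 50).
#' @param term_size_range Inclusive size range (default `c(10, 30)`).
#' @param universe Character vector of genes, or an integer size.
#' @param overlap_spec Optional list of planted pairs, each
#'   `list(size_a =, size_b =, shared =)`; planted terms are named
#'   `planted<i>a` / `planted<i>b`.
#' @param seed Integer seed.
#' @return A `"gene_set_collection"`.
#' @export
simulate_gmt <- function(n_terms = 50L, term_size_range = c(10L, 30L),
                         universe = 500L, overlap_spec = NULL, seed = 1L) {
  if (length(universe) == 1L && is.numeric(universe))
    universe <- sprintf("G%05d", seq_len(universe))
  if (max(term_size_range) > length(universe))
    stop_config("term sizes exceed the universe")
  with_seed(seed, {
    sets <- list()
    for (i in seq_len(n_terms)) {
      sz <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
      sets[[sprintf("term%03d", i)]] <- sort(sample(universe, sz))
    }
    for (i in seq_along(overlap_spec)) {
      sp <- overlap_spec[[i]]
      if (sp$shared > min(sp$size_a, sp$size_b) ||
          sp$size_a + sp$size_b - sp$shared > length(universe))
        stop_config("infeasible overlap_spec entry ", i)
      pool <- sample(universe, sp$size_a + sp$size_b - sp$shared)
      shared <- pool[seq_len(sp$shared)]
      only_a <- pool[sp$shared + seq_len(sp$size_a - sp$shared)]
      only_b <- pool[sp$size_a + seq_len(sp$size_b - sp$shared)]
      sets[[sprintf("planted%da", i)]] <- sort(c(shared, only_a))
      sets[[sprintf("planted%db", i)]] <- sort(c(shared, only_b))
    }
    structure(sets,
              descriptions = stats::setNames(rep("synthetic", length(sets)),
                                             names(sets)),
              class = "gene_set_collection")
  })
}
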