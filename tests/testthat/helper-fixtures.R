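# Fixtures and independent oracles shared across test files.
# Everything is built in code; nothing is read from stored binaries.

toy_channel_map <- function(n_rep = 3L,
                            conditions = c("senescent", "young")) {
  data.frame(channel = c("126", "127N", "127C", "128N", "128C", "129N")[seq_len(2 * n_rep)],
             condition = rep(conditions, each = n_rep),
             replicate = rep(seq_len(n_rep), 2),
             stringsAsFactors = FALSE)
}

# A tiny 3-peptide, 6-channel quant table with friendly round numbers.
toy_peptide_df <- function() {
  cm <- toy_channel_map()
  df <- data.frame(peptide_id = c("pepA1", "pepA2", "pepB1"),
                   protein_group = c("PA", "PA", "PB"),
                   is_unique = c(TRUE, TRUE, TRUE),
                   isolation_purity = c(0.95, 0.9, 0.85),
                   stringsAsFactors = FALSE)
  m <- rbind(c(800, 820, 810, 400, 410, 390),
             c(1600, 1580, 1620, 800, 790, 810),
             c(100, 110, 90, 100, 105, 95))
  colnames(m) <- cm$channel
  cbind(df, as.data.frame(m, check.names = FALSE))
}

write_toy_peptide_tsv <- function(path = tempfile(fileext = ".tsv"),
                                  df = toy_peptide_df()) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Exhaustive hypergeometric right-tail oracle from binomial coefficients,
# independent of stats::phyper.
hyper_tail_oracle <- function(overlap, size_a, size_b, universe) {
  i <- overlap:min(size_a, size_b)
  sum(choose(size_a, i) * choose(universe - size_a, size_b - i)) /
    choose(universe, size_b)
}

expect_same_bytes <- function(a, b) {
  expect_identical(readBin(a, "raw", file.size(a)),
                   readBin(b, "raw", file.size(b)))
}

# Score recovery of planted fold-change blocks: ARI between planted block
# labels and each planted gene's argmax-activation cluster.
planted_ari <- function(fit_or_clustering, truth) {
  planted <- truth$block > 0
  hard <- hard_clusters(fit_or_clustering)[truth$gene_id[planted]]
  adjusted_rand_index(hard, truth$block[planted])
}
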