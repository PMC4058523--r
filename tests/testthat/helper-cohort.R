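# Small simulated cohorts shared by several test files: full study design
# (6 controls + 19 cases) but fewer features, so unit tests stay fast.
small_truth <- function(n_regulators = 4L) {
  ground_truth(n_regulators = n_regulators, targets_per_regulator = 4L,
               exclusive_per_regulator = 3L)
}

small_cohort <- function(seed = 42L, n_regulators = 4L, n_mirna = 20L,
                         n_gene = 60L) {
  generate_cohort(small_truth(n_regulators), n_mirna = n_mirna,
                  n_gene = n_gene, seed = seed)
}

write_expr_fixture <- function(path, values) {
  df <- data.frame(feature_id = rownames(values), values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
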