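# Small fixture builders shared across test files.

# Complete abundance table with iid log10 values, four groups.
make_complete_table <- function(n_per_group = 10, n_proteins = 12, seed = 1,
                                state = "log10-imputed") {
  set.seed(seed)
  n <- 4 * n_per_group
  v <- matrix(stats::rnorm(n * n_proteins, 6, 0.5), n, n_proteins,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              sprintf("P%04d", seq_len(n_proteins))))
  design <- study_design(rownames(v),
                         rep(c("+", "+", "-", "-"), each = n_per_group),
                         rep(c("+", "-", "+", "-"), each = n_per_group))
  list(table = abundance_table(v, state), design = design)
}

# Minimal synthetic config with no planted structure.
plain_config <- function(n_per_group = 20, n_proteins = 40, seed = 1, ...) {
  synthetic_config(n_per_group = n_per_group, n_proteins = n_proteins,
                   block_spec = list(), hub_spec = list(),
                   shifted_spec = list(), seed = seed, ...)
}

# Writes a tiny proteinGroups-style TSV; returns its path.
write_toy_proteingroups <- function(dir = tempdir(), with_flags = FALSE) {
  lines <- c(
    paste(c("Protein IDs", if (with_flags) "Reverse",
            paste("LFQ intensity", c("A", "B", "C", "D"))), collapse = "\t"),
    paste(c("P1", if (with_flags) "", "1e6", "2e6", "0", "4e6"), collapse = "\t"),
    paste(c("P2", if (with_flags) "", "5e5", "6e5", "7e5", "8e5"), collapse = "\t"),
    paste(c("P3", if (with_flags) "+", "1e5", "2e5", "3e5", "4e5"), collapse = "\t")
  )
  path <- tempfile("proteinGroups", tmpdir = dir, fileext = ".txt")
  writeLines(lines, path)
  path
}
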