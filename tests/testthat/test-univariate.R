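# Kruskal-Wallis screen, Dunn's post-hoc, Benjamini-Hochberg, trends.

test_that("Benjamini-Hochberg matches the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.42), 0.42)
  set.seed(31)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(benjamini_hochberg(p), brute_bh(p), tolerance = 1e-14)
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("Kruskal-Wallis H matches direct evaluation and is rank-invariant", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- factor(rep(c("a", "b", "c"), each = 2))
  expect_equal(unname(stats::kruskal.test(v, g)$statistic), 32 / 7,
               tolerance = 1e-12)
  fx <- make_complete_table(n_per_group = 8, n_proteins = 15, seed = 3)
  # force ties on some proteins
  fx$table$values[, 1:3] <- round(fx$table$values[, 1:3], 1)
  res <- kruskal_wallis_screen(fx$table, fx$design)
  g4 <- factor(fx$design$group)
  for (j in seq_len(ncol(fx$table$values))) {
    expect_equal(res$H[j], brute_kw_h(fx$table$values[, j], g4),
                 tolerance = 1e-10)
  }
  expect_equal(res$p_adj, brute_bh(res$p), tolerance = 1e-12)
  # monotone transform leaves H unchanged
  fx2 <- fx
  fx2$table$values <- exp(fx$table$values)
  expect_equal(kruskal_wallis_screen(fx2$table, fx$design)$H, res$H,
               tolerance = 1e-12)
  # complete ties convention
  fx3 <- fx
  fx3$table$values[, 1] <- 1
  r3 <- kruskal_wallis_screen(fx3$table, fx$design)
  expect_equal(r3$H[1], 0)
  expect_equal(r3$p[1], 1)
})

test_that("group-size preconditions are enforced", {
  fx <- make_complete_table(n_per_group = 2, n_proteins = 4, seed = 1)
  sub <- fx$design[-1, ]
  tab <- abundance_table(fx$table$values[-1, , drop = FALSE], "log10-imputed")
  expect_error(kruskal_wallis_screen(tab, sub), "at least 2 samples")
})

test_that("Dunn z agrees with the tie-corrected formula and is antisymmetric", {
  fx <- make_complete_table(n_per_group = 10, n_proteins = 8, seed = 11)
  fx$table$values[, 1] <- round(fx$table$values[, 1], 1)  # ties
  kw <- kruskal_wallis_screen(fx$table, fx$design)
  kw$p <- rep(0.01, nrow(kw))   # gate everything in for the oracle check
  dn <- dunn_posthoc(fx$table, fx$design, kw = kw)
  g <- factor(fx$design$group)
  for (r in sample(nrow(dn), 20)) {
    expect_equal(dn$z[r],
                 brute_dunn_z(fx$table$values[, dn$protein_id[r]], g,
                              dn$group1[r], dn$group2[r]),
                 tolerance = 1e-10)
  }
  expect_equal(dn$p_adj, brute_bh(dn$p), tolerance = 1e-12)
  # antisymmetry: reverse a pair by relabelling the design factors
  swapped <- fx$design
  swapped$group <- chartr("+-", "-+", swapped$group)
  swapped$mother_allergy <- chartr("+-", "-+", swapped$mother_allergy)
  swapped$child_allergy <- chartr("+-", "-+", swapped$child_allergy)
  dn2 <- dunn_posthoc(fx$table, swapped, kw = kw)
  key1 <- paste(dn$protein_id, dn$group1, dn$group2)
  key2 <- paste(dn2$protein_id,
                chartr("+-", "-+", dn2$group2), chartr("+-", "-+", dn2$group1))
  m <- match(key1, key2)
  expect_false(anyNA(m))
  expect_equal(dn$z, -dn2$z[m], tolerance = 1e-12)
  expect_equal(dn$p, dn2$p[m], tolerance = 1e-12)
  expect_identical(dn$trend,
                   ifelse(dn2$trend[m] == "up", "down", "up"))
})

test_that("Dunn behaviour at the boundaries", {
  # all groups identical -> z = 0, p = 1 for every pair
  fx <- make_complete_table(n_per_group = 5, n_proteins = 2, seed = 2)
  fx$table$values[] <- rep(c(1, 2, 3, 4, 5), 8)
  kw <- data.frame(protein_id = protein_ids(fx$table),
                   H = 0, p = 0.01, p_adj = 0.04)
  dn <- dunn_posthoc(fx$table, fx$design, kw = kw)
  expect_true(all(dn$z == 0))
  expect_true(all(dn$p == 1))
  # strictly ordered non-overlapping groups: |z| largest for extreme pair
  fx2 <- make_complete_table(n_per_group = 6, n_proteins = 1, seed = 3)
  g <- factor(fx2$design$group)
  ord <- c("M-/C-", "M-/C+", "M+/C-", "M+/C+")
  fx2$table$values[, 1] <- match(as.character(g), ord) * 10 +
    stats::runif(24)
  kw2 <- data.frame(protein_id = "P0001", H = 20, p = 1e-4, p_adj = 1e-4)
  dn2 <- dunn_posthoc(fx2$table, fx2$design, kw = kw2)
  extreme <- which((dn2$group1 == "M+/C+" & dn2$group2 == "M-/C-") |
                   (dn2$group1 == "M-/C-" & dn2$group2 == "M+/C+"))
  expect_equal(which.max(abs(dn2$z)), extreme)
  # empty candidate set -> empty frame, not an error
  kw0 <- data.frame(protein_id = protein_ids(fx2$table),
                    H = 0, p = 0.9, p_adj = 0.9)
  expect_identical(nrow(dunn_posthoc(fx2$table, fx2$design, kw = kw0)), 0L)
})

test_that("per-protein BH family is available for Dunn", {
  fx <- make_complete_table(n_per_group = 8, n_proteins = 6, seed = 13)
  kw <- kruskal_wallis_screen(fx$table, fx$design)
  kw$p <- rep(0.01, nrow(kw))
  dn <- dunn_posthoc(fx$table, fx$design, kw = kw, family = "per_protein")
  for (pid in unique(dn$protein_id)) {
    sel <- dn$protein_id == pid
    expect_equal(dn$p_adj[sel], brute_bh(dn$p[sel]), tolerance = 1e-12)
  }
})

test_that("null data keeps the BH-significant fraction near nominal", {
  hits <- 0
  total <- 0
  for (rep in 1:50) {
    fx <- make_complete_table(n_per_group = 6, n_proteins = 20,
                              seed = 100 + rep)
    res <- kruskal_wallis_screen(fx$table, fx$design)
    hits <- hits + sum(res$p_adj < 0.05)
    total <- total + nrow(res)
  }
  expect_lte(hits / total, 0.05 + 2 * sqrt(0.05 * 0.95 / total))
})

test_that("abundance trends report ratios and keyword counts", {
  fx <- make_complete_table(n_per_group = 4, n_proteins = 2, seed = 5)
  g <- factor(fx$design$group)
  # protein 1: means 6 vs 5 on log10 scale -> ratio 1.2
  fx$table$values[, 1] <- ifelse(g == "M-/C+", 6, 5)
  fx$table$values[, 2] <- 4  # equal means -> tie
  ann <- data.frame(protein_id = "P0001", keyword = "Immunoglobulin")
  tr <- abundance_trend_summary(fx$table, fx$design, ann,
                                pair = c("M-/C+", "M-/C-"))
  expect_equal(tr$per_protein$ratio[1], 1.2, tolerance = 1e-12)
  expect_identical(tr$per_protein$higher_in[1], "M-/C+")
  expect_equal(tr$per_protein$ratio[2], 1)
  expect_identical(tr$per_protein$higher_in[2], "tie")
  expect_identical(tr$per_protein$keyword[2], "unannotated")
})

test_that("a planted 77-up / 6-down keyword set is counted 77 of 83", {
  cfg <- synthetic_config(
    n_per_group = 75, n_proteins = 100,
    block_spec = list(), hub_spec = list(),
    shifted_spec = list(
      list(proteins = 1:77, keyword = "Immunoglobulin",
           group = "M-/C+", shift = 0.5),
      list(proteins = 78:83, keyword = "Immunoglobulin",
           group = "M-/C+", shift = -0.5)
    ),
    censor_quantile = 0, seed = 42
  )
  ds <- generate_lfq_dataset(cfg)
  tab <- abundance_table(log10(ds$abundance$values), "log10-imputed")
  tr <- abundance_trend_summary(tab, ds$design, ds$annotation,
                                pair = c("M-/C+", "M-/C-"))
  ig <- tr$per_keyword[tr$per_keyword$keyword == "Immunoglobulin", ]
  expect_equal(ig$n, 83)
  expect_equal(ig$n_higher_group1, 77)
})
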