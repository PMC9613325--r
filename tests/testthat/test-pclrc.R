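# PCLRC network inference: Spearman, CLR, edge probabilities, network
# construction, connectivity, differential connectivity, selection.

test_that("Spearman matrix honours monotone relations and ties", {
  set.seed(2)
  n <- 9
  a <- sort(stats::rnorm(n))
  v <- cbind(p1 = a, p2 = exp(a), p3 = -a^3, p4 = stats::rnorm(n))
  rownames(v) <- sprintf("s%d", 1:n)
  r <- spearman_matrix(v)
  expect_equal(r["p1", "p2"], 1)
  expect_equal(r["p1", "p3"], -1)
  expect_identical(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 4))
  # monotone transform invariance of the whole matrix
  expect_equal(spearman_matrix(exp(v)), r, tolerance = 1e-12)
  # tie handling matches rank-then-Pearson
  v5 <- cbind(x = c(1, 2, 2, 3, 4), y = c(2, 1, 4, 4, 5))
  rownames(v5) <- sprintf("s%d", 1:5)
  r5 <- spearman_matrix(v5)
  expect_equal(r5["x", "y"],
               stats::cor(rank(v5[, 1]), rank(v5[, 2])), tolerance = 1e-12)
  # constant protein: zeroed with a warning
  vc <- cbind(v, p5 = rep(1, n))
  expect_warning(rc <- spearman_matrix(vc), "constant")
  expect_true(all(rc["p5", -5] == 0))
})

test_that("CLR scores match hand arithmetic and contracts", {
  # all off-diagonal similarities equal -> zero deviation -> all scores 0
  r_flat <- matrix(0.4, 5, 5); diag(r_flat) <- 1
  expect_true(all(clr_transform(r_flat) == 0))
  # 4x4 oracle
  r4 <- matrix(c(1, .8, .1, -.3,
                 .8, 1, .2, .1,
                 .1, .2, 1, .6,
                 -.3, .1, .6, 1), 4, 4)
  expect_equal(clr_transform(r4), brute_clr(r4), tolerance = 1e-12)
  # random symmetric inputs: symmetry, non-negativity, zero diagonal
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(stats::runif(36, -1, 1), 6)
    r <- (m + t(m)) / 2; diag(r) <- 1
    cl <- clr_transform(r)
    expect_identical(cl, t(cl))
    expect_true(all(cl >= 0))
    expect_true(all(diag(cl) == 0))
    expect_equal(clr_transform(r), brute_clr(r), tolerance = 1e-12)
  }
  expect_error(clr_transform(matrix(stats::runif(9), 3)), "symmetric")
})

test_that("edge probabilities use the documented defaults and counting identity", {
  expect_equal(formals(estimate_edge_probabilities)$n_iterations, 1000)
  expect_equal(formals(estimate_edge_probabilities)$subsample_fraction, 0.75)
  # J = 25 -> 300 pairs; keep 0.30 -> exactly 90 edges per iteration
  fx <- make_complete_table(n_per_group = 10, n_proteins = 25, seed = 5)
  m <- fx$table$values
  ep <- estimate_edge_probabilities(m, n_iterations = 50, seed = 3)
  expect_equal(mean(ep$p[upper.tri(ep$p)]), 0.30, tolerance = 1e-9)
  expect_identical(ep$p, t(ep$p))
  expect_true(all(ep$p >= 0 & ep$p <= 1))
  expect_equal(unname(diag(ep$p)), rep(1, 25))
  # identical seed and data -> identical probabilities
  ep2 <- estimate_edge_probabilities(m, n_iterations = 50, seed = 3)
  expect_identical(ep$p, ep2$p)
  expect_error(estimate_edge_probabilities(m, keep_fraction = 0),
               "keep_fraction")
  expect_error(estimate_edge_probabilities(m[1:4, ]), "subsample size")
})

test_that("a planted strong pair is retained against an independent background", {
  cfg <- synthetic_config(
    n_per_group = 75, n_proteins = 32,
    block_spec = list(list(size = 2, rho = 0.95, groups = "M+/C+",
                           tag = "Pair")),
    hub_spec = list(), shifted_spec = list(), censor_quantile = 0, seed = 23
  )
  ds <- generate_lfq_dataset(cfg)
  m <- log10(ds$abundance$values[ds$design$group == "M+/C+", ])
  ep <- estimate_edge_probabilities(m, n_iterations = 200, seed = 8)
  expect_gte(ep$p["P0001", "P0002"], 0.99)
  ut <- upper.tri(ep$p)
  null_p <- ep$p[ut][-1]  # all pairs except the planted one
  expect_lt(stats::median(null_p), ep$keep_fraction)
})

test_that("network thresholding substitutes full-data correlations", {
  r <- matrix(c(1, .9, -.5, .9, 1, .2, -.5, .2, 1), 3, 3,
              dimnames = list(paste0("p", 1:3), paste0("p", 1:3)))
  p <- matrix(c(1, .995, .98, .995, 1, 1, .98, 1, 1), 3, 3,
              dimnames = dimnames(r))
  net <- build_network(r, p, tau = 0.99)
  expect_equal(net["p1", "p2"], 0.9)   # p = 0.995 -> retained
  expect_equal(net["p1", "p3"], 0)     # p = 0.98  -> dropped
  expect_equal(net["p2", "p3"], 0.2)
  expect_equal(unname(diag(unclass(net))), rep(1, 3))
  # tau = 0 keeps everything
  net0 <- build_network(r, p, tau = 0)
  expect_equal(unclass(net0)[upper.tri(r)], r[upper.tri(r)])
  # retained weights are exactly the similarity entries
  nz <- which(unclass(net) != 0 & upper.tri(net))
  expect_identical(unclass(net)[nz], r[nz])
  expect_error(build_network(r, p, tau = 1.5), "tau")
})

test_that("connectivity equals weighted degree with the self term cancelled", {
  w <- matrix(c(1, 0.5, -0.3, 0,
                0.5, 1, 0, 0,
                -0.3, 0, 1, 0,
                0, 0, 0, 1), 4, 4,
              dimnames = list(paste0("p", 1:4), paste0("p", 1:4)))
  chi <- connectivity(w)
  expect_equal(unname(chi["p1"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(chi["p4"]), 0)
  expect_equal(unname(connectivity(diag(5) + 0)), rep(0, 5))
  bad <- w; diag(bad) <- 0
  expect_error(connectivity(bad), "diagonal")
})

test_that("connectivity on binary networks equals graph degree", {
  set.seed(12)
  for (i in 1:20) {
    J <- sample(5:15, 1)
    a <- matrix(stats::rbinom(J * J, 1, 0.3), J)
    a <- 1 * ((a + t(a)) > 0)
    diag(a) <- 1
    dimnames(a) <- list(paste0("p", 1:J), paste0("p", 1:J))
    g <- igraph::graph_from_adjacency_matrix(a - diag(J), mode = "undirected")
    expect_equal(unname(connectivity(a)), unname(igraph::degree(g)))
  }
})

test_that("differential connectivity subtracts profiles and is antisymmetric", {
  chi_a <- c(p1 = 6, p2 = 1)
  chi_b <- c(p1 = 4, p2 = 1)
  d <- differential_connectivity(chi_a, chi_b)
  expect_equal(unname(d["p1"]), 2)
  expect_equal(unname(d["p2"]), 0)
  expect_equal(differential_connectivity(chi_b, chi_a), -d)
  expect_error(differential_connectivity(chi_a, c(p2 = 1, p1 = 4)),
               "same proteins")
})

test_that("permutation machinery enforces its floor and budget", {
  fx <- make_complete_table(n_per_group = 8, n_proteins = 6, seed = 3)
  g <- factor(fx$design$group)
  ma <- fx$table$values[g == "M+/C+", ]
  mb <- fx$table$values[g == "M-/C-", ]
  expect_error(dc_permutation_pvalues(ma, mb, n_permutations = 10),
               ">= 19")
  dp <- dc_permutation_pvalues(ma, mb, n_permutations = 19,
                               n_iterations = 20, seed = 2)
  expect_true(all(dp$p >= 1 / 20))
  expect_true(all(dp$p_adj >= dp$p))
  expect_equal(dp$p_adj, brute_bh(dp$p), tolerance = 1e-12)
  expect_error(dc_permutation_pvalues(ma, mb[, rev(seq_len(ncol(mb)))],
                                      n_permutations = 19),
               "same protein set")
})

test_that("candidate selection applies the threshold and intersects", {
  d1 <- c(a = 51, b = 49, c = -60, d = 0)
  d2 <- c(a = 70, b = 52, c = -55, d = 2)
  d3 <- c(a = 55, b = 1, c = -51, d = 100)
  sel <- select_candidates(list(x = d1, y = d2, z = d3),
                           delta_threshold = 50)
  expect_identical(sel$selected$x, c("a", "c"))
  expect_identical(sel$intersection,
                   Reduce(intersect, list(c("a", "c"), c("a", "b", "c"),
                                          c("a", "c", "d"))))
  # signed mode drops the negative-delta protein
  sel_s <- select_candidates(list(x = d1), delta_threshold = 50,
                             signed = TRUE)
  expect_identical(sel_s$selected$x, "a")
  # threshold 0 selects every nonzero |delta|
  sel0 <- select_candidates(list(x = d1), delta_threshold = 0)
  expect_identical(sel0$selected$x, c("a", "b", "c"))
})

test_that("a group with weaker planted structure shows lower connectivity", {
  all_groups <- c("M+/C+", "M+/C-", "M-/C+", "M-/C-")
  cfg <- synthetic_config(
    n_per_group = 40, n_proteins = 30,
    block_spec = list(
      list(size = 5, rho = 0.9, groups = all_groups[1:3], tag = "A"),
      list(size = 5, rho = 0.9, groups = all_groups[1:3], tag = "B"),
      list(size = 5, rho = 0.9, groups = all_groups[1:3], tag = "C")
    ),
    hub_spec = list(), shifted_spec = list(), censor_quantile = 0, seed = 15
  )
  ds <- generate_lfq_dataset(cfg)
  chi <- function(gr) {
    m <- log10(ds$abundance$values[ds$design$group == gr, ])
    r <- spearman_matrix(m, warn_constant = FALSE)
    ep <- estimate_edge_probabilities(m, n_iterations = 100,
                                      keep_fraction = 0.1,
                                      seed = derive_seed(5, gr))
    connectivity(build_network(r, ep))
  }
  chi_active <- chi("M+/C+")
  chi_quiet <- chi("M-/C-")
  wt <- suppressWarnings(
    stats::wilcox.test(chi_active, chi_quiet, alternative = "greater")
  )
  expect_lt(wt$p.value, 0.01)
})

test_that("edge lists serialise retained edges with probabilities", {
  r <- matrix(c(1, .9, 0, .9, 1, 0, 0, 0, 1), 3, 3,
              dimnames = list(paste0("p", 1:3), paste0("p", 1:3)))
  p <- matrix(1, 3, 3, dimnames = dimnames(r))
  net <- build_network(r, p)
  path <- file.path(withr::local_tempdir(), "edges.tsv")
  write_edge_list(net, p, path)
  el <- utils::read.delim(path)
  expect_equal(nrow(el), 1L)
  expect_equal(el$weight, 0.9)
  expect_equal(el$probability, 1)
})
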