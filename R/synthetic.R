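# Synthetic LFQ data generator.  Emulates the statistical structure the
# pipeline assumes -- four mother/child allergy groups of equal size,
# log-normal LFQ intensities, group-specific correlation blocks and hubs
# planted through a Gaussian copula, keyword-tagged abundance shifts and
# probabilistic left-censoring -- so that every downstream stage can be
# tested against known ground truth.

#' Configuration for the synthetic LFQ generator
#'
#' Defaults mirror the cohort layout the pipeline targets: 4 groups x 75
#' samples and 687 proteins with log10 intensities around 6, a set of 83
#' immunoglobulin-tagged proteins shifted in the group with a non-allergic
#' mother and an allergic child (77 up, 6 down), correlation blocks that
#' are denser in the groups where mother and/or child are allergic, one
#' differential hub, and logistic left-censoring around the 30th
#' percentile of each protein.
#'
#' @param n_per_group Samples per group (default 75).
#' @param n_proteins Number of proteins (default 687).
#' @param base_log10_mean,base_log10_sd Protein-level mean and spread of
#'   log10 intensity (defaults 6.0 and 0.8).
#' @param noise_log10_sd Within-protein sample spread in log10 units
#'   (default 0.4).
#' @param block_spec List of blocks, each
#'   `list(size =, rho =, groups =, tag =)`: a compound-symmetric
#'   correlation block of `size` consecutive proteins with within-block
#'   correlation `rho`, active in `groups`, annotated with keyword `tag`.
#'   Blocks occupy protein indices sequentially from 1.
#' @param hub_spec List of hubs, each
#'   `list(neighbors = c("M+/C+" = 6, ...), rho =, tag =)`: a star of
#'   pairwise-correlated neighbours around a hub protein; `neighbors`
#'   gives the per-group neighbour count.  Hubs are placed after the
#'   blocks, each followed by its `max(neighbors)` neighbour proteins.
#' @param shifted_spec List of shifted sets, each
#'   `list(proteins =, keyword =, group =, shift =)`: `shift` log10 units
#'   added to the listed proteins in `group`.  `proteins = NULL` defers
#'   placement to the first free indices after blocks and hubs (use
#'   `n =` to give the count).
#' @param censor_quantile Left-censoring severity: per-protein censoring
#'   bound at this quantile of the true values (default 0.3; 0 disables
#'   censoring).  Must be below 1.
#' @param censor_softness Logistic width of the missingness probability
#'   curve in log10 units (default 0.05, a sharp detection limit with a
#'   transition of roughly 12% relative intensity; larger values blur the
#'   censoring).
#' @param seed Master integer seed (default 2022).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = 75,
                             n_proteins = 687,
                             base_log10_mean = 6.0,
                             base_log10_sd = 0.8,
                             noise_log10_sd = 0.4,
                             block_spec = default_block_spec(),
                             hub_spec = default_hub_spec(),
                             shifted_spec = default_shifted_spec(),
                             censor_quantile = 0.3,
                             censor_softness = 0.05,
                             seed = 2022) {
  cfg <- list(n_per_group = n_per_group, n_proteins = n_proteins,
              base_log10_mean = base_log10_mean, base_log10_sd = base_log10_sd,
              noise_log10_sd = noise_log10_sd, block_spec = block_spec,
              hub_spec = hub_spec, shifted_spec = shifted_spec,
              censor_quantile = censor_quantile,
              censor_softness = censor_softness, seed = seed)
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

default_block_spec <- function() {
  list(
    list(size = 25, rho = 0.7, groups = GROUP_LEVELS, tag = "Milk protein"),
    list(size = 20, rho = 0.7, groups = c("M+/C+", "M+/C-", "M-/C+"),
         tag = "Translation"),
    list(size = 15, rho = 0.6, groups = c("M+/C+", "M+/C-"),
         tag = "Gluconeogenesis")
  )
}

default_hub_spec <- function() {
  list(
    list(neighbors = c("M+/C+" = 12, "M+/C-" = 10, "M-/C+" = 10, "M-/C-" = 2),
         rho = 0.9, tag = "Chaperone")
  )
}

default_shifted_spec <- function() {
  list(
    list(proteins = NULL, n = 77, keyword = "Immunoglobulin",
         group = "M-/C+", shift = 0.2),
    list(proteins = NULL, n = 6, keyword = "Immunoglobulin",
         group = "M-/C+", shift = -0.2)
  )
}

# Resolves block/hub/shift protein-index layout and validates it.
synthetic_layout <- function(cfg) {
  J <- cfg$n_proteins
  cursor <- 0L
  blocks <- lapply(cfg$block_spec, function(b) {
    idx <- cursor + seq_len(b$size)
    cursor <<- cursor + b$size
    c(b, list(proteins = idx))
  })
  hubs <- lapply(cfg$hub_spec, function(h) {
    kmax <- max(h$neighbors)
    if (kmax >= J) stop("hub neighbour count must be below n_proteins")
    hub <- cursor + 1L
    nbrs <- cursor + 1L + seq_len(kmax)
    cursor <<- cursor + 1L + kmax
    c(h, list(hub = hub, neighbor_pool = nbrs))
  })
  shifted <- lapply(cfg$shifted_spec, function(s) {
    if (is.null(s$proteins)) {
      n <- if (!is.null(s$n)) s$n else stop("shifted set needs proteins or n")
      s$proteins <- cursor + seq_len(n)
      cursor <<- cursor + n
    }
    if (any(s$proteins < 1 | s$proteins > J)) {
      stop("shifted protein index out of range")
    }
    s
  })
  if (cursor > J) {
    stop("block/hub/shift layout needs ", cursor,
         " proteins but n_proteins = ", J)
  }
  structured <- c(unlist(lapply(blocks, `[[`, "proteins")),
                  unlist(lapply(hubs, function(h) c(h$hub, h$neighbor_pool))))
  if (anyDuplicated(structured)) {
    stop("blocks and hubs claim overlapping protein indices")
  }
  list(blocks = blocks, hubs = hubs, shifted = shifted)
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_per_group < 2) stop("n_per_group must be >= 2")
  if (cfg$censor_quantile < 0 || cfg$censor_quantile >= 1) {
    stop("censor_quantile must lie in [0, 1)")
  }
  if (cfg$censor_softness <= 0) stop("censor_softness must be positive")
  if (sum(vapply(cfg$block_spec, `[[`, numeric(1), "size")) > cfg$n_proteins) {
    stop("block sizes exceed n_proteins")
  }
  for (b in cfg$block_spec) {
    if (!all(b$groups %in% GROUP_LEVELS)) stop("unknown group in block_spec")
    if (b$rho < 0 || b$rho >= 1) stop("block rho must lie in [0, 1)")
  }
  for (h in cfg$hub_spec) {
    if (!all(names(h$neighbors) %in% GROUP_LEVELS)) {
      stop("hub neighbour counts must be named by group")
    }
  }
  synthetic_layout(cfg)  # errors on inconsistent indices
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> 4 x %d samples, %d proteins, censor_quantile %.2f, seed %d\n",
    x$n_per_group, x$n_proteins, x$censor_quantile, x$seed
  ))
  invisible(x)
}

# Per-group correlation matrix on the latent log10 scale.  Blocks are
# compound-symmetric; hubs use a one-factor star (hub loading 0.95, so the
# hub-neighbour correlation is rho and neighbour-neighbour correlation is
# (rho / 0.95)^2) which keeps the matrix positive definite.
build_group_correlation <- function(cfg, group) {
  lay <- synthetic_layout(cfg)
  J <- cfg$n_proteins
  R <- diag(J)
  for (b in lay$blocks) {
    if (!group %in% b$groups) next
    idx <- b$proteins
    R[idx, idx] <- b$rho
    diag(R)[idx] <- 1
  }
  for (h in lay$hubs) {
    k <- if (group %in% names(h$neighbors)) h$neighbors[[group]] else 0
    if (k == 0) next
    nbrs <- h$neighbor_pool[seq_len(k)]
    lam_h <- 0.95
    lam_n <- h$rho / lam_h
    if (lam_n >= 1) stop("hub rho too large for the one-factor construction")
    R[h$hub, nbrs] <- R[nbrs, h$hub] <- h$rho
    R[nbrs, nbrs] <- lam_n^2
    diag(R)[nbrs] <- 1
  }
  R
}

#' Generate a synthetic LFQ dataset
#'
#' Draws per-protein log10 means, plants the configured correlation
#' structure per group through a Gaussian copula on the latent log10
#' values, applies the configured abundance shifts, and censors: each
#' cell goes missing with probability following a decreasing logistic in
#' its true value, centred at the protein's `censor_quantile` quantile.
#' Abundances are `10^log10`; missing cells are `NA` in the abundance
#' table but retain their true values in the truth object.
#'
#' @param config A [synthetic_config()].
#' @return List with `abundance` (raw `abundance_table` with missing
#'   cells), `design` (study design), `annotation` (protein_id/keyword
#'   data frame) and `truth`: list with `log10` (uncensored samples x
#'   proteins matrix), `censoring_bound` (per protein), `differential`
#'   (shifted protein ids), `group_networks` (reference binary
#'   adjacencies) and `layout`.
#' @export
generate_lfq_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  lay <- synthetic_layout(cfg)
  J <- cfg$n_proteins
  n <- cfg$n_per_group
  prot <- sprintf("P%04d", seq_len(J))

  design <- study_design(
    sample_id = sprintf("S%03d", seq_len(4 * n)),
    mother_allergy = rep(c("+", "+", "-", "-"), each = n),
    child_allergy = rep(c("+", "-", "+", "-"), each = n)
  )

  X <- matrix(NA_real_, 4 * n, J, dimnames = list(design$sample_id, prot))
  with_seed(derive_seed(cfg$seed, "lfq/means"), {
    mu <- stats::rnorm(J, cfg$base_log10_mean, cfg$base_log10_sd)
  })
  for (g in GROUP_LEVELS) {
    R <- build_group_correlation(cfg, g)
    U <- chol(R)
    Z <- with_seed(derive_seed(cfg$seed, paste0("lfq/latent/", g)), {
      matrix(stats::rnorm(n * J), n, J) %*% U
    })
    rows <- design$group == g
    X[rows, ] <- sweep(cfg$noise_log10_sd * Z, 2, mu, `+`)
  }
  for (s in lay$shifted) {
    rows <- design$group == s$group
    X[rows, s$proteins] <- X[rows, s$proteins] + s$shift
  }

  # Probabilistic left-censoring: decreasing logistic in the true value.
  if (cfg$censor_quantile > 0) {
    bound <- apply(X, 2, stats::quantile, probs = cfg$censor_quantile)
    B <- matrix(bound, nrow(X), ncol(X), byrow = TRUE)
    pmiss <- stats::plogis((B - X) / cfg$censor_softness)
    miss <- with_seed(derive_seed(cfg$seed, "lfq/censor"), {
      matrix(stats::runif(length(X)) < pmiss, nrow(X))
    })
  } else {
    bound <- rep(-Inf, J)
    miss <- matrix(FALSE, nrow(X), ncol(X))
  }
  names(bound) <- prot

  A <- 10^X
  A[miss] <- NA_real_

  keyword <- rep("Other", J)
  for (b in lay$blocks) keyword[b$proteins] <- b$tag
  for (h in lay$hubs) keyword[c(h$hub, h$neighbor_pool)] <- h$tag
  for (s in lay$shifted) keyword[s$proteins] <- s$keyword
  annotation <- data.frame(protein_id = prot, keyword = keyword,
                           stringsAsFactors = FALSE)

  differential <- sort(unique(unlist(lapply(lay$shifted, `[[`, "proteins"))))
  list(
    abundance = abundance_table(A, state = "raw"),
    design = design,
    annotation = annotation,
    truth = list(
      log10 = X,
      censoring_bound = bound,
      differential = prot[differential],
      group_networks = generate_group_networks(cfg),
      layout = lay
    )
  )
}

#' Reference binary adjacency matrices per group
#'
#' The ground-truth network implied by the configuration: unit diagonal,
#' complete subgraphs over each block active in the group, and hub-to-
#' neighbour edges for the group's neighbour count.  (Second-order
#' neighbour-neighbour correlations of the hub construction are treated as
#' background, not edges.)
#'
#' @param config A [synthetic_config()].
#' @return Named list of J x J binary symmetric matrices with unit
#'   diagonal, one per group.
#' @export
generate_group_networks <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lay <- synthetic_layout(config)
  J <- config$n_proteins
  prot <- sprintf("P%04d", seq_len(J))
  out <- lapply(stats::setNames(GROUP_LEVELS, GROUP_LEVELS), function(g) {
    A <- diag(J)
    dimnames(A) <- list(prot, prot)
    for (b in lay$blocks) {
      if (!g %in% b$groups) next
      A[b$proteins, b$proteins] <- 1
    }
    for (h in lay$hubs) {
      k <- if (g %in% names(h$neighbors)) h$neighbors[[g]] else 0
      if (k == 0) next
      nbrs <- h$neighbor_pool[seq_len(k)]
      A[h$hub, nbrs] <- A[nbrs, h$hub] <- 1
    }
    A
  })
  out
}

#' Generate a collection of matrices from the COVSCA model
#'
#' Inverts the COVSCA model for recovery tests:
#' `S_k = sum_l c_kl z_l z_l' + noise`, with symmetric Gaussian noise of
#' standard deviation `noise_sd`.
#'
#' @param n_matrices Number of matrices K.
#' @param prototypes List of unit-norm loading vectors (or single-column
#'   matrices).
#' @param weights K x L matrix of non-negative weights.
#' @param noise_sd Standard deviation of the symmetric noise (default 0).
#' @param seed Integer seed for the noise.
#' @return List of K symmetric matrices.
#' @export
generate_covariance_set <- function(n_matrices, prototypes, weights,
                                    noise_sd = 0, seed = 1) {
  protos <- lapply(prototypes, function(z) {
    z <- as.matrix(z)
    if (ncol(z) != 1) stop("prototypes must be vectors (rank 1)")
    z
  })
  weights <- as.matrix(weights)
  if (nrow(weights) != n_matrices || ncol(weights) != length(protos)) {
    stop("weights must be n_matrices x length(prototypes)")
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  J <- nrow(protos[[1]])
  with_seed(seed, {
    lapply(seq_len(n_matrices), function(k) {
      S <- matrix(0, J, J)
      for (l in seq_along(protos)) {
        S <- S + weights[k, l] * tcrossprod(protos[[l]])
      }
      if (noise_sd > 0) {
        E <- matrix(stats::rnorm(J * J, sd = noise_sd), J, J)
        S <- S + (E + t(E)) / 2
      }
      S
    })
  })
}

#' Write the synthetic dataset as the pipeline's three input files
#'
#' Emits `protein_table.tsv` (proteinGroups dialect with
#' `LFQ intensity <sample>` columns, missing written as 0), `design.csv`,
#' `annotation.csv` and `truth.json` into `dir`.
#'
#' @param dataset A [generate_lfq_dataset()] result.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_synthetic_inputs <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    protein_table = file.path(dir, "protein_table.tsv"),
    design = file.path(dir, "design.csv"),
    annotation = file.path(dir, "annotation.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_protein_table(dataset$abundance, paths[["protein_table"]])
  utils::write.csv(dataset$design[c("sample_id", "mother_allergy", "child_allergy")],
                   paths[["design"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$annotation, paths[["annotation"]],
                   row.names = FALSE, quote = FALSE)
  truth <- dataset$truth
  jsonlite::write_json(
    list(
      log10 = truth$log10,
      censoring_bound = truth$censoring_bound,
      differential = truth$differential
    ),
    paths[["truth"]], digits = NA, auto_unbox = TRUE
  )
  invisible(paths)
}
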