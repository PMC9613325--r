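# PCLRC: probabilistic correlation networks per study group.  Resampled
# Spearman correlation matrices are background-corrected with a CLR-style
# z-score transform; the fraction of resamples in which an edge ranks in
# the top `keep_fraction` gives its retention probability, and edges with
# probability >= tau keep their full-data Spearman weight.  Node
# connectivity and differential connectivity follow, with a label
# permutation null.

#' Spearman correlation matrix of one group
#'
#' Average-rank ties; constant proteins are rank-degenerate and get zero
#' correlations (with one warning) instead of NA.
#'
#' @param m Numeric matrix, samples x proteins, no missing cells (an
#'   `abundance_table` is also accepted).
#' @param warn_constant Warn when constant proteins are zeroed.
#' @return Symmetric proteins x proteins matrix with unit diagonal.
#' @export
spearman_matrix <- function(m, warn_constant = TRUE) {
  if (inherits(m, "abundance_table")) m <- m$values
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("spearman_matrix requires a complete matrix")
  if (nrow(m) < 3) stop("at least 3 samples required")
  r <- suppressWarnings(stats::cor(m, method = "spearman"))
  if (anyNA(r)) {
    if (warn_constant) {
      const <- colnames(m)[apply(m, 2, function(v) length(unique(v)) == 1)]
      warning("constant proteins set to zero correlation: ",
              paste(utils::head(const, 5), collapse = ", "))
    }
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  r
}

#' CLR background correction of a similarity matrix
#'
#' Operates on absolute similarities `M = |r|` with the diagonal excluded
#' from the row statistics: `z_ij^(i) = max(0, (M_ij - mu_i) / sd_i)` and
#' `CLR_ij = sqrt(z_ij^(i)^2 + z_ij^(j)^2)`.  Rows with zero spread yield
#' zero scores.  The output is symmetric, non-negative, with zero diagonal.
#'
#' @param r Symmetric similarity matrix (e.g. Spearman correlations).
#' @return Matrix of CLR scores.
#' @export
clr_transform <- function(r) {
  stopifnot(is.matrix(r))
  if (!isSymmetric(unname(r), tol = 1e-8)) stop("similarity matrix must be symmetric")
  M <- abs(r)
  diag(M) <- NA              # exclude self-similarity from row statistics
  mu <- rowMeans(M, na.rm = TRUE)
  sd_ <- apply(M, 1, stats::sd, na.rm = TRUE)
  z <- (M - mu) / ifelse(sd_ > 0, sd_, Inf)   # sd 0 -> z 0 via Inf divisor
  z[z < 0] <- 0
  z[is.na(z)] <- 0
  out <- sqrt(z^2 + t(z)^2)
  diag(out) <- 0
  out
}

#' Edge retention probabilities by resampled CLR ranking
#'
#' Per iteration, a fraction of the samples is drawn without replacement,
#' Spearman correlations are computed and CLR-corrected, and the top
#' `keep_fraction` of upper-triangle edges by CLR score are marked as
#' retained (ties broken deterministically by score then index order).
#' The retention probability of an edge is its retained count divided by
#' `n_iterations`.
#'
#' @param m Numeric matrix (samples x proteins) or `abundance_table` of one
#'   group, no missing cells.
#' @param n_iterations Resampling iterations (default 1000).
#' @param subsample_fraction Fraction of samples drawn per iteration
#'   (default 0.75, rounded up).
#' @param keep_fraction Fraction of upper-triangle edges retained per
#'   iteration (default 0.30).
#' @param seed Integer seed for the subsample streams.
#' @return Object of class `edge_probabilities`: list with `p` (symmetric
#'   probability matrix, unit diagonal) and the parameters used.
#' @export
estimate_edge_probabilities <- function(m, n_iterations = 1000,
                                        subsample_fraction = 0.75,
                                        keep_fraction = 0.30, seed = 1) {
  if (inherits(m, "abundance_table")) m <- m$values
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("estimate_edge_probabilities requires a complete matrix")
  if (keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must lie in (0, 1]")
  }
  n <- nrow(m)
  ns <- ceiling(subsample_fraction * n)
  if (ns < 4) stop("subsample size ", ns, " too small (need >= 4 samples)")
  J <- ncol(m)
  ut <- upper.tri(matrix(0, J, J))
  n_pairs <- sum(ut)
  keep_n <- max(1L, round(keep_fraction * n_pairs))
  counts <- numeric(n_pairs)

  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      idx <- sample.int(n, ns)
      r <- spearman_matrix(m[idx, , drop = FALSE], warn_constant = FALSE)
      s <- clr_transform(r)[ut]
      ord <- order(s, seq_along(s), decreasing = c(TRUE, FALSE), method = "radix")
      counts[ord[seq_len(keep_n)]] <- counts[ord[seq_len(keep_n)]] + 1
    }
  })

  p <- matrix(0, J, J, dimnames = list(colnames(m), colnames(m)))
  p[ut] <- counts / n_iterations
  p <- p + t(p)
  diag(p) <- 1
  structure(
    list(p = p, n_iterations = n_iterations,
         subsample_fraction = subsample_fraction,
         keep_fraction = keep_fraction),
    class = "edge_probabilities"
  )
}

#' Build the thresholded association network
#'
#' Edges with retention probability at least `tau` keep their full-data
#' Spearman weight (sign preserved); all other off-diagonal entries are
#' zero.  The diagonal is set to 1 so the connectivity formula's self-term
#' cancels.
#'
#' @param similarity Spearman matrix from [spearman_matrix()].
#' @param probabilities [estimate_edge_probabilities()] result (or a bare
#'   probability matrix).
#' @param tau Retention threshold (default 0.99).
#' @return Weighted adjacency matrix of class `association_network`.
#' @export
build_network <- function(similarity, probabilities, tau = 0.99) {
  p <- if (inherits(probabilities, "edge_probabilities")) probabilities$p else probabilities
  stopifnot(is.matrix(similarity), is.matrix(p))
  if (!all(dim(similarity) == dim(p))) stop("dimension mismatch")
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  w <- ifelse(p >= tau, similarity, 0)
  diag(w) <- 1
  dimnames(w) <- dimnames(similarity)
  class(w) <- c("association_network", class(w))
  w
}

#' Node connectivity of an association network
#'
#' `chi_i = (sum_j |w_ij|) - 1`: the weighted node strength, with the unit
#' diagonal cancelling the self term.  On a binary adjacency this equals
#' the node degree; an isolated protein has connectivity 0.
#'
#' @param network Weighted adjacency with unit diagonal.
#' @return Named numeric vector of per-protein connectivities.
#' @export
connectivity <- function(network) {
  w <- unclass(network)
  stopifnot(is.matrix(w))
  if (any(abs(diag(w) - 1) > 1e-12)) {
    stop("network diagonal must be 1 (self term convention)")
  }
  rowSums(abs(w)) - 1
}

#' Differential connectivity between two group networks
#'
#' Elementwise difference `Delta_i = chi_i(a) - chi_i(b)` over a shared
#' protein set.
#'
#' @param profile_a,profile_b Named connectivity vectors from
#'   [connectivity()].
#' @return Named numeric vector of differences.
#' @export
differential_connectivity <- function(profile_a, profile_b) {
  if (is.null(names(profile_a)) || is.null(names(profile_b)) ||
      !identical(names(profile_a), names(profile_b))) {
    stop("connectivity profiles must cover the same proteins in the same order")
  }
  profile_a - profile_b
}

# One PCLRC network + connectivity for a group matrix, under a given seed.
pclrc_connectivity <- function(m, n_iterations, subsample_fraction,
                               keep_fraction, tau, seed) {
  r <- spearman_matrix(m, warn_constant = FALSE)
  ep <- estimate_edge_probabilities(m, n_iterations = n_iterations,
                                    subsample_fraction = subsample_fraction,
                                    keep_fraction = keep_fraction, seed = seed)
  connectivity(build_network(r, ep, tau = tau))
}

#' Permutation p-values for differential connectivity
#'
#' Pools the two groups, permutes the group assignment preserving group
#' sizes, recomputes both PCLRC networks per permutation at a reduced
#' iteration budget, and compares permuted against observed differential
#' connectivity: two-sided raw
#' `p = (1 + #\{|Delta_perm| >= |Delta_obs|\}) / (n_permutations + 1)`,
#' Benjamini-Hochberg adjusted across proteins.  The observed statistic is
#' computed at the same reduced budget so observed and permuted values are
#' exchangeable under the null.
#'
#' @param m_a,m_b Complete samples x proteins matrices (or
#'   `abundance_table`s) of two disjoint groups, same proteins.
#' @param n_permutations Label permutations (>= 19 so p < 0.05 is reachable).
#' @param n_iterations PCLRC iterations per network per permutation
#'   (default 100).
#' @param subsample_fraction,keep_fraction,tau Passed to the PCLRC steps.
#' @param seed Integer seed.
#' @return Data frame with `protein_id`, `delta`, `p`, `p_adj`.
#' @export
dc_permutation_pvalues <- function(m_a, m_b, n_permutations = 99,
                                   n_iterations = 100,
                                   subsample_fraction = 0.75,
                                   keep_fraction = 0.30, tau = 0.99,
                                   seed = 1) {
  if (inherits(m_a, "abundance_table")) m_a <- m_a$values
  if (inherits(m_b, "abundance_table")) m_b <- m_b$values
  stopifnot(is.matrix(m_a), is.matrix(m_b))
  if (!identical(colnames(m_a), colnames(m_b))) {
    stop("the two groups must share the same protein set")
  }
  if (n_permutations < 19) {
    stop("n_permutations must be >= 19 to allow p < 0.05")
  }
  na <- nrow(m_a); nb <- nrow(m_b)
  pooled <- rbind(m_a, m_b)

  delta_for <- function(ma, mb, tag) {
    chi_a <- pclrc_connectivity(ma, n_iterations, subsample_fraction,
                                keep_fraction, tau,
                                derive_seed(seed, paste0(tag, "/a")))
    chi_b <- pclrc_connectivity(mb, n_iterations, subsample_fraction,
                                keep_fraction, tau,
                                derive_seed(seed, paste0(tag, "/b")))
    differential_connectivity(chi_a, chi_b)
  }

  obs <- delta_for(m_a, m_b, "dc/observed")
  exceed <- rep(0L, length(obs))
  for (b in seq_len(n_permutations)) {
    idx <- with_seed(derive_seed(seed, paste0("dc/permute/", b)),
                     sample.int(na + nb))
    perm <- delta_for(pooled[idx[seq_len(na)], , drop = FALSE],
                      pooled[idx[na + seq_len(nb)], , drop = FALSE],
                      paste0("dc/perm/", b))
    exceed <- exceed + (abs(perm) >= abs(obs))
  }
  p <- (1 + exceed) / (n_permutations + 1)
  data.frame(
    protein_id = names(obs),
    delta = unname(obs),
    p = unname(p),
    p_adj = benjamini_hochberg(unname(p)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Select differentially connected candidate proteins
#'
#' Per comparison, proteins whose differential connectivity exceeds
#' `delta_threshold` in magnitude (or signed, if `signed = TRUE`), plus the
#' intersection across comparisons.
#'
#' @param deltas Named list of differential-connectivity vectors (one per
#'   comparison), all over the same proteins.
#' @param delta_threshold Selection threshold (default 50).
#' @param signed Use signed `delta > threshold` instead of `|delta|`.
#' @return List with `selected` (named list of protein-id vectors) and
#'   `intersection`.
#' @export
select_candidates <- function(deltas, delta_threshold = 50, signed = FALSE) {
  stopifnot(is.list(deltas), length(deltas) >= 1)
  selected <- lapply(deltas, function(d) {
    v <- if (signed) d else abs(d)
    names(d)[v > delta_threshold]
  })
  list(selected = selected,
       intersection = Reduce(intersect, selected))
}

#' Write a weighted edge list
#'
#' One row per retained (nonzero, off-diagonal) edge with its weight and,
#' when available, retention probability.
#'
#' @param network Association network matrix.
#' @param probabilities Optional `edge_probabilities` (or matrix).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, probabilities = NULL, path) {
  w <- unclass(network)
  ut <- upper.tri(w)
  keep <- ut & w != 0
  idx <- which(keep, arr.ind = TRUE)
  df <- data.frame(
    protein_i = rownames(w)[idx[, 1]],
    protein_j = colnames(w)[idx[, 2]],
    weight = w[keep],
    stringsAsFactors = FALSE
  )
  if (!is.null(probabilities)) {
    p <- if (inherits(probabilities, "edge_probabilities")) probabilities$p else probabilities
    df$probability <- p[keep]
  }
  df <- df[order(df$protein_i, df$protein_j), , drop = FALSE]
  write_tsv(df, path)
}
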