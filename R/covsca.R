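# COVSCA: simultaneous component analysis of several symmetric matrices.
# The K group matrices are modelled as non-negative combinations of L
# shared low-rank prototypes, S_k ~ sum_l c_kl Z_l Z_l', fitted by
# alternating minimisation of the total squared Frobenius residual.

# Exact non-negative least squares for small L: minimise
# 0.5 x'Gx - b'x subject to x >= 0 by enumerating active sets.  G is the
# (L x L) Gram matrix of prototype features; L is tiny (2-4) in practice,
# so enumeration is both exact and cheap.
nnls_small <- function(G, b) {
  L <- length(b)
  best <- rep(0, L)
  best_obj <- 0
  for (mask in seq_len(2^L) - 1L) {
    act <- which(bitwAnd(mask, 2^(seq_len(L) - 1L)) > 0)
    if (length(act) == 0) next
    sol <- tryCatch(solve(G[act, act, drop = FALSE], b[act]),
                    error = function(e) NULL)
    if (is.null(sol) || any(sol < 0)) next
    x <- rep(0, L)
    x[act] <- sol
    obj <- 0.5 * sum(x * (G %*% x)) - sum(b * x)
    if (obj < best_obj - 1e-15) {
      best <- x
      best_obj <- obj
    }
  }
  best
}

# Reconstruction sum_l c_l Z_l Z_l' for one matrix.
covsca_reconstruct_one <- function(weights_k, loadings) {
  J <- nrow(loadings[[1]])
  out <- matrix(0, J, J)
  for (l in seq_along(loadings)) {
    if (weights_k[l] != 0) {
      out <- out + weights_k[l] * tcrossprod(loadings[[l]])
    }
  }
  out
}

covsca_objective <- function(S, weights, loadings) {
  sum(vapply(seq_along(S), function(k) {
    sum((S[[k]] - covsca_reconstruct_one(weights[k, ], loadings))^2)
  }, numeric(1)))
}

# One alternating-minimisation run from a given set of starting loadings.
covsca_run <- function(S, L, ranks, loadings, max_iter, tol) {
  K <- length(S)
  J <- nrow(S[[1]])
  weights <- matrix(0, K, L)
  trace <- numeric(0)
  obj <- Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # (a) weights step: exact NNLS per matrix over the prototype features.
    G <- matrix(0, L, L)
    for (l in seq_len(L)) {
      for (m in l:L) {
        G[l, m] <- G[m, l] <- sum(crossprod(loadings[[l]], loadings[[m]])^2)
      }
    }
    for (k in seq_len(K)) {
      b <- vapply(seq_len(L), function(l) {
        sum(loadings[[l]] * (S[[k]] %*% loadings[[l]]))
      }, numeric(1))
      weights[k, ] <- nnls_small(G, b)
    }
    # (b) loading step: per prototype, dominant eigenvectors of the
    # weighted residual aggregate (exact subproblem solution, so the
    # objective cannot increase).
    for (l in seq_len(L)) {
      if (all(weights[, l] == 0)) next
      M <- matrix(0, J, J)
      for (k in seq_len(K)) {
        if (weights[k, l] == 0) next
        resid <- S[[k]]
        for (mm in seq_len(L)) {
          if (mm != l && weights[k, mm] != 0) {
            resid <- resid - weights[k, mm] * tcrossprod(loadings[[mm]])
          }
        }
        M <- M + weights[k, l] * resid
      }
      eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
      loadings[[l]] <- eg$vectors[, seq_len(ranks[l]), drop = FALSE]
    }
    new_obj <- covsca_objective(S, weights, loadings)
    trace <- c(trace, new_obj)
    if (is.finite(obj) && obj - new_obj < tol * max(obj, 1e-300)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  list(weights = weights, loadings = loadings, objective = obj,
       trace = trace, converged = converged)
}

#' Fit a COVSCA model to a collection of symmetric matrices
#'
#' Alternating minimisation of
#' `sum_k || S_k - sum_l c_kl Z_l Z_l' ||_F^2` with non-negative weights
#' `c_kl` and unit-norm prototype loadings `Z_l` (orthonormal columns for
#' ranks above 1).  The weights step is an exact small non-negative least
#' squares; the loading step is a dominant-eigenvector update, so the
#' objective is non-increasing across iterations.  The best of `n_starts`
#' random initialisations plus one spectral start (eigenvectors of the mean
#' matrix) is returned, with component signs canonicalised (largest-
#' magnitude loading entry positive).
#'
#' @param S List of K symmetric matrices with identical dimensions.
#' @param L Number of prototypes (default 2).
#' @param ranks Integer vector of prototype ranks (default all 1).
#' @param n_starts Random restarts (default 20).
#' @param max_iter Iteration cap per start (default 1000).
#' @param tol Relative objective-decrease tolerance (default 1e-8).
#' @param seed Integer seed for the random starts.
#' @return Object of class `covsca_model`: list with `weights` (K x L),
#'   `loadings` (list of J x R_l matrices), `gof` (percent), `objective`,
#'   `trace` (objective per iteration of the winning start), `converged`,
#'   `n_starts`, `ranks`.
#' @export
fit_covsca <- function(S, L = 2, ranks = rep(1, L), n_starts = 20,
                       max_iter = 1000, tol = 1e-8, seed = 1) {
  stopifnot(is.list(S), length(S) >= 2, length(ranks) == L)
  K <- length(S)
  J <- nrow(S[[1]])
  for (k in seq_len(K)) {
    if (!is.matrix(S[[k]]) || !all(dim(S[[k]]) == J)) {
      stop("all matrices must be square with identical dimensions")
    }
    if (!isSymmetric(unname(S[[k]]), tol = 1e-10)) {
      stop("matrix ", k, " is not symmetric")
    }
  }
  if (L > K * J) stop("L exceeds K * J")

  total_ss <- sum(vapply(S, function(s) sum(s^2), numeric(1)))
  if (total_ss == 0) stop("all-zero collection cannot be fitted")

  unit_cols <- function(m) {
    qr.Q(qr(m))[, seq_len(ncol(m)), drop = FALSE]
  }
  spectral_start <- local({
    eg <- eigen(Reduce(`+`, S) / K, symmetric = TRUE)
    offs <- c(0, cumsum(ranks))
    lapply(seq_len(L), function(l) {
      cols <- (offs[l] + 1):offs[l + 1]
      cols <- pmin(cols, ncol(eg$vectors))
      eg$vectors[, cols, drop = FALSE]
    })
  })

  best <- NULL
  with_seed(seed, {
    for (st in seq_len(n_starts + 1)) {
      start <- if (st == 1) {
        spectral_start
      } else {
        lapply(seq_len(L), function(l) unit_cols(matrix(stats::rnorm(J * ranks[l]), J)))
      }
      run <- covsca_run(S, L, ranks, start, max_iter, tol)
      if (is.null(best) || run$objective < best$objective) best <- run
    }
  })

  # Sign canonicalisation: ZZ' is sign-invariant, so flips are free.
  for (l in seq_len(L)) {
    for (cc in seq_len(ncol(best$loadings[[l]]))) {
      v <- best$loadings[[l]][, cc]
      if (v[which.max(abs(v))] < 0) best$loadings[[l]][, cc] <- -v
    }
    rownames(best$loadings[[l]]) <- rownames(S[[1]])
  }
  dimnames(best$weights) <- list(names(S), paste0("component_", seq_len(L)))

  structure(
    list(weights = best$weights, loadings = best$loadings,
         gof = 100 * (1 - best$objective / total_ss),
         objective = best$objective, trace = best$trace,
         converged = best$converged, n_starts = n_starts, ranks = ranks),
    class = "covsca_model"
  )
}

#' @export
print.covsca_model <- function(x, ...) {
  cat(sprintf("<covsca_model> %d prototypes (ranks %s), GOF %.2f%%\n",
              length(x$loadings), paste(x$ranks, collapse = ","), x$gof))
  invisible(x)
}

#' Goodness of fit of a COVSCA model
#'
#' `100 * (1 - sum_k ||S_k - S_k_hat||_F^2 / sum_k ||S_k||_F^2)`.
#'
#' @param model A `covsca_model`.
#' @param S The collection the model was fitted to.
#' @return Percent of total squared Frobenius norm explained.
#' @export
goodness_of_fit <- function(model, S) {
  stopifnot(inherits(model, "covsca_model"), is.list(S))
  total_ss <- sum(vapply(S, function(s) sum(s^2), numeric(1)))
  if (total_ss == 0) stop("all-zero collection")
  resid <- covsca_objective(S, model$weights, model$loadings)
  100 * (1 - resid / total_ss)
}

#' Standardise COVSCA loadings and flag salient proteins
#'
#' Per component (loading column), loadings are z-scored across proteins
#' and proteins with `|z| > z_threshold` are flagged as the drivers of the
#' between-network differences.
#'
#' @param model A `covsca_model`.
#' @param z_threshold Selection threshold on `|z|` (default 2).
#' @return Data frame with `component`, `protein_id`, `loading`, `z`,
#'   `selected`.
#' @export
loading_selection <- function(model, z_threshold = 2) {
  stopifnot(inherits(model, "covsca_model"))
  rows <- list()
  for (l in seq_along(model$loadings)) {
    Z <- model$loadings[[l]]
    for (cc in seq_len(ncol(Z))) {
      v <- Z[, cc]
      s <- stats::sd(v)
      if (s == 0) stop("zero-variance loading vector in component ", l)
      z <- (v - mean(v)) / s
      comp <- if (ncol(Z) == 1) paste0("component_", l) else
        paste0("component_", l, ".", cc)
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp,
        protein_id = if (is.null(rownames(Z))) as.character(seq_along(v)) else rownames(Z),
        loading = unname(v),
        z = unname(z),
        selected = abs(z) > z_threshold,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
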