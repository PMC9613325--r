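# Left-censored (MNAR) imputation by ridge-regularised truncated-normal
# Gibbs sweeps.  Missing LFQ values are assumed to fall below the
# detection limit, so every imputed draw is truncated above at the
# protein's observed minimum on the log10 scale.

#' Impute left-censored missing values
#'
#' Iterative scheme on the log10 matrix: missing cells start at a fraction
#' of the protein's observed minimum; each sweep regresses every
#' incompletely observed protein on its most correlated peers
#' (ridge-regularised least squares on the currently completed matrix) and
#' redraws its missing cells from a normal centred at the prediction,
#' truncated above at that protein's observed minimum.  Sweeping stops when
#' the mean relative change of imputed cells drops below `tol` or after
#' `sweeps` sweeps; the returned matrix averages the imputed cells over the
#' last `average_last` sweeps to damp Monte-Carlo noise.
#'
#' Observed cells are never altered, and every imputed value respects the
#' truncation bound.
#'
#' @param x An `abundance_table` in state `"log10"` (a table without missing
#'   cells is returned unchanged in state `"log10-imputed"`).
#' @param sweeps Maximum number of Gibbs sweeps (default 20).
#' @param ridge_lambda Ridge penalty for the per-protein predictor
#'   (default 1, on standardised predictors' scale).
#' @param n_predictors Number of most-correlated peer proteins used as
#'   predictors (default 20).
#' @param init_fraction Missing cells start at `init_fraction` times the
#'   protein's observed minimum (default 0.9; log10 LFQ values are
#'   positive, so this starts below the bound).
#' @param tol Convergence threshold on the mean relative change of imputed
#'   cells per sweep (default 1e-3).
#' @param average_last Number of final sweeps averaged into the completed
#'   matrix (default 5).
#' @param seed Optional integer seed for the truncated-normal draws.
#' @return An object of class `imputation_result`: list with `table` (the
#'   completed `abundance_table`, state `"log10-imputed"`), `bounds`
#'   (per-protein truncation bound), `sweeps_run` and `convergence` (mean
#'   relative change per sweep).
#' @export
impute_left_censored <- function(x, sweeps = 20, ridge_lambda = 1,
                                 n_predictors = 20, init_fraction = 0.9,
                                 tol = 1e-3, average_last = 5, seed = NULL) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$state != "log10") stop("impute_left_censored expects state 'log10'")
  V <- x$values
  miss <- is.na(V)
  all_missing <- colSums(!miss) == 0
  if (any(all_missing)) {
    stop("fully missing proteins (apply the group-validity filter first): ",
         paste(utils::head(colnames(V)[all_missing], 5), collapse = ", "))
  }
  bounds <- apply(V, 2, min, na.rm = TRUE)

  if (!any(miss)) {
    return(structure(
      list(table = abundance_table(V, "log10-imputed"),
           bounds = bounds, sweeps_run = 0L, convergence = numeric(0)),
      class = "imputation_result"
    ))
  }

  miss_cols <- which(colSums(miss) > 0)
  # Start every missing cell below its truncation bound.
  for (j in miss_cols) {
    V[miss[, j], j] <- min(init_fraction * bounds[j], bounds[j])
  }

  J <- ncol(V)
  trace <- numeric(0)
  history <- list()

  with_seed(seed, {
    for (s in seq_len(sweeps)) {
      prev <- V[miss]
      cm <- suppressWarnings(stats::cor(V))
      cm[is.na(cm)] <- 0
      for (j in miss_cols) {
        mrows <- miss[, j]
        orows <- !mrows
        # Predictors: peers most correlated with protein j on current data.
        cj <- abs(cm[j, ])
        cj[j] <- -Inf
        m <- min(n_predictors, J - 1, max(1L, sum(orows) - 2L))
        pred <- order(cj, decreasing = TRUE)[seq_len(m)]
        Xo <- V[orows, pred, drop = FALSE]
        yo <- V[orows, j]
        mu_x <- colMeans(Xo)
        mu_y <- mean(yo)
        Xc <- sweep(Xo, 2, mu_x)
        G <- crossprod(Xc) + diag(ridge_lambda, m)
        beta <- solve(G, crossprod(Xc, yo - mu_y))
        fit_o <- mu_y + Xc %*% beta
        sigma <- sqrt(sum((yo - fit_o)^2) / max(1L, length(yo) - 1L))
        fit_m <- mu_y + sweep(V[mrows, pred, drop = FALSE], 2, mu_x) %*% beta
        V[mrows, j] <- rtruncnorm_upper(drop(fit_m), sigma, bounds[j])
      }
      delta <- mean(abs(V[miss] - prev) / pmax(abs(prev), 1e-8))
      trace <- c(trace, delta)
      history[[length(history) + 1L]] <- V[miss]
      if (length(history) > average_last) history[[1]] <- NULL
      if (delta < tol) break
    }
  })

  V[miss] <- Reduce(`+`, history) / length(history)
  # The mean of truncated draws respects the bound; clamp guards rounding.
  V[miss] <- pmin(V[miss], bounds[col(V)][miss])

  structure(
    list(table = abundance_table(V, "log10-imputed"),
         bounds = bounds, sweeps_run = length(trace), convergence = trace),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> %d sweeps, final change %.2e\n",
              x$sweeps_run,
              if (length(x$convergence)) utils::tail(x$convergence, 1) else 0))
  invisible(x)
}

# Draw from N(mean, sd) truncated above at `upper`, by inverse-CDF.
# Degenerate cases (sd ~ 0 or the upper tail numerically empty) collapse
# to min(mean, upper) resp. the bound itself.
rtruncnorm_upper <- function(mean, sd, upper) {
  n <- length(mean)
  if (sd <= 0 || !is.finite(sd)) return(pmin(mean, upper))
  pu <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n) * pu
  out <- stats::qnorm(pmax(u, 1e-300), mean, sd)
  out[pu < 1e-12] <- upper
  pmin(out, upper)
}

#' Constant-minimum imputation baseline
#'
#' Replaces every missing cell with its protein's observed minimum.  Used
#' as the reference against which the truncated-normal imputer's accuracy
#' is judged on synthetic left-censored data.
#'
#' @param x An `abundance_table` in state `"log10"`.
#' @return An `abundance_table` in state `"log10-imputed"`.
#' @export
impute_minimum <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$state != "log10") stop("impute_minimum expects state 'log10'")
  V <- x$values
  if (any(colSums(!is.na(V)) == 0)) stop("fully missing protein")
  bounds <- apply(V, 2, min, na.rm = TRUE)
  miss <- is.na(V)
  V[miss] <- bounds[col(V)][miss]
  abundance_table(V, "log10-imputed")
}
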