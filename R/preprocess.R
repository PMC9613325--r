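# Preprocessing: group-validity filter, log10 transform, unit-variance
# scaling.  Imputation lives in impute.R.

#' Filter proteins by per-group valid-value count
#'
#' Retains exactly the proteins observed (non-missing) at least `min_valid`
#' times in at least one study group.  This keeps proteins detected in only
#' one of the four groups, which a pooled-count filter would discard.
#'
#' @param x An `abundance_table` in state `"raw"` or `"log10"`.
#' @param design Study design data frame.
#' @param min_valid Minimum valid values required in some group (default 25).
#' @return The filtered `abundance_table`; per-group valid counts of the
#'   retained proteins are attached as attribute `valid_counts`.
#' @export
filter_by_group_validity <- function(x, design, min_valid = 25) {
  stopifnot(inherits(x, "abundance_table"))
  if (!x$state %in% c("raw", "log10")) {
    stop("filter applies to raw or log10 tables, not state '", x$state, "'")
  }
  g <- design_groups(x, design)
  sizes <- table(g)
  if (min_valid > max(sizes)) {
    stop("min_valid (", min_valid, ") exceeds the largest group size (",
         max(sizes), ")")
  }
  valid <- !is.na(x$values)
  counts <- rowsum(valid + 0, g)  # groups x proteins
  keep <- apply(counts >= min_valid, 2, any)
  out <- abundance_table(x$values[, keep, drop = FALSE], x$state)
  attr(out, "valid_counts") <- counts[, keep, drop = FALSE]
  out
}

#' Log10-transform observed abundances
#'
#' Missing cells stay missing; observed cells must be strictly positive.
#'
#' @param x An `abundance_table` in state `"raw"`.
#' @return An `abundance_table` in state `"log10"`.
#' @export
log10_transform <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$state != "raw") stop("log10_transform expects state 'raw'")
  bad <- which(!is.na(x$values) & x$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    labs <- apply(utils::head(bad, 5), 1, function(rc) {
      paste0(rownames(x$values)[rc[1]], "/", colnames(x$values)[rc[2]])
    })
    stop("non-positive observed values at: ", paste(labs, collapse = ", "))
  }
  abundance_table(log10(x$values), state = "log10")
}

#' Scale proteins to zero mean and unit variance
#'
#' @param x An `abundance_table` in state `"log10-imputed"` (or `"scaled"`,
#'   on which the operation is idempotent).
#' @return An `abundance_table` in state `"scaled"`.
#' @export
scale_unit_variance <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (!x$state %in% c("log10-imputed", "scaled")) {
    stop("scale_unit_variance expects state 'log10-imputed' or 'scaled'")
  }
  sds <- apply(x$values, 2, stats::sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero)) {
    stop("zero-variance proteins cannot be scaled: ",
         paste(utils::head(colnames(x$values)[zero], 10), collapse = ", "))
  }
  v <- scale(x$values, center = TRUE, scale = TRUE)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  abundance_table(unclass(v), state = "scaled")
}
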