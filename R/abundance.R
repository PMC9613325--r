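# Core containers: the samples x proteins abundance matrix and the 2x2
# mother/child allergy study design.

# Canonical order of the four mother/child allergy groups.
GROUP_LEVELS <- c("M+/C+", "M+/C-", "M-/C+", "M-/C-")

#' Construct an abundance table
#'
#' A light container for a samples x proteins LFQ matrix.  Missing values
#' are explicit `NA`s; zeros in LFQ exports are mapped to `NA` at read time
#' (non-detection, not true zero).  The `state` field tracks the
#' preprocessing stage so downstream functions can enforce their
#' preconditions.
#'
#' @param values Numeric matrix, samples in rows and proteins in columns,
#'   with unique `rownames` (sample ids) and `colnames` (protein ids).
#' @param state One of `"raw"`, `"log10"`, `"log10-imputed"`, `"scaled"`.
#' @return An object of class `abundance_table` with fields `values` and
#'   `state`.
#' @export
abundance_table <- function(values,
                            state = c("raw", "log10", "log10-imputed", "scaled")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x proteins)")
  }
  if (nrow(values) > 0 && is.null(rownames(values))) {
    stop("`values` must carry sample ids as rownames")
  }
  if (ncol(values) > 0 && is.null(colnames(values))) {
    stop("`values` must carry protein ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate protein ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (state == "raw" && any(values <= 0, na.rm = TRUE)) {
    stop("raw abundances must be strictly positive (zeros are missing values)")
  }
  if (state %in% c("log10-imputed", "scaled") && anyNA(values)) {
    stop("state '", state, "' admits no missing cells")
  }
  structure(list(values = values, state = state), class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf(
    "<abundance_table> %d samples x %d proteins, state = %s, %.1f%% missing\n",
    nrow(x$values), ncol(x$values), x$state,
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
as.matrix.abundance_table <- function(x, ...) x$values

#' Sample and protein identifiers of an abundance table
#'
#' @param x An `abundance_table`.
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) {
  ids <- rownames(x$values)
  if (is.null(ids)) character(0) else ids
}

#' @rdname sample_ids
#' @export
protein_ids <- function(x) {
  ids <- colnames(x$values)
  if (is.null(ids)) character(0) else ids
}

#' Construct a study design for the 2x2 mother/child allergy layout
#'
#' @param sample_id Character vector of unique sample ids.
#' @param mother_allergy,child_allergy Character vectors over `"+"` / `"-"`.
#' @return A data frame with columns `sample_id`, `mother_allergy`,
#'   `child_allergy` and the derived `group` label (`"M+/C-"` etc.).
#' @export
study_design <- function(sample_id, mother_allergy, child_allergy) {
  stopifnot(length(sample_id) == length(mother_allergy),
            length(sample_id) == length(child_allergy))
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in design")
  ok <- c("+", "-")
  if (!all(mother_allergy %in% ok) || !all(child_allergy %in% ok)) {
    stop("allergy status must be coded '+' or '-'")
  }
  data.frame(
    sample_id = as.character(sample_id),
    mother_allergy = mother_allergy,
    child_allergy = child_allergy,
    group = paste0("M", mother_allergy, "/C", child_allergy),
    stringsAsFactors = FALSE
  )
}

# Group labels aligned to the samples of `x`, as a factor.  Errors if any
# sample is unlabelled; by default requires all four groups to be present.
design_groups <- function(x, design, require_all_groups = FALSE) {
  ids <- sample_ids(x)
  idx <- match(ids, design$sample_id)
  if (anyNA(idx)) {
    stop("samples missing from design: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  }
  g <- factor(design$group[idx], levels = intersect(GROUP_LEVELS, design$group))
  if (require_all_groups && nlevels(g) < 4) {
    stop("all four mother/child allergy groups must be non-empty")
  }
  g
}

# Named list of per-group value matrices (samples x proteins).
group_matrices <- function(x, design) {
  g <- design_groups(x, design)
  lapply(stats::setNames(levels(g), levels(g)),
         function(lv) x$values[g == lv, , drop = FALSE])
}
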