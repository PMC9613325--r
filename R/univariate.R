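# Univariate screening: Kruskal-Wallis across the four mother/child
# allergy groups, Dunn's post-hoc pairwise comparisons, Benjamini-Hochberg
# correction and abundance-trend (volcano) summaries.

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing entries")
  }
  stats::p.adjust(p, method = "BH")
}

#' Kruskal-Wallis screen across study groups
#'
#' Applies the tie-corrected Kruskal-Wallis test to every protein, with the
#' chi-square reference on (groups - 1) degrees of freedom, and adjusts the
#' p-values across proteins by Benjamini-Hochberg.
#'
#' @param x An `abundance_table` (state `"log10-imputed"` in the standard
#'   pipeline; any complete table is accepted).
#' @param design Study design data frame.
#' @return Data frame with columns `protein_id`, `H`, `p`, `p_adj`.
#' @export
kruskal_wallis_screen <- function(x, design) {
  stopifnot(inherits(x, "abundance_table"))
  if (anyNA(x$values)) stop("Kruskal-Wallis screen requires a complete matrix")
  g <- design_groups(x, design)
  if (nlevels(g) < 2) stop("at least two groups required")
  if (any(table(g) < 2)) stop("every group needs at least 2 samples")
  res <- apply(x$values, 2, function(v) {
    if (length(unique(v)) == 1) return(c(H = 0, p = 1))
    kt <- stats::kruskal.test(v, g)
    c(H = unname(kt$statistic), p = unname(kt$p.value))
  })
  data.frame(
    protein_id = colnames(x$values),
    H = res["H", ],
    p = res["p", ],
    p_adj = benjamini_hochberg(res["p", ]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# Tie-corrected Dunn z statistic for one pair of groups, given pooled
# ranks.  N is the pooled sample size across *all* groups (Dunn's test
# ranks all groups jointly).
dunn_z <- function(ranks, g, a, b) {
  N <- length(ranks)
  ties <- table(ranks[duplicated(ranks) | duplicated(ranks, fromLast = TRUE)])
  tie_term <- if (length(ties)) sum(ties^3 - ties) / (12 * (N - 1)) else 0
  ra <- mean(ranks[g == a]); rb <- mean(ranks[g == b])
  na <- sum(g == a); nb <- sum(g == b)
  se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / na + 1 / nb))
  if (se == 0) return(0)
  (ra - rb) / se
}

#' Dunn's post-hoc pairwise comparisons
#'
#' For every candidate protein (uncorrected Kruskal-Wallis p below
#' `candidate_alpha`) and every pair of groups, computes the tie-corrected
#' Dunn z statistic on the jointly ranked data, a two-sided normal p-value,
#' and a Benjamini-Hochberg adjustment.  The adjustment family is either
#' all (protein, pair) tests pooled (default, conservative) or within each
#' protein.
#'
#' The `trend` column reports whether mean log10 abundance is higher
#' (`"up"`) or lower (`"down"`) in `group1` than in `group2`.
#'
#' @param x A complete `abundance_table`.
#' @param design Study design data frame.
#' @param kw Optional precomputed [kruskal_wallis_screen()] result.
#' @param candidate_alpha Uncorrected Kruskal-Wallis gate (default 0.05).
#' @param family `"pooled"` or `"per_protein"` Benjamini-Hochberg family.
#' @return Data frame with columns `protein_id`, `group1`, `group2`, `z`,
#'   `p`, `p_adj`, `trend`.  Empty (zero rows) when no protein passes the
#'   gate.
#' @export
dunn_posthoc <- function(x, design, kw = NULL, candidate_alpha = 0.05,
                         family = c("pooled", "per_protein")) {
  family <- match.arg(family)
  stopifnot(inherits(x, "abundance_table"))
  if (is.null(kw)) kw <- kruskal_wallis_screen(x, design)
  g <- design_groups(x, design)
  cand <- kw$protein_id[kw$p < candidate_alpha]
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  rows <- list()
  for (pid in cand) {
    v <- x$values[, pid]
    rk <- rank(v)
    gm <- tapply(v, g, mean)
    for (q in seq_len(ncol(pairs))) {
      a <- pairs[1, q]; b <- pairs[2, q]
      z <- dunn_z(rk, g, a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, group1 = a, group2 = b, z = z,
        p = 2 * stats::pnorm(-abs(z)),
        trend = if (gm[[a]] >= gm[[b]]) "up" else "down",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(protein_id = character(0), group1 = character(0),
                      group2 = character(0), z = numeric(0), p = numeric(0),
                      p_adj = numeric(0), trend = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- if (family == "pooled") {
    benjamini_hochberg(out$p)
  } else {
    stats::ave(out$p, out$protein_id, FUN = benjamini_hochberg)
  }
  out[c("protein_id", "group1", "group2", "z", "p", "p_adj", "trend")]
}

#' Abundance-trend summary for one pair of groups
#'
#' Per protein: the ratio of group-mean log10 abundances (volcano x-axis)
#' and the group in which the mean is higher.  Per keyword: counts of
#' proteins higher in each group.  Proteins absent from the annotation are
#' tallied under `"unannotated"`.
#'
#' @param x A complete `abundance_table` in log10 units.
#' @param design Study design data frame.
#' @param annotation Data frame with `protein_id`, `keyword`.
#' @param pair Character vector of two group labels, `c(group1, group2)`.
#' @return List with data frames `per_protein` (`protein_id`, `keyword`,
#'   `mean_log10_group1`, `mean_log10_group2`, `ratio`, `higher_in`) and
#'   `per_keyword` (`keyword`, `n`, `n_higher_group1`, `n_higher_group2`).
#' @export
abundance_trend_summary <- function(x, design, annotation, pair) {
  stopifnot(inherits(x, "abundance_table"), length(pair) == 2)
  if (anyNA(x$values)) stop("trend summary requires a complete matrix")
  g <- design_groups(x, design)
  if (!all(pair %in% levels(g))) stop("unknown group in pair: ",
                                      paste(setdiff(pair, levels(g)), collapse = ", "))
  m1 <- colMeans(x$values[g == pair[1], , drop = FALSE])
  m2 <- colMeans(x$values[g == pair[2], , drop = FALSE])
  kw <- annotation$keyword[match(colnames(x$values), annotation$protein_id)]
  kw[is.na(kw)] <- "unannotated"
  per_protein <- data.frame(
    protein_id = colnames(x$values),
    keyword = kw,
    mean_log10_group1 = m1,
    mean_log10_group2 = m2,
    ratio = m1 / m2,
    higher_in = ifelse(m1 > m2, pair[1], ifelse(m2 > m1, pair[2], "tie")),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  per_keyword <- do.call(rbind, lapply(split(per_protein, per_protein$keyword),
    function(d) data.frame(
      keyword = d$keyword[1],
      n = nrow(d),
      n_higher_group1 = sum(d$higher_in == pair[1]),
      n_higher_group2 = sum(d$higher_in == pair[2]),
      stringsAsFactors = FALSE
    )))
  rownames(per_keyword) <- NULL
  list(per_protein = per_protein, per_keyword = per_keyword,
       pair = pair)
}
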