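# Two-list overrepresentation analysis: upper-tail hypergeometric test of
# each annotation term among a selected protein set against the identified-
# protein background, Benjamini-Hochberg corrected across terms.

#' Two-list hypergeometric overrepresentation test
#'
#' For each term with at least one background member: with `N` background
#' proteins, `K` of them carrying the term, and `n` target proteins of
#' which `k` carry the term, the p-value is the upper hypergeometric tail
#' `P(X >= k)` (via `stats::phyper`).  Terms are adjusted across each other
#' by Benjamini-Hochberg.
#'
#' @param target Character vector of selected protein ids (must be a
#'   subset of `background`; may be empty).
#' @param background Character vector of all identified protein ids.
#' @param annotations Data frame with columns `protein_id` and a term
#'   column (`keyword` or `term`); multiple rows per protein allowed.
#' @return Data frame sorted by adjusted p: `term`, `background_size`,
#'   `term_size`, `target_size`, `overlap`, `p`, `p_adj`.
#' @export
overrepresentation_test <- function(target, background, annotations) {
  background <- unique(as.character(background))
  target <- unique(as.character(target))
  if (length(background) == 0) stop("background set is empty")
  missing_t <- setdiff(target, background)
  if (length(missing_t) > 0) {
    stop("target proteins outside the background: ",
         paste(utils::head(missing_t, 5), collapse = ", "))
  }
  term_col <- intersect(c("term", "keyword"), names(annotations))
  if (length(term_col) == 0 || !"protein_id" %in% names(annotations)) {
    stop("annotations need columns protein_id and term/keyword")
  }
  ann <- annotations[annotations$protein_id %in% background, , drop = FALSE]
  terms <- split(unique(ann[c("protein_id", term_col[1])])$protein_id,
                 unique(ann[c("protein_id", term_col[1])])[[term_col[1]]])
  N <- length(background)
  n <- length(target)
  rows <- lapply(names(terms), function(tm) {
    members <- terms[[tm]]
    K <- length(members)
    k <- length(intersect(members, target))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, background_size = N, term_size = K,
               target_size = n, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(0), background_size = integer(0),
                      term_size = integer(0), target_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE))
  }
  out$p_adj <- benjamini_hochberg(out$p)
  out <- out[order(out$p_adj, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
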