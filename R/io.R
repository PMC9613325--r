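# Readers and writers for the three input tables: MaxQuant-style
# proteinGroups TSV (or plain samples x proteins TSV), design CSV and
# annotation CSV.

#' Read a protein abundance table
#'
#' Auto-detects the dialect from the header.  A MaxQuant-style
#' `proteinGroups.txt` export is recognised by its `"LFQ intensity <sample>"`
#' columns (proteins in rows); otherwise the file is read as a plain
#' samples x proteins TSV whose first column holds sample ids.  Zeros and
#' blank cells are mapped to missing (`NA`): in LFQ exports a zero encodes
#' non-detection, not a true zero abundance.
#'
#' @param path Path to a tab-separated file.
#' @param exclude_flagged Drop rows flagged `"+"` in `Reverse`,
#'   `Potential contaminant` or `Only identified by site` columns (when
#'   present).  The number of excluded rows is attached as attribute
#'   `n_excluded`.
#' @return An [abundance_table()] in state `"raw"`.
#' @export
read_protein_table <- function(path, exclude_flagged = TRUE) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  lfq_cols <- grep("^LFQ intensity ", header, value = TRUE)
  id_like <- intersect(c("Protein IDs", "Majority protein IDs", "Protein ID"),
                       header)

  if (length(lfq_cols) > 0) {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
    id_col <- if (length(id_like) > 0) id_like[[1]] else header[[1]]
    flag_cols <- intersect(
      c("Reverse", "Potential contaminant", "Contaminant",
        "Only identified by site"),
      names(df)
    )
    n_excluded <- 0L
    if (exclude_flagged && length(flag_cols) > 0) {
      flagged <- Reduce(`|`, lapply(flag_cols, function(cl) {
        !is.na(df[[cl]]) & df[[cl]] == "+"
      }))
      n_excluded <- sum(flagged)
      df <- df[!flagged, , drop = FALSE]
    }
    prot <- as.character(df[[id_col]])
    if (anyDuplicated(prot)) {
      stop("duplicate protein ids in ", path, ": ",
           paste(unique(prot[duplicated(prot)]), collapse = ", "))
    }
    m <- as.matrix(df[, lfq_cols, drop = FALSE])
    storage.mode(m) <- "double"
    m[!is.na(m) & m == 0] <- NA_real_
    m <- t(m)  # -> samples x proteins
    rownames(m) <- sub("^LFQ intensity ", "", lfq_cols)
    colnames(m) <- prot
    out <- abundance_table(m, state = "raw")
    attr(out, "n_excluded") <- n_excluded
    return(out)
  }

  if (length(id_like) > 0) {
    stop("no 'LFQ intensity <sample>' columns detected; header parsed as: ",
         paste(utils::head(header, 8), collapse = " | "))
  }

  # Plain samples x proteins table, first column = sample id.
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  smp <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  m[!is.na(m) & m == 0] <- NA_real_
  rownames(m) <- smp
  out <- abundance_table(m, state = "raw")
  attr(out, "n_excluded") <- 0L
  out
}

#' Write an abundance table as a proteinGroups-style TSV
#'
#' Emits the dialect [read_protein_table()] consumes: one protein per row,
#' a `Protein IDs` column and one `LFQ intensity <sample>` column per
#' sample.  Missing cells are written as `0` (the LFQ non-detection
#' convention).
#'
#' @param x An `abundance_table` in state `"raw"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  if (x$state != "raw") stop("only raw abundance tables are written as LFQ exports")
  v <- t(x$values)  # proteins x samples
  v[is.na(v)] <- 0
  df <- data.frame(`Protein IDs` = rownames(v), check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(format(v, digits = 15, trim = TRUE, scientific = FALSE),
                        stringsAsFactors = FALSE)
  names(vals) <- paste("LFQ intensity", colnames(v))
  df <- cbind(df, vals)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a study design CSV
#'
#' Expects columns `sample_id`, `mother_allergy`, `child_allergy` with
#' `"+"`/`"-"` coding.
#'
#' @param path Path to a CSV file.
#' @return A design data frame (see [study_design()]).
#' @export
read_design_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("sample_id", "mother_allergy", "child_allergy")
  if (!all(need %in% names(df))) {
    stop("design CSV must have columns: ", paste(need, collapse = ", "))
  }
  study_design(df$sample_id, df$mother_allergy, df$child_allergy)
}

#' Read a protein annotation CSV
#'
#' Expects columns `protein_id` and `keyword`; a protein may appear on
#' several rows (one per keyword).
#'
#' @param path Path to a CSV file.
#' @return A data frame with columns `protein_id`, `keyword`.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "keyword")
  if (!all(need %in% names(df))) {
    stop("annotation CSV must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

# Deterministic TSV writer used for all pipeline outputs.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
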