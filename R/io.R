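# Tab-separated I/O: count tables (genes as rows, first column "gene"),
# sample sheets, and generic result tables. All output is plain text with a
# single header line; floats use 6 significant digits; gene order is
# preserved.

#' Read a count table
#'
#' Expects a tab-separated file whose first column (`gene`) holds gene ids
#' and whose remaining columns are sample counts.
#'
#' @param path file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_count_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene") {
    stop("count table must have 'gene' as its first column")
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene
  storage.mode(m) <- "double"
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers")
  }
  m
}

#' Write a count table
#'
#' @param counts genes x samples matrix with dimnames.
#' @param path file path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with columns `sample`, `time`, `fraction`, `replicate`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "time", "fraction", "replicate")
  miss <- setdiff(need, names(ss))
  if (length(miss)) {
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  }
  ss
}

#' Write a tab-separated result table
#'
#' Numeric columns are serialized with 6 significant digits.
#'
#' @param df data.frame.
#' @param path file path.
#' @export
write_result_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 6)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @param samples sample-sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  write_result_table(samples, path)
}
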