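# Tab-delimited matrix round-trips (features x samples).

#' Write a feature-by-sample matrix as tab-delimited text
#'
#' Header row of sample IDs, first column `feature_id`, values serialized at
#' 15 significant digits so that `read_matrix(write_matrix(x))` round-trips
#' to < 1e-9 absolute error.
#'
#' @param values numeric matrix with feature rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(values, path) {
  values <- as.matrix(values)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs: ",
         rownames(values)[duplicated(rownames(values))][1])
  dt <- data.table::data.table(feature_id = rownames(values) %||% character(0))
  for (j in seq_len(ncol(values)))
    dt[[colnames(values)[j]]] <- sprintf("%.15g", values[, j])
  if (nrow(values) == 0)
    dt <- data.table::setDT(c(list(feature_id = character(0)),
      stats::setNames(rep(list(character(0)), ncol(values)), colnames(values))))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a feature-by-sample matrix written by [write_matrix()]
#'
#' @param path input path.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, fill = FALSE,
                          colClasses = list(character = 1L))
  if (names(dt)[1] != "feature_id") stop("malformed matrix file: ", path)
  ids <- dt[[1]]
  if (anyDuplicated(ids)) stop("duplicate feature IDs in ", path)
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Convert a BinnedCoverage to / from the matrix file layout
#'
#' Features (bins) become rows, samples columns.
#' @param x a [binned_coverage()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_binned_coverage <- function(x, path) {
  write_matrix(t(x$values), path)
}
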