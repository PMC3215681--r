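# Tab-delimited interchange. All tables are TSV with a header row; gene
# identifiers live in the first column. Windows line endings are accepted.

#' Write / read a genes-by-design expression matrix as TSV
#'
#' The first column is `gene_id`; remaining columns follow the
#' `dose_time_rep` naming used throughout the package. Values round-trip
#' at full double precision.
#'
#' @param m Numeric matrix with gene ids as row names.
#' @param path Output file.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_matrix_tsv
#' @return For `read_matrix_tsv`, the numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene_id")
    stop("read_matrix_tsv: first column must be 'gene_id' in ", path,
         call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("read_matrix_tsv: duplicate gene_id '",
         df$gene_id[duplicated(df$gene_id)][1], "' in ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)[1, ]
    stop("read_matrix_tsv: non-numeric cell at row ", bad[1], ", column ",
         colnames(df)[bad[2] + 1], " in ", path, call. = FALSE)
  }
  rownames(m) <- df$gene_id
  m
}

#' Write / read a keyed table (e.g. p-values, labels, maps) as TSV
#'
#' @param df data.frame to write.
#' @param path File path.
#' @param required Column names that must be present on read.
#' @param key Column that must be unique (NULL to skip the check).
#' @export
write_table_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_table_tsv
#' @return For `read_table_tsv`, the data.frame.
#' @export
read_table_tsv <- function(path, required = NULL, key = "gene_id") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("read_table_tsv: missing column(s) ",
         paste(missing, collapse = ", "), " in ", path, call. = FALSE)
  if (!is.null(key) && key %in% colnames(df) && anyDuplicated(df[[key]]))
    stop("read_table_tsv: duplicate ", key, " '",
         df[[key]][duplicated(df[[key]])][1], "' in ", path, call. = FALSE)
  df
}
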