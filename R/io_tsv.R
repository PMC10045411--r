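# Plain-text table interfaces: expression P/A calls, ortholog maps,
# metabolite measurements, and measurement-to-exchange mappings.

#' Read present/absent expression calls from TSV
#'
#' Expected layout: a `gene_id` column followed by one column per replicate
#' containing `P`/`A` calls (or TRUE/FALSE).
#'
#' @param path TSV file.
#' @param condition condition label attached to the result.
#' @return an [expression_calls()] object.
#' @export
read_expression_tsv <- function(path, condition = "unknown") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df))
    abort_rgem("expression TSV must have a 'gene_id' column", "rgem_io_error")
  mat <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(mat) <- df$gene_id
  expression_calls(if (is.logical(mat)) mat else matrix(toupper(mat) == "P",
                                                        nrow(mat), ncol(mat),
                                                        dimnames = dimnames(mat)),
                   condition)
}

#' Write expression calls to TSV
#' @param calls an [expression_calls()] object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_expression_tsv <- function(calls, path) {
  mat <- ifelse(calls$calls, "P", "A")
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog mapping table (columns `source_id`, `target_id`)
#' @param path TSV file.
#' @return data.frame with `source_id`, `target_id`.
#' @export
read_ortholog_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source_id", "target_id") %in% names(df)))
    abort_rgem("ortholog TSV must have 'source_id' and 'target_id' columns",
               "rgem_io_error")
  df[, c("source_id", "target_id")]
}

#' Read metabolite measurements (columns `metabolite_id`, `fold_change`,
#' `p_value`)
#' @param path TSV file.
#' @return data.frame validated as a measurement table.
#' @export
read_measurements_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite_id", "fold_change", "p_value")
  if (!all(need %in% names(df)))
    abort_rgem(sprintf("measurements TSV must have columns: %s",
                       paste(need, collapse = ", ")), "rgem_io_error")
  validate_measurements(df[, need])
}

#' Read a measurement-to-exchange mapping (columns `metabolite_id`,
#' `exchange_id`)
#' @param path TSV file.
#' @return data.frame with `metabolite_id`, `exchange_id`.
#' @export
read_exchange_map_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("metabolite_id", "exchange_id") %in% names(df)))
    abort_rgem("mapping TSV must have 'metabolite_id' and 'exchange_id' columns",
               "rgem_io_error")
  df[, c("metabolite_id", "exchange_id")]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
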