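#' Read a medium definition from TSV
#'
#' Columns: `exchange_id`, `allowance`, optional logical/0-1 `trace`.
#'
#' @param path TSV path.
#' @param name medium name (default: file name).
#' @return a [medium_spec()].
#' @export
read_medium_tsv <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("exchange_id", "allowance")
  if (!all(need %in% names(df))) {
    stop("medium TSV needs columns: ", paste(need, collapse = ", "))
  }
  trace <- character()
  if ("trace" %in% names(df)) {
    trace <- df$exchange_id[as.logical(df$trace) %in% TRUE]
  }
  medium_spec(name,
              stats::setNames(df$allowance, df$exchange_id),
              trace_set = trace)
}

#' Read an expression matrix from TSV (genes x samples)
#'
#' First column holds gene ids; remaining columns are samples. A `# scale:`
#' comment line (or the `scale` argument) declares log2 vs linear values.
#'
#' @param path TSV path.
#' @param scale "linear" or "log2"; default read from a `# scale:` header
#'   comment, else "linear".
#' @return numeric matrix with a `scale` attribute.
#' @export
read_expression_tsv <- function(path, scale = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(scale)) {
    scale <- if (grepl("^#\\s*scale:\\s*log2", first)) "log2" else "linear"
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  attr(m, "scale") <- scale
  m
}

#' Write an expression matrix as TSV
#' @param expr matrix with optional `scale` attribute.
#' @param path output path.
#' @export
write_expression_tsv <- function(expr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sc <- attr(expr, "scale")
  if (!is.null(sc)) writeLines(paste0("# scale: ", sc), con)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a drug signature from TSV (`gene`, `direction` in up/down)
#'
#' @param path TSV path.
#' @param drug drug name (default: file name).
#' @return a [drug_signature()].
#' @export
read_signature_tsv <- function(path, drug = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "direction") %in% names(df))) {
    stop("signature TSV needs columns: gene, direction")
  }
  drug_signature(drug,
                 up_genes = df$gene[df$direction == "up"],
                 down_genes = df$gene[df$direction == "down"])
}

#' Read a drug-response AUC table (cell lines x compounds) from CSV
#'
#' First column holds cell-line ids.
#'
#' @param path CSV path.
#' @return numeric matrix.
#' @export
read_auc_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write an AUC table as CSV
#' @param auc matrix (cell lines x compounds).
#' @param path output path.
#' @export
write_auc_csv <- function(auc, path) {
  df <- data.frame(cell_line = rownames(auc), auc, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
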