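# Text-format glue: expression TSV, design tables, GMT gene sets, outputs.

#' Read an expression matrix from TSV
#'
#' Expected layout: first column gene identifiers, header row of sample
#' labels, tab-separated numeric values.
#'
#' @param path file path or connection.
#' @return numeric matrix, genes x samples, with dimnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df)
  if (!is.numeric(X)) stop("expression matrix contains non-numeric values")
  X
}

#' Write an expression matrix as TSV
#'
#' @param X numeric matrix, genes x samples (dimnames used for labels).
#' @param path output file path.
#' @param digits significant digits for numeric formatting.
#' @export
write_expression_tsv <- function(X, path, digits = 10L) {
  df <- data.frame(gene = rownames(X),
                   signif(X, digits), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample design table
#'
#' Two tab-separated columns with header: sample label, condition.
#'
#' @param path file path.
#' @return named character vector mapping sample -> condition.
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("design table needs two columns: sample, condition")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Derive condition labels from sample names
#'
#' Samples named `"condition.replicate"` (e.g. `"1h.2"`) are grouped by the
#' part before the final dot; names without a dot are their own condition.
#'
#' @param samples character vector of sample labels.
#' @return character vector of condition labels.
#' @export
conditions_from_labels <- function(samples) {
  sub("\\.[^.]*$", "", samples)
}

#' Convert a genes-by-samples matrix to an observation matrix
#'
#' The factorization operates on observations (conditions or time points) as
#' rows and genes as columns. Replicate samples of the same condition are
#' optionally averaged into one observation row.
#'
#' @param expr numeric matrix, genes x samples.
#' @param design optional named sample -> condition map (see
#'   [read_design_tsv()]); if `NULL`, conditions are derived from sample
#'   labels via [conditions_from_labels()].
#' @param average if `TRUE` (default) average replicates per condition.
#' @return numeric matrix, observations x genes.
#' @export
as_observation_matrix <- function(expr, design = NULL, average = TRUE) {
  X <- t(expr)
  if (!average) return(X)
  samples <- rownames(X)
  cond <- if (is.null(design)) {
    conditions_from_labels(samples)
  } else {
    unmatched <- setdiff(samples, names(design))
    if (length(unmatched) > 0L) {
      stop("samples missing from design: ", paste(unmatched, collapse = ", "))
    }
    design[samples]
  }
  average_replicates(X, cond)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("GMT line %d has fewer than 3 fields", bad[1L]))
  }
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

.write_matrix_tsv <- function(M, path, row_label, digits = 10L) {
  df <- data.frame(rownames(M), signif(as.matrix(M), digits),
                   check.names = FALSE)
  names(df)[1L] <- row_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write factorization outputs to a directory
#'
#' Emits `mixing.tsv` (observations x sources), `sources.tsv` (sources x
#' genes), `eigenvalues.tsv` and `run_metadata.txt`.
#'
#' @param result a `grade_result`.
#' @param dir output directory (created if absent).
#' @param digits significant digits in numeric output.
#' @export
write_grade_result <- function(result, dir, digits = 10L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(result$S)
  A <- result$A
  rownames(A) <- rownames(A) %||% paste0("obs", seq_len(nrow(A)))
  colnames(A) <- paste0("source", seq_len(n))
  S <- result$S
  rownames(S) <- paste0("source", seq_len(n))
  colnames(S) <- result$genes %||% paste0("g", seq_len(ncol(S)))
  .write_matrix_tsv(A, file.path(dir, "mixing.tsv"), "observation", digits)
  .write_matrix_tsv(S, file.path(dir, "sources.tsv"), "source", digits)
  ev <- data.frame(source = paste0("source", seq_len(n)),
                   eigenvalue = signif(result$eigenvalues, digits))
  utils::write.table(ev, file.path(dir, "eigenvalues.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- c(sprintf("package: grade %s",
                    as.character(utils::packageVersion("grade"))),
            sprintf("tau: %d", result$tau),
            sprintf("n_sources: %d", n),
            sprintf("sigma2: %g", result$whitening$sigma2),
            sprintf("ties: %s", isTRUE(result$ties)),
            sprintf("R: %s", R.version.string))
  writeLines(meta, file.path(dir, "run_metadata.txt"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
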