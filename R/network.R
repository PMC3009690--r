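# Prior-knowledge regulatory network: edge lists, weight matrices, G-shift.

#' Construct a regulatory graph from an edge table
#'
#' A regulatory graph is a directed, weighted graph over gene (or other
#' feature) identifiers. Edge weights are signed reals: positive weights
#' encode activating interactions, negative weights inhibiting ones.
#' Self-loops are permitted.
#'
#' @param edges data.frame with columns `source`, `target`, `weight`.
#' @param nodes optional character vector of node identifiers; the union of
#'   edge endpoints is always included, so this only adds isolated nodes.
#' @return An object of class `regulatory_graph`: a list with elements
#'   `edges` (data.frame) and `nodes` (character).
#' @export
regulatory_graph <- function(edges = NULL, nodes = character()) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "weight") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)
  if (anyNA(edges$weight)) {
    stop("edge weights must be numeric and non-missing")
  }
  key <- paste0(edges$source, "\r", edges$target)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    for (k in unique(dup)) {
      w <- unique(edges$weight[key == k])
      if (length(w) > 1L) {
        pair <- strsplit(k, "\r", fixed = TRUE)[[1L]]
        stop(sprintf("conflicting weights for duplicate edge %s -> %s: %s",
                     pair[1L], pair[2L], paste(w, collapse = ", ")))
      }
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  rownames(edges) <- NULL
  nodes <- union(as.character(nodes), union(edges$source, edges$target))
  structure(list(edges = edges, nodes = nodes), class = "regulatory_graph")
}

#' @export
print.regulatory_graph <- function(x, ...) {
  cat(sprintf("regulatory_graph: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    cat(sprintf("  weights in [%g, %g]\n",
                min(x$edges$weight), max(x$edges$weight)))
  }
  invisible(x)
}

#' Number of edges in a regulatory graph
#' @param graph a `regulatory_graph`.
#' @return integer edge count.
#' @export
n_edges <- function(graph) nrow(graph$edges)

# Interaction-keyword table used by curated-database exports that annotate
# edges with an effect term instead of a numeric weight. Activating terms
# map to +1, inhibiting terms to -1 (the minimal signed encoding).
.interaction_keywords <- c(
  "transactivation"          = 1,
  "increase of abundance"    = 1,
  "expression"               = 1,
  "activation"               = 1,
  "dna binding"              = 1,
  "increase of dna binding"  = 1,
  "transrepression"          = -1,
  "decrease of abundance"    = -1,
  "decrease of dna binding"  = -1,
  "inhibition"               = -1
)

.parse_weight <- function(tok, lineno) {
  w <- suppressWarnings(as.numeric(tok))
  if (!is.na(w)) return(w)
  kw <- .interaction_keywords[tolower(trimws(tok))]
  if (is.na(kw)) {
    stop(sprintf("line %d: cannot parse weight or interaction keyword '%s'",
                 lineno, tok))
  }
  unname(kw)
}

#' Read a network edge list
#'
#' Reads a directed weighted edge list into a [regulatory_graph()]. Two
#' dialects are supported:
#' \describe{
#'   \item{tsv}{three tab-separated columns: source, target, weight. The
#'     weight field may also be an interaction keyword (e.g.
#'     "activation", "inhibition"), mapped to +1/-1.}
#'   \item{sif}{source, relation, target; the relation is mapped through the
#'     same keyword table.}
#' }
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path file path or connection.
#' @param dialect `"tsv"` (default) or `"sif"`.
#' @param header logical; skip a first header line (tsv only).
#' @return a `regulatory_graph`.
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif"), header = FALSE) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  if (header && length(lines) > 0L) {
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0L) return(regulatory_graph())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected 3 tab-separated fields, got %d",
                 lineno[bad[1L]], length(parts[[bad[1L]]])))
  }
  fld <- function(i) vapply(parts, function(p) trimws(p[[i]]), "")
  if (dialect == "tsv") {
    src <- fld(1L); tgt <- fld(2L); wtok <- fld(3L)
  } else {
    src <- fld(1L); wtok <- fld(2L); tgt <- fld(3L)
  }
  w <- mapply(.parse_weight, wtok, lineno)
  regulatory_graph(data.frame(source = src, target = tgt, weight = w,
                              stringsAsFactors = FALSE))
}

#' Build the sparse weight matrix of a regulatory graph
#'
#' Aligns the graph with an ordered gene index and returns the l-by-l
#' propagator W, where `W[i, j]` is the weight of edge i -> j. Genes in the
#' index but absent from the network get all-zero rows and columns, so they
#' do not propagate activity (they contribute to zero-shift statistics only).
#'
#' @param graph a `regulatory_graph`.
#' @param index character vector of gene identifiers defining matrix order.
#' @param drop_missing if `TRUE`, silently drop edges whose endpoints are not
#'   in `index`; if `FALSE` (default), such edges are an error.
#' @param normalize_case if `TRUE`, match identifiers case-insensitively by
#'   upper-casing both sides. Default is exact, case-sensitive matching.
#' @return a sparse `Matrix::dgCMatrix` with `dimnames = list(index, index)`.
#' @export
to_weight_matrix <- function(graph, index, drop_missing = FALSE,
                             normalize_case = FALSE) {
  index <- as.character(index)
  if (anyDuplicated(index)) stop("gene index contains duplicate identifiers")
  e <- graph$edges
  src <- e$source; tgt <- e$target
  idx <- index
  if (normalize_case) {
    src <- toupper(src); tgt <- toupper(tgt); idx <- toupper(idx)
    if (anyDuplicated(idx)) stop("gene index not unique after case folding")
  }
  i <- match(src, idx)
  j <- match(tgt, idx)
  missing <- is.na(i) | is.na(j)
  if (any(missing) && !drop_missing) {
    offender <- unique(c(src[is.na(i)], tgt[is.na(j)]))
    stop(sprintf("network nodes not found in gene index: %s%s",
                 paste(utils::head(offender, 5L), collapse = ", "),
                 if (length(offender) > 5L) ", ..." else ""))
  }
  i <- i[!missing]; j <- j[!missing]; w <- e$weight[!missing]
  l <- length(index)
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(l, l),
                       dimnames = list(index, index))
}

#' Shift a data matrix along a graph
#'
#' The G-shift propagates feature activity one step along the weighted
#' directed graph encoded in W: the shifted activity of feature i is the
#' weight-summed activity of its predecessors. For a data matrix X (rows =
#' observations, columns = features) a shift by `tau >= 0` is `X %*% W^tau`;
#' negative shifts propagate against edge direction, `X %*% t(W)^|tau|`.
#' On the line graph 1 -> 2 -> ... -> l with unit weights this is exactly
#' the classic lag operator.
#'
#' W^tau is never materialized: the product is accumulated by repeated
#' sparse multiplication, which keeps the cost linear in the number of
#' edges.
#'
#' @param X numeric matrix (m x l) or vector (treated as 1 x l).
#' @param W weight matrix (l x l), dense or sparse.
#' @param tau integer shift; `tau = 0` returns `X` unchanged.
#' @return dense numeric matrix of the same shape as `X`.
#' @export
g_shift <- function(X, W, tau) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  stopifnot(length(tau) == 1L, tau == round(tau))
  if (ncol(X) != nrow(W) || nrow(W) != ncol(W)) {
    stop(sprintf("dimension mismatch: X has %d columns but W is %d x %d",
                 ncol(X), nrow(W), ncol(W)))
  }
  if (tau == 0) return(X)
  P <- if (tau > 0) W else Matrix::t(W)
  out <- X
  for (k in seq_len(abs(tau))) out <- out %*% P
  out <- as.matrix(out)
  dimnames(out) <- dimnames(X)
  out
}
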