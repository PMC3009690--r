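# Gene selection: expression filtering, probe collapsing and the
# moderated-t significance screen.

#' Filter genes by expression level
#'
#' A gene counts as expressed if its unlogged signal exceeds the threshold
#' in at least one sample (strictly above).
#'
#' @param X numeric matrix of unlogged intensities, genes x samples,
#'   nonnegative.
#' @param threshold expression cutoff (default 100).
#' @return list with `kept` (character vector of retained gene ids, or row
#'   indices when unnamed) and `report` (a `filter_report`: genes in/kept,
#'   rule, threshold).
#' @export
expression_filter <- function(X, threshold = 100) {
  X <- as.matrix(X)
  if (nrow(X) > 0L && any(X < 0)) stop("expected nonnegative intensities")
  if (nrow(X) > 0L && max(X) < 30) {
    warning("all intensities below 30: data look log-scaled, ",
            "but the filter expects unlogged values")
  }
  keep <- if (nrow(X) == 0L) logical(0) else
    apply(X, 1L, function(v) max(v) > threshold)
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  report <- structure(list(genes_in = nrow(X), genes_kept = sum(keep),
                           rule = sprintf("max signal > %g in >= 1 sample",
                                          threshold),
                           threshold = threshold),
                      class = "filter_report")
  list(kept = ids[keep], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("expression filter: kept %d of %d genes (%s)\n",
              x$genes_kept, x$genes_in, x$rule))
  invisible(x)
}

#' Collapse probe sets to genes
#'
#' When several probe sets map to one gene, keep the probe set with the
#' highest average intensity.
#'
#' @param X numeric matrix, probe sets x samples.
#' @param probe2gene named character vector mapping probe id -> gene id.
#' @param strategy currently only `"max_mean"`.
#' @return numeric matrix, genes x samples.
#' @export
collapse_probes <- function(X, probe2gene, strategy = c("max_mean")) {
  strategy <- match.arg(strategy)
  X <- as.matrix(X)
  probes <- rownames(X)
  if (is.null(probes)) stop("probe matrix must have probe-id rownames")
  gene <- probe2gene[probes]
  if (anyNA(gene)) stop("probes without gene mapping: ",
                        paste(utils::head(probes[is.na(gene)], 5L),
                              collapse = ", "))
  avg <- rowMeans(X)
  ord <- order(gene, -avg)
  pick <- ord[!duplicated(gene[ord])]
  out <- X[pick, , drop = FALSE]
  rownames(out) <- unname(gene[pick])
  out
}

#' Moderated-t screen for regulated genes
#'
#' Fits a per-gene linear model over conditions, tests every non-baseline
#' condition against the baseline with empirical-Bayes moderated
#' t-statistics (variance shrinkage toward a pooled prior, via limma), and
#' adjusts p-values by Benjamini-Hochberg across all genes and contrasts
#' jointly. A gene is significant if any contrast has adjusted p below
#' `alpha`.
#'
#' @param X log-scale matrix, genes x samples.
#' @param design condition label per sample (character or factor).
#' @param baseline the reference condition label.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @return list with `significant` (gene ids), `table` (genes x contrasts
#'   matrix of adjusted p-values), `raw_p` (same shape, unadjusted).
#' @export
moderated_t_screen <- function(X, design, baseline, alpha = 0.05) {
  X <- as.matrix(X)
  design <- as.character(design)
  stopifnot(length(design) == ncol(X))
  if (!baseline %in% design) stop("baseline condition not present in design")
  cond <- factor(design, levels = c(baseline, setdiff(unique(design),
                                                      baseline)))
  if (ncol(X) - nlevels(cond) < 1L) {
    stop("no residual degrees of freedom: need replicates to estimate ",
         "within-condition variance")
  }
  mm <- stats::model.matrix(~0 + cond)
  colnames(mm) <- levels(cond)
  fit <- limma::lmFit(X, mm)
  others <- setdiff(levels(cond), baseline)
  # condition labels like "0h" are not syntactic names, so the contrast
  # matrix (each condition minus baseline) is built directly
  contr <- matrix(0, ncol(mm), length(others),
                  dimnames = list(colnames(mm), others))
  contr[baseline, ] <- -1
  for (o in others) contr[o, o] <- 1
  fit2 <- limma::eBayes(limma::contrasts.fit(fit, contr))
  raw_p <- fit2$p.value
  adj <- matrix(bh_adjust(as.numeric(raw_p)), nrow(raw_p), ncol(raw_p),
                dimnames = dimnames(raw_p))
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  sig <- ids[apply(adj, 1L, function(p) any(p < alpha))]
  list(significant = sig, table = adj, raw_p = raw_p)
}
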