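# Differential-use / differential-expression statistics and hallmark calls.

#' Two-sample t-test (Welch by default)
#'
#' Thin wrapper over [stats::t.test()] with the degenerate cases pinned down:
#' when both groups are constant, equal values give `t = 0, p = 1` and
#' different values give `p = 0` with `degenerate = TRUE`. Welch's
#' unequal-variance form is the default because group variances across
#' heterogeneous cell lines and tissues rarely match; `pooled = TRUE` restores
#' the classical Student test.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance (Student) form.
#' @return list with elements `t`, `p`, `degenerate`.
#' @examples
#' welchT(c(1, 2, 3), c(4, 5, 6))
#' @export
welchT <- function(x, y, pooled = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    .validationError("both groups need at least 2 observations")
  if (anyNA(x) || anyNA(y)) .validationError("missing values are not allowed")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1, degenerate = FALSE))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(tt$statistic), p = unname(tt$p.value), degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input
#' (a wrapper over [stats::p.adjust()] with input validation).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted values, same length and order as `p`.
#' @export
bhFDR <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    .validationError("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differentially used features between two groups
#'
#' Per-feature Welch t-tests between two matrices of per-sample values
#' (fluxes for "differentially used" reactions, RPKM for differentially
#' expressed genes), with Benjamini-Hochberg correction across features.
#' Features with zero variance in both groups and equal means get `p = 1`.
#'
#' @param groupA,groupB numeric matrices, features x samples, same row order;
#'   at least 2 samples (columns) each.
#' @param featureIds feature identifiers; defaults to `rownames(groupA)`.
#' @param fdrLevel significance level on the adjusted values; default 0.01.
#' @param pooled passed to [welchT()].
#' @return data.frame with columns `feature_id`, `t`, `p`, `q`, `mean_a`,
#'   `mean_b`, `significant` (q < `fdrLevel`), in input feature order.
#' @export
differentialUse <- function(groupA, groupB, featureIds = rownames(groupA),
                            fdrLevel = 0.01, pooled = FALSE) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (nrow(groupA) != nrow(groupB))
    .validationError("both groups must have the same features (rows)")
  if (ncol(groupA) < 2L || ncol(groupB) < 2L)
    .validationError("need at least 2 samples per group")
  if (is.null(featureIds)) featureIds <- as.character(seq_len(nrow(groupA)))
  if (length(featureIds) != nrow(groupA))
    .validationError("featureIds must match the number of rows")
  if (nrow(groupA) < 2L)
    warning("fewer than 2 features: the FDR adjustment is vacuous", call. = FALSE)
  res <- t(vapply(seq_len(nrow(groupA)), function(i) {
    wt <- welchT(groupA[i, ], groupB[i, ], pooled = pooled)
    c(t = wt$t, p = wt$p)
  }, c(t = 0, p = 0)))
  q <- bhFDR(res[, "p"])
  data.frame(feature_id = featureIds, t = res[, "t"], p = res[, "p"], q = q,
             mean_a = rowMeans(groupA), mean_b = rowMeans(groupB),
             significant = q < fdrLevel,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Metabolic hallmarks: differentially used reactions with differentially expressed genes
#'
#' Intersects reaction-level and gene-level differential calls through the
#' model's gene associations: a reaction is a hallmark when it is itself
#' significant at `fdrLevel` and at least one of its associated genes is too.
#'
#' @param diffReactions data.frame from [differentialUse()] over reactions.
#' @param diffGenes data.frame from [differentialUse()] over genes.
#' @param model a [MetabolicModel-class] supplying the gene associations.
#' @param fdrLevel significance level; default 0.01.
#' @return data.frame with columns `reaction_id`, `genes`
#'   (semicolon-separated significant genes), `reaction_q`, `min_gene_q`.
#' @export
hallmarks <- function(diffReactions, diffGenes, model, fdrLevel = 0.01) {
  sigR <- diffReactions[diffReactions$q < fdrLevel, , drop = FALSE]
  sigG <- diffGenes[diffGenes$q < fdrLevel, , drop = FALSE]
  ga <- geneAssociations(model)
  rows <- lapply(seq_len(nrow(sigR)), function(i) {
    rid <- sigR$feature_id[i]
    genes <- intersect(ga[[rid]], sigG$feature_id)
    if (!length(genes)) return(NULL)
    data.frame(reaction_id = rid,
               genes = paste(genes, collapse = ";"),
               reaction_q = sigR$q[i],
               min_gene_q = min(sigG$q[match(genes, sigG$feature_id)]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(reaction_id = character(0), genes = character(0),
                      reaction_q = numeric(0), min_gene_q = numeric(0)))
  do.call(rbind, rows)
}
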