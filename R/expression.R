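#' Load an RPKM expression table
#'
#' Reads a CSV/TSV with one gene-id column and one column per sample (the
#' Human Protein Atlas export layout) and extracts one sample as an
#' [ExpressionProfile-class]. The delimiter is auto-detected from the
#' extension (`.csv` is comma-separated, anything else tab-separated). Missing
#' or empty cells become 0; negative values are rejected.
#'
#' @param path path to the table.
#' @param sample name of the sample column to extract.
#' @param geneCol name of the gene-id column; default `"gene"`.
#' @return an [ExpressionProfile-class].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("gene,A549,U251", "g1,12.5,3", "g2,,7"), tf)
#' p <- readExpressionTable(tf, "A549")
#' expressionValues(p)   # g2 is 0: empty cell
#' @export
readExpressionTable <- function(path, sample, geneCol = "gene") {
  if (!file.exists(path)) .ioError(sprintf("expression table not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", na.strings = c("", "NA"))
  if (!geneCol %in% names(df))
    .configError(sprintf("no gene-id column %s in %s (columns: %s)",
                         dQuote(geneCol), basename(path),
                         paste(names(df), collapse = ", ")))
  if (!sample %in% names(df))
    .configError(sprintf("no sample column %s in %s (available: %s)",
                         dQuote(sample), basename(path),
                         paste(setdiff(names(df), geneCol), collapse = ", ")))
  genes <- as.character(df[[geneCol]])
  if (anyDuplicated(genes))
    .validationError(sprintf("duplicated gene id(s) in %s: %s", basename(path),
                             paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  vals <- suppressWarnings(as.numeric(df[[sample]]))
  vals[is.na(vals)] <- 0
  if (any(vals < 0))
    .validationError(sprintf("negative RPKM value(s) for sample %s in %s",
                             sample, basename(path)))
  expressionProfile(sample, stats::setNames(vals, genes))
}

#' Construct an expression profile directly
#'
#' @param sample sample identifier.
#' @param values named numeric vector, gene id -> RPKM (>= 0).
#' @return an [ExpressionProfile-class].
#' @export
expressionProfile <- function(sample, values) {
  new("ExpressionProfile", sampleId = sample, values = values)
}

#' Expression level of a reaction
#'
#' The expression assigned to a gene-associated reaction is the maximum RPKM
#' over its associated genes: when several genes enable a reaction, the highest
#' expressed one is taken to set the capacity. Genes absent from the profile
#' contribute 0 (absence is read as non-expression).
#'
#' @param model a [MetabolicModel-class].
#' @param reaction a reaction id with a non-empty gene association.
#' @param profile an [ExpressionProfile-class].
#' @return the reaction's RPKM level (numeric scalar).
#' @examples
#' m <- makeFixtureModel("CHAIN3")
#' p <- expressionProfile("s", c(g1 = 37))
#' reactionExpression(m, "R1", p)
#' @export
reactionExpression <- function(model, reaction, profile) {
  i <- match(reaction, reactionIds(model))
  if (is.na(i)) .validationError(sprintf("unknown reaction id: %s", reaction))
  g <- model@genes[[i]]
  if (!length(g))
    .contractError(sprintf(
      "reaction %s has no gene association; callers must skip gene-less reactions",
      reaction))
  .maxExpression(g, profile@values)
}

.maxExpression <- function(genes, values) {
  hit <- values[genes]
  hit[is.na(hit)] <- 0
  max(hit)
}

#' Round up to a granularity
#'
#' Smallest multiple of `g` that is greater than or equal to `x`; 0 maps to 0.
#' Discretising expression this way (default granularity 10 RPKM) avoids
#' numerical noise in the downstream linear programs. Vectorised over `x`.
#'
#' @param x non-negative numeric vector (RPKM).
#' @param g positive granularity.
#' @return numeric vector of the same length as `x`.
#' @examples
#' roundUpTo(c(0, 37, 40), 10)   # 0, 40, 40
#' @export
roundUpTo <- function(x, g) {
  if (g <= 0) .validationError("granularity must be > 0")
  if (any(x < 0)) .validationError("cannot round negative expression values")
  m <- ceiling(x / g) * g
  # exact correction for floating-point quotients that land just above an integer
  over <- (m - g) >= x
  m[over] <- m[over] - g
  m
}
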