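#' Load a genes x samples expression matrix from TSV
#'
#' Reads a tab-separated matrix whose first row holds sample identifiers and
#' whose first column holds gene symbols. Rows with an empty gene symbol are
#' dropped (probe sets without a symbol carry no usable identity); rows
#' sharing a symbol are collapsed by averaging.
#'
#' @param path path to the TSV file.
#' @param groupFile optional path to a two-column TSV (sample, group) mapping
#'   each sample to its biological group.
#' @param logTransformed logical; `TRUE` when the file already holds log2
#'   values.
#' @return A [MirExpression-class] object.
#' @export
loadExpression <- function(path, groupFile = NULL, logTransformed = FALSE) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (nrow(tab) == 0L) stop("expression file '", path, "' has no data rows")
  sym <- trimws(tab[[1L]])
  body <- tab[, -1L, drop = FALSE]
  vals <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body))))
  vals <- matrix(vals, nrow = nrow(body),
                 dimnames = list(NULL, colnames(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "malformed numeric cell at row '%s' (line %d), column '%s'",
      sym[bad[1L]], bad[1L] + 1L, colnames(vals)[bad[2L]]))
  }
  keep <- !is.na(sym) & sym != ""
  sym <- sym[keep]
  vals <- vals[keep, , drop = FALSE]
  if (!nrow(vals)) stop("no rows with a gene symbol in '", path, "'")
  if (anyDuplicated(sym)) {
    grp <- factor(sym, levels = unique(sym))
    vals <- rowsum(vals, grp) / as.vector(table(grp))
    sym <- levels(grp)
  }
  rownames(vals) <- sym
  groups <- NULL
  if (!is.null(groupFile)) {
    gm <- read.delim(groupFile, header = FALSE, sep = "\t",
                     colClasses = "character")
    groups <- setNames(gm[[2L]], gm[[1L]])
  }
  MirExpression(vals, groupLabels = groups, logTransformed = logTransformed)
}

.recordStep <- function(x, step) {
  metadata(x)$steps <- c(metadata(x)$steps, step)
  x
}

#' @rdname averageGroups
#' @export
setGeneric("averageGroups", function(x) standardGeneric("averageGroups"))

#' Average samples within each biological group
#'
#' Replaces the sample columns by one column per biological group, the
#' arithmetic mean of the group's member samples. Groups keep their
#' first-appearance order.
#'
#' @param x a [MirExpression-class] with group labels for every sample.
#' @return A [MirExpression-class] with one column per group.
#' @export
setMethod("averageGroups", "MirExpression", function(x) {
  g <- groupLabels(x)
  if (is.null(g)) stop("no group labels present")
  miss <- colnames(x)[is.na(g) | g == ""]
  g <- as.character(g)
  if (length(miss))
    stop("samples without a group label: ", paste(miss, collapse = ", "))
  lev <- unique(g)
  m <- exprValues(x)
  out <- vapply(lev, function(gr)
    rowMeans(m[, g == gr, drop = FALSE]), numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), lev))
  res <- MirExpression(out, groupLabels = setNames(lev, lev),
                       logTransformed = isLogTransformed(x))
  metadata(res)$steps <- metadata(x)$steps
  .recordStep(res, "averageGroups")
})

#' @rdname clipOutliers
#' @export
setGeneric("clipOutliers", function(x, ...) standardGeneric("clipOutliers"))

#' Clip per-gene outliers at quartile fences
#'
#' Per gene (row), computes lower/upper quantiles `qLow`/`qHigh` (linear
#' interpolation between order statistics) and replaces values below
#' `l = qLow - multiplier * (qHigh - qLow)` with `l` and values above
#' `u = qHigh + multiplier * (qHigh - qLow)` with `u` (Tukey fences at the
#' default 25th/75th percentiles and multiplier 1.5). Constant rows collapse
#' the fences onto the constant and pass through unchanged.
#'
#' @param x a [MirExpression-class].
#' @param qLow,qHigh fence quantile levels in percent (defaults 25 and 75).
#' @param multiplier fence width as a multiple of the inter-quantile range.
#' @param literalQuartiles if `TRUE`, use the literal second and fourth
#'   quartiles (median and maximum) instead of the 25th/75th percentiles.
#' @return A clipped [MirExpression-class]; idempotent.
#' @export
setMethod("clipOutliers", "MirExpression",
          function(x, qLow = 25, qHigh = 75, multiplier = 1.5,
                   literalQuartiles = FALSE) {
  stopifnot(qLow < qHigh, multiplier > 0)
  if (literalQuartiles) { qLow <- 50; qHigh <- 100 }
  m <- exprValues(x)
  p <- c(qLow, qHigh) / 100
  for (i in seq_len(nrow(m))) {
    q <- quantile(m[i, ], probs = p, names = FALSE, type = 7)
    iqr <- q[2L] - q[1L]
    m[i, ] <- pmin(pmax(m[i, ], q[1L] - multiplier * iqr),
                   q[2L] + multiplier * iqr)
  }
  res <- MirExpression(m, groupLabels = groupLabels(x),
                       logTransformed = isLogTransformed(x))
  metadata(res)$steps <- metadata(x)$steps
  .recordStep(res, "clipOutliers")
})

#' @rdname logTransform
#' @export
setGeneric("logTransform", function(x, ...) standardGeneric("logTransform"))

#' Log2-transform expression values
#'
#' Elementwise `log2(value + offset)`. Repression by several miRNAs is
#' treated as multiplicative on the linear scale, hence additive after the
#' log transform; the regression model therefore consumes log2 values. The
#' object records that the transform has been applied and refuses to apply
#' it twice.
#'
#' @param x a [MirExpression-class] on linear scale.
#' @param offset non-negative pseudo-value added before taking logs.
#' @return A log2-scale [MirExpression-class].
#' @export
setMethod("logTransform", "MirExpression", function(x, offset = 0) {
  stopifnot(offset >= 0)
  if (isLogTransformed(x))
    stop("values are already on log2 scale")
  m <- exprValues(x)
  bad <- which(m + offset <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive value after offset at gene '%s', sample '%s'",
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  res <- MirExpression(log2(m + offset), groupLabels = groupLabels(x),
                       logTransformed = TRUE)
  metadata(res)$steps <- metadata(x)$steps
  .recordStep(res, "logTransform")
})

#' @rdname centerRows
#' @export
setGeneric("centerRows", function(x) standardGeneric("centerRows"))

#' Center each gene's profile to its down-regulation profile
#'
#' Subtracts the row mean from each gene's profile, yielding the
#' down-regulation profile used as the regression response: negative entries
#' mark samples in which the gene sits below its own average expression.
#'
#' @param x a [MirExpression-class].
#' @return A list with `delta` (genes x samples matrix of centered
#'   profiles, each row summing to zero) and `rowMean` (named vector of the
#'   subtracted means).
#' @export
setMethod("centerRows", "MirExpression", function(x) {
  m <- exprValues(x)
  mu <- rowMeans(m)
  list(delta = m - mu, rowMean = mu)
})

#' @rdname geneVariation
#' @export
setGeneric("geneVariation", function(x) standardGeneric("geneVariation"))

#' Gene-variation index
#'
#' Variance (unbiased, n-1 denominator) of each gene's expression across all
#' samples/groups. Genes under miRNA control tend to vary more across
#' conditions, so the index is itself a simple repression predictor.
#'
#' @param x a [MirExpression-class] with at least two columns.
#' @return data.frame with columns `gene_id` and `variance`.
#' @export
setMethod("geneVariation", "MirExpression", function(x) {
  if (ncol(x) < 2L)
    stop("gene variation requires at least two samples (n-1 denominator)")
  m <- exprValues(x)
  data.frame(gene_id = rownames(m),
             variance = apply(m, 1L, var),
             row.names = NULL)
})

#' @rdname varianceFilter
#' @export
setGeneric("varianceFilter", function(x, ...) standardGeneric("varianceFilter"))

#' Drop genes with near-constant expression
#'
#' Keeps genes whose gene-variation index is at least `minVariance`; a gene
#' that never moves carries no down-regulation signal to regress on. Kept and
#' dropped gene lists are recorded in `metadata(x)$varianceFilter`.
#'
#' @param x a [MirExpression-class].
#' @param minVariance non-negative variance threshold (default 0: filter off).
#' @return The filtered [MirExpression-class].
#' @export
setMethod("varianceFilter", "MirExpression", function(x, minVariance = 0) {
  stopifnot(minVariance >= 0)
  gv <- geneVariation(x)
  keep <- gv$variance >= minVariance
  if (!any(keep))
    warning("variance filter removed every gene")
  m <- exprValues(x)[keep, , drop = FALSE]
  res <- MirExpression(m, groupLabels = groupLabels(x),
                       logTransformed = isLogTransformed(x))
  metadata(res)$steps <- metadata(x)$steps
  metadata(res)$varianceFilter <- list(kept = gv$gene_id[keep],
                                       dropped = gv$gene_id[!keep],
                                       minVariance = minVariance)
  .recordStep(res, "varianceFilter")
})

#' Standard expression preprocessing pipeline
#'
#' Applies, in order: group averaging (when labels are present), per-gene
#' quartile-fence clipping, log2 transform (skipped when the input is
#' already on log scale or `log = FALSE`), and the variance filter.
#' Averaging precedes the log transform because linear-scale intensities
#' average on the scale they were measured on; clipping acts on the matrix
#' the regression actually consumes.
#'
#' @param x a [MirExpression-class].
#' @param clip logical, apply quartile-fence clipping.
#' @param qLow,qHigh,multiplier,literalQuartiles see [clipOutliers()].
#' @param log logical, apply [logTransform()] if not yet applied.
#' @param offset log offset.
#' @param minVariance variance-filter threshold.
#' @return A preprocessed [MirExpression-class].
#' @export
preprocessExpression <- function(x, clip = TRUE, qLow = 25, qHigh = 75,
                                 multiplier = 1.5, literalQuartiles = FALSE,
                                 log = TRUE, offset = 0, minVariance = 0) {
  if (!is.null(groupLabels(x)) &&
      length(unique(groupLabels(x))) < ncol(x))
    x <- averageGroups(x)
  if (clip)
    x <- clipOutliers(x, qLow = qLow, qHigh = qHigh, multiplier = multiplier,
                      literalQuartiles = literalQuartiles)
  if (log && !isLogTransformed(x))
    x <- logTransform(x, offset = offset)
  if (minVariance > 0)
    x <- varianceFilter(x, minVariance = minVariance)
  x
}

#' Write an expression matrix (or centered profiles) to TSV
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param idColumn header for the first (gene symbol) column.
#' @return `path`, invisibly.
#' @export
writeExpressionTSV <- function(m, path, idColumn = "gene_id") {
  out <- data.frame(rownames(m), m, check.names = FALSE)
  names(out)[1L] <- idColumn
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
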