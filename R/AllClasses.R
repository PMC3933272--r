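#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom Matrix Matrix
#' @importFrom Matrix sparseMatrix colSums rowSums
#' @importFrom stats quantile var cor median rnorm rexp runif rbinom phyper
#'   fisher.test p.adjust wilcox.test optim setNames sd
#' @importFrom utils read.delim write.table head
NULL

#' MirExpression: a genes x samples expression container
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `exprs` assay of finite expression values (log2 scale once
#' [logTransform()] has been applied), unique non-empty gene symbols as row
#' names, unique sample labels as column names, and an optional per-sample
#' biological-group label in `colData(x)$group`. Flags recording which
#' preprocessing steps have been applied live in `metadata(x)`.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @export
setClass("MirExpression", contains = "SummarizedExperiment")

.validMirExpression <- function(object) {
  msg <- NULL
  m <- assay(object, "exprs")
  if (nrow(m) > 0 &&
      (is.null(rownames(m)) || anyNA(rownames(m)) || any(rownames(m) == "")))
    msg <- c(msg, "gene identifiers (rownames) must be non-empty")
  if (anyDuplicated(rownames(m)))
    msg <- c(msg, "gene identifiers must be unique")
  if (ncol(m) > 0 && (is.null(colnames(m)) || anyDuplicated(colnames(m))))
    msg <- c(msg, "sample identifiers (colnames) must be present and unique")
  if (!all(is.finite(m)))
    msg <- c(msg, "expression values must all be finite")
  if (is.null(msg)) TRUE else msg
}
setValidity("MirExpression", .validMirExpression)

#' Construct a MirExpression object
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample labels).
#' @param groupLabels optional character vector (or named map, names =
#'   sample labels) assigning each sample to a biological group.
#' @param logTransformed logical; set `TRUE` when `values` are already on
#'   log2 scale so that [logTransform()] is not applied twice.
#' @return A [MirExpression-class] object.
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' MirExpression(m, logTransformed = TRUE)
#' @export
MirExpression <- function(values, groupLabels = NULL, logTransformed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  cd <- DataFrame(row.names = colnames(values))
  if (!is.null(groupLabels)) {
    if (!is.null(names(groupLabels)))
      groupLabels <- groupLabels[colnames(values)]
    if (length(groupLabels) != ncol(values))
      stop("'groupLabels' must have one entry per sample")
    # unlabeled samples (NA/empty) are tolerated here; averageGroups
    # reports them
    cd$group <- as.character(groupLabels)
  }
  se <- SummarizedExperiment(assays = list(exprs = values), colData = cd)
  obj <- new("MirExpression", se)
  metadata(obj)$logTransformed <- isTRUE(logTransformed)
  metadata(obj)$steps <- character()
  obj
}

#' @describeIn MirExpression expression matrix accessor.
#' @param x a `MirExpression` object.
#' @export
exprValues <- function(x) assay(x, "exprs")

#' @describeIn MirExpression per-sample group labels (`NULL` when absent).
#' @export
groupLabels <- function(x) {
  if ("group" %in% colnames(colData(x))) colData(x)$group else NULL
}

#' @describeIn MirExpression has the log2 transform been applied?
#' @export
isLogTransformed <- function(x) isTRUE(metadata(x)$logTransformed)

setMethod("show", "MirExpression", function(object) {
  cat("MirExpression:", nrow(object), "genes x", ncol(object), "samples\n")
  g <- groupLabels(object)
  if (!is.null(g))
    cat("  groups:", length(unique(g)), "\n")
  st <- metadata(object)$steps
  cat("  log2 scale:", isLogTransformed(object),
      if (length(st)) paste0("| steps: ", paste(st, collapse = " -> ")) else "",
      "\n")
})

#' MirTargetNetwork: candidate miRNA-family x mRNA network
#'
#' Binary gene x miRNA-family incidence (sequence-predicted candidate
#' regulation), optionally annotated with per-site records carrying the site
#' start, 3'UTR length and the relative site position (start / UTR length).
#'
#' @slot genes ordered character vector of gene symbols.
#' @slot families ordered character vector of miRNA family identifiers.
#' @slot adjacency sparse logical gene x family incidence matrix.
#' @slot sites data.frame of site records (`gene_id`, `family_id`,
#'   `site_start`, `utr_length`, `relative_position`); zero rows when the
#'   network was built from a plain edge list.
#' @export
setClass("MirTargetNetwork",
         representation(genes = "character", families = "character",
                        adjacency = "Matrix", sites = "data.frame"))

.validMirTargetNetwork <- function(object) {
  msg <- NULL
  A <- object@adjacency
  if (nrow(A) != length(object@genes) || ncol(A) != length(object@families))
    msg <- c(msg, "adjacency dimensions must match gene/family vectors")
  if (anyDuplicated(object@genes) || anyDuplicated(object@families))
    msg <- c(msg, "gene and family identifiers must be unique")
  s <- object@sites
  if (nrow(s)) {
    need <- c("gene_id", "family_id", "site_start", "utr_length",
              "relative_position")
    if (!all(need %in% names(s))) {
      msg <- c(msg, "site table is missing required columns")
    } else {
      if (any(s$site_start < 1) || any(s$site_start > s$utr_length))
        msg <- c(msg, "site_start must lie in [1, utr_length]")
      if (any(abs(s$relative_position - s$site_start / s$utr_length) > 1e-12))
        msg <- c(msg, "relative_position must equal site_start / utr_length")
      gi <- match(s$gene_id, object@genes)
      fi <- match(s$family_id, object@families)
      if (anyNA(gi) || anyNA(fi))
        msg <- c(msg, "every site must refer to a known gene and family")
      else if (!all(A[cbind(gi, fi)] != 0))
        msg <- c(msg, "every site must have a matching adjacency edge")
    }
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("MirTargetNetwork", .validMirTargetNetwork)

#' Construct a MirTargetNetwork from an edge data.frame
#'
#' @param edges data.frame with columns `gene_id` and `family_id` (one row
#'   per candidate pair; duplicates are collapsed).
#' @param sites optional data.frame of site records with columns `gene_id`,
#'   `family_id`, `site_start`, `utr_length`. Sites imply edges.
#' @return A [MirTargetNetwork-class] object; genes and families are sorted
#'   lexicographically for determinism.
#' @export
MirTargetNetwork <- function(edges, sites = NULL) {
  if (!is.null(sites) && nrow(sites)) {
    bad <- which(sites$site_start > sites$utr_length | sites$site_start < 1)
    if (length(bad))
      stop("invalid site record(s) at row(s) ", paste(bad, collapse = ", "),
           ": site_start must lie in [1, utr_length]")
    sites$relative_position <- sites$site_start / sites$utr_length
    edges <- rbind(if (!is.null(edges)) edges[, c("gene_id", "family_id")],
                   sites[, c("gene_id", "family_id")])
  } else {
    sites <- data.frame(gene_id = character(), family_id = character(),
                        site_start = integer(), utr_length = integer(),
                        relative_position = numeric())
  }
  edges <- unique(edges[, c("gene_id", "family_id")])
  if (!nrow(edges)) stop("network has no edges")
  genes <- sort(unique(as.character(edges$gene_id)))
  fams <- sort(unique(as.character(edges$family_id)))
  A <- Matrix::sparseMatrix(i = match(edges$gene_id, genes),
                            j = match(edges$family_id, fams),
                            x = 1, dims = c(length(genes), length(fams)),
                            dimnames = list(genes, fams))
  new("MirTargetNetwork", genes = genes, families = fams,
      adjacency = A != 0, sites = as.data.frame(sites))
}

#' @describeIn MirTargetNetwork gene symbols in the network.
#' @param net a `MirTargetNetwork`.
#' @export
networkGenes <- function(net) net@genes

#' @describeIn MirTargetNetwork miRNA family identifiers in the network.
#' @export
mirnaFamilies <- function(net) net@families

#' @describeIn MirTargetNetwork sparse logical gene x family incidence.
#' @export
adjacencyMatrix <- function(net) net@adjacency

#' @describeIn MirTargetNetwork per-site records (may have zero rows).
#' @export
siteRecords <- function(net) net@sites

setMethod("show", "MirTargetNetwork", function(object) {
  cat("MirTargetNetwork:", length(object@genes), "genes x",
      length(object@families), "miRNA families,",
      sum(object@adjacency), "edges\n")
  if (nrow(object@sites))
    cat("  sites:", nrow(object@sites), "records with relative positions\n")
})

#' MirActivity: inferred per-sample miRNA family activities
#'
#' Columns are unit-norm activity vectors (one per retained miRNA family),
#' inferred as the normalised negative mean expression of the family's
#' candidate targets. Families whose targets give an all-zero vector are kept
#' but flagged degenerate; families with too few usable targets are dropped
#' and listed in `excludedFamilies`.
#'
#' @slot W numeric matrix, samples/groups x families; each column has
#'   Euclidean norm 1 (or is all-zero and flagged degenerate).
#' @slot nTargetsUsed named integer, profiles averaged per family.
#' @slot degenerate named logical, `TRUE` for all-zero columns.
#' @slot excludedFamilies families dropped for having fewer than
#'   `minTargets` usable target profiles.
#' @export
setClass("MirActivity",
         representation(W = "matrix", nTargetsUsed = "integer",
                        degenerate = "logical",
                        excludedFamilies = "character"))

.validMirActivity <- function(object) {
  msg <- NULL
  W <- object@W
  if (ncol(W) != length(object@nTargetsUsed) ||
      ncol(W) != length(object@degenerate))
    msg <- c(msg, "per-family annotations must match the number of columns")
  nrm <- sqrt(colSums(W^2))
  ok <- ifelse(object@degenerate, nrm < 1e-9, abs(nrm - 1) < 1e-9)
  if (length(ok) && !all(ok))
    msg <- c(msg, "columns must be unit-norm (or all-zero when degenerate)")
  if (is.null(msg)) TRUE else msg
}
setValidity("MirActivity", .validMirActivity)

#' @describeIn MirActivity the samples x families activity matrix.
#' @param a a `MirActivity` object.
#' @export
activityValues <- function(a) a@W

#' @describeIn MirActivity number of target profiles behind each column.
#' @export
nTargetsUsed <- function(a) a@nTargetsUsed

#' @describeIn MirActivity logical flag per family: all-zero column?
#' @export
isDegenerate <- function(a) a@degenerate

#' @describeIn MirActivity families excluded for too few usable targets.
#' @export
excludedFamilies <- function(a) a@excludedFamilies

setMethod("show", "MirActivity", function(object) {
  cat("MirActivity:", nrow(object@W), "samples x", ncol(object@W),
      "miRNA families\n")
  if (any(object@degenerate))
    cat("  degenerate (all-zero) families:", sum(object@degenerate), "\n")
  if (length(object@excludedFamilies))
    cat("  excluded (too few targets):",
        length(object@excludedFamilies), "\n")
})
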