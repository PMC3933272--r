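#' Load a candidate network from a two-column edge list
#'
#' @param path TSV with columns (gene symbol, miRNA family ID); a header row
#'   is detected and skipped when its first field is `gene_id` or `gene`.
#' @return A [MirTargetNetwork-class] (deduplicated; identifiers sorted).
#' @export
loadEdgeList <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("edge list '", path, "' is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("malformed edge at line ", bad[1L], " of '", path, "'")
  first <- tolower(parts[[1L]][1L])
  if (first %in% c("gene", "gene_id", "symbol")) parts <- parts[-1L]
  if (!length(parts)) stop("edge list '", path, "' has no edges")
  edges <- data.frame(gene_id = vapply(parts, `[`, "", 1L),
                      family_id = vapply(parts, `[`, "", 2L))
  MirTargetNetwork(edges)
}

#' Load a candidate network from a site table
#'
#' Each row records one seed-match site: gene symbol, miRNA family, 1-based
#' site start within the 3'UTR, and the 3'UTR length. The relative site
#' position is the start divided by the UTR length; a pair with one or more
#' sites gets a single adjacency edge.
#'
#' @param path TSV with columns (gene, family, site_start, utr_length);
#'   header detected as in [loadEdgeList()].
#' @return A [MirTargetNetwork-class] with site records attached.
#' @export
loadSiteTable <- function(path) {
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character")
  if (tolower(tab[1L, 1L]) %in% c("gene", "gene_id", "symbol"))
    tab <- tab[-1L, , drop = FALSE]
  if (!nrow(tab)) stop("site table '", path, "' is empty")
  sites <- data.frame(gene_id = tab[[1L]], family_id = tab[[2L]],
                      site_start = as.integer(tab[[3L]]),
                      utr_length = as.integer(tab[[4L]]))
  if (anyNA(sites$site_start) || anyNA(sites$utr_length))
    stop("non-integer site coordinates in '", path, "'")
  MirTargetNetwork(edges = NULL, sites = sites)
}

#' Write a network's edges to a two-column TSV
#'
#' @param net a [MirTargetNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  idx <- Matrix::which(adjacencyMatrix(net), arr.ind = TRUE)
  out <- data.frame(gene_id = networkGenes(net)[idx[, 1L]],
                    family_id = mirnaFamilies(net)[idx[, 2L]])
  out <- out[order(out$gene_id, out$family_id), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify a site by its relative position in the 3'UTR
#'
#' Sites near either 3'UTR terminus are more effective than sites in the
#' middle; the default thresholds split the UTR at relative positions 0.25
#' and 0.75 with strict inequalities, so a site exactly at a threshold is
#' `middle`.
#'
#' @param relativePosition numeric vector of relative site positions in
#'   (0, 1].
#' @param low,high strict thresholds for the terminal classes.
#' @return factor with levels `near_orf`, `middle`, `near_polya`.
#' @export
positionClass <- function(relativePosition, low = 0.25, high = 0.75) {
  stopifnot(all(relativePosition > 0), all(relativePosition <= 1))
  cls <- ifelse(relativePosition < low, "near_orf",
                ifelse(relativePosition > high, "near_polya", "middle"))
  factor(cls, levels = c("near_orf", "middle", "near_polya"))
}

#' Candidate targets of a miRNA family
#'
#' @param net a [MirTargetNetwork-class].
#' @param familyId family identifier present in the network.
#' @return sorted character vector of target gene symbols.
#' @export
targetsOf <- function(net, familyId) {
  j <- match(familyId, mirnaFamilies(net))
  if (is.na(j)) stop("unknown miRNA family '", familyId, "'")
  sort(networkGenes(net)[as.vector(adjacencyMatrix(net)[, j])])
}

#' Candidate regulators of a gene
#'
#' @param net a [MirTargetNetwork-class].
#' @param geneId gene symbol present in the network.
#' @return sorted character vector of miRNA family identifiers (possibly
#'   empty: such a gene receives no regression and no scores).
#' @export
regulatorsOf <- function(net, geneId) {
  i <- match(geneId, networkGenes(net))
  if (is.na(i)) stop("unknown gene '", geneId, "'")
  sort(mirnaFamilies(net)[as.vector(adjacencyMatrix(net)[i, ])])
}
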