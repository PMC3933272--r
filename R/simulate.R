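.smoothActivities <- function(nSamples, nFamilies) {
  # low-order random Fourier series per family: smooth across the sample
  # axis, emulating biological-group structure rather than i.i.d. noise
  t <- seq(0, 1, length.out = nSamples)
  raw <- vapply(seq_len(nFamilies), function(k) {
    freqs <- sample(1:5, 3, replace = TRUE)
    amps <- rnorm(3)
    phases <- runif(3, 0, 2 * pi)
    rowSums(vapply(1:3, function(i)
      amps[i] * sin(2 * pi * freqs[i] * t + phases[i]), numeric(nSamples)))
  }, numeric(nSamples))
  # orthonormalise against the constant vector and each other: planted
  # activities are mean-zero, unit-norm and mutually orthogonal, so the
  # per-gene regression problem is identifiable by construction
  q <- qr.Q(qr(cbind(1, raw)))[, -1L, drop = FALSE]
  sgn <- sign(colSums(q * raw))
  sgn[sgn == 0] <- 1
  sweep(q, 2L, sgn, `*`)
}

#' Simulate an expression/network bundle with planted ground truth
#'
#' Generates the full input set the scoring pipeline consumes, with the
#' statistical structure the model assumes: smooth, mutually orthogonal
#' unit-norm planted activity vectors; a random candidate network in which
#' each edge is functional with probability `fracFunctional`; exponential
#' non-negative planted coefficients on functional edges; and log2-scale
#' expression `baseline - coefficients %*% activities + Gaussian noise`
#' (repression multiplicative on the linear scale, hence additive in log2).
#' One site per edge is placed uniformly along a random-length 3'UTR;
#' `positionBoost > 0` multiplies the coefficient of terminally-sited edges
#' by `1 + positionBoost`.
#'
#' @param nGenes,nFamilies,nSamples problem dimensions.
#' @param edgeDensity probability that a (gene, family) pair is a candidate
#'   edge.
#' @param fracFunctional probability that a candidate edge carries a
#'   non-zero planted coefficient.
#' @param coefScale mean of the exponential planted-coefficient
#'   distribution (log2 scale).
#' @param noiseSd per-entry Gaussian noise sd (log2 scale).
#' @param positionBoost optional multiplicative boost for terminal sites.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return list with `expr` ([MirExpression-class], log2 scale), `net`
#'   ([MirTargetNetwork-class] with site records) and `truth` (list:
#'   `activities` M x K, `coefficients` genes x K, `baseline`, `noiseSd`,
#'   `seed`).
#' @export
simulateBundle <- function(nGenes = 500, nFamilies = 20, nSamples = 100,
                           edgeDensity = 0.1, fracFunctional = 0.6,
                           coefScale = 2, noiseSd = 0.25,
                           positionBoost = 0, seed = 1) {
  stopifnot(nGenes >= 1, nFamilies >= 1, nSamples >= 2,
            edgeDensity > 0, edgeDensity <= 1,
            fracFunctional > 0, fracFunctional <= 1,
            coefScale > 0, noiseSd >= 0, nSamples > nFamilies)
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(nGenes))
  fams <- sprintf("miR-F%03d", seq_len(nFamilies))
  samples <- sprintf("S%04d", seq_len(nSamples))
  act <- .smoothActivities(nSamples, nFamilies)
  dimnames(act) <- list(samples, fams)
  adj <- matrix(rbinom(nGenes * nFamilies, 1, edgeDensity) == 1,
                nGenes, nFamilies, dimnames = list(genes, fams))
  if (!any(adj)) stop("edge density too low: the sampled network is empty")
  coef <- matrix(0, nGenes, nFamilies, dimnames = list(genes, fams))
  nEdges <- sum(adj)
  functional <- rbinom(nEdges, 1, fracFunctional) == 1
  coef[adj][functional] <- rexp(sum(functional), rate = 1 / coefScale)
  idx <- which(adj, arr.ind = TRUE)
  utr <- sample(300:3000, nEdges, replace = TRUE)
  start <- pmax(1L, as.integer(ceiling(runif(nEdges) * utr)))
  sites <- data.frame(gene_id = genes[idx[, 1L]],
                      family_id = fams[idx[, 2L]],
                      site_start = start, utr_length = utr)
  if (positionBoost > 0) {
    terminal <- positionClass(start / utr) != "middle"
    coef[adj] <- coef[adj] * ifelse(terminal, 1 + positionBoost, 1)
  }
  baseline <- rnorm(nGenes, mean = 8, sd = 1)
  expr <- baseline - coef %*% t(act) +
    matrix(rnorm(nGenes * nSamples, 0, noiseSd), nGenes, nSamples)
  dimnames(expr) <- list(genes, samples)
  net <- MirTargetNetwork(edges = NULL, sites = sites)
  list(expr = MirExpression(expr, logTransformed = TRUE),
       net = net,
       truth = list(activities = act, coefficients = coef,
                    baseline = setNames(baseline, genes),
                    noiseSd = noiseSd, seed = seed))
}

#' Simulate an over-expression response table
#'
#' Mimics a transfection assay: over-expressing family k changes gene g's
#' log-fold expression by `-effectScale * coefficients[g, k]` plus Gaussian
#' measurement noise; genes without a functional planted edge respond with
#' noise only. Every gene is measured for every selected family, as in a
#' genome-wide array readout.
#'
#' @param truth the `truth` element of [simulateBundle()].
#' @param families families to "transfect" (default: all).
#' @param effectScale scaling of planted coefficient to log-fold change.
#' @param noiseSd measurement noise sd.
#' @param seed integer seed.
#' @return data.frame with columns `gene_id`, `family_id`, `response`.
#' @export
simulateOverexpression <- function(truth, families = NULL, effectScale = 1,
                                   noiseSd = 0.1, seed = 1) {
  coef <- truth$coefficients
  if (is.null(families)) families <- colnames(coef)
  stopifnot(all(families %in% colnames(coef)))
  set.seed(seed)
  out <- expand.grid(gene_id = rownames(coef), family_id = families,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$response <- -effectScale * coef[cbind(out$gene_id, out$family_id)] +
    rnorm(nrow(out), 0, noiseSd)
  out
}

#' Write a simulated bundle to TSV files
#'
#' Emits the same plain-text formats the pipeline reads: the expression
#' matrix, the site table, the edge list and the planted truth
#' (coefficients long format plus activities).
#'
#' @param bundle output of [simulateBundle()].
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, c("expression.tsv", "sites.tsv", "edges.tsv",
                        "truth_coefficients.tsv", "truth_activities.tsv"))
  writeExpressionTSV(exprValues(bundle$expr), f[1L])
  s <- siteRecords(bundle$net)
  write.table(s[, c("gene_id", "family_id", "site_start", "utr_length")],
              f[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  writeEdgeList(bundle$net, f[3L])
  co <- bundle$truth$coefficients
  idx <- which(co > 0, arr.ind = TRUE)
  write.table(data.frame(gene_id = rownames(co)[idx[, 1L]],
                         family_id = colnames(co)[idx[, 2L]],
                         coefficient = co[idx]),
              f[4L], sep = "\t", quote = FALSE, row.names = FALSE)
  writeExpressionTSV(t(bundle$truth$activities), f[5L],
                     idColumn = "family_id")
  invisible(f)
}
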