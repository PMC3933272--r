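#' Soft-threshold operator
#'
#' `sign(x) * max(|x| - t, 0)`: the shrinkage operator arising in
#' coordinate-descent solutions of L1-penalised least squares.
#'
#' @param x numeric.
#' @param t non-negative threshold.
#' @return numeric of the same length as `x`.
#' @export
softThreshold <- function(x, t) {
  stopifnot(all(t >= 0))
  sign(x) * pmax(abs(x) - t, 0)
}

#' Solver configuration for the non-negative elastic net
#'
#' @param lambda1 non-negative L1 penalty weight (sparsity).
#' @param lambda2 non-negative L2 penalty weight (shrinkage).
#' @param maxIter maximum number of full coordinate sweeps.
#' @param tol convergence threshold on the maximum absolute coefficient
#'   change per sweep. The default (1e-8) is tighter than the change one
#'   would notice in any score so that the first-order optimality
#'   (stationarity/complementarity) certificate holds to ~1e-6 at the
#'   returned solution.
#' @param lambdaSelection `"fixed"` uses `lambda1`/`lambda2` as given;
#'   `"cv"` selects one global pair by k-fold cross-validation over samples
#'   from `lambdaGrid` (or an automatic log-spaced grid).
#' @param cvFolds number of CV folds (over samples).
#' @param lambdaGrid optional data.frame with columns `lambda1`, `lambda2`.
#' @param seed integer seed controlling the CV fold assignment.
#' @return A list of class `baymirConfig`.
#' @export
baymirConfig <- function(lambda1 = 0, lambda2 = 0, maxIter = 1000,
                         tol = 1e-8, lambdaSelection = c("cv", "fixed"),
                         cvFolds = 5, lambdaGrid = NULL, seed = 1) {
  lambdaSelection <- match.arg(lambdaSelection)
  stopifnot(lambda1 >= 0, lambda2 >= 0, tol > 0, maxIter >= 1)
  if (lambdaSelection == "cv") stopifnot(cvFolds >= 2)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, maxIter = maxIter,
                 tol = tol, lambdaSelection = lambdaSelection,
                 cvFolds = cvFolds, lambdaGrid = lambdaGrid, seed = seed),
            class = "baymirConfig")
}

#' Penalised objective of the non-negative elastic net
#'
#' `0.5 * sum((deltaY - W h)^2) + lambda1 * sum(h) + 0.5 * lambda2 *
#' sum(h^2)` for `h >= 0` (on the feasible orthant the L1 term is linear).
#' The 1/2 factors are the conventional scaling under which the coordinate
#' update carries the penalty weights unscaled; any other scaling is a
#' reparametrisation of `lambda1`/`lambda2`.
#'
#' @param h non-negative coefficient vector.
#' @param deltaY centered response vector.
#' @param W regressor matrix (samples x regulators).
#' @param lambda1,lambda2 penalty weights.
#' @return scalar objective value.
#' @export
nnenObjective <- function(h, deltaY, W, lambda1, lambda2) {
  r <- deltaY - as.vector(W %*% h)
  0.5 * sum(r^2) + lambda1 * sum(h) + 0.5 * lambda2 * sum(h^2)
}

#' Fit one gene: non-negative elastic net by coordinate descent
#'
#' Minimises [nnenObjective()] over the non-negative orthant. Each
#' coordinate update is the soft-thresholded least-squares update
#' `h_j = S(w_j . (r + w_j h_j), lambda1) / (||w_j||^2 + lambda2)` clamped
#' at zero, which on the feasible orthant reduces to the one-sided form
#' `(rho_j - lambda1)_+ / (||w_j||^2 + lambda2)`. Coefficients start at
#' zero, so `lambda1 >= max_j |w_j . deltaY|` yields the all-zero solution
#' without any update. Sweeps continue until the maximum absolute
#' coefficient change falls below `tol` or `maxIter` is reached; the
#' objective never increases across updates.
#'
#' @param deltaY centered response vector (length M >= 2).
#' @param W numeric matrix (M x K) of the gene's candidate regulators'
#'   activity vectors; all-zero (degenerate) columns keep coefficient 0.
#' @param lambda1,lambda2 penalty weights.
#' @param maxIter,tol see [baymirConfig()].
#' @return list with `h` (named non-negative coefficients), `converged`,
#'   `nIter`, `sse` (residual sum of squares) and `objective`.
#' @export
fitGene <- function(deltaY, W, lambda1 = 0, lambda2 = 0,
                    maxIter = 1000, tol = 1e-8) {
  W <- as.matrix(W)
  if (!all(is.finite(deltaY)) || !all(is.finite(W)))
    stop("non-finite values in the regression inputs")
  stopifnot(length(deltaY) == nrow(W), length(deltaY) >= 2,
            lambda1 >= 0, lambda2 >= 0)
  K <- ncol(W)
  wss <- colSums(W^2)
  h <- numeric(K)
  r <- deltaY
  converged <- FALSE
  it <- 0L
  active <- which(wss > 0)
  while (it < maxIter) {
    it <- it + 1L
    maxDelta <- 0
    for (j in active) {
      rho <- sum(W[, j] * r) + wss[j] * h[j]
      # one-sided soft threshold + projection onto h_j >= 0
      hj <- max(rho - lambda1, 0) / (wss[j] + lambda2)
      d <- hj - h[j]
      if (d != 0) {
        r <- r - W[, j] * d
        h[j] <- hj
        maxDelta <- max(maxDelta, abs(d))
      }
    }
    if (maxDelta < tol) { converged <- TRUE; break }
  }
  names(h) <- colnames(W)
  list(h = h, converged = converged, nIter = it, sse = sum(r^2),
       objective = 0.5 * sum(r^2) + lambda1 * sum(h) +
         0.5 * lambda2 * sum(h^2))
}

#' First-order optimality check for a fitted coefficient vector
#'
#' Gradient of the objective w.r.t. `h_j` is
#' `g_j = -w_j . r + lambda1 + lambda2 * h_j`. At a constrained minimum,
#' `g_j = 0` where `h_j > 0` and `g_j >= 0` where `h_j = 0`
#' (stationarity / complementarity on the non-negative orthant).
#'
#' @inheritParams fitGene
#' @param h fitted coefficient vector.
#' @return maximum scaled violation: `max(|g_j|)` over positive
#'   coordinates and `max(-g_j, 0)` over zero coordinates, divided by
#'   `max(1, max_j |w_j . deltaY|)`.
#' @export
kktViolation <- function(h, deltaY, W, lambda1 = 0, lambda2 = 0) {
  W <- as.matrix(W)
  r <- deltaY - as.vector(W %*% h)
  g <- -as.vector(crossprod(W, r)) + lambda1 + lambda2 * h
  scale <- max(1, max(abs(crossprod(W, deltaY))))
  v <- ifelse(h > 0, abs(g), pmax(-g, 0))
  wss <- colSums(W^2)
  v[wss == 0] <- 0  # degenerate columns carry no constraint
  max(v) / scale
}

#' Smallest L1 weight yielding the all-zero solution
#'
#' With coefficients initialised at zero, no coordinate moves once
#' `lambda1 >= max_j |w_j . deltaY|`; this bound is the per-gene
#' `lambda_max` anchoring the automatic penalty path.
#'
#' @inheritParams fitGene
#' @return scalar `lambda_max` (0 for an empty regressor set).
#' @export
lambdaMax <- function(deltaY, W) {
  W <- as.matrix(W)
  if (!ncol(W)) return(0)
  # same summation order as the coordinate update, so the screening
  # property lambda1 >= lambda_max -> h = 0 holds bit-exactly
  max(abs(vapply(seq_len(ncol(W)),
                 function(j) sum(W[, j] * deltaY), 1)))
}

.downRegulation <- function(centered) {
  # the regression response: the DOWN-regulation profile, positive where a
  # gene sits below its own average expression, so that positive activity
  # (targets repressed) earns a positive coefficient
  -(if (is.list(centered)) centered$delta else centered)
}

.geneRegressors <- function(delta, W, net) {
  A <- adjacencyMatrix(net)
  fams <- colnames(W)
  genes <- intersect(rownames(delta), networkGenes(net))
  out <- lapply(genes, function(g) {
    regs <- mirnaFamilies(net)[as.vector(A[match(g, networkGenes(net)), ])]
    intersect(sort(regs), fams)
  })
  names(out) <- genes
  out[lengths(out) > 0]
}

#' Score every candidate miRNA-mRNA pair
#'
#' Runs one non-negative elastic-net fit per gene with at least one
#' candidate regulator, regressing the gene's down-regulation profile (the
#' negated centered profile: positive where the gene sits below its own
#' mean) on the activity vectors of its regulators. The fitted
#' coefficients are the repression scores: a positive score says the
#' family's inferred activity helps explain the gene's down-regulation
#' (over and above the other candidate regulators), a zero score marks a
#' lack of expression evidence for that pair.
#'
#' @param centered output of [centerRows()] (or a genes x samples matrix of
#'   centered profiles).
#' @param activity a [MirActivity-class] whose families are a subset of the
#'   network's.
#' @param net a [MirTargetNetwork-class].
#' @param config a [baymirConfig()]; with `lambdaSelection = "cv"` one
#'   global penalty pair is chosen by [selectLambda()] first.
#' @return data.frame (one row per scored pair) with columns `gene_id`,
#'   `family_id`, `score`, `converged`, `n_iter`, `residual_sse`,
#'   `lambda1`, `lambda2`. The configuration used (including the selected
#'   penalties) is attached as `attr(, "config")`.
#' @export
fitAll <- function(centered, activity, net, config = baymirConfig()) {
  delta <- .downRegulation(centered)
  W <- activityValues(activity)
  missing <- setdiff(colnames(W), mirnaFamilies(net))
  if (length(missing))
    stop("activity families absent from the network: ",
         paste(missing, collapse = ", "))
  regs <- .geneRegressors(delta, W, net)
  if (!length(regs)) stop("no gene has a scorable regulator")
  if (config$lambdaSelection == "cv") {
    sel <- selectLambda(centered, activity, net, grid = config$lambdaGrid,
                        config = config)
    config$lambda1 <- sel$lambda1
    config$lambda2 <- sel$lambda2
  }
  rows <- vector("list", length(regs))
  for (i in seq_along(regs)) {
    g <- names(regs)[i]
    fams <- regs[[i]]
    fit <- fitGene(delta[g, ], W[, fams, drop = FALSE],
                   lambda1 = config$lambda1, lambda2 = config$lambda2,
                   maxIter = config$maxIter, tol = config$tol)
    rows[[i]] <- data.frame(gene_id = g, family_id = fams,
                            score = unname(fit$h),
                            converged = fit$converged, n_iter = fit$nIter,
                            residual_sse = fit$sse,
                            lambda1 = config$lambda1,
                            lambda2 = config$lambda2, row.names = NULL)
  }
  st <- do.call(rbind, rows)
  attr(st, "config") <- config
  st
}

#' Choose one global penalty pair by cross-validation over samples
#'
#' Samples (columns of the centered profiles) are split into `cvFolds`
#' folds; for each candidate `(lambda1, lambda2)` every gene is fitted on
#' the training samples and its held-out squared error accumulated. The
#' pair minimising the mean held-out SSE wins; ties break toward larger
#' `lambda1`, then larger `lambda2` (the sparser, smoother model).
#'
#' @param centered as in [fitAll()].
#' @param activity a [MirActivity-class].
#' @param net a [MirTargetNetwork-class].
#' @param grid data.frame with columns `lambda1`, `lambda2`; when `NULL`, a
#'   10-point logarithmic `lambda1` path from the global `lambda_max` down
#'   (plus 0) is crossed with `lambda2` in {0, 0.1, 1}.
#' @param config a [baymirConfig()] supplying `cvFolds`, `maxIter`, `tol`
#'   and `seed`.
#' @return list with `lambda1`, `lambda2` and the full `cvTable`.
#' @export
selectLambda <- function(centered, activity, net, grid = NULL,
                         config = baymirConfig(lambdaSelection = "fixed")) {
  delta <- .downRegulation(centered)
  W <- activityValues(activity)
  M <- ncol(delta)
  if (M < config$cvFolds)
    stop("fewer samples (", M, ") than CV folds (", config$cvFolds, ")")
  regs <- .geneRegressors(delta, W, net)
  if (is.null(grid)) {
    lmax <- max(vapply(names(regs), function(g)
      lambdaMax(delta[g, ], W[, regs[[g]], drop = FALSE]), 0))
    l1 <- c(0, exp(seq(log(lmax), log(lmax * 1e-3), length.out = 9)))
    grid <- expand.grid(lambda1 = l1, lambda2 = c(0, 0.1, 1))
  }
  stopifnot(nrow(grid) >= 1)
  set.seed(config$seed)
  fold <- sample(rep_len(seq_len(config$cvFolds), M))
  err <- numeric(nrow(grid))
  for (f in seq_len(config$cvFolds)) {
    train <- fold != f
    for (p in seq_len(nrow(grid))) {
      sse <- 0
      for (g in names(regs)) {
        Wg <- W[, regs[[g]], drop = FALSE]
        fit <- fitGene(delta[g, train], Wg[train, , drop = FALSE],
                       lambda1 = grid$lambda1[p], lambda2 = grid$lambda2[p],
                       maxIter = config$maxIter, tol = config$tol)
        pred <- as.vector(Wg[!train, , drop = FALSE] %*% fit$h)
        sse <- sse + sum((delta[g, !train] - pred)^2)
      }
      err[p] <- err[p] + sse
    }
  }
  cv <- cbind(grid, cvError = err / (config$cvFolds * length(regs)))
  best <- which(cv$cvError <= min(cv$cvError) + 1e-12)
  best <- best[order(-cv$lambda1[best], -cv$lambda2[best])][1L]
  list(lambda1 = cv$lambda1[best], lambda2 = cv$lambda2[best], cvTable = cv)
}

#' Write a score table to TSV
#'
#' @param scores data.frame from [fitAll()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScoreTable <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
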