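# Independent oracles and small fixture builders used across test files.

# Brute-force minimiser of 0.5*||d - W h||^2 + l1*sum(h) + 0.5*l2*sum(h^2)
# over h >= 0, via projected quasi-Newton (L-BFGS-B with a zero lower
# bound) run to tight tolerance. Independent of the coordinate-descent path.
oracleNNEN <- function(d, W, l1, l2) {
  obj <- function(h) {
    r <- d - as.vector(W %*% h)
    0.5 * sum(r^2) + l1 * sum(h) + 0.5 * l2 * sum(h^2)
  }
  gr <- function(h) {
    r <- d - as.vector(W %*% h)
    -as.vector(crossprod(W, r)) + l1 + l2 * h
  }
  fit <- stats::optim(rep(0, ncol(W)), obj, gr, method = "L-BFGS-B",
                      lower = 0, control = list(factr = 10, maxit = 2000))
  list(h = fit$par, objective = fit$value)
}

# Rank-based AUROC (probability a positive outranks a negative, ties 0.5)
aurocScore <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n0 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Linear-interpolation percentile computed from first principles
linPercentile <- function(x, p) {
  x <- sort(x)
  hpos <- (length(x) - 1) * p + 1
  lo <- floor(hpos); hi <- ceiling(hpos)
  x[lo] + (hpos - lo) * (x[hi] - x[lo])
}

# Random solver instance with unit-norm regressor columns
randomInstance <- function(M = 30, K = NULL) {
  if (is.null(K)) K <- sample(1:4, 1)
  W <- matrix(rnorm(M * K), M, K)
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  list(d = rnorm(M), W = W)
}

# Write a small expression TSV (first column gene symbols)
writeExprFixture <- function(mat, symbols, path = tempfile(fileext = ".tsv")) {
  tab <- cbind(gene_id = symbols, as.data.frame(mat))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Wrap a matrix of unit-norm columns as a MirActivity object
asActivity <- function(W, nTargets = rep(1L, ncol(W))) {
  new("MirActivity", W = W,
      nTargetsUsed = stats::setNames(as.integer(nTargets), colnames(W)),
      degenerate = stats::setNames(sqrt(colSums(W^2)) < 1e-9, colnames(W)),
      excludedFamilies = character())
}
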