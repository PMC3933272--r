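#' Infer per-family miRNA activity vectors from target expression
#'
#' Because miRNAs repress their targets, samples in which a miRNA is active
#' show depressed expression of its target set. The activity vector of family
#' k is therefore taken as the negative mean of its candidate targets'
#' expression profiles, then scaled to unit Euclidean norm:
#' `w_k = -(1/N_k) * sum_i y_i`, `w_k <- w_k / ||w_k||`.
#'
#' The per-gene profiles entering the mean are, by default, z-scored (mean 0,
#' sd 1 per gene) so that high-variance genes do not dominate the average;
#' `input = "centered"` subtracts only the gene mean, `input = "raw"` uses
#' the profiles as stored.
#'
#' @param expr a preprocessed [MirExpression-class] (log2 scale).
#' @param net a [MirTargetNetwork-class]; families are inferred from the
#'   targets that are present in `expr`.
#' @param minTargets families with fewer usable target profiles are dropped
#'   (activity from very few genes is noise-dominated) and listed in
#'   [excludedFamilies()].
#' @param input which version of each target profile enters the average.
#' @return A [MirActivity-class] with one unit-norm column per retained
#'   family; families whose mean profile is identically zero are kept but
#'   flagged degenerate.
#' @export
inferActivity <- function(expr, net, minTargets = 5,
                          input = c("zscore", "centered", "raw")) {
  input <- match.arg(input)
  m <- exprValues(expr)
  if (input != "raw") {
    mu <- rowMeans(m)
    m <- m - mu
    if (input == "zscore") {
      s <- apply(m, 1L, sd)
      ok <- s > 0
      m[ok, ] <- m[ok, , drop = FALSE] / s[ok]
      # constant genes stay all-zero: they carry no signal either way
    }
  }
  fams <- mirnaFamilies(net)
  A <- adjacencyMatrix(net)
  present <- intersect(networkGenes(net), rownames(m))
  W <- matrix(0, nrow = ncol(m), ncol = 0,
              dimnames = list(colnames(m), NULL))
  nUsed <- integer(); degen <- logical(); excluded <- character()
  for (k in seq_along(fams)) {
    tg <- intersect(networkGenes(net)[as.vector(A[, k])], present)
    if (length(tg) < minTargets) {
      excluded <- c(excluded, fams[k])
      next
    }
    w <- -colMeans(m[tg, , drop = FALSE])
    nrm <- sqrt(sum(w^2))
    if (nrm < 1e-12) {
      w <- rep(0, length(w))
      degen <- c(degen, TRUE)
    } else {
      w <- w / nrm
      degen <- c(degen, FALSE)
    }
    W <- cbind(W, w)
    colnames(W)[ncol(W)] <- fams[k]
    nUsed <- c(nUsed, length(tg))
  }
  if (length(excluded))
    warning(length(excluded), " family(ies) excluded: fewer than ",
            minTargets, " usable targets")
  new("MirActivity", W = W,
      nTargetsUsed = setNames(nUsed, colnames(W)),
      degenerate = setNames(degen, colnames(W)),
      excludedFamilies = excluded)
}

#' Correlate inferred activities with measured miRNA expression
#'
#' Pearson correlation between each inferred activity vector and a matched
#' measured miRNA expression profile over the shared samples, together with
#' a permutation reference: each activity vector is permuted over samples
#' `nPerm` times and the fraction of permuted correlations exceeding the
#' observed one is reported.
#'
#' @param activity a [MirActivity-class].
#' @param mirnaExpr a [MirExpression-class] of measured miRNA expression
#'   (rows = miRNA IDs) over the same samples.
#' @param mapping data.frame with columns `family_id`, `mirna_id` pairing
#'   activity columns with expression rows.
#' @param nPerm number of sample permutations per pair.
#' @param seed integer seed for the permutations.
#' @return data.frame with columns `family_id`, `mirna_id`, `pearson_r`
#'   (`NA` when either vector has zero variance) and `perm_frac_exceeding`.
#' @export
activityExpressionCorrelation <- function(activity, mirnaExpr, mapping,
                                          nPerm = 100, seed = 1) {
  W <- activityValues(activity)
  E <- exprValues(mirnaExpr)
  shared <- intersect(rownames(W), colnames(E))
  if (length(shared) < 3L)
    stop("activity and miRNA expression share fewer than 3 samples")
  set.seed(seed)
  res <- lapply(seq_len(nrow(mapping)), function(i) {
    fam <- mapping$family_id[i]; mir <- mapping$mirna_id[i]
    if (!fam %in% colnames(W) || !mir %in% rownames(E))
      stop("unmatched pair (", fam, ", ", mir, ")")
    a <- W[shared, fam]; e <- E[mir, shared]
    if (sd(a) == 0 || sd(e) == 0)
      return(data.frame(family_id = fam, mirna_id = mir,
                        pearson_r = NA_real_,
                        perm_frac_exceeding = NA_real_))
    r <- cor(a, e)
    rp <- replicate(nPerm, cor(sample(a), e))
    data.frame(family_id = fam, mirna_id = mir, pearson_r = r,
               perm_frac_exceeding = mean(rp > r))
  })
  do.call(rbind, res)
}
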