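.joinScoresResponses <- function(scores, responses) {
  key <- function(d) paste(d$gene_id, d$family_id, sep = "\r")
  if (anyDuplicated(key(responses)))
    stop("duplicate (gene, family) rows in the response table")
  i <- match(key(scores), key(responses))
  ok <- !is.na(i)
  data.frame(gene_id = scores$gene_id[ok],
             family_id = scores$family_id[ok],
             score = scores$score[ok],
             response = responses$response[i[ok]], row.names = NULL)
}

#' Mean response per score-quantile bin
#'
#' Ranks scored pairs by score (ties broken by a stable sort on gene then
#' family), splits them into `nBins` equal-count bins (sizes differ by at
#' most one) and reports each bin's mean response with a normal-approximation
#' 95% confidence interval (`mean +/- 1.96 * sd / sqrt(n)`). When the
#' response is a log-fold change from an over-expression assay, an
#' informative score shows bin means decreasing (more repression) as the
#' score bin rises.
#'
#' @param scores data.frame with `gene_id`, `family_id`, `score`.
#' @param responses data.frame with `gene_id`, `family_id`, `response`.
#' @param nBins number of quantile bins (default 5).
#' @return data.frame with one row per bin (ascending score): `bin`, `n`,
#'   `mean_score`, `mean_response`, `ci_lower`, `ci_upper`.
#' @export
scoreBinResponse <- function(scores, responses, nBins = 5) {
  d <- .joinScoresResponses(scores, responses)
  if (nrow(d) < nBins)
    stop("fewer scored pairs (", nrow(d), ") than bins (", nBins, ")")
  d <- d[order(d$score, d$gene_id, d$family_id, method = "radix"), ]
  sizes <- rep(nrow(d) %/% nBins, nBins)
  extra <- nrow(d) %% nBins
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  d$bin <- rep(seq_len(nBins), sizes)
  out <- lapply(split(d, d$bin), function(b) {
    m <- mean(b$response)
    se <- if (nrow(b) > 1) sd(b$response) / sqrt(nrow(b)) else 0
    data.frame(bin = b$bin[1L], n = nrow(b), mean_score = mean(b$score),
               mean_response = m, ci_lower = m - 1.96 * se,
               ci_upper = m + 1.96 * se)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Median-split repression metric
#'
#' For each miRNA family, pairs scoring strictly above that family's median
#' score are pooled; the metric is the negative mean response over the pool
#' (larger = the high-scoring half is more repressed). Families whose scores
#' are all equal have no pair above the median and are skipped with a
#' warning.
#'
#' @inheritParams scoreBinResponse
#' @return list with `metric` (pooled negative mean response), `n` (pairs in
#'   the pool) and `perFamily` (data.frame of per-family metrics).
#' @export
medianSplitMetric <- function(scores, responses) {
  d <- .joinScoresResponses(scores, responses)
  parts <- split(d, d$family_id)
  pool <- list(); perFam <- list()
  for (fam in names(parts)) {
    p <- parts[[fam]]
    if (nrow(p) < 2L) next
    med <- median(p$score)
    hi <- p[p$score > med, , drop = FALSE]
    if (!nrow(hi)) {
      warning("family '", fam, "' skipped: no score above its median")
      next
    }
    pool[[fam]] <- hi
    perFam[[fam]] <- data.frame(family_id = fam, n_above = nrow(hi),
                                metric = -mean(hi$response))
  }
  if (!length(pool)) stop("no family with pairs above its median score")
  pooled <- do.call(rbind, pool)
  list(metric = -mean(pooled$response), n = nrow(pooled),
       perFamily = do.call(rbind, c(perFam, list(make.row.names = FALSE))))
}

#' Upper-tail hypergeometric enrichment
#'
#' Probability of drawing at least the observed overlap between a selected
#' gene set (e.g. the above-median-score genes) and a reference set (e.g.
#' experimentally validated targets) when sampling without replacement from
#' the universe: `P(X >= k)`.
#'
#' @param highSet,validated character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return list with `p_value`, `overlap`, `n_high`, `n_validated`,
#'   `n_universe`.
#' @export
hypergeomEnrichment <- function(highSet, validated, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  highSet <- unique(highSet); validated <- unique(validated)
  if (!all(highSet %in% universe) || !all(validated %in% universe))
    stop("highSet and validated must be subsets of the universe")
  k <- length(intersect(highSet, validated))
  p <- phyper(k - 1, length(validated),
              length(universe) - length(validated),
              length(highSet), lower.tail = FALSE)
  list(p_value = p, overlap = k, n_high = length(highSet),
       n_validated = length(validated), n_universe = length(universe))
}

#' Category enrichment of per-family target sets
#'
#' One-sided Fisher exact test of each (family target set, annotation
#' category) 2x2 table against the universe, with Benjamini-Hochberg
#' correction applied per family across its categories (set
#' `poolFamilies = TRUE` to correct across all family x category tests at
#' once). Categories with no member in the universe are skipped with a
#' warning.
#'
#' @param targetSets named list: family id -> character vector of target
#'   genes.
#' @param categories named list: category id -> character vector of genes.
#' @param universe character vector of eligible genes.
#' @param fdrCutoff results with BH q-value at or below this are flagged
#'   enriched (default 0.1).
#' @param poolFamilies pool all tests into one BH correction?
#' @return data.frame with columns `family_id`, `category_id`, `overlap`,
#'   `n_set`, `n_category`, `n_universe`, `p_value`, `fdr_q`, `enriched`.
#' @export
categoryEnrichment <- function(targetSets, categories, universe,
                               fdrCutoff = 0.1, poolFamilies = FALSE) {
  universe <- unique(universe)
  if (!length(categories)) stop("no annotation categories supplied")
  empty <- vapply(categories,
                  function(g) !length(intersect(g, universe)), TRUE)
  if (any(empty)) {
    warning("categories disjoint from the universe skipped: ",
            paste(names(categories)[empty], collapse = ", "))
    categories <- categories[!empty]
  }
  rows <- list()
  for (fam in names(targetSets)) {
    tset <- intersect(unique(targetSets[[fam]]), universe)
    for (cat in names(categories)) {
      cset <- intersect(unique(categories[[cat]]), universe)
      k <- length(intersect(tset, cset))
      tab <- matrix(c(k, length(tset) - k, length(cset) - k,
                      length(universe) - length(tset) - length(cset) + k),
                    2L, 2L)
      p <- fisher.test(tab, alternative = "greater")$p.value
      rows[[length(rows) + 1L]] <-
        data.frame(family_id = fam, category_id = cat, overlap = k,
                   n_set = length(tset), n_category = length(cset),
                   n_universe = length(universe), p_value = p)
    }
  }
  res <- do.call(rbind, rows)
  if (poolFamilies) {
    res$fdr_q <- p.adjust(res$p_value, method = "BH")
  } else {
    res$fdr_q <- NA_real_
    for (fam in unique(res$family_id)) {
      i <- res$family_id == fam
      res$fdr_q[i] <- p.adjust(res$p_value[i], method = "BH")
    }
  }
  res$enriched <- res$fdr_q <= fdrCutoff
  res
}

#' Rank-sum association between scores and site position
#'
#' Maps each scored pair to its most extreme site (maximum distance of the
#' relative position from 0.5 — pairs, not sites, carry the score and the
#' terminal placement is what matters), classifies it with
#' [positionClass()], and compares score distributions by
#' Wilcoxon-Mann-Whitney rank-sum tests: terminal (either end) vs middle,
#' and near-poly(A) vs near-ORF. Exact p-values are used for small untied
#' groups, the normal approximation with tie correction otherwise. An empty
#' group skips that comparison.
#'
#' @param scores data.frame with `gene_id`, `family_id`, `score`.
#' @param sites data.frame of site records (as in [siteRecords()]).
#' @param low,high thresholds passed to [positionClass()].
#' @return data.frame with one row per comparison: `comparison`,
#'   `n_group1`, `n_group2`, `median_group1`, `median_group2`,
#'   `p_two_sided`, `p_greater` (group1 shifted above group2).
#' @export
positionScoreAssociation <- function(scores, sites, low = 0.25,
                                     high = 0.75) {
  key <- paste(sites$gene_id, sites$family_id, sep = "\r")
  ext <- abs(sites$relative_position - 0.5)
  best <- tapply(seq_len(nrow(sites)),
                 key, function(i) i[which.max(ext[i])])
  rel <- setNames(sites$relative_position[unlist(best)], names(best))
  skey <- paste(scores$gene_id, scores$family_id, sep = "\r")
  pos <- rel[skey]
  if (anyNA(pos))
    stop("scored pair(s) without a site record: ",
         paste(head(skey[is.na(pos)]), collapse = ", "))
  cls <- positionClass(pos, low = low, high = high)
  comp <- function(label, s1, s2) {
    if (!length(s1) || !length(s2)) return(NULL)
    exact <- length(s1) <= 10 && length(s2) <= 10 &&
      !anyDuplicated(c(s1, s2))
    p2 <- suppressWarnings(
      wilcox.test(s1, s2, exact = exact, correct = !exact)$p.value)
    pg <- suppressWarnings(
      wilcox.test(s1, s2, alternative = "greater", exact = exact,
                  correct = !exact)$p.value)
    data.frame(comparison = label, n_group1 = length(s1),
               n_group2 = length(s2), median_group1 = median(s1),
               median_group2 = median(s2), p_two_sided = p2,
               p_greater = pg)
  }
  s <- scores$score
  terminal <- s[cls != "middle"]
  out <- rbind(
    comp("terminal_vs_middle", terminal, s[cls == "middle"]),
    comp("near_polya_vs_near_orf", s[cls == "near_polya"],
         s[cls == "near_orf"]))
  if (is.null(out))
    warning("all comparisons skipped: an entire position class is empty")
  out
}
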