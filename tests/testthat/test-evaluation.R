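.pairScores <- function(scores, genes = NULL) {
  n <- length(scores)
  data.frame(gene_id = if (is.null(genes)) sprintf("G%02d", seq_len(n))
             else genes,
             family_id = "F1", score = scores)
}

test_that("score bins are equal-count and their means are exact", {
  scores <- .pairScores(1:10)
  responses <- data.frame(gene_id = scores$gene_id, family_id = "F1",
                          response = -(1:10) / 10)
  out <- scoreBinResponse(scores, responses, nBins = 5)
  expect_equal(out$n, rep(2L, 5))
  expect_equal(out$mean_response, c(-0.15, -0.35, -0.55, -0.75, -0.95))
  # monotone: stronger repression in higher score bins
  expect_true(all(diff(out$mean_response) < 0))

  # constant response: every bin mean equals it, zero-width CI direction
  responses$response <- 0.3
  outc <- scoreBinResponse(scores, responses, nBins = 5)
  expect_equal(outc$mean_response, rep(0.3, 5))
  expect_equal(outc$ci_lower, rep(0.3, 5))

  # bin sizes differ by at most one when counts do not divide evenly
  s13 <- .pairScores(rnorm(13))
  r13 <- data.frame(gene_id = s13$gene_id, family_id = "F1",
                    response = rnorm(13))
  expect_lte(diff(range(scoreBinResponse(s13, r13, 5)$n)), 1)

  expect_error(scoreBinResponse(.pairScores(1:3), responses, nBins = 5),
               "fewer")
})

test_that("median-split metric pools above-median pairs per family", {
  scores <- .pairScores(c(1, 2, 3, 4))
  responses <- data.frame(gene_id = scores$gene_id, family_id = "F1",
                          response = c(0, 0, -1, -1))
  out <- medianSplitMetric(scores, responses)
  expect_equal(out$metric, 1.0)
  expect_identical(out$n, 2L)

  # null responses give a zero metric
  responses$response <- 0
  expect_equal(medianSplitMetric(scores, responses)$metric, 0)

  # all-equal scores: family skipped with a warning
  tied <- .pairScores(rep(1, 4))
  expect_warning(expect_error(medianSplitMetric(tied, responses),
                              "no family"),
                 "median")
})

test_that("random scores give a metric near the overall mean response", {
  set.seed(15)
  n <- 200
  responses <- data.frame(gene_id = sprintf("G%03d", 1:n),
                          family_id = rep(c("F1", "F2"), each = n / 2),
                          response = rnorm(n, -0.2, 0.5))
  ref <- replicate(200, {
    sc <- data.frame(gene_id = responses$gene_id,
                     family_id = responses$family_id,
                     score = sample(n))
    medianSplitMetric(sc, responses)$metric
  })
  # permuted-score metrics scatter around -mean(all responses)
  expect_lt(abs(mean(ref) - (-mean(responses$response))),
            2 * sd(ref) / sqrt(200) + 0.02)
  one <- medianSplitMetric(
    data.frame(gene_id = responses$gene_id,
               family_id = responses$family_id, score = sample(n)),
    responses)$metric
  expect_gt(one, quantile(ref, 0.005) - 0.1)
  expect_lt(one, quantile(ref, 0.995) + 0.1)
})

test_that("hypergeometric enrichment matches closed-form combinatorics", {
  u <- sprintf("G%02d", 1:10)
  res <- hypergeomEnrichment(u[1:5], u[1:5], u)
  expect_equal(res$p_value, 1 / choose(10, 5))
  expect_identical(res$overlap, 5L)

  # empty validated set is vacuous
  expect_equal(hypergeomEnrichment(u[1:5], character(), u)$p_value, 1)

  # exhaustive tail enumeration oracle on random small instances
  set.seed(16)
  for (i in 1:10) {
    N <- sample(8:14, 1)
    uu <- sprintf("g%02d", seq_len(N))
    hi <- sample(uu, sample(2:(N - 2), 1))
    va <- sample(uu, sample(2:(N - 2), 1))
    k <- length(intersect(hi, va))
    tail <- sum(vapply(k:min(length(hi), length(va)), function(kk)
      choose(length(va), kk) * choose(N - length(va), length(hi) - kk) /
        choose(N, length(hi)), 1))
    expect_equal(hypergeomEnrichment(hi, va, uu)$p_value, tail,
                 tolerance = 1e-12)
  }
  expect_error(hypergeomEnrichment("a", "a", character()), "universe")
})

test_that("category enrichment is Fisher + per-family BH", {
  u <- sprintf("G%02d", 1:10)
  res <- categoryEnrichment(list(F1 = u[1:5]),
                            list(C1 = u[1:5]), u)
  # one-sided Fisher p equals the hypergeometric tail for the same table
  expect_equal(res$p_value,
               hypergeomEnrichment(u[1:5], u[1:5], u)$p_value)
  # single-category BH is the identity; enriched flag at the 0.1 cutoff
  expect_equal(res$fdr_q, res$p_value)
  expect_true(res$enriched)

  # BH step-up invariants across several categories
  set.seed(17)
  cats <- lapply(1:6, function(i) sample(u, 5))
  names(cats) <- paste0("C", 1:6)
  res2 <- categoryEnrichment(list(F1 = u[1:5]), cats, u)
  o <- order(res2$p_value)
  expect_true(all(res2$fdr_q >= res2$p_value - 1e-12))
  expect_true(all(diff(res2$fdr_q[o]) >= -1e-12))
  expect_true(all(res2$fdr_q <= 1))
  # pooling families corrects across the whole table at once
  res3 <- categoryEnrichment(list(F1 = u[1:5], F2 = u[6:10]), cats, u,
                             poolFamilies = TRUE)
  expect_equal(res3$fdr_q, p.adjust(res3$p_value, "BH"))

  expect_warning(
    categoryEnrichment(list(F1 = u[1:3]),
                       list(C1 = u[1:2], C2 = "absent"), u),
    "skipped")
  expect_error(categoryEnrichment(list(F1 = u[1:3]), list(), u),
               "categories")
})

test_that("position-score association uses exact small-sample rank sums", {
  sites <- data.frame(
    gene_id = sprintf("G%d", 1:6), family_id = "F1",
    site_start = c(90, 92, 95, 50, 52, 55), utr_length = 100,
    relative_position = c(90, 92, 95, 50, 52, 55) / 100)
  scores <- .pairScores(c(5, 6, 7, 1, 2, 3), genes = sprintf("G%d", 1:6))
  out <- positionScoreAssociation(scores, sites)
  row <- out[out$comparison == "terminal_vs_middle", ]
  expect_equal(row$p_greater, 1 / choose(6, 3))
  expect_equal(row$median_group1, 6)
  expect_equal(row$median_group2, 2)
  # only one terminal class present: the polyA-vs-ORF comparison is skipped
  expect_identical(out$comparison, "terminal_vs_middle")

  # a pair's most extreme site decides its class
  sites2 <- rbind(sites,
                  data.frame(gene_id = "G4", family_id = "F1",
                             site_start = 98, utr_length = 100,
                             relative_position = 0.98))
  out2 <- positionScoreAssociation(scores, sites2)
  expect_equal(out2$n_group1[out2$comparison == "terminal_vs_middle"], 4)

  # identical distributions: two-sided p is not systematically small
  set.seed(18)
  ps <- replicate(40, {
    sc <- .pairScores(rnorm(20), genes = sprintf("H%02d", 1:20))
    st <- data.frame(gene_id = sc$gene_id, family_id = "F1",
                     site_start = sample(c(10, 50), 20, TRUE),
                     utr_length = 100)
    st$relative_position <- st$site_start / st$utr_length
    res <- positionScoreAssociation(sc, st)
    res$p_two_sided[res$comparison == "terminal_vs_middle"]
  })
  ps <- unlist(ps)
  expect_gt(mean(ps), 0.05)
})
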