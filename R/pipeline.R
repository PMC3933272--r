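#' End-to-end scoring pipeline
#'
#' Convenience wrapper chaining the full workflow: preprocess the
#' expression matrix ([preprocessExpression()]), infer per-family activity
#' vectors ([inferActivity()]), center each gene's profile
#' ([centerRows()]) and score every candidate pair ([fitAll()]).
#'
#' @param expr a [MirExpression-class] (raw or log2 scale).
#' @param net a [MirTargetNetwork-class].
#' @param config a [baymirConfig()].
#' @param minTargets,activityInput passed to [inferActivity()].
#' @param ... further arguments to [preprocessExpression()].
#' @return list with `scores` (the score table from [fitAll()]),
#'   `activity` ([MirActivity-class]), `geneVariation` (data.frame) and
#'   `expr` (the preprocessed matrix).
#' @examples
#' b <- simulateBundle(nGenes = 60, nFamilies = 4, nSamples = 40, seed = 7)
#' res <- runBaymir(b$expr, b$net,
#'                  config = baymirConfig(lambda1 = 0.05,
#'                                        lambdaSelection = "fixed"))
#' head(res$scores)
#' @export
runBaymir <- function(expr, net, config = baymirConfig(), minTargets = 5,
                      activityInput = "zscore", ...) {
  expr <- preprocessExpression(expr, ...)
  activity <- inferActivity(expr, net, minTargets = minTargets,
                            input = activityInput)
  centered <- centerRows(expr)
  scores <- fitAll(centered, activity, net, config = config)
  list(scores = scores, activity = activity,
       geneVariation = geneVariation(expr), expr = expr)
}
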