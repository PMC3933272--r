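# The reference synthetic bundle (500 genes, 20 families, 100 samples,
# noise sd 0.25, seed 1) scored once with the default configuration and
# shared across test files.
.bundleCache <- new.env(parent = emptyenv())

defaultBundleFit <- function() {
  if (!is.null(.bundleCache$fit)) return(.bundleCache$fit)
  bundle <- simulateBundle(seed = 1)
  activity <- inferActivity(bundle$expr, bundle$net)
  centered <- centerRows(bundle$expr)
  scores <- fitAll(centered, activity, bundle$net, baymirConfig())
  .bundleCache$fit <- list(bundle = bundle, activity = activity,
                           centered = centered, scores = scores,
                           planted = bundle$truth$coefficients[
                             cbind(scores$gene_id, scores$family_id)])
  .bundleCache$fit
}
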