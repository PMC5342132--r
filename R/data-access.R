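#' Reference MRD pairs: 10^4-event subsample vs full training file
#'
#' Ten published AML MRD determinations (percent of events), each computed
#' twice from the same specimen: once with a model trained on a 10^4-event
#' stratified subsample and once with the full ~2 x 10^5-event training
#' file. Used to check that subsampled training does not bias the MRD
#' estimate (paired t-test on these pairs gives p = 0.0792).
#'
#' @return A [paired_results()] with `a` = subsample estimate and `b` =
#'   full-training-file estimate.
#' @export
mrd_subsample_pairs <- function() {
  path <- system.file("extdata", "mrd_subsample_pairs.csv", package = "flowMRD",
                      mustWork = TRUE)
  df <- utils::read.csv(path)
  paired_results(df$subsample_1e4, df$full_2e5, ids = df$case)
}
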