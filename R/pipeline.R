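#' Dependency pipeline: raw platform screens to lineage-specific calls
#'
#' Chains the unification and essentiality stages: align the CRISPR and
#' shRNA matrices, impute one-platform missingness by loess, combine with
#' mixing ratio `theta`, then compute efficacies, Gaussian thresholds,
#' essential calls, the lineage-specific set and selectivity.
#'
#' @inheritParams unify_screens
#' @inheritParams essentiality_screen
#' @return The [essentiality_screen()] result, with `unified` (the
#'   [unify_screens()] output) appended.
#' @export
dependency_pipeline <- function(crispr, shrna, metadata, lineage = "MM",
                                theta = 0.6, x_target = 25, x_background = 1,
                                tail_p = 0.001, span = 0.5, min_pairs = 30) {
  unified <- unify_screens(crispr, shrna, theta = theta, span = span,
                           min_pairs = min_pairs)
  out <- essentiality_screen(unified, metadata, lineage = lineage,
                             x_target = x_target, x_background = x_background,
                             tail_p = tail_p)
  out$unified <- unified
  out
}
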