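#' Align two platform screens onto their common grid
#'
#' Intersects the gene symbols and cell-line identifiers of the CRISPR and
#' shRNA matrices. Genes and lines present on only one platform are dropped;
#' their counts are attached as attributes and reported in a message.
#'
#' @param crispr,shrna [screen_matrix()] objects.
#' @return List with the two matrices restricted to the common grid and the
#'   unmatched counts (`unmatched_genes`, `unmatched_lines`).
#' @export
align_screens <- function(crispr, shrna) {
  stopifnot(inherits(crispr, "screen_matrix"), inherits(shrna, "screen_matrix"))
  genes <- intersect(rownames(crispr), rownames(shrna))
  lines <- intersect(colnames(crispr), colnames(shrna))
  if (!length(genes) || !length(lines))
    stop("no common genes or cell lines between platforms")
  n_ug <- (nrow(crispr) - length(genes)) + (nrow(shrna) - length(genes))
  n_ul <- (ncol(crispr) - length(lines)) + (ncol(shrna) - length(lines))
  if (n_ug + n_ul > 0)
    message("align_screens: dropped ", n_ug, " platform-specific gene(s) and ",
            n_ul, " line(s)")
  list(crispr = screen_matrix(unclass(crispr)[genes, lines, drop = FALSE], "crispr"),
       shrna = screen_matrix(unclass(shrna)[genes, lines, drop = FALSE], "shrna"),
       unmatched_genes = n_ug, unmatched_lines = n_ul)
}

loess_predict_clamped <- function(x_obs, y_obs, x_new, span, degree) {
  # clamp query points to the observed predictor range: loess extrapolation
  # beyond the design range is undefined for local quadratics
  x_new <- pmin(pmax(x_new, min(x_obs)), max(x_obs))
  fit <- stats::loess(y_obs ~ x_obs, span = span, degree = degree,
                      family = "gaussian")
  as.numeric(stats::predict(fit, data.frame(x_obs = x_new)))
}

#' Impute missing platform scores from the other platform
#'
#' For each cell line a local polynomial regression (loess) of the observed
#' CRISPR scores against the observed shRNA scores, across genes, predicts
#' the CRISPR score of genes missing on the CRISPR platform from their shRNA
#' score, and symmetrically for missing shRNA scores. Predictor values
#' outside the observed range are clamped to the range boundary so the fit
#' is never extrapolated. Entries missing on both platforms cannot be
#' recovered: they remain missing and are returned in a flag table.
#'
#' @param crispr,shrna [screen_matrix()] objects on the same gene x line grid
#'   (use [align_screens()] first). Every line must have at least
#'   `min_pairs` genes observed on both platforms.
#' @param span,degree Loess parameters (defaults 0.5 and 2).
#' @param min_pairs Minimum doubly-observed genes per line.
#' @return List with imputed `crispr` and `shrna` matrices and `both_missing`,
#'   a data frame of gene/line pairs unobserved on both platforms.
#' @export
impute_missing <- function(crispr, shrna, span = 0.5, degree = 2,
                           min_pairs = 30) {
  stopifnot(identical(dimnames(crispr), dimnames(shrna)))
  C <- unclass(crispr); R <- unclass(shrna)
  both_na <- is.na(C) & is.na(R)
  for (j in seq_len(ncol(C))) {
    c_j <- C[, j]; r_j <- R[, j]
    obs <- !is.na(c_j) & !is.na(r_j)
    need_c <- is.na(c_j) & !is.na(r_j)
    need_r <- is.na(r_j) & !is.na(c_j)
    if (!any(need_c) && !any(need_r)) next
    if (sum(obs) < min_pairs)
      stop("cell line '", colnames(C)[j], "' has only ", sum(obs),
           " genes observed on both platforms (need >= ", min_pairs, ")")
    if (any(need_c))
      C[need_c, j] <- loess_predict_clamped(r_j[obs], c_j[obs], r_j[need_c],
                                            span, degree)
    if (any(need_r))
      R[need_r, j] <- loess_predict_clamped(c_j[obs], r_j[obs], c_j[need_r],
                                            span, degree)
  }
  flag <- which(both_na, arr.ind = TRUE)
  both_missing <- data.frame(gene = rownames(C)[flag[, 1]],
                             line = colnames(C)[flag[, 2]],
                             stringsAsFactors = FALSE)
  list(crispr = screen_matrix(C, "crispr"),
       shrna = screen_matrix(R, "shrna"),
       both_missing = both_missing)
}

#' Data-driven mixing ratio from the first principal component
#'
#' Pools all (CRISPR, shRNA) score pairs over genes and cell lines,
#' mean-centres the 2-D cloud, and takes the first principal axis
#' \eqn{(v_C, v_R)} (sign fixed so \eqn{v_C > 0}), the direction maximising
#' the variance of the pooled scatter. The mixing ratio for which the
#' unified-score axis is parallel to this component is
#' \eqn{\theta^* = v_C / (v_C + v_R)}.
#'
#' @param crispr,shrna Complete (post-imputation) [screen_matrix()] objects
#'   on the same grid; pairs still missing on both platforms are ignored.
#' @return The estimated mixing ratio (scalar).
#' @export
select_theta <- function(crispr, shrna) {
  stopifnot(identical(dim(crispr), dim(shrna)))
  pts <- cbind(C = as.numeric(crispr), R = as.numeric(shrna))
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3) stop("too few complete score pairs for PCA")
  if (all(pts[, 1] == pts[1, 1]) && all(pts[, 2] == pts[1, 2]))
    stop("degenerate score cloud: all pairs identical")
  v <- stats::prcomp(pts, center = TRUE, scale. = FALSE)$rotation[, 1]
  if (v[1] < 0) v <- -v
  if (v[1] + v[2] <= 0)
    stop("first principal axis has non-positive component sum; ",
         "platforms are anti-correlated and no mixing ratio in [0, 1] exists")
  unname(v[1] / (v[1] + v[2]))
}

#' Unified perturbation score
#'
#' Elementwise weighted average of the two platform scores,
#' \eqn{S^{\theta} = \theta S^C + (1 - \theta) S^R}, where \eqn{\theta} is
#' the mixing ratio. The default \eqn{\theta = 0.6} weights CRISPR 60:40
#' over shRNA, close to the principal-component-optimal ratio on DepMap-scale
#' data while keeping a round weighting. Genes with any remaining missing
#' pair (unrecoverable by imputation) are dropped and recorded.
#'
#' @param crispr,shrna Imputed [screen_matrix()] objects on the same grid.
#' @param theta Mixing ratio in \[0, 1\].
#' @return A `unified_scores` object: the unified [screen_matrix()] with
#'   attributes `theta`, `dropped_genes` and `n_genes_common`.
#' @export
unify <- function(crispr, shrna, theta = 0.6) {
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) ||
      theta < 0 || theta > 1)
    stop("theta must be a single number in [0, 1]")
  stopifnot(identical(dimnames(crispr), dimnames(shrna)))
  s <- theta * unclass(crispr) + (1 - theta) * unclass(shrna)
  dropped <- rownames(s)[apply(is.na(s), 1, any)]
  if (length(dropped))
    message("unify: dropped ", length(dropped),
            " gene(s) with unrecoverable missing scores")
  s <- s[setdiff(rownames(s), dropped), , drop = FALSE]
  out <- screen_matrix(s, "unified")
  attr(out, "theta") <- theta
  attr(out, "dropped_genes") <- dropped
  attr(out, "n_genes_common") <- nrow(s)
  class(out) <- c("unified_scores", class(out))
  out
}

#' One-call unification of two raw platform screens
#'
#' Convenience wrapper: [align_screens()], [impute_missing()], then
#' [unify()], also reporting the data-driven mixing ratio from
#' [select_theta()] alongside the ratio actually applied.
#'
#' @inheritParams impute_missing
#' @inheritParams unify
#' @param theta Mixing ratio to apply, or `"pca"` to apply the data-driven
#'   estimate.
#' @return A `unified_scores` object with attribute `theta_pca`.
#' @export
unify_screens <- function(crispr, shrna, theta = 0.6, span = 0.5, degree = 2,
                          min_pairs = 30) {
  al <- align_screens(crispr, shrna)
  imp <- impute_missing(al$crispr, al$shrna, span = span, degree = degree,
                        min_pairs = min_pairs)
  theta_pca <- select_theta(imp$crispr, imp$shrna)
  if (identical(theta, "pca")) theta <- theta_pca
  out <- unify(imp$crispr, imp$shrna, theta = theta)
  attr(out, "theta_pca") <- theta_pca
  out
}
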