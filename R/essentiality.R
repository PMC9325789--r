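#' Map a percentile to a cell-line count
#'
#' The efficacy of a gene is read off at the X-th percentile most-sensitive
#' cell line; this maps the percentile to the order-statistic index
#' `k = max(1, floor(n_lines * X / 100))`. With 34 target-lineage lines and
#' X = 25 this selects the 8th most-sensitive line; with a 449-line
#' background and X = 1 it selects the 4th.
#'
#' @param n_lines Number of cell lines (>= 1).
#' @param X Percentile in (0, 100).
#' @return Integer order-statistic index, at least 1.
#' @export
percentile_count <- function(n_lines, X) {
  if (n_lines < 1) stop("n_lines must be >= 1")
  if (X <= 0 || X >= 100) stop("X must be in (0, 100)")
  max(1L, as.integer(floor(n_lines * X / 100)))
}

subset_scores <- function(unified, lines) {
  stopifnot(inherits(unified, "screen_matrix"))
  missing_lines <- setdiff(lines, colnames(unified))
  if (length(missing_lines))
    stop("lines absent from score matrix: ", paste(missing_lines, collapse = ", "))
  unclass(unified)[, lines, drop = FALSE]
}

per_gene_order_stat <- function(scores, k, decreasing = FALSE) {
  dropped <- rownames(scores)[apply(is.na(scores), 1, any)]
  if (length(dropped)) {
    message(length(dropped), " gene(s) with missing scores in subset dropped")
    scores <- scores[setdiff(rownames(scores), dropped), , drop = FALSE]
  }
  vals <- apply(scores, 1, function(x) sort(x, decreasing = decreasing)[k])
  attr(vals, "dropped") <- dropped
  vals
}

#' Per-gene efficacy
#'
#' Efficacy measures how essential a gene is in the cell lines most
#' sensitive to its loss: the unified score at the X-th percentile
#' most-sensitive line, i.e. the k-th smallest score across the chosen
#' lines with k from [percentile_count()].
#'
#' @param unified A [screen_matrix()] (typically platform `"unified"`).
#' @param lines Character vector of cell-line identifiers to use (>= 2).
#' @param X Percentile in (0, 50) (25 for small lineage panels, 1 for large
#'   pan-cancer backgrounds).
#' @return Named numeric vector of efficacies; genes with any missing score
#'   among `lines` are dropped and listed in the `"dropped"` attribute.
#' @export
efficacy <- function(unified, lines, X = 25) {
  if (length(lines) < 2) stop("need >= 2 cell lines")
  if (X <= 0 || X >= 50) stop("X must be in (0, 50)")
  scores <- subset_scores(unified, lines)
  k <- percentile_count(length(lines), X)
  per_gene_order_stat(scores, k, decreasing = FALSE)
}

#' Per-gene dispersion
#'
#' Dispersion is the spread of a gene's response across cell lines: the
#' difference between the (100-X)-th and X-th percentile of its scores,
#' computed as (k-th largest) - (k-th smallest) with k from
#' [percentile_count()]. Always non-negative; large for cell-line-selective
#' dependencies, small for uniformly essential or uniformly inert genes.
#'
#' @inheritParams efficacy
#' @return Named numeric vector of dispersions (attribute `"dropped"` as in
#'   [efficacy()]).
#' @export
dispersion <- function(unified, lines, X = 25) {
  if (length(lines) < 2) stop("need >= 2 cell lines")
  if (X <= 0 || X >= 50) stop("X must be in (0, 50)")
  scores <- subset_scores(unified, lines)
  k <- percentile_count(length(lines), X)
  lo <- per_gene_order_stat(scores, k, decreasing = FALSE)
  hi <- per_gene_order_stat(scores, k, decreasing = TRUE)
  out <- hi - lo
  attr(out, "dropped") <- attr(lo, "dropped")
  out
}

#' Fit a Gaussian essentiality threshold to an efficacy distribution
#'
#' The bulk of genes is not essential, so the efficacy distribution is
#' dominated by a near-Gaussian central mode with a left tail of essential
#' genes. A Gaussian kernel density estimate is evaluated on a 512-point
#' grid spanning the data range plus one bandwidth on each side; a scaled
#' normal density `c * phi((s - mu) / sigma)` is then fitted by least
#' squares to the KDE restricted to the interval between the two
#' half-maximum crossings around its mode, with the grid argmax seeding the
#' location. Fitting only near the mode keeps the essential-gene tail from
#' inflating sigma, and refining the location within the least-squares step
#' makes mu much less noisy than the raw argmax. The essentiality threshold
#' is the lower-tail quantile `T = mu + sigma * qnorm(tail_p)`.
#'
#' @param efficacies Numeric vector of per-gene efficacies (>= 100 finite
#'   values).
#' @param tail_p Lower-tail probability defining the threshold (default
#'   0.001).
#' @param bandwidth `"silverman"` (default, `stats::bw.nrd0`), `"scott"`
#'   (`stats::bw.nrd`), or a positive number.
#' @return A `gaussian_fit` list: `mu`, `sigma`, `threshold`, `tail_p`, `bw`.
#' @export
fit_gaussian_threshold <- function(efficacies, tail_p = 0.001,
                                   bandwidth = "silverman") {
  x <- efficacies[is.finite(efficacies)]
  if (length(x) < 100) stop("need >= 100 finite efficacies to fit a threshold")
  if (tail_p <= 0 || tail_p >= 0.5) stop("tail_p must be in (0, 0.5)")
  bw <- if (is.numeric(bandwidth)) bandwidth
        else switch(match.arg(bandwidth, c("silverman", "scott")),
                    silverman = stats::bw.nrd0(x), scott = stats::bw.nrd(x))
  dens <- stats::density(x, bw = bw, n = 512, from = min(x) - bw,
                         to = max(x) + bw)
  i_mode <- which.max(dens$y)
  mu <- dens$x[i_mode]
  half <- dens$y[i_mode] / 2
  below <- dens$y < half
  left <- which(below[seq_len(i_mode)])
  right <- which(below[i_mode:length(below)]) + i_mode - 1L
  if (!length(left) || !length(right))
    stop("no half-maximum interval brackets the KDE mode; the density may be ",
         "multimodal at this bandwidth - try a larger one")
  idx <- (max(left) + 1L):(min(right) - 1L)
  s <- dens$x[idx]; y <- dens$y[idx]
  # init sigma from the log-quadratic closed form, then refine (c, mu, sigma)
  # on the density scale; the joint fit averages over the whole half-max
  # window instead of trusting a single noisy argmax
  lsq <- stats::lm(log(y) ~ I((s - mu)^2))
  sigma0 <- sqrt(max(-1 / (2 * stats::coef(lsq)[2]), 1e-8))
  obj <- function(p) {
    sum((exp(p[1]) * stats::dnorm(s, p[2], exp(p[3])) - y)^2)
  }
  opt <- stats::optim(c(unname(stats::coef(lsq)[1]) + log(sqrt(2 * pi) * sigma0),
                        mu, log(sigma0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  mu <- unname(opt$par[2])
  sigma <- unname(exp(opt$par[3]))
  structure(list(mu = mu, sigma = sigma,
                 threshold = mu + sigma * stats::qnorm(tail_p),
                 tail_p = tail_p, bw = bw),
            class = "gaussian_fit")
}

#' @exportS3Method base::print
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mu=%.4f sigma=%.4f threshold=%.4f (tail p=%g)\n",
              x$mu, x$sigma, x$threshold, x$tail_p))
  invisible(x)
}

#' Call essential genes against a fitted threshold
#'
#' A gene is essential when its efficacy lies strictly below the
#' essentiality threshold.
#'
#' @param efficacies Named numeric vector from [efficacy()].
#' @param fit A [fit_gaussian_threshold()] result.
#' @return Named logical vector.
#' @export
call_essential <- function(efficacies, fit) {
  stopifnot(inherits(fit, "gaussian_fit"))
  efficacies < fit$threshold
}

#' Lineage-specific essential genes
#'
#' Set difference between the genes essential in the target lineage and
#' those essential in the background panel, with the overlap sizes needed
#' for a Venn summary.
#'
#' @param essential_mm Character vector (or named logical) of genes essential
#'   in the target lineage.
#' @param essential_other Same for the background panel.
#' @return List with `specific` (target-only genes), `shared`, and `sizes`
#'   (named counts: target, background, shared, specific).
#' @export
lineage_specific <- function(essential_mm, essential_other) {
  if (is.logical(essential_mm)) essential_mm <- names(which(essential_mm))
  if (is.logical(essential_other)) essential_other <- names(which(essential_other))
  specific <- setdiff(essential_mm, essential_other)
  shared <- intersect(essential_mm, essential_other)
  list(specific = specific, shared = shared,
       sizes = c(target = length(essential_mm),
                 background = length(essential_other),
                 shared = length(shared), specific = length(specific)))
}

#' Selectivity from dispersion residuals
#'
#' Across genes, dispersion is approximately linear in efficacy for the
#' commonly essential and non-essential majority; selectively essential
#' genes sit above that trend. An ordinary least-squares line
#' `D_hat = a + b * E` is fitted over all genes and each gene's selectivity
#' is the normalised residual `U = (D - D_hat) / D_hat` (set
#' `denominator = "observed"` to normalise by the observed dispersion D
#' instead). Genes whose fitted dispersion is non-positive have undefined
#' selectivity and are returned as `NA` with a flag.
#'
#' @param efficacies,dispersions Named numeric vectors over the same genes.
#' @param denominator `"fitted"` (default) or `"observed"`.
#' @return Data frame with columns `gene`, `efficacy`, `dispersion`,
#'   `dispersion_fit`, `residual`, `selectivity`, `undefined`; attributes
#'   `intercept` and `slope` carry the fitted line.
#' @export
selectivity <- function(efficacies, dispersions,
                        denominator = c("fitted", "observed")) {
  denominator <- match.arg(denominator)
  genes <- intersect(names(efficacies), names(dispersions))
  E <- efficacies[genes]; D <- dispersions[genes]
  keep <- is.finite(E) & is.finite(D)
  if (sum(keep) < 10) stop("need >= 10 genes with finite efficacy and dispersion")
  E <- E[keep]; D <- D[keep]; genes <- genes[keep]
  if (stats::var(E) == 0) stop("zero variance in efficacy; trend line undefined")
  fit <- stats::lm(D ~ E)
  D_hat <- as.numeric(stats::fitted(fit))
  R <- D - D_hat
  den <- if (denominator == "fitted") D_hat else D
  undefined <- den <= 0
  U <- ifelse(undefined, NA_real_, R / den)
  out <- data.frame(gene = genes, efficacy = unname(E), dispersion = unname(D),
                    dispersion_fit = D_hat, residual = unname(R),
                    selectivity = unname(U), undefined = undefined,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "intercept") <- unname(stats::coef(fit)[1])
  attr(out, "slope") <- unname(stats::coef(fit)[2])
  out
}

#' Full essentiality stage over a unified screen
#'
#' Runs the essentiality arm end to end on a unified score matrix: efficacy
#' and dispersion in the target-lineage lines (percentile `x_target`) and in
#' the background lines (percentile `x_background`), Gaussian thresholds for
#' both groups, essential calls, the lineage-specific set difference, and
#' selectivity within the target lineage.
#'
#' @param unified A [screen_matrix()] of unified scores.
#' @param metadata A [line_metadata()] covering the matrix's cell lines.
#' @param lineage Lineage label defining the target group (default `"MM"`).
#' @param x_target,x_background Efficacy percentiles for the target and
#'   background groups (defaults 25 and 1).
#' @param tail_p Gaussian lower-tail probability (default 0.001).
#' @param bandwidth Passed to [fit_gaussian_threshold()].
#' @return List: `records` (per-gene data frame with efficacy, dispersion,
#'   selectivity and essential flags), `fit_target`, `fit_background`,
#'   `venn` (from [lineage_specific()]).
#' @export
essentiality_screen <- function(unified, metadata, lineage = "MM",
                                x_target = 25, x_background = 1,
                                tail_p = 0.001, bandwidth = "silverman") {
  stopifnot(inherits(metadata, "line_metadata"))
  lines_t <- metadata$line_id[metadata$lineage == lineage]
  lines_b <- metadata$line_id[metadata$lineage != lineage]
  lines_t <- intersect(lines_t, colnames(unified))
  lines_b <- intersect(lines_b, colnames(unified))
  if (length(lines_t) < 2) stop("fewer than 2 '", lineage, "' lines in matrix")
  if (length(lines_b) < 2) stop("fewer than 2 background lines in matrix")

  eff_t <- efficacy(unified, lines_t, x_target)
  eff_b <- efficacy(unified, lines_b, x_background)
  fit_t <- fit_gaussian_threshold(eff_t, tail_p = tail_p, bandwidth = bandwidth)
  fit_b <- fit_gaussian_threshold(eff_b, tail_p = tail_p, bandwidth = bandwidth)
  ess_t <- call_essential(eff_t, fit_t)
  ess_b <- call_essential(eff_b, fit_b)
  venn <- lineage_specific(ess_t, ess_b)

  disp_t <- dispersion(unified, lines_t, x_target)
  sel <- selectivity(eff_t, disp_t)
  records <- data.frame(gene = names(eff_t), efficacy = unname(eff_t),
                        essential_target = unname(ess_t),
                        essential_background = unname(ess_b[names(eff_t)]),
                        lineage_specific = names(eff_t) %in% venn$specific,
                        stringsAsFactors = FALSE, row.names = NULL)
  records <- merge(records,
                   sel[, c("gene", "dispersion", "dispersion_fit", "residual",
                           "selectivity")],
                   by = "gene", all.x = TRUE, sort = FALSE)
  list(records = records, fit_target = fit_t, fit_background = fit_b,
       venn = venn)
}
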