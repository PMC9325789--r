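#' Ground truth for simulated dependency screens
#'
#' Describes the generative model behind [simulate_screens()]: each gene is
#' non-essential, commonly essential (essential in every lineage), or
#' lineage-essential (essential only in the target lineage). The latent gene
#' effect per gene x line is the class mean plus Gaussian biological noise;
#' the CRISPR readout adds platform noise and the shRNA readout is a linear
#' coupling of the same latent effect plus its own platform noise. Entries
#' are masked missing independently.
#'
#' @param frac_common Fraction of genes commonly essential.
#' @param frac_lineage Fraction of genes essential only in the target lineage.
#' @param mean_essential Mean latent effect of essential gene/line pairs
#'   (negative: stronger dropout).
#' @param mean_nonessential Mean latent effect otherwise.
#' @param noise_sd Biological noise sd on the latent effect.
#' @param slope Linear coupling of shRNA to the latent effect.
#' @param platform_sd Per-platform measurement noise sd.
#' @param missing_rate Independent missingness probability per entry, in
#'   \[0, 1).
#' @return A `screen_truth` list.
#' @export
screen_truth <- function(frac_common = 0.10, frac_lineage = 0.025,
                         mean_essential = -1.5, mean_nonessential = 0,
                         noise_sd = 0.25, slope = 1, platform_sd = 0.25,
                         missing_rate = 0.01) {
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (mean_essential >= 0) stop("essential class mean must be negative")
  if (frac_common + frac_lineage > 1) stop("class fractions exceed 1")
  structure(list(frac_common = frac_common, frac_lineage = frac_lineage,
                 mean_essential = mean_essential,
                 mean_nonessential = mean_nonessential,
                 noise_sd = noise_sd, slope = slope, platform_sd = platform_sd,
                 missing_rate = missing_rate),
            class = "screen_truth")
}

#' Simulate coupled CRISPR and shRNA dependency screens
#'
#' Generates two platform score matrices over a shared gene x cell-line grid
#' with known gene classes, for parameter-recovery testing of the unification
#' and essentiality stages. Cell lines are split into a target-lineage group
#' (labelled `"MM"`) and a background group (`"other"`); lineage-essential
#' genes take their (negative) essential mean only in target-lineage lines.
#'
#' @param n_genes Number of genes (>= 2).
#' @param n_mm_lines Number of target-lineage cell lines (>= 2).
#' @param n_other_lines Number of background cell lines (>= 2).
#' @param truth A [screen_truth()].
#' @param seed Integer seed (mandatory; one RNG stream per call).
#' @return List with elements `crispr` and `shrna` ([screen_matrix()]s),
#'   `metadata` ([line_metadata()]), and `classes` (named character vector of
#'   true gene classes).
#' @export
simulate_screens <- function(n_genes, n_mm_lines, n_other_lines,
                             truth = screen_truth(), seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (n_genes < 2) stop("n_genes must be >= 2")
  if (n_mm_lines < 2) stop("n_mm_lines must be >= 2 (percentile undefined)")
  if (n_other_lines < 2) stop("n_other_lines must be >= 2")
  stopifnot(inherits(truth, "screen_truth"))

  set.seed(seed)  # single stream keyed by seed
  n_common <- round(truth$frac_common * n_genes)
  n_lineage <- round(truth$frac_lineage * n_genes)
  classes <- rep(c("common_essential", "lineage_essential", "nonessential"),
                 c(n_common, n_lineage, n_genes - n_common - n_lineage))
  classes <- sample(classes)
  genes <- sprintf("G%04d", seq_len(n_genes))
  names(classes) <- genes
  lines <- c(sprintf("MM_%03d", seq_len(n_mm_lines)),
             sprintf("OT_%03d", seq_len(n_other_lines)))
  n_lines <- length(lines)
  is_mm <- rep(c(TRUE, FALSE), c(n_mm_lines, n_other_lines))

  mu <- matrix(truth$mean_nonessential, n_genes, n_lines)
  mu[classes == "common_essential", ] <- truth$mean_essential
  mu[classes == "lineage_essential", is_mm] <- truth$mean_essential
  latent <- mu + matrix(stats::rnorm(n_genes * n_lines, 0, truth$noise_sd),
                        n_genes, n_lines)
  crispr <- latent +
    matrix(stats::rnorm(n_genes * n_lines, 0, truth$platform_sd), n_genes, n_lines)
  shrna <- truth$slope * latent +
    matrix(stats::rnorm(n_genes * n_lines, 0, truth$platform_sd), n_genes, n_lines)
  if (truth$missing_rate > 0) {
    crispr[matrix(stats::runif(n_genes * n_lines) < truth$missing_rate,
                  n_genes, n_lines)] <- NA
    shrna[matrix(stats::runif(n_genes * n_lines) < truth$missing_rate,
                 n_genes, n_lines)] <- NA
  }
  dimnames(crispr) <- dimnames(shrna) <- list(genes, lines)
  list(crispr = screen_matrix(crispr, "crispr"),
       shrna = screen_matrix(shrna, "shrna"),
       metadata = line_metadata(lines, ifelse(is_mm, "MM", "other")),
       classes = classes)
}

#' Ground truth for simulated survival cohorts
#'
#' Parameters of the proportional-hazards generative model in
#' [simulate_cohort()]. Event times are exponential with hazard
#' `baseline_rate * exp(lp)`, where the linear predictor collects a
#' low-expression group contrast per planted gene (bottom quartile vs rest)
#' and the age/sex/ISS covariate effects. Censoring is independent
#' exponential with its rate solved to hit the requested censoring fraction
#' in expectation.
#'
#' @param log_hr Named numeric vector: per-gene log hazard ratio for the
#'   low-expression contrast. Genes not named carry no effect.
#' @param baseline_rate Baseline exponential event rate per month.
#' @param censoring Target censoring fraction in \[0, 1).
#' @param age_coef,sex_coef,iss_coef Covariate log-hazard effects (age per
#'   year, sex indicator, ISS per stage above 1).
#' @param pfs_rate_ratio Progression hazard as a multiple of the death
#'   hazard; PFS is the minimum of the progression and death times, so
#'   PFS <= OS always.
#' @return A `cohort_truth` list.
#' @export
cohort_truth <- function(log_hr = numeric(), baseline_rate = 0.015,
                         censoring = 0.3, age_coef = 0.02, sex_coef = 0.1,
                         iss_coef = 0.3, pfs_rate_ratio = 1.5) {
  if (censoring < 0 || censoring >= 1) stop("censoring must be in [0, 1)")
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  structure(list(log_hr = log_hr, baseline_rate = baseline_rate,
                 censoring = censoring, age_coef = age_coef,
                 sex_coef = sex_coef, iss_coef = iss_coef,
                 pfs_rate_ratio = pfs_rate_ratio),
            class = "cohort_truth")
}

#' Simulate a patient cohort with expression-linked survival
#'
#' Expression is standard normal per gene and patient. For each gene with a
#' planted log hazard ratio, patients in the bottom expression quartile get
#' that contribution to their log hazard, mirroring the low-vs-high
#' expression contrast tested downstream. Demographics: age ~ N(65, 10), sex
#' ~ Bernoulli(0.5), ISS uniform on \{1, 2, 3\}.
#'
#' @param n_patients Number of patients (>= 20).
#' @param genes Character vector of gene symbols to simulate.
#' @param truth A [cohort_truth()]; every name in `truth$log_hr` must appear
#'   in `genes`.
#' @param seed Integer seed.
#' @param name Cohort label.
#' @return A [cohort_survival()].
#' @export
simulate_cohort <- function(n_patients, genes, truth = cohort_truth(), seed,
                            name = "simulated") {
  if (missing(seed)) stop("'seed' is mandatory")
  if (n_patients < 20) stop("n_patients must be >= 20")
  stopifnot(inherits(truth, "cohort_truth"))
  unknown <- setdiff(names(truth$log_hr), genes)
  if (length(unknown))
    stop("log_hr given for gene(s) not in 'genes': ",
         paste(unknown, collapse = ", "))
  set.seed(seed)
  patients <- sprintf("P%04d", seq_len(n_patients))
  expr <- matrix(stats::rnorm(length(genes) * n_patients), length(genes),
                 n_patients, dimnames = list(genes, patients))
  age <- stats::rnorm(n_patients, 65, 10)
  sex <- stats::rbinom(n_patients, 1, 0.5)
  iss <- sample(1:3, n_patients, replace = TRUE)

  lp <- truth$age_coef * (age - 65) + truth$sex_coef * sex +
    truth$iss_coef * (iss - 1)
  for (g in names(truth$log_hr)) {
    low <- expr[g, ] <= stats::quantile(expr[g, ], 0.25)
    lp <- lp + truth$log_hr[[g]] * as.numeric(low)
  }
  rate_os <- truth$baseline_rate * exp(lp)
  t_death <- stats::rexp(n_patients, rate_os)
  t_prog <- stats::rexp(n_patients, rate_os * (truth$pfs_rate_ratio - 1) +
                          .Machine$double.eps)
  t_pfs_lat <- pmin(t_death, if (truth$pfs_rate_ratio > 1) t_prog else Inf)

  if (truth$censoring > 0) {
    # E[censored] for exponential censoring at rate r: mean_i r / (rate_i + r)
    target <- truth$censoring
    f <- function(r) mean(r / (rate_os + r)) - target
    r_cens <- stats::uniroot(f, c(1e-10, 1e6))$root
    t_cens <- stats::rexp(n_patients, r_cens)
  } else {
    t_cens <- rep(Inf, n_patients)
  }
  os_time <- pmin(t_death, t_cens)
  os_event <- as.numeric(t_death <= t_cens)
  pfs_time <- pmin(t_pfs_lat, t_cens)
  pfs_event <- as.numeric(t_pfs_lat <= t_cens)

  clin <- data.frame(patient_id = patients, os_time = os_time,
                     os_event = os_event, pfs_time = pfs_time,
                     pfs_event = pfs_event, age = age, sex = sex, iss = iss,
                     stringsAsFactors = FALSE)
  cohort_survival(expr, clin, name = name)
}

#' Simulate an annotation collection with one planted term
#'
#' Builds `n_terms` random gene sets drawn from `genes` plus one planted term
#' whose membership is exactly `planted_term_members`, for testing that the
#' over-representation stage recovers a known enriched term.
#'
#' @param genes Universe of gene symbols to draw random terms from.
#' @param n_terms Number of random terms (may be 0).
#' @param planted_term_members Non-empty character vector; the planted term's
#'   exact membership.
#' @param seed Integer seed.
#' @param size_range Length-2 integer range of random term sizes.
#' @return A [gene_set_collection()]; the planted term has id `"PLANTED"`.
#' @export
simulate_annotations <- function(genes, n_terms, planted_term_members, seed,
                                 size_range = c(10, 50)) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (!length(planted_term_members)) stop("planted term members must be non-empty")
  set.seed(seed)
  sets <- list(PLANTED = unique(as.character(planted_term_members)))
  if (n_terms > 0) {
    sizes <- sample(size_range[1]:min(size_range[2], length(genes)), n_terms,
                    replace = TRUE)
    rand <- lapply(sizes, function(k) sample(genes, k))
    names(rand) <- sprintf("RAND%03d", seq_len(n_terms))
    sets <- c(sets, rand)
  }
  gene_set_collection(sets)
}
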