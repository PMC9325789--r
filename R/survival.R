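#' Assign patients to expression quartile groups
#'
#' Splits patients on a gene's tumour expression into a low group (bottom
#' 25%), a high group (top 25%) and an excluded middle. Cutoffs are the
#' empirical 25th and 75th percentiles under the linear-interpolation
#' definition; boundary ties go to the extreme groups (<= 25th percentile is
#' low, >= 75th is high), which keeps the extreme groups at or above their
#' nominal size when expression values are heavily tied.
#'
#' @param expr Named numeric vector of per-patient expression (n >= 8).
#' @return List: `group` (named factor with levels low/excluded/high) and
#'   `cutoffs` (the two percentiles).
#' @export
expression_groups <- function(expr) {
  if (length(expr) < 8) stop("need >= 8 patients to form quartile groups")
  if (any(!is.finite(expr))) stop("non-finite expression values")
  if (max(expr) == min(expr)) stop("constant expression; groups undefined")
  q <- stats::quantile(expr, c(0.25, 0.75), type = 7, names = FALSE)
  grp <- ifelse(expr <= q[1], "low", ifelse(expr >= q[2], "high", "excluded"))
  n <- length(expr)
  if (sum(grp == "low") >= 0.3 * n || sum(grp == "high") >= 0.3 * n)
    warning(sprintf("heavy ties: group sizes low=%d high=%d of n=%d",
                    sum(grp == "low"), sum(grp == "high"), n))
  group <- factor(grp, levels = c("high", "low", "excluded"))
  names(group) <- names(expr)
  list(group = group, cutoffs = c(p25 = q[1], p75 = q[2]))
}

#' Kaplan-Meier curves and log-rank test for two groups
#'
#' Product-limit survival estimates per group and the two-sided log-rank
#' chi-square test (1 df) for a difference between them.
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @param groups Two-level factor (or coercible) of group membership.
#' @return List: `fit` (a [survival::survfit] object with both curves),
#'   `chisq`, `p`.
#' @export
km_logrank <- function(times, events, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("need exactly two non-empty groups")
  surv <- survival::Surv(times, events)
  fit <- survival::survfit(surv ~ groups)
  if (sum(events) == 0) return(list(fit = fit, chisq = 0, p = 1))
  sd <- survival::survdiff(surv ~ groups)
  list(fit = fit, chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Adjusted Cox proportional-hazards fit for a low-vs-high contrast
#'
#' Partial-likelihood fit (Efron tie handling) of a binary low-expression
#' indicator (high expression is the reference, so HR > 1 means low
#' expression is adverse) with optional adjustment for age (continuous), sex
#' (binary) and ISS stage (two indicator contrasts against stage 1).
#' Patients with missing ISS are dropped (complete-case) and counted. A
#' monotone partial likelihood (e.g. a group with no events) is returned as
#' a flagged result with an unstable CI rather than an error.
#'
#' @param times,events Follow-up times and 0/1 event indicators.
#' @param low Logical: low-expression group membership.
#' @param age,sex,iss Optional covariates; `iss` in \{1, 2, 3, NA\}.
#' @return One-row data frame: `log_hr`, `se`, `hr`, `ci_low`, `ci_high`,
#'   `p_wald`, `n_low`, `n_high`, `n_events`, `n_dropped_iss`, `flagged`.
#' @export
cox_fit <- function(times, events, low, age = NULL, sex = NULL, iss = NULL) {
  low <- as.logical(low)
  if (all(low) || !any(low)) stop("all patients in one expression group")
  df <- data.frame(times = times, events = events, low = as.numeric(low))
  form <- survival::Surv(times, events) ~ low
  if (!is.null(age)) { df$age <- age; form <- stats::update(form, . ~ . + age) }
  if (!is.null(sex)) { df$sex <- sex; form <- stats::update(form, . ~ . + sex) }
  n_dropped <- 0L
  if (!is.null(iss)) {
    df$iss <- factor(iss, levels = c(1, 2, 3))
    n_dropped <- sum(is.na(df$iss))
    df <- df[!is.na(df$iss), , drop = FALSE]
    form <- stats::update(form, . ~ . + iss)
  }
  if (sum(df$events) < 10) stop("fewer than 10 events after exclusions")
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(form, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- stats::coef(fit)
  if (anyNA(co)) stop("singular covariate matrix in Cox fit")
  b <- co[["low"]]
  se <- sqrt(diag(stats::vcov(fit)))[["low"]]
  data.frame(log_hr = b, se = se, hr = exp(b),
             ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
             p_wald = 2 * stats::pnorm(-abs(b / se)),
             n_low = sum(df$low == 1), n_high = sum(df$low == 0),
             n_events = sum(df$events), n_dropped_iss = n_dropped,
             flagged = flagged, row.names = NULL)
}

#' DerSimonian-Laird random-effects meta-analysis of log hazard ratios
#'
#' Pools per-cohort log hazard ratios under a random-effects model with the
#' method-of-moments between-study variance: fixed weights `w = 1/se^2`,
#' Cochran's `Q = sum w (y - y_FE)^2`, `tau2 = max(0, (Q - (k-1)) /
#' (sum w - sum w^2 / sum w))`, random weights `1/(se^2 + tau2)`. A single
#' cohort passes through with `tau2 = 0` and `Q` undefined.
#'
#' @param log_hrs Per-cohort log hazard ratios.
#' @param ses Per-cohort standard errors (all > 0).
#' @return One-row data frame: `pooled_log_hr`, `pooled_se`, `pooled_hr`,
#'   `ci_low`, `ci_high`, `tau2`, `Q`, `q_df`, `p_Q`, `p_meta`, `k`.
#' @export
meta_random_effects <- function(log_hrs, ses) {
  if (length(log_hrs) != length(ses)) stop("log_hrs and ses lengths differ")
  if (any(!is.finite(ses)) || any(ses <= 0)) stop("all ses must be positive")
  k <- length(log_hrs)
  if (k == 0) stop("no cohorts to pool")
  if (k == 1) {
    b <- log_hrs[1]; se <- ses[1]
    return(data.frame(pooled_log_hr = b, pooled_se = se, pooled_hr = exp(b),
                      ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
                      tau2 = 0, Q = NA_real_, q_df = 0, p_Q = NA_real_,
                      p_meta = 2 * stats::pnorm(-abs(b / se)), k = 1L,
                      row.names = NULL))
  }
  fit <- metafor::rma(yi = log_hrs, sei = ses, method = "DL", test = "z")
  b <- as.numeric(fit$b); se <- fit$se
  data.frame(pooled_log_hr = b, pooled_se = se, pooled_hr = exp(b),
             ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
             tau2 = fit$tau2, Q = fit$QE, q_df = k - 1L, p_Q = fit$QEp,
             p_meta = fit$pval, k = as.integer(k), row.names = NULL)
}

#' Benjamini-Hochberg step-up false-discovery control
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @param fdr Target false-discovery rate (default 0.05).
#' @return List: `q` (BH-adjusted values, order-preserving) and `reject`
#'   (logical, `q <= fdr`). Empty input gives empty output.
#' @export
bh_adjust <- function(pvals, fdr = 0.05) {
  if (!length(pvals)) return(list(q = numeric(), reject = logical()))
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, reject = !is.na(q) & q <= fdr)
}

#' Schoenfeld power approximation for a two-group survival comparison
#'
#' Power of a two-sided level-`alpha` log-rank/Cox test to detect hazard
#' ratio `hr` with `n_events` events split between the groups in proportion
#' `allocation_p`: `Phi(|ln hr| * sqrt(d * p * (1 - p)) - z_{1 - alpha/2})`.
#'
#' @param n_events Expected total number of events (>= 1).
#' @param allocation_p Fraction of patients in one group, in (0, 1).
#' @param hr Hazard ratio to detect (> 0).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
power_two_group <- function(n_events, allocation_p, hr, alpha = 0.05) {
  if (hr <= 0) stop("hr must be positive")
  if (n_events < 1) stop("n_events must be >= 1")
  if (allocation_p <= 0 || allocation_p >= 1) stop("allocation_p must be in (0, 1)")
  stats::pnorm(abs(log(hr)) * sqrt(n_events * allocation_p * (1 - allocation_p)) -
                 stats::qnorm(1 - alpha / 2))
}

#' Expression-survival screen across genes and cohorts
#'
#' For each gene and endpoint: per cohort, assign expression quartile groups,
#' run the log-rank test, and fit the adjusted Cox model for the low-vs-high
#' contrast; then pool cohorts by DerSimonian-Laird random-effects
#' meta-analysis. Benjamini-Hochberg control is applied across genes
#' separately within each endpoint. Genes absent from some cohorts are
#' pooled over the cohorts that carry them; a gene absent from every cohort
#' is an error.
#'
#' @param genes Character vector of genes to screen.
#' @param cohorts List of [cohort_survival()] objects.
#' @param endpoints Subset of `c("os", "pfs")`.
#' @param fdr Benjamini-Hochberg target rate (default 0.05).
#' @param adjust Adjust for age, sex and ISS (default `TRUE`); unadjusted
#'   fits use the group indicator alone.
#' @return List of data frames: `per_cohort` (one row per gene x cohort x
#'   endpoint, Cox + log-rank columns) and `meta` (one row per gene x
#'   endpoint with pooled results, `q_bh`, `reject`).
#' @export
run_survival_screen <- function(genes, cohorts, endpoints = c("os", "pfs"),
                                fdr = 0.05, adjust = TRUE) {
  endpoints <- match.arg(endpoints, c("os", "pfs"), several.ok = TRUE)
  stopifnot(length(cohorts) >= 1,
            all(vapply(cohorts, inherits, TRUE, "cohort_survival")))
  absent <- vapply(genes, function(g)
    !any(vapply(cohorts, function(co) g %in% rownames(co$expression), TRUE)), TRUE)
  if (any(absent))
    stop("gene(s) absent from all cohorts: ",
         paste(genes[absent], collapse = ", "))

  per_rows <- list(); meta_rows <- list()
  for (ep in endpoints) {
    for (g in genes) {
      fits <- list()
      for (co in cohorts) {
        if (!g %in% rownames(co$expression)) next
        grp <- expression_groups(co$expression[g, ])$group
        keep <- grp != "excluded"
        cl <- co$clinical[keep, , drop = FALSE]
        low <- grp[keep] == "low"
        tm <- cl[[paste0(ep, "_time")]]; ev <- cl[[paste0(ep, "_event")]]
        lr <- km_logrank(tm, ev, ifelse(low, "low", "high"))
        cx <- if (adjust)
          cox_fit(tm, ev, low, age = cl$age, sex = cl$sex, iss = cl$iss)
        else cox_fit(tm, ev, low)
        cx <- cbind(gene = g, cohort = co$name, endpoint = ep,
                    logrank_p = lr$p, cx, stringsAsFactors = FALSE)
        fits[[length(fits) + 1L]] <- cx
      }
      ct <- do.call(rbind, fits)
      per_rows[[length(per_rows) + 1L]] <- ct
      ok <- !ct$flagged & is.finite(ct$se)
      mt <- meta_random_effects(ct$log_hr[ok], ct$se[ok])
      meta_rows[[length(meta_rows) + 1L]] <-
        cbind(gene = g, endpoint = ep, mt, stringsAsFactors = FALSE)
    }
  }
  per_cohort <- do.call(rbind, per_rows)
  meta <- do.call(rbind, meta_rows)
  meta$q_bh <- NA_real_; meta$reject <- NA
  for (ep in endpoints) {
    i <- meta$endpoint == ep
    adj <- bh_adjust(meta$p_meta[i], fdr = fdr)
    meta$q_bh[i] <- adj$q
    meta$reject[i] <- adj$reject
  }
  rownames(per_cohort) <- rownames(meta) <- NULL
  list(per_cohort = per_cohort, meta = meta)
}
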