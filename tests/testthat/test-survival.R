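# Independent oracle: log-rank statistic from explicit risk-set enumeration,
# sum over event times of (O - E) with hypergeometric variance.
logrank_enum_oracle <- function(times, events, is_a) {
  ts <- sort(unique(times[events == 1]))
  O_E <- 0; V <- 0
  for (t in ts) {
    at_risk <- times >= t
    d <- sum(events == 1 & times == t)
    d_a <- sum(events == 1 & times == t & is_a)
    n <- sum(at_risk); n_a <- sum(at_risk & is_a)
    O_E <- O_E + d_a - d * n_a / n
    if (n > 1)
      V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  (O_E)^2 / V
}

# Independent oracle: DerSimonian-Laird from its closed-form formulas.
dl_oracle <- function(y, se) {
  w <- 1 / se^2
  y_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - y_fe)^2)
  tau2 <- max(0, (Q - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(pooled = sum(ws * y) / sum(ws), se = sum(ws)^-0.5, Q = Q, tau2 = tau2)
}

test_that("quartile groups split 1..8 into exact extremes", {
  x <- setNames(1:8, paste0("P", 1:8))
  g <- expression_groups(x)
  expect_setequal(names(g$group)[g$group == "low"], c("P1", "P2"))
  expect_setequal(names(g$group)[g$group == "high"], c("P7", "P8"))
  expect_identical(sum(g$group == "excluded"), 4L)
})

test_that("boundary ties go to the extreme groups with a warning on heavy ties", {
  x <- setNames(c(rep(0, 3), 2:8), paste0("P", 1:10))   # 30% tied at the minimum
  expect_warning(g <- expression_groups(x), "ties")
  expect_identical(sum(g$group == "low"), 3L)

  expect_error(expression_groups(setNames(1:7, paste0("P", 1:7))), ">= 8")
  expect_error(expression_groups(setNames(rep(1, 10), paste0("P", 1:10))),
               "constant")
})

test_that("log-rank agrees with risk-set enumeration and degenerates to p = 1", {
  times <- c(1, 2, 3, 4); events <- c(1, 1, 1, 1)
  grp <- c("A", "A", "B", "B")
  got <- km_logrank(times, events, grp)
  expect_equal(got$chisq, logrank_enum_oracle(times, events, grp == "A"),
               tolerance = 1e-10)

  set.seed(31)
  t2 <- rexp(40); e2 <- rbinom(40, 1, 0.7); g2 <- rep(c("A", "B"), 20)
  got2 <- km_logrank(t2, e2, g2)
  expect_equal(got2$chisq, logrank_enum_oracle(t2, e2, g2 == "A"),
               tolerance = 1e-10)

  # identical groups: statistic 0, p 1
  same <- km_logrank(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  # KM estimate reaches zero after the last event when nobody is censored
  sf <- km_logrank(times, events, grp)$fit
  expect_equal(min(sf$surv), 0)
})

test_that("Cox fit recovers a null and a planted hazard ratio", {
  tr <- cohort_truth(log_hr = c(GNULL = 0, GHIT = log(2)), censoring = 0.25)
  co <- simulate_cohort(1500, c("GNULL", "GHIT"), tr, seed = 32)
  for (g in c("GNULL", "GHIT")) {
    grp <- expression_groups(co$expression[g, ])$group
    keep <- grp != "excluded"
    cl <- co$clinical[keep, ]
    fit <- cox_fit(cl$os_time, cl$os_event, grp[keep] == "low",
                   age = cl$age, sex = cl$sex, iss = cl$iss)
    if (g == "GNULL") {
      expect_lt(fit$ci_low, 1); expect_gt(fit$ci_high, 1)
    } else {
      expect_gt(fit$hr, 1.4)
    }
    expect_true(fit$ci_low < fit$hr && fit$hr < fit$ci_high)
    expect_equal(fit$ci_low, exp(fit$log_hr - 1.96 * fit$se))
  }
})

test_that("Cox fit handles missing ISS, separation and degenerate groups", {
  tr <- cohort_truth(censoring = 0.2)
  co <- simulate_cohort(300, "G", tr, seed = 33)
  cl <- co$clinical
  low <- co$expression["G", ] <= quantile(co$expression["G", ], 0.25)

  iss_na <- cl$iss; iss_na[1:20] <- NA
  fit <- cox_fit(cl$os_time, cl$os_event, low, age = cl$age, sex = cl$sex,
                 iss = iss_na)
  expect_identical(fit$n_dropped_iss, 20L)
  expect_identical(fit$n_low + fit$n_high, 280L)

  expect_error(cox_fit(cl$os_time, cl$os_event, rep(TRUE, 300)), "one expression group")

  # perfect separation: the low group never has an event -> flagged, no crash
  ev <- cl$os_event; ev[low] <- 0
  if (sum(ev) >= 10) {
    fit2 <- cox_fit(cl$os_time, ev, low)
    expect_true(fit2$flagged)
  }
})

test_that("DL meta-analysis matches the closed-form hand computation", {
  got <- meta_random_effects(c(0, 1), c(1, 1))
  expect_equal(got$Q, 0.5, tolerance = 1e-12)
  expect_equal(got$tau2, 0, tolerance = 1e-12)
  expect_equal(got$pooled_log_hr, 0.5, tolerance = 1e-12)
  expect_equal(got$pooled_se, 1 / sqrt(2), tolerance = 1e-12)

  ident <- meta_random_effects(c(0.3, 0.3), c(0.2, 0.2))
  expect_equal(ident$pooled_log_hr, 0.3, tolerance = 1e-12)
  expect_equal(ident$Q, 0, tolerance = 1e-12)
  expect_equal(ident$tau2, 0)

  one <- meta_random_effects(0.4, 0.1)
  expect_equal(one$pooled_log_hr, 0.4)
  expect_equal(one$pooled_se, 0.1)
  expect_equal(one$tau2, 0)
  expect_true(is.na(one$Q))

  expect_error(meta_random_effects(c(0, 1), c(1, 0)), "positive")
})

test_that("DL agrees with the closed-form oracle on random inputs and reduces to fixed effects", {
  set.seed(34)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    y <- rnorm(k); se <- runif(k, 0.1, 0.6)
    got <- meta_random_effects(y, se)
    ora <- dl_oracle(y, se)
    expect_equal(got$pooled_log_hr, ora$pooled, tolerance = 1e-10)
    expect_equal(got$pooled_se, ora$se, tolerance = 1e-10)
    expect_equal(got$Q, ora$Q, tolerance = 1e-10)
    expect_equal(got$tau2, ora$tau2, tolerance = 1e-10)
    if (ora$tau2 == 0) {
      w <- 1 / se^2   # fixed-effect inverse-variance pooling
      expect_equal(got$pooled_log_hr, sum(w * y) / sum(w), tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment matches a step-up enumeration and is order-invariant", {
  got <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), fdr = 0.05)
  expect_true(all(got$reject))                    # 0.04 <= 4/4 * 0.05

  single <- bh_adjust(0.03)
  expect_equal(single$q, 0.03)

  # brute-force step-up: q_i = min_{j >= rank(i)} m p_(j) / j
  set.seed(35)
  p <- runif(20)^2
  q_oracle <- sapply(seq_along(p), function(i) {
    r <- rank(p, ties.method = "first")[i]
    o <- sort(p)
    min(pmin(length(p) * o[r:length(p)] / (r:length(p)), 1))
  })
  expect_equal(bh_adjust(p)$q, q_oracle, tolerance = 1e-12)

  for (rep in 1:20) {
    perm <- sample(length(p))
    expect_identical(sort(bh_adjust(p[perm])$q), sort(bh_adjust(p)$q))
  }

  # BH rejections contain all Bonferroni rejections
  bonf <- p <= 0.05 / length(p)
  expect_true(all(bh_adjust(p)$reject[bonf]))

  empty <- bh_adjust(numeric())
  expect_length(empty$q, 0)
  expect_error(bh_adjust(c(0.5, 0)), "p-values")
})

test_that("Schoenfeld power approximation matches direct normal evaluation", {
  expect_equal(power_two_group(100, 0.5, 1, 0.05), pnorm(-qnorm(0.975)),
               tolerance = 1e-12)                 # alpha/2 at the null
  expect_equal(power_two_group(100, 0.5, 2, 0.05),
               pnorm(log(2) * 5 - qnorm(0.975)), tolerance = 1e-12)
  pw <- vapply(c(50, 100, 200, 400), power_two_group, 0,
               allocation_p = 0.5, hr = 1.3)
  expect_true(all(diff(pw) > 0))
  expect_error(power_two_group(100, 0.5, -1), "hr")
})

test_that("survival screen pools cohorts and applies BH per endpoint", {
  genes <- c("GHIT", "GN1", "GN2")
  tr <- cohort_truth(log_hr = c(GHIT = 0.6), censoring = 0.3)
  cohorts <- list(simulate_cohort(500, genes, tr, seed = 36, name = "c1"),
                  simulate_cohort(300, genes, tr, seed = 37, name = "c2"))
  res <- run_survival_screen(genes, cohorts, endpoints = "os")
  expect_identical(nrow(res$meta), 3L)
  expect_identical(nrow(res$per_cohort), 6L)
  hit <- res$meta[res$meta$gene == "GHIT", ]
  expect_identical(hit$k, 2L)
  expect_gt(hit$pooled_hr, 1)
  expect_true(hit$reject)
  expect_true(all(res$meta$q_bh >= res$meta$p_meta))

  # single cohort: meta columns equal the single fit
  res1 <- run_survival_screen("GHIT", cohorts[1], endpoints = "os")
  pc <- res1$per_cohort
  expect_equal(res1$meta$pooled_log_hr, pc$log_hr)
  expect_equal(res1$meta$pooled_se, pc$se)

  # a gene absent everywhere is an error; absent from one cohort is pooled
  expect_error(run_survival_screen("NOPE", cohorts, endpoints = "os"),
               "absent from all")
  small <- cohorts
  small[[2]]$expression <- small[[2]]$expression[c("GN1", "GN2"), ]
  res2 <- run_survival_screen(genes, small, endpoints = "os")
  expect_identical(res2$meta$k[res2$meta$gene == "GHIT"], 1L)
})
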