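test_that("conditional logit log-likelihood matches closed forms", {
  attrs <- tiny_attrs()
  ch <- tiny_choices(seed = 2)
  enc <- encode_design_matrix(ch, attrs)
  n_sets <- nrow(enc) / 2

  # beta = 0: uniform choice over 2 alternatives
  expect_equal(clogit_loglik(c(0, 0, 0), enc), -n_sets * log(2))

  # one set, V_A - V_B = ln 3, A chosen: LL = ln(3/4)
  one <- encode_design_matrix(one_set_choices(), attrs)
  beta <- c(0, 0, log(3) / 10)       # fee differs by 10 euro between A and B
  expect_equal(clogit_loglik(beta, one), log(3 / 4))

  # location invariance: shifting a covariate by a set-level constant
  # leaves the likelihood unchanged
  enc2 <- enc
  shift <- rep(stats::rnorm(n_sets), each = 2)
  enc2$fee <- enc2$fee + shift
  b <- c(0.3, -0.2, 0.05)
  expect_equal(clogit_loglik(b, enc2), clogit_loglik(b, enc))

  expect_error(clogit_loglik(c(0, 0), enc), "covariates")
})

test_that("the MLE equals a staged grid-search oracle on a tiny instance", {
  attrs <- dce_attributes(
    dce_attribute("svc", c("basic", "plus")),
    dce_attribute("fee", c("0", "1"), coding = "continuous",
                  level_values = c(0, 1))
  )
  # 6 two-alternative sets, 2 covariates, hand-laid profiles and choices
  ch <- data.frame(
    respondent_id = rep(sprintf("r%d", 1:6), each = 2),
    group = "intervention", block = 1L,
    set_id = rep(1:6, each = 2), alternative = rep(c("A", "B"), 6),
    svc = c(2L, 1L, 2L, 1L, 1L, 2L, 2L, 1L, 1L, 2L, 1L, 2L),
    fee = c(1L, 2L, 2L, 1L, 1L, 2L, 1L, 1L, 2L, 1L, 2L, 2L),
    chosen = c(1L, 0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L)
  )
  enc <- encode_design_matrix(ch, attrs)
  fit <- fit_clogit(enc)

  # independent oracle: within-set covariate differences give the paired
  # logit likelihood sum log(plogis(D beta)); maximize by refined grid
  X <- as.matrix(enc[, attr(enc, "covariates")])
  iA <- seq(1, nrow(X), 2)
  D <- (X[iA, ] - X[iA + 1, ]) * ifelse(enc$chosen[iA] == 1, 1, -1)
  ll_grid <- function(G) colSums(log(stats::plogis(D %*% t(G))))
  centre <- c(0, 0)
  for (stage in list(c(5, 0.1), c(0.15, 0.002), c(0.004, 0.00005))) {
    g1 <- seq(centre[1] - stage[1], centre[1] + stage[1], by = stage[2])
    g2 <- seq(centre[2] - stage[1], centre[2] + stage[1], by = stage[2])
    G <- as.matrix(expand.grid(g1, g2))
    centre <- unname(G[which.max(ll_grid(G)), ])
  }
  expect_lt(max(abs(unname(fit$coefficients) - centre)), 1e-4)
  expect_true(fit$converged)
})

test_that("the fit agrees with the stratified proportional-hazards oracle", {
  skip_if_not_installed("survival")
  attrs <- tiny_attrs()
  ch <- tiny_choices(n = c(intervention = 60L, control = 0L), seed = 17)
  enc <- encode_design_matrix(ch, attrs)
  fit <- fit_clogit(enc)

  df <- as.data.frame(enc)
  df$stratum <- paste(df$respondent_id, df$set_id)
  # one "event" (the chosen alternative) per stratum makes the Cox partial
  # likelihood the conditional logit likelihood
  oracle <- survival::coxph(
    survival::Surv(rep(1, nrow(df)), chosen) ~ svc.plus + svc.premium +
      fee + survival::strata(stratum),
    data = df, ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(oracle)),
               tolerance = 1e-4)
  expect_equal(unname(diag(fit$vcov)), unname(diag(vcov(oracle))),
               tolerance = 1e-4)
  expect_equal(fit$ll_full, unname(oracle$loglik[2]), tolerance = 1e-6)
})

test_that("parameter recovery improves with sample size", {
  attrs <- tiny_attrs()
  truth <- c(svc.plus = 0.5, svc.premium = 1.0, fee = -0.06)
  for (n in c(100L, 500L)) {
    ch <- tiny_choices(beta = truth, n = c(intervention = n, control = 0L),
                       seed = 100 + n)
    fit <- fit_clogit(encode_design_matrix(ch, attrs))
    expect_lt(max(abs(fit$coefficients - truth) / fit$se), 3)
  }
})

test_that("degenerate inputs raise diagnostics instead of silent estimates", {
  attrs <- tiny_attrs()
  # svc identical within every set: its dummies cannot be identified
  ch <- one_set_choices()
  ch2 <- ch; ch2$respondent_id <- "r2"; ch2$chosen <- c(0L, 1L)
  both <- rbind(ch, ch2)
  expect_error(fit_clogit(encode_design_matrix(both, attrs)),
               "never differ within choice sets")

  # separation: the cheaper alternative is always chosen
  des <- tiny_design()
  sep <- simulate_choices(attrs, c(svc.plus = 0, svc.premium = 0, fee = 0),
                          design = des,
                          n_respondents = c(intervention = 30L, control = 0L),
                          seed = 3)
  fee_val <- c(0, 10, 20)[sep$fee]
  for (k in unique(paste(sep$respondent_id, sep$set_id))) {
    idx <- which(paste(sep$respondent_id, sep$set_id) == k)
    f <- fee_val[idx]
    sep$chosen[idx] <- as.integer(seq_along(idx) ==
                                    which(f == min(f))[1])
  }
  enc <- encode_design_matrix(sep, attrs)
  expect_error(fit_clogit(enc), "separation|converge")
})

test_that("the log-likelihood is concave along random segments", {
  attrs <- tiny_attrs()
  enc <- encode_design_matrix(tiny_choices(seed = 23), attrs)
  set.seed(40)
  for (i in 1:10) {
    b1 <- stats::rnorm(3); b2 <- stats::rnorm(3)
    mid <- clogit_loglik((b1 + b2) / 2, enc)
    expect_gte(mid, (clogit_loglik(b1, enc) + clogit_loglik(b2, enc)) / 2 - 1e-10)
  }
})

test_that("the likelihood-ratio test has the documented null behaviour", {
  attrs <- tiny_attrs()
  fit <- fit_clogit(encode_design_matrix(tiny_choices(seed = 51), attrs))
  lr <- lr_test(fit)
  expect_equal(lr$statistic, 2 * (fit$ll_full - fit$ll_null))
  expect_equal(lr$df, 3L)
  expect_gte(lr$statistic, 0)

  # LL_full == LL_0 gives chi-square 0, p = 1
  null_fit <- fit
  null_fit$ll_full <- null_fit$ll_null
  lr0 <- lr_test(null_fit)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)

  # the five-attribute pharmacy space yields 9 coefficients / df
  expect_length(choiceval:::covariate_names(pharmacy_dce_attributes()), 9L)
})

test_that("cluster bootstrap is reproducible and fails on degenerate cohorts", {
  attrs <- tiny_attrs()
  enc <- encode_design_matrix(tiny_choices(n = c(intervention = 50L,
                                                 control = 0L),
                                           seed = 61), attrs)
  b1 <- bootstrap_coefficients(enc, reps = 20, seed = 77)
  b2 <- bootstrap_coefficients(enc, reps = 20, seed = 77)
  expect_identical(b1$ci, b2$ci)
  expect_true(all(b1$ci[, "lower"] <= b1$ci[, "upper"]))
  expect_error(bootstrap_coefficients(enc, reps = 1, seed = 1), ">= 2")

  one <- enc[enc$respondent_id == enc$respondent_id[1], ]
  attr(one, "covariates") <- attr(enc, "covariates")
  expect_error(bootstrap_coefficients(one, reps = 10, seed = 1),
               "bootstrap unstable|never differ")

  # CI covers the truth on a well-sized cohort
  truth <- c(svc.plus = 0.4, svc.premium = 0.9, fee = -0.05)
  expect_true(all(b1$ci[, "lower"] <= truth & truth <= b1$ci[, "upper"]))
})

test_that("group filtering fits separate models per cohort", {
  attrs <- tiny_attrs()
  fx_beta <- list(
    intervention = c(svc.plus = 0.6, svc.premium = 1.1, fee = -0.04),
    control = c(svc.plus = 0.2, svc.premium = 0.5, fee = -0.08)
  )
  ch <- simulate_choices(attrs, fx_beta, design = tiny_design(),
                         n_respondents = c(intervention = 60L, control = 40L),
                         seed = 71)
  f_all <- fit_choice_model(ch, attrs, group = "all")
  f_int <- fit_choice_model(ch, attrs, group = "intervention")
  f_ctl <- fit_choice_model(ch, attrs, group = "control")
  expect_equal(f_all$n_individuals, 100L)
  expect_equal(f_int$n_individuals, 60L)
  expect_equal(f_ctl$n_individuals, 40L)
  expect_equal(f_all$n_obs, f_int$n_obs + f_ctl$n_obs)
})
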