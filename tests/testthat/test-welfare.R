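fixture_result <- function(group = "intervention", vcov = NULL) {
  fx <- pharmacy_dce_fixture()
  clogit_result(fx$beta[[group]], vcov = vcov,
                p_values = fx$p_values[[group]], attrs = fx$attributes)
}

test_that("marginal WTA is the coefficient ratio on the cost scale", {
  res <- fixture_result("intervention")
  w1 <- marginal_wta(res, "pharmacy_model.office_30min_q6mo")
  expect_equal(w1$wta, 0.948 / 0.003)
  expect_equal(round(w1$wta, 2), 316.00)
  w2 <- marginal_wta(res, "waiting_time.same_day_routine_15d")
  expect_equal(round(w2$wta, 2), 349.67)
  # insignificant cost coefficient carries a caveat, not an error
  expect_match(w1$caveats, "not significant")

  # zero numerator gives zero WTA
  attrs0 <- dce_attributes(
    dce_attribute("x", c("l1", "l2")),
    dce_attribute("nhs_cost", c("0", "30"), coding = "continuous",
                  level_values = c(0, 30)))
  res0 <- clogit_result(c(x.l2 = 0, nhs_cost = 0.003), attrs = attrs0)
  expect_equal(marginal_wta(res0, "x.l2")$wta, 0)

  # exactly-zero cost coefficient is an explicit error, not infinity
  resz <- fixture_result("intervention")
  resz$coefficients["nhs_cost"] <- 0
  expect_error(marginal_wta(resz, "integration.full"), "undefined")

  # sign convention flag
  expect_equal(marginal_wta(res, "integration.full", negate = TRUE)$wta,
               -0.634 / 0.003)
})

test_that("every published WTA cell is the printed coefficient ratio", {
  cells <- list(
    all = c(pharmacy_model.office_15min_q3mo = 275.50,
            pharmacy_model.office_30min_q6mo = 444.00,
            integration.partial = 188.00,
            integration.full = 311.00,
            waiting_time.urgent_48h_routine_30d = 190.50,
            waiting_time.same_day_routine_15d = 575.00),
    intervention = c(pharmacy_model.office_15min_q3mo = 201.67,
                     pharmacy_model.office_30min_q6mo = 316.00,
                     integration.partial = 139.00,
                     integration.full = 211.33,
                     waiting_time.urgent_48h_routine_30d = 89.00,
                     waiting_time.same_day_routine_15d = 349.67),
    control = c(pharmacy_model.office_15min_q3mo = 481.00,
                pharmacy_model.office_30min_q6mo = 792.00,
                integration.partial = 308.00,
                integration.full = 617.00,
                waiting_time.urgent_48h_routine_30d = 585.00,
                waiting_time.same_day_routine_15d = 1349.00)
  )
  for (g in names(cells)) {
    res <- fixture_result(g)
    for (lev in names(cells[[g]])) {
      expect_lt(abs(marginal_wta(res, lev)$wta - cells[[g]][[lev]]), 0.01)
    }
  }
})

test_that("Krinsky-Robb intervals behave like the parametric bootstrap", {
  fx <- pharmacy_dce_fixture()
  p <- length(fx$beta$intervention)

  # degenerate normal: zero covariance collapses the CI to the point
  res0 <- fixture_result("intervention",
                         vcov = matrix(0, p, p,
                                       dimnames = list(names(fx$beta$intervention),
                                                       names(fx$beta$intervention))))
  k0 <- krinsky_robb_ci(res0, "integration.full", reps = 50, seed = 5)
  expect_equal(k0$ci, rep(k0$wta, 2))

  # determinism
  V <- diag(c(rep(0.02, p - 1), 1e-6))
  dimnames(V) <- list(names(fx$beta$intervention), names(fx$beta$intervention))
  res <- fixture_result("intervention", vcov = V)
  k1 <- krinsky_robb_ci(res, "integration.full", reps = 200, seed = 9)
  k2 <- krinsky_robb_ci(res, "integration.full", reps = 200, seed = 9)
  expect_identical(k1$ci, k2$ci)

  # independent simulation oracle for a diagonal-covariance ratio
  attrs2 <- dce_attributes(
    dce_attribute("svc", c("basic", "plus")),
    dce_attribute("fee", c("0", "1"), coding = "continuous",
                  level_values = c(0, 1)))
  beta2 <- c(svc.plus = 1.0, fee = 0.5)
  V2 <- diag(c(0.04, 0.0025))
  dimnames(V2) <- list(names(beta2), names(beta2))
  res2 <- clogit_result(beta2, vcov = V2, attrs = attrs2)
  k <- krinsky_robb_ci(res2, "svc.plus", reps = 100000, seed = 13)
  set.seed(1401)
  oracle <- stats::rnorm(100000, 1.0, 0.2) / stats::rnorm(100000, 0.5, 0.05)
  oq <- stats::quantile(oracle, c(0.025, 0.975))
  expect_lt(abs(k$ci[1] - oq[[1]]), 0.05)
  expect_lt(abs(k$ci[2] - oq[[2]]), 0.05)

  # CI width is non-decreasing in the covariance scale
  widths <- vapply(c(1, 4, 9), function(s) {
    r <- clogit_result(beta2, vcov = s * V2, attrs = attrs2)
    ci <- krinsky_robb_ci(r, "svc.plus", reps = 2000, seed = 21)$ci
    diff(ci)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))

  # a non-PSD covariance errors unless repair is requested
  Vbad <- V2; Vbad[1, 2] <- Vbad[2, 1] <- 0.5
  resbad <- clogit_result(beta2, vcov = Vbad, attrs = attrs2)
  expect_error(krinsky_robb_ci(resbad, "svc.plus", reps = 10, seed = 1),
               "positive semi-definite")
  krep <- krinsky_robb_ci(resbad, "svc.plus", reps = 10, seed = 1,
                          repair_covariance = TRUE)
  expect_length(krep$ci, 2L)
})

test_that("relative importance is the share of the utility range", {
  attrs <- dce_attributes(
    dce_attribute("x", c("a", "b")),
    dce_attribute("y", c("a", "b")),
    dce_attribute("z", c("a", "b")),
    dce_attribute("fee", c("0", "1"), coding = "continuous",
                  level_values = c(0, 1)))
  beta <- c(x.b = 2, y.b = 1, z.b = 1, fee = 0.001)
  res <- clogit_result(beta, attrs = attrs)
  ri <- relative_importance(res, include = c("x", "y", "z"))
  expect_equal(unname(ri), c(0.5, 0.25, 0.25))
  expect_equal(sum(ri), 1)

  # equal ranges split evenly
  ri2 <- relative_importance(clogit_result(c(x.b = 1, y.b = 1, z.b = 0.5,
                                             fee = 0.001), attrs = attrs),
                             include = c("x", "y"))
  expect_equal(unname(ri2), c(0.5, 0.5))

  # scale invariance
  ri3 <- relative_importance(clogit_result(10 * beta, attrs = attrs),
                             include = c("x", "y", "z"))
  expect_equal(ri3, ri)

  # significance screen keeps the attributes the p-values support, and the
  # published ordering emerges: waiting time > pharmacy model > integration
  res_all <- fixture_result("all")
  ri4 <- relative_importance(res_all)
  expect_setequal(names(ri4), c("pharmacy_model", "integration", "waiting_time"))
  expect_true(ri4["waiting_time"] > ri4["pharmacy_model"])
  expect_true(ri4["pharmacy_model"] > ri4["integration"])

  expect_error(relative_importance(res, include = character(0)), "screen")
  expect_error(relative_importance(clogit_result(c(x.b = 0, y.b = 0,
                                                   z.b = 0, fee = 0.001),
                                                 attrs = attrs),
                                   include = c("x", "y")), "zero")
})

test_that("scenario utilities are linear in the encoded covariates", {
  fx <- pharmacy_dce_fixture()
  res <- fixture_result("intervention")

  expect_equal(scenario_utility(res, c(1L, 1L, 1L, 1L, 1L)), 0)
  expect_equal(scenario_utility(res, fx$scenarios$best),
               0.948 + 0.634 + 1.049)
  # adding cost c changes V by beta_cost * c exactly
  v0 <- scenario_utility(res, c(3L, 3L, 3L, 1L, 1L))
  v76 <- scenario_utility(res, c(3L, 3L, 3L, 1L, 4L))
  expect_equal(v76 - v0, 0.003 * 76)
})

test_that("scenario WTA sums the per-attribute marginal values", {
  fx <- pharmacy_dce_fixture()
  res <- fixture_result("intervention")
  tot <- total_scenario_wta(res, fx$scenarios$best, fx$scenarios$worst)
  expect_equal(round(tot$per_attribute[["pharmacy_model"]], 2), 316.00)
  expect_equal(round(tot$per_attribute[["integration"]], 2), 211.33)
  expect_equal(round(tot$per_attribute[["waiting_time"]], 2), 349.67)
  expect_equal(round(tot$total, 2), 877.00)

  expect_equal(total_scenario_wta(res, fx$scenarios$best,
                                  fx$scenarios$best)$total, 0)
  # single-attribute move equals that attribute's marginal WTA
  single <- total_scenario_wta(res, c(1L, 3L, 1L, 1L, 1L),
                               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(single$total, marginal_wta(res, "integration.full")$wta)
  # differing on the cost attribute has no WTA
  expect_error(total_scenario_wta(res, c(1L, 1L, 1L, 1L, 2L),
                                  c(1L, 1L, 1L, 1L, 1L)), "undefined")
})

test_that("compensating variation reduces to summed WTA for single states", {
  fx <- pharmacy_dce_fixture()
  res <- fixture_result("intervention")
  expect_equal(compensating_variation(res, fx$scenarios$worst,
                                      fx$scenarios$worst), 0)
  cv <- compensating_variation(res, scenario0 = fx$scenarios$worst,
                               scenario1 = fx$scenarios$best)
  expect_equal(round(cv, 2), 877.00)

  # two-alternative states with hand-set utilities: log-sum arithmetic
  attrs2 <- dce_attributes(
    dce_attribute("svc", c("basic", "plus")),
    dce_attribute("fee", c("0", "1"), coding = "continuous",
                  level_values = c(0, 1)))
  beta2 <- c(svc.plus = log(3), fee = 1)
  s0 <- list(c(1L, 1L), c(1L, 1L))          # utilities (0, 0)
  s1 <- list(c(1L, 1L), c(2L, 1L))          # utilities (0, ln 3)
  expect_equal(compensating_variation(beta2, s0, s1, attrs = attrs2),
               log(4 / 2))

  # exact identity on random coefficient vectors
  set.seed(55)
  attrs <- fx$attributes
  for (i in 1:10) {
    beta <- stats::setNames(c(stats::rnorm(8), stats::runif(1, 0.001, 0.05)),
                            names(fx$beta$all))
    res_r <- clogit_result(beta, attrs = attrs)
    best <- c(sample(3, 3, replace = TRUE), 1L, 2L)
    worst <- c(sample(3, 3, replace = TRUE), 1L, 2L)
    tot <- total_scenario_wta(res_r, best, worst)$total
    cv_r <- compensating_variation(res_r, scenario0 = worst, scenario1 = best)
    expect_equal(cv_r, tot, tolerance = 1e-10)
  }
})

test_that("net benefit is WTA minus incremental cost, unclamped", {
  expect_equal(net_benefit(877.00, 88.80), 788.20)
  expect_equal(net_benefit(50, 50), 0)
  expect_equal(net_benefit(10, 25), -15)

  fx <- pharmacy_dce_fixture()
  res <- fixture_result("intervention")
  val <- scenario_valuation(res, fx$scenarios$best, fx$scenarios$worst,
                            incremental_cost = fx$incremental_cost)
  expect_equal(round(val$net_benefit, 2), 788.20)
  expect_equal(val$net_benefit, val$total_wta - fx$incremental_cost)
})
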