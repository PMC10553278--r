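# resolve the cost coefficient (the single continuous attribute's column)
.cost_coef_name <- function(attrs) cost_attribute(attrs)$name

.get_attrs <- function(result, attrs) {
  attrs <- attrs %||% result$attributes_spec
  if (is.null(attrs)) stop_invalid("an attribute specification is required")
  attrs
}

#' Marginal willingness-to-accept for an attribute level
#'
#' The WTA for moving from the reference level to a given attribute level is
#' the ratio of that level's coefficient to the cost coefficient,
#' `beta_x / beta_cost`, in euro per year on the cost attribute's scale
#' (annual cost to the NHS). The plain ratio is the default sign
#' convention — under the WTA framing the cost coefficient is expected
#' non-negative; `negate = TRUE` gives the textbook `-beta_x / beta_cost`.
#' When the cost coefficient is not significant at `p_warn` the estimate
#' carries a caveat (the ratio is reported but is statistically fragile).
#'
#' @param result a `dce_clogit` (fitted or assembled via [clogit_result()]).
#' @param level coefficient name of the attribute level.
#' @param attrs a `dce_attributes` set (defaults to the one on `result`).
#' @param negate use the `-beta_x / beta_cost` convention.
#' @param p_warn significance threshold for the cost-coefficient caveat.
#' @return a `wta_estimate`: `level`, `wta` (euro/year), `ci` (NULL until
#'   [krinsky_robb_ci()] is applied), `caveats`.
#' @export
marginal_wta <- function(result, level, attrs = NULL, negate = FALSE,
                         p_warn = 0.05) {
  attrs <- .get_attrs(result, attrs)
  beta <- result$coefficients
  cost <- .cost_coef_name(attrs)
  if (!cost %in% names(beta)) stop_invalid("no cost coefficient '", cost, "' in result")
  if (!level %in% names(beta)) stop_invalid("unknown coefficient '", level, "'")
  b_cost <- unname(beta[cost])
  if (b_cost == 0) {
    stop_invalid("WTA undefined: cost coefficient is exactly zero")
  }
  wta <- unname(beta[level]) / b_cost * (if (negate) -1 else 1)
  caveats <- character()
  p_cost <- result$p_values[cost]
  if (!is.null(result$p_values) && is.finite(p_cost) && p_cost >= p_warn) {
    caveats <- sprintf(
      "cost coefficient not significant (p = %.3g); WTA ratio is fragile",
      p_cost)
  }
  structure(list(level = level, wta = wta, ci = NULL,
                 negate = negate, caveats = caveats),
            class = "wta_estimate")
}

#' @export
print.wta_estimate <- function(x, ...) {
  cat(sprintf("WTA[%s] = %.2f euro/year", x$level, x$wta))
  if (!is.null(x$ci)) {
    cat(sprintf(" (%.1f to %.1f, %d Krinsky-Robb draws)",
                x$ci[1L], x$ci[2L], x$reps))
  }
  cat("\n")
  for (cv in x$caveats) cat("  caveat:", cv, "\n")
  invisible(x)
}

#' Krinsky-Robb confidence interval for a WTA ratio
#'
#' Parametric bootstrap for a nonlinear function of the coefficients: draws
#' coefficient vectors from a multivariate normal with the estimated mean
#' and covariance, recomputes the WTA ratio for each draw, and returns
#' percentile bounds. Draws whose cost coefficient is numerically zero
#' (|beta_cost| < 1e-12) are rejected and redrawn; their count is reported.
#'
#' @param result a `dce_clogit` with a covariance matrix.
#' @param level coefficient name of the attribute level.
#' @param reps number of draws, default 1000.
#' @param seed integer seed.
#' @param alpha two-sided error rate (default 0.05 for a 95% CI).
#' @param attrs attribute set (defaults to the one on `result`).
#' @param negate sign convention, as in [marginal_wta()].
#' @param repair_covariance project a non-positive-semi-definite covariance
#'   to the nearest PSD matrix before drawing (default FALSE: error out).
#' @return a `wta_estimate` with `ci`, `reps`, `seed`, `n_rejected`.
#' @export
krinsky_robb_ci <- function(result, level, reps = 1000L, seed = 1L,
                            alpha = 0.05, attrs = NULL, negate = FALSE,
                            repair_covariance = FALSE) {
  attrs <- .get_attrs(result, attrs)
  est <- marginal_wta(result, level, attrs = attrs, negate = negate)
  V <- result$vcov
  if (is.null(V)) stop_invalid("result carries no covariance matrix")
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    if (!repair_covariance) {
      stop_invalid("covariance matrix is not positive semi-definite ",
                   "(smallest eigenvalue ", signif(min(ev), 3),
                   "); rerun with repair_covariance = TRUE to project ",
                   "to the nearest PSD matrix")
    }
    V <- as.matrix(Matrix::nearPD(V, ensureSymmetry = TRUE)$mat)
  }
  beta <- result$coefficients
  cost <- .cost_coef_name(attrs)
  ratios <- with_seed(seed, {
    out <- numeric(reps)
    rejected <- 0L
    filled <- 0L
    while (filled < reps) {
      need <- reps - filled
      draw <- MASS::mvrnorm(need, mu = beta, Sigma = V)
      if (need == 1L) draw <- matrix(draw, nrow = 1L,
                                     dimnames = list(NULL, names(beta)))
      ok <- abs(draw[, cost]) >= 1e-12
      rejected <- rejected + sum(!ok)
      keep <- draw[ok, , drop = FALSE]
      if (nrow(keep)) {
        r <- keep[, level] / keep[, cost] * (if (negate) -1 else 1)
        out[filled + seq_along(r)] <- r
        filled <- filled + length(r)
      }
      if (rejected > 100 * reps) {
        stop_invalid("Krinsky-Robb draws degenerate: cost coefficient ",
                     "numerically zero in almost all draws")
      }
    }
    attr(out, "rejected") <- rejected
    out
  })
  est$ci <- unname(stats::quantile(ratios, probs = c(alpha / 2, 1 - alpha / 2)))
  est$reps <- as.integer(reps)
  est$seed <- as.integer(seed)
  est$n_rejected <- attr(ratios, "rejected")
  est
}

#' Relative importance of the attributes
#'
#' Each attribute's utility range (highest minus lowest level utility, with
#' the reference level at zero) divided by the sum of ranges over the
#' included attributes. By default only attributes with at least one
#' coefficient significant at `p_threshold` are included; attributes can
#' also be fixed explicitly via `include`.
#'
#' Shares sum to one and are invariant to rescaling all coefficients by a
#' positive constant.
#'
#' @param result a `dce_clogit` (needs p-values unless `include` is given).
#' @param attrs attribute set (defaults to the one on `result`).
#' @param p_threshold significance threshold for inclusion, default 0.05.
#' @param include character vector of attribute names overriding the
#'   significance screen.
#' @return named numeric vector of shares summing to 1.
#' @export
relative_importance <- function(result, attrs = NULL, p_threshold = 0.05,
                                include = NULL) {
  attrs <- .get_attrs(result, attrs)
  beta <- result$coefficients
  util_levels <- function(a) {
    if (a$coding == "continuous") {
      unname(beta[a$name]) * a$level_values
    } else {
      u <- numeric(length(a$levels))
      nonref <- setdiff(seq_along(a$levels), a$reference)
      u[nonref] <- beta[paste(a$name, a$levels[nonref], sep = ".")]
      u
    }
  }
  coef_names_of <- function(a) {
    if (a$coding == "continuous") a$name
    else paste(a$name, a$levels[-a$reference], sep = ".")
  }
  if (is.null(include)) {
    if (is.null(result$p_values)) {
      stop_invalid("result has no p-values; pass `include` explicitly")
    }
    include <- names(attrs)[vapply(attrs, function(a) {
      any(result$p_values[coef_names_of(a)] < p_threshold, na.rm = TRUE)
    }, logical(1))]
  }
  unknown <- setdiff(include, names(attrs))
  if (length(unknown)) stop_invalid("unknown attribute(s): ",
                                    paste(unknown, collapse = ", "))
  if (length(include) == 0L) stop_invalid("no attributes pass the significance screen")
  ranges <- vapply(attrs[include], function(a) {
    u <- util_levels(a)
    max(u) - min(u)
  }, numeric(1))
  if (all(ranges == 0)) stop_invalid("all utility ranges are zero; importance undefined")
  ranges / sum(ranges)
}

#' Utility of a scenario profile
#'
#' The deterministic utility `V = beta . x` of a single profile under the
#' analysis encoding (reference levels contribute zero; the cost column
#' contributes `beta_cost * cost`).
#'
#' @param result a `dce_clogit`, or a named coefficient vector.
#' @param profile integer vector of level indices (attribute order).
#' @param attrs attribute set.
#' @return utility value.
#' @export
scenario_utility <- function(result, profile, attrs = NULL) {
  beta <- if (inherits(result, "dce_clogit")) result$coefficients else result
  attrs <- if (inherits(result, "dce_clogit")) .get_attrs(result, attrs) else {
    if (is.null(attrs)) stop_invalid("`attrs` is required") else attrs
  }
  X <- encode_profiles(matrix(profile, nrow = 1L), attrs)
  missing <- setdiff(colnames(X), names(beta))
  if (length(missing)) stop_invalid("coefficients missing for: ",
                                    paste(missing, collapse = ", "))
  sum(beta[colnames(X)] * drop(X))
}

#' Total scenario WTA between two profiles
#'
#' Sums the per-attribute marginal WTAs for moving from the `worst` to the
#' `best` profile. The two profiles may differ only on attributes with a
#' defined WTA (categorical attributes; a difference on the cost attribute
#' itself has no WTA and is an error).
#'
#' @param result a `dce_clogit`.
#' @param best,worst integer vectors of level indices.
#' @param attrs attribute set (defaults to the one on `result`).
#' @param negate sign convention, as in [marginal_wta()].
#' @return list with `per_attribute` (named euro/year) and `total`.
#' @export
total_scenario_wta <- function(result, best, worst, attrs = NULL,
                               negate = FALSE) {
  attrs <- .get_attrs(result, attrs)
  if (length(best) != length(attrs) || length(worst) != length(attrs)) {
    stop_invalid("profiles must have one level index per attribute")
  }
  beta <- result$coefficients
  cost <- .cost_coef_name(attrs)
  per <- numeric(0)
  for (j in seq_along(attrs)) {
    a <- attrs[[j]]
    if (best[j] == worst[j]) next
    if (a$coding == "continuous") {
      stop_invalid("profiles differ on cost attribute '", a$name,
                   "', for which WTA is undefined")
    }
    lev_beta <- function(l) {
      if (l == a$reference) 0 else unname(beta[paste(a$name, a$levels[l], sep = ".")])
    }
    b_cost <- unname(beta[cost])
    if (b_cost == 0) stop_invalid("WTA undefined: cost coefficient is zero")
    per[a$name] <- (lev_beta(best[j]) - lev_beta(worst[j])) / b_cost *
      (if (negate) -1 else 1)
  }
  list(per_attribute = per, total = sum(per))
}

#' Compensating variation between two choice states
#'
#' The money-metric welfare change for moving from state 0 to state 1, each
#' state a set of available alternative profiles:
#' `CV = (1 / beta_cost) * (log sum_j exp(V_j^1) - log sum_j exp(V_j^0))`.
#' With a single alternative per state this reduces to
#' `(V^1 - V^0) / beta_cost`, the sum of marginal WTAs when the states
#' share the same cost level.
#'
#' @param result a `dce_clogit`, or a named coefficient vector (then pass
#'   `attrs`).
#' @param scenario0,scenario1 list of profiles (integer level vectors), or a
#'   single profile.
#' @param attrs attribute set.
#' @param negate flip the sign (textbook WTP convention).
#' @return compensating variation in euro per year.
#' @export
compensating_variation <- function(result, scenario0, scenario1,
                                   attrs = NULL, negate = FALSE) {
  beta <- if (inherits(result, "dce_clogit")) result$coefficients else result
  attrs <- if (inherits(result, "dce_clogit")) .get_attrs(result, attrs) else {
    if (is.null(attrs)) stop_invalid("`attrs` is required") else attrs
  }
  cost <- .cost_coef_name(attrs)
  b_cost <- unname(beta[cost])
  if (is.na(b_cost) || b_cost == 0) {
    stop_invalid("compensating variation undefined: cost coefficient is zero")
  }
  as_list <- function(s) if (is.list(s)) s else list(s)
  logsum <- function(profiles) {
    logsumexp(vapply(as_list(profiles), function(p) {
      scenario_utility(beta, p, attrs)
    }, numeric(1)))
  }
  cv <- (logsum(scenario1) - logsum(scenario0)) / b_cost
  if (negate) -cv else cv
}

#' Net benefit of a programme
#'
#' Cost-benefit bottom line: aggregate willingness-to-accept minus the
#' programme's incremental cost, both in euro per patient-year. Negative
#' values pass through unmodified.
#'
#' @param total_wta aggregate WTA (euro/year).
#' @param incremental_cost incremental programme cost (euro/year).
#' @return net benefit (euro/year).
#' @examples
#' net_benefit(877, 88.80)  # 788.20
#' @export
net_benefit <- function(total_wta, incremental_cost) {
  total_wta - incremental_cost
}

#' Full scenario valuation (WTA, compensating variation, net benefit)
#'
#' Convenience bundle for the welfare stage: per-attribute marginal WTAs for
#' the best-versus-worst scenario, their total, the single-alternative
#' compensating variation, and the net benefit against an incremental
#' programme cost.
#'
#' @param result a `dce_clogit`.
#' @param best,worst scenario profiles (integer level vectors).
#' @param incremental_cost incremental cost in euro per year.
#' @param attrs attribute set (defaults to the one on `result`).
#' @return a `scenario_valuation` list: `best`, `worst`, `per_attribute`,
#'   `total_wta`, `compensating_variation`, `incremental_cost`,
#'   `net_benefit`.
#' @export
scenario_valuation <- function(result, best, worst, incremental_cost,
                               attrs = NULL) {
  attrs <- .get_attrs(result, attrs)
  wta <- total_scenario_wta(result, best, worst, attrs = attrs)
  cv <- compensating_variation(result, scenario0 = worst, scenario1 = best,
                               attrs = attrs)
  structure(
    list(best = best, worst = worst,
         per_attribute = wta$per_attribute, total_wta = wta$total,
         compensating_variation = cv,
         incremental_cost = incremental_cost,
         net_benefit = net_benefit(wta$total, incremental_cost)),
    class = "scenario_valuation"
  )
}

#' @export
print.scenario_valuation <- function(x, ...) {
  cat("Scenario valuation (best vs worst bundle)\n")
  for (nm in names(x$per_attribute)) {
    cat(sprintf("  %-28s %10.2f euro/yr\n", nm, x$per_attribute[nm]))
  }
  cat(sprintf("  %-28s %10.2f euro/yr\n", "total WTA", x$total_wta))
  cat(sprintf("  %-28s %10.2f euro/yr\n", "compensating variation",
              x$compensating_variation))
  cat(sprintf("  %-28s %10.2f euro/yr\n", "incremental cost",
              x$incremental_cost))
  cat(sprintf("  %-28s %10.2f euro/yr\n", "net benefit", x$net_benefit))
  invisible(x)
}
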