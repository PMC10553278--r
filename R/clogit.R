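#' Conditional logit log-likelihood
#'
#' The conditional (McFadden) logit log-likelihood over choice sets:
#' `LL = sum over sets [ V_chosen - log sum_alternatives exp(V_alt) ]`
#' with `V = beta . x` per encoded alternative row. Computed with a
#' log-sum-exp stabilization so it is finite for any finite inputs, and
#' invariant to adding a set-constant to every alternative's utility.
#'
#' @param beta coefficient vector (length = number of covariates).
#' @param data encoded choice data from [encode_design_matrix()].
#' @return log-likelihood value.
#' @export
clogit_loglik <- function(beta, data) {
  pieces <- .clogit_pieces(data)
  if (length(beta) != ncol(pieces$X)) {
    stop_invalid("`beta` has length ", length(beta), " but there are ",
                 ncol(pieces$X), " covariates")
  }
  .clogit_ll(as.numeric(beta), pieces)$ll
}

# split encoded data into the matrices the likelihood machinery uses;
# strata are (respondent, set) pairs
.clogit_pieces <- function(data) {
  covs <- attr(data, "covariates") %||%
    setdiff(names(data), c("respondent_id", "set_id", "chosen"))
  X <- as.matrix(data[, covs, drop = FALSE])
  storage.mode(X) <- "double"
  stratum <- factor(paste(data$respondent_id, data$set_id, sep = "\r"))
  y <- as.integer(data$chosen)
  if (!all(tapply(y, stratum, sum) == 1L)) {
    stop_invalid("every choice set must have exactly one chosen alternative")
  }
  list(X = X, y = y, stratum = stratum,
       respondent = as.character(data$respondent_id))
}

# log-likelihood, gradient, and Hessian at beta
.clogit_ll <- function(beta, pieces, want_deriv = FALSE) {
  X <- pieces$X
  s <- pieces$stratum
  eta <- drop(X %*% beta)
  m <- stats::ave(eta, s, FUN = max)
  w <- exp(eta - m)
  denom <- stats::ave(w, s, FUN = sum)
  ll <- sum((eta - (m + log(denom)))[pieces$y == 1L])
  if (!want_deriv) return(list(ll = ll))
  p <- w / denom
  grad <- drop(crossprod(X, pieces$y - p))
  Xbar <- rowsum(p * X, s, reorder = FALSE)      # per-set mean covariates
  H <- -(crossprod(X, p * X) - crossprod(Xbar))
  list(ll = ll, grad = grad, hessian = H)
}

#' Fit a conditional logit model by maximum likelihood
#'
#' Newton-Raphson with analytic gradient and Hessian on the (globally
#' concave) conditional logit log-likelihood, with step halving; the
#' covariance matrix is the inverse observed information at the optimum.
#' Covariates that never vary within choice sets, or that perfectly
#' predict choice (separation), are reported as errors rather than
#' silently returned.
#'
#' @param data encoded choice data from [encode_design_matrix()].
#' @param start optional starting coefficient vector (default zero).
#' @param tol convergence tolerance on the gradient norm.
#' @param max_iter iteration cap.
#' @return a `dce_clogit` object: `coefficients`, `vcov`, `se`, `z`,
#'   `p_values`, `ll_full`, `ll_null`, `lr` (chi-square), `df`, `p_lr`,
#'   `n_individuals`, `n_obs`, `n_sets`, `converged`, `iterations`.
#' @export
fit_clogit <- function(data, start = NULL, tol = 1e-8, max_iter = 200L) {
  pieces <- .clogit_pieces(data)
  X <- pieces$X
  p <- ncol(X)
  # identification: covariates must vary within sets and be of full rank
  # after within-set centering
  Xc <- X - apply(X, 2L, function(col) stats::ave(col, pieces$stratum))
  const <- which(apply(abs(Xc), 2L, max) < 1e-12)
  if (length(const)) {
    stop_invalid("covariate(s) never differ within choice sets: ",
                 paste(colnames(X)[const], collapse = ", "))
  }
  qrx <- qr(Xc)
  if (qrx$rank < p) {
    dropped <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    stop_invalid("within-set design matrix is singular; collinear columns: ",
                 paste(dropped, collapse = ", "))
  }
  beta <- if (is.null(start)) numeric(p) else as.numeric(start)
  if (length(beta) != p) stop_invalid("`start` must have length ", p)
  cur <- .clogit_ll(beta, pieces, want_deriv = TRUE)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    gnorm <- sqrt(sum(cur$grad^2))
    if (gnorm < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(-cur$hessian, cur$grad), error = function(e) NULL)
    if (is.null(step)) {
      stop_invalid("observed information is singular at the current estimate; ",
                   "the model may be unidentified")
    }
    # step halving keeps the ascent monotone
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      cand_ll <- .clogit_ll(cand, pieces)$ll
      if (cand_ll >= cur$ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- beta + lambda * step
    cur <- .clogit_ll(beta, pieces, want_deriv = TRUE)
    if (max(abs(beta)) > 50) {
      worst <- colnames(X)[which.max(abs(beta))]
      stop_invalid("separation detected: covariate '", worst,
                   "' perfectly predicts choice (|beta| diverging)")
    }
  }
  if (!converged) {
    gnorm <- sqrt(sum(cur$grad^2))
    if (gnorm >= tol) {
      worst <- colnames(X)[which.max(abs(beta))]
      stop_invalid("conditional logit did not converge in ", max_iter,
                   " iterations (gradient norm ", signif(gnorm, 3),
                   "); largest coefficient: '", worst, "'")
    }
  }
  # separation diagnostic: a coefficient whose utility contribution spans
  # more than +-15 on the Gumbel scale drives its choice probabilities to
  # within ~3e-7 of 0/1, i.e. the MLE is effectively infinite
  scaled <- abs(beta) * apply(Xc, 2L, stats::sd)
  if (any(scaled > 15)) {
    worst <- colnames(X)[which.max(scaled)]
    stop_invalid("separation detected: covariate '", worst,
                 "' perfectly predicts choice (estimate diverging)")
  }
  vcov <- solve(-cur$hessian)
  vcov <- (vcov + t(vcov)) / 2
  se <- sqrt(diag(vcov))
  names(beta) <- colnames(X)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  n_sets <- nlevels(pieces$stratum)
  ll0 <- -sum(log(tabulate(pieces$stratum)))
  z <- beta / se
  res <- structure(
    list(coefficients = beta, vcov = vcov, se = se, z = z,
         p_values = 2 * stats::pnorm(-abs(z)),
         ll_full = cur$ll, ll_null = ll0,
         lr = 2 * (cur$ll - ll0), df = p,
         p_lr = stats::pchisq(2 * (cur$ll - ll0), df = p, lower.tail = FALSE),
         n_individuals = length(unique(pieces$respondent)),
         n_obs = nrow(X), n_sets = n_sets,
         converged = converged, iterations = iter,
         gradient_norm = sqrt(sum(cur$grad^2)),
         bootstrap = NULL, attributes_spec = NULL),
    class = "dce_clogit"
  )
  res
}

#' Assemble an estimation result from externally given coefficients
#'
#' Builds a `dce_clogit`-shaped object from a coefficient vector (and
#' optionally a covariance matrix and p-values), e.g. published regression
#' tables, so the welfare functions can be applied without refitting.
#'
#' @param coefficients named coefficient vector.
#' @param vcov covariance matrix (default: zero matrix, i.e. coefficients
#'   treated as fixed).
#' @param p_values optional named vector of p-values.
#' @param attrs optional `dce_attributes` set carried for welfare analysis.
#' @return a `dce_clogit` object.
#' @export
clogit_result <- function(coefficients, vcov = NULL, p_values = NULL,
                          attrs = NULL) {
  p <- length(coefficients)
  if (is.null(names(coefficients))) stop_invalid("coefficients must be named")
  if (is.null(vcov)) {
    vcov <- matrix(0, p, p, dimnames = list(names(coefficients),
                                            names(coefficients)))
  }
  structure(
    list(coefficients = coefficients, vcov = vcov,
         se = sqrt(diag(vcov)), z = NULL, p_values = p_values,
         ll_full = NA_real_, ll_null = NA_real_, lr = NA_real_,
         df = p, p_lr = NA_real_, n_individuals = NA_integer_,
         n_obs = NA_integer_, n_sets = NA_integer_, converged = NA,
         iterations = NA_integer_, gradient_norm = NA_real_,
         bootstrap = NULL, attributes_spec = attrs),
    class = "dce_clogit"
  )
}

#' Likelihood-ratio test of the fitted model against the null
#'
#' Chi-square statistic `2 (LL_full - LL_0)` with degrees of freedom equal
#' to the number of coefficients, against the null model with all
#' coefficients zero (uniform choice probabilities).
#'
#' @param result a fitted `dce_clogit`.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(result) {
  if (is.na(result$ll_full) || is.na(result$ll_null)) {
    stop_invalid("result does not carry log-likelihoods (fixture result?)")
  }
  stat <- 2 * (result$ll_full - result$ll_null)
  list(statistic = stat, df = result$df,
       p_value = stats::pchisq(stat, df = result$df, lower.tail = FALSE))
}

#' Cluster bootstrap confidence intervals for the coefficients
#'
#' Resamples respondents (the independent clusters of a panel of choice
#' sets) with replacement at the original cohort size, refits the model on
#' each replicate, and returns percentile confidence bounds. Replicates
#' whose refit fails (e.g. separation in a small resample) are skipped and
#' counted; more than 20% failures aborts.
#'
#' @param data encoded choice data from [encode_design_matrix()].
#' @param reps number of bootstrap replications (>= 2), default 1000.
#' @param seed integer seed.
#' @param conf confidence level, default 0.95.
#' @return list with `ci` (matrix: coefficient x lower/upper), `reps`,
#'   `n_failed`, `seed`, `conf`.
#' @export
bootstrap_coefficients <- function(data, reps = 1000L, seed = 1L,
                                   conf = 0.95) {
  if (reps < 2L) stop_invalid("`reps` must be >= 2")
  covs <- attr(data, "covariates") %||%
    setdiff(names(data), c("respondent_id", "set_id", "chosen"))
  ids <- unique(as.character(data$respondent_id))
  rows_of <- split(seq_len(nrow(data)), as.character(data$respondent_id))
  draws <- with_seed(seed, matrix(sample(length(ids), length(ids) * reps,
                                         replace = TRUE), nrow = reps))
  est <- matrix(NA_real_, reps, length(covs),
                dimnames = list(NULL, covs))
  n_failed <- 0L
  for (r in seq_len(reps)) {
    take <- draws[r, ]
    idx <- unlist(rows_of[take], use.names = FALSE)
    boot <- data[idx, , drop = FALSE]
    # duplicated respondents must stay distinct clusters/strata
    reps_per <- lengths(rows_of[take])
    boot$respondent_id <- rep(paste0("b", seq_along(take)), reps_per)
    attr(boot, "covariates") <- covs
    fit <- tryCatch(fit_clogit(boot), error = function(e) NULL)
    if (is.null(fit)) n_failed <- n_failed + 1L else est[r, ] <- fit$coefficients
  }
  if (n_failed > 0.2 * reps) {
    stop_invalid("bootstrap unstable: ", n_failed, " of ", reps,
                 " replicate refits failed")
  }
  alpha <- (1 - conf) / 2
  ci <- t(apply(est, 2L, stats::quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  list(ci = ci, reps = reps, n_failed = n_failed, seed = seed, conf = conf)
}

#' Fit the choice model for a respondent group
#'
#' Convenience wrapper tying the pipeline together: filters the requested
#' group, encodes the covariates, fits the conditional logit, and
#' optionally attaches cluster-bootstrap confidence intervals. The
#' attribute specification is carried on the result for the welfare
#' functions.
#'
#' @param choices long-format choice observations.
#' @param attrs a `dce_attributes` set.
#' @param group `"all"`, `"intervention"` or `"control"`.
#' @param bootstrap number of bootstrap replications (0 = none).
#' @param seed seed for the bootstrap.
#' @return a `dce_clogit` with `attributes_spec` and `group` filled in.
#' @export
fit_choice_model <- function(choices, attrs,
                             group = c("all", "intervention", "control"),
                             bootstrap = 0L, seed = 1L) {
  group <- match.arg(group)
  if (group != "all") choices <- choices[choices$group == group, , drop = FALSE]
  if (nrow(choices) == 0L) stop_invalid("no observations for group '", group, "'")
  enc <- encode_design_matrix(choices, attrs)
  res <- fit_clogit(enc)
  res$attributes_spec <- attrs
  res$group <- group
  if (bootstrap > 0L) {
    res$bootstrap <- bootstrap_coefficients(enc, reps = bootstrap, seed = seed)
  }
  res
}

#' @export
print.dce_clogit <- function(x, digits = 3, ...) {
  cat("Conditional logit estimation\n")
  if (!is.na(x$n_individuals)) {
    cat("  individuals (observations): ", x$n_individuals, " (", x$n_obs, ")\n",
        sep = "")
  }
  tab <- data.frame(beta = round(x$coefficients, digits))
  if (!is.null(x$se) && all(is.finite(x$se))) tab$se <- round(x$se, digits)
  if (!is.null(x$p_values)) tab$p <- round(x$p_values, digits)
  if (!is.null(x$bootstrap)) {
    tab$boot_lower <- round(x$bootstrap$ci[, "lower"], digits)
    tab$boot_upper <- round(x$bootstrap$ci[, "upper"], digits)
  }
  print(tab)
  if (!is.na(x$ll_full)) {
    cat(sprintf("  LL(full) = %.3f, LL(0) = %.3f, LR chi-square(%d) = %.2f, p = %.3g\n",
                x$ll_full, x$ll_null, x$df, x$lr, x$p_lr))
  }
  invisible(x)
}
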