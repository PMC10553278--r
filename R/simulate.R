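#' Attribute space of the pharmacy collaborative-care DCE
#'
#' The five attributes of a pharmacy / primary-care collaborative
#' hypertension and hyperlipidemia management experiment: model of pharmacy
#' intervention, integration with primary care, waiting time to get a
#' medical appointment, chance of having a stroke in five years (all
#' three-level categorical, level 1 = usual care = reference), and annual
#' cost to the NHS (continuous over levels 0, 30, 51, 76 euro/year). The
#' full factorial has 3^4 x 4 = 324 profiles.
#'
#' @return a `dce_attributes` set.
#' @export
pharmacy_dce_attributes <- function() {
  dce_attributes(
    dce_attribute("pharmacy_model",
                  c("counter_5min", "office_15min_q3mo", "office_30min_q6mo")),
    dce_attribute("integration", c("weak", "partial", "full")),
    dce_attribute("waiting_time",
                  c("urgent_7d_routine_45d", "urgent_48h_routine_30d",
                    "same_day_routine_15d")),
    dce_attribute("stroke_risk", c("same", "slightly_lower", "much_lower")),
    dce_attribute("nhs_cost", c("0", "30", "51", "76"),
                  coding = "continuous", level_values = c(0, 30, 51, 76))
  )
}

#' Built-in example study fixture
#'
#' Coefficient fixtures for the pharmacy collaborative-care DCE: attribute
#' space, conditional logit coefficient vectors and p-values for three
#' respondent groups (all respondents, the intervention arm and the control
#' arm of the underlying trial), the best/worst scenario profiles used in
#' the welfare analysis (best = 30-minute comprehensive pharmacy
#' intervention, full integration, same-day/15-day waiting time; stroke
#' risk and cost at reference), the trial's annual incremental cost per
#' patient (88.80 euro), and the cohort sizes (78 intervention / 44
#' control).
#'
#' @return list with `attributes`, `beta` (list of 3 named vectors),
#'   `p_values` (idem), `scenarios` (`best`, `worst`), `incremental_cost`,
#'   `cohort`, `n_sets`, `n_blocks`, `sets_per_respondent`.
#' @export
pharmacy_dce_fixture <- function() {
  attrs <- pharmacy_dce_attributes()
  nm <- covariate_names(attrs)
  mk <- function(v) stats::setNames(v, nm)
  list(
    attributes = attrs,
    beta = list(
      all          = mk(c(0.551, 0.888, 0.376, 0.622, 0.381, 1.150,
                          0.121, 0.067, 0.002)),
      intervention = mk(c(0.605, 0.948, 0.417, 0.634, 0.267, 1.049,
                          0.181, 0.232, 0.003)),
      control      = mk(c(0.481, 0.792, 0.308, 0.617, 0.585, 1.349,
                          0.022, -0.220, 0.001))
    ),
    p_values = list(
      all          = mk(c(0.003, 0.000, 0.023, 0.001, 0.022, 0.000,
                          0.589, 0.712, 0.510)),
      intervention = mk(c(0.009, 0.000, 0.043, 0.007, 0.199, 0.000,
                          0.516, 0.309, 0.514)),
      control      = mk(c(0.119, 0.026, 0.269, 0.055, 0.038, 0.000,
                          0.954, 0.463, 0.805))
    ),
    scenarios = list(best = c(3L, 3L, 3L, 1L, 1L),
                     worst = c(1L, 1L, 1L, 1L, 1L)),
    incremental_cost = 88.80,
    cohort = c(intervention = 78L, control = 44L),
    n_sets = 36L, n_blocks = 9L, sets_per_respondent = 4L
  )
}

#' Simulate choice data under the random-utility model
#'
#' Generates long-format choices with exactly the statistical structure the
#' conditional logit assumes: each respondent is randomly assigned one
#' questionnaire block, and in each of their choice sets the utility of
#' alternative j is `U_j = beta . x_j + e_j` with `e_j` i.i.d. standard
#' Gumbel (type-I extreme value), the chosen alternative being the argmax.
#' Group differences are simulated by using a different true coefficient
#' vector per group. Deterministic given `seed`.
#'
#' @param attrs a `dce_attributes` set.
#' @param beta named coefficient vector (analysis coding), or a list with
#'   components `intervention` and `control`.
#' @param design a `dce_design`; if `NULL`, one is generated by
#'   [search_fractional_design()] with 36 sets in 9 blocks.
#' @param n_respondents named integer vector, default
#'   `c(intervention = 78, control = 44)`; groups with 0 respondents are
#'   dropped.
#' @param sets_per_respondent choice sets answered per respondent (at most
#'   the block size), default 4.
#' @param seed integer seed.
#' @return long-format choice data frame (see [validate_choices()]).
#' @export
simulate_choices <- function(attrs, beta, design = NULL,
                             n_respondents = c(intervention = 78L, control = 44L),
                             sets_per_respondent = 4L, seed = 1L) {
  if (!inherits(attrs, "dce_attributes")) attrs <- dce_attributes(attrs)
  if (is.null(design)) {
    design <- search_fractional_design(attrs, n_sets = 36L, n_blocks = 9L,
                                       seed = derive_seed(seed, 7L),
                                       restarts = 2L)
  }
  sets <- design$sets
  block_size <- length(unique(sets$set_id)) / design$n_blocks
  if (sets_per_respondent < 1L || sets_per_respondent > block_size) {
    stop_invalid("`sets_per_respondent` must be between 1 and the block size (",
                 block_size, ")")
  }
  if (is.null(names(n_respondents)) ||
      !all(names(n_respondents) %in% c("intervention", "control"))) {
    stop_invalid("`n_respondents` must be named 'intervention'/'control'")
  }
  n_respondents <- n_respondents[n_respondents > 0L]
  if (length(n_respondents) == 0L) stop_invalid("no respondents requested")
  beta_of <- function(group) {
    b <- if (is.list(beta)) beta[[group]] else beta
    if (is.null(b)) stop_invalid("no coefficient vector for group '", group, "'")
    nm <- covariate_names(attrs)
    if (!all(nm %in% names(b))) {
      stop_invalid("beta is missing coefficients: ",
                   paste(setdiff(nm, names(b)), collapse = ", "))
    }
    b[nm]
  }
  X <- encode_profiles(as.matrix(sets[, names(attrs), drop = FALSE]), attrs)
  with_seed(seed, {
    out <- vector("list", sum(n_respondents))
    k <- 0L
    for (group in names(n_respondents)) {
      bg <- beta_of(group)
      V_all <- drop(X %*% bg)
      prefix <- if (group == "intervention") "I" else "C"
      for (i in seq_len(n_respondents[[group]])) {
        k <- k + 1L
        block <- sample.int(design$n_blocks, 1L)
        bsets <- sets[sets$block == block, ]
        ids <- sort(unique(bsets$set_id))[seq_len(sets_per_respondent)]
        take <- which(sets$block == block & sets$set_id %in% ids)
        rows <- sets[take, ]
        V <- V_all[take]
        eps <- -log(-log(stats::runif(length(take))))
        U <- V + eps
        chosen <- integer(length(take))
        for (s in unique(rows$set_id)) {
          idx <- which(rows$set_id == s)
          chosen[idx[which.max(U[idx])]] <- 1L
        }
        out[[k]] <- data.frame(
          respondent_id = sprintf("%s%03d", prefix, i),
          group = group, set_id = rows$set_id, block = rows$block,
          alternative = rows$alternative,
          rows[, names(attrs), drop = FALSE],
          chosen = chosen, stringsAsFactors = FALSE
        )
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Inject single-attribute dominant responders
#'
#' Overwrites the choices of a randomly selected fraction of respondents so
#' that, in every choice set where exactly one alternative carries the best
#' level of the given attribute, they pick that alternative (uninformative
#' sets are left untouched). Used to emulate non-trading behaviour and to
#' validate the dominance screen. Deterministic given `seed`.
#'
#' @param choices long-format choice observations.
#' @param attrs a `dce_attributes` set.
#' @param attribute attribute name.
#' @param fraction fraction of respondents to convert, in \[0, 1\].
#' @param seed integer seed.
#' @param best optional best-level override (default [best_levels()]).
#' @return the modified choice data frame, with the converted respondent
#'   ids in `attr(, "injected")`.
#' @export
inject_dominant_responders <- function(choices, attrs, attribute, fraction,
                                       seed = 1L, best = NULL) {
  if (!attribute %in% names(attrs)) {
    stop_invalid("unknown attribute '", attribute, "'")
  }
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop_invalid("`fraction` must be in [0, 1]")
  }
  best_l <- (best %||% best_levels(attrs))[[attribute]]
  ids <- unique(choices$respondent_id)
  n_take <- round(fraction * length(ids))
  if (n_take == 0L) {
    attr(choices, "injected") <- character(0)
    return(choices)
  }
  take <- with_seed(seed, sample(ids, n_take))
  for (id in take) {
    rows <- which(choices$respondent_id == id)
    sub <- choices[rows, ]
    for (s in unique(sub$set_id)) {
      idx <- rows[sub$set_id == s]
      hit <- choices[[attribute]][idx] == best_l
      if (sum(hit) == 1L) {
        choices$chosen[idx] <- as.integer(hit)
      }
    }
  }
  attr(choices, "injected") <- sort(as.character(take))
  choices
}
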