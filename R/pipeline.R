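# normalize and validate a pipeline configuration before any computation
.pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_invalid("config must be a list or a YAML/JSON path")
  def <- list(
    out_dir = NULL,
    attrs = NULL,                      # path to YAML, or NULL for the fixture
    choices = NULL,                    # path to CSV, or NULL to simulate
    design = list(generate = TRUE, n_sets = 36L, n_blocks = 9L, seed = 1L,
                  restarts = 10L),
    simulate = list(beta = "fixture", seed = 1L,
                    n_intervention = 78L, n_control = 44L,
                    sets_per_respondent = 4L),
    estimation = list(groups = c("all", "intervention", "control"),
                      bootstrap = 0L, seed = 1L),
    welfare = list(group = "intervention", kr_reps = 1000L, seed = 1L,
                   alpha = 0.05, incremental_cost = 88.80)
  )
  cfg <- utils::modifyList(def, config)
  if (is.null(cfg$out_dir)) stop_invalid("config needs `out_dir`")
  for (nm in c("kr_reps")) {
    if (cfg$welfare[[nm]] < 2L) stop_invalid("welfare `", nm, "` must be >= 2")
  }
  if (cfg$estimation$bootstrap != 0L && cfg$estimation$bootstrap < 2L) {
    stop_invalid("estimation `bootstrap` must be 0 or >= 2")
  }
  bad <- setdiff(cfg$estimation$groups, c("all", "intervention", "control"))
  if (length(bad)) stop_invalid("unknown estimation group(s): ",
                                paste(bad, collapse = ", "))
  cfg
}

# stable hash of the normalized config for provenance; the output location
# does not affect the scientific content, so it is excluded
.config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full DCE valuation pipeline
#'
#' Orchestrates design generation (optional), data simulation or loading,
#' validation, dominance QC, per-group conditional logit estimation,
#' welfare analysis and cost-benefit analysis. Writes a machine-readable
#' `results.json` (with config hash and every seed for provenance), Table
#' style CSV summaries of the coefficient and scenario results, and a
#' human-readable `report.txt` with a caveats block (cost-coefficient
#' significance, bootstrap failures, dominance counts). A failure in any
#' stage aborts with the stage name and removes partial outputs.
#'
#' Identical configurations produce byte-identical `results.json`.
#'
#' @param config list, or path to a YAML/JSON configuration. Recognised
#'   sections: `out_dir`; `attrs` (YAML path, default: built-in pharmacy
#'   DCE attributes); `choices` (CSV path, default: simulate); `design`
#'   (`generate`, `n_sets`, `n_blocks`, `seed`, `restarts`); `simulate`
#'   (`beta` = "fixture" or named list, `seed`, `n_intervention`,
#'   `n_control`, `sets_per_respondent`); `estimation` (`groups`,
#'   `bootstrap`, `seed`); `welfare` (`group`, `kr_reps`, `seed`, `alpha`,
#'   `incremental_cost`).
#' @return (invisibly) the results list written to `results.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- .pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- file.path(cfg$out_dir, c("results.json", "coefficients.csv",
                                      "scenario.csv", "report.txt",
                                      "design.csv", "design.csv.attrs.yaml",
                                      "choices.csv"))
  written <- character(0)
  stage <- "setup"
  res <- tryCatch({
    fixture <- pharmacy_dce_fixture()
    stage <- "attributes"
    attrs <- if (is.null(cfg$attrs)) fixture$attributes else read_attributes(cfg$attrs)

    stage <- "design"
    design <- NULL
    if (is.null(cfg$choices)) {
      design <- search_fractional_design(
        attrs, n_sets = cfg$design$n_sets, n_blocks = cfg$design$n_blocks,
        seed = cfg$design$seed, restarts = cfg$design$restarts)
      write_design(design, file.path(cfg$out_dir, "design.csv"))
      written <- c(written, file.path(cfg$out_dir,
                                      c("design.csv", "design.csv.attrs.yaml")))
    }

    stage <- "choices"
    if (is.null(cfg$choices)) {
      beta <- cfg$simulate$beta
      if (identical(beta, "fixture")) {
        beta <- fixture$beta[c("intervention", "control")]
      }
      choices <- simulate_choices(
        attrs, beta, design = design,
        n_respondents = c(intervention = as.integer(cfg$simulate$n_intervention),
                          control = as.integer(cfg$simulate$n_control)),
        sets_per_respondent = cfg$simulate$sets_per_respondent,
        seed = cfg$simulate$seed)
      write_choices(choices, file.path(cfg$out_dir, "choices.csv"))
      written <- c(written, file.path(cfg$out_dir, "choices.csv"))
    } else {
      choices <- read_choices(cfg$choices, attrs)
    }

    stage <- "validation"
    validate_choices(choices, attrs)

    stage <- "dominance QC"
    dominance <- detect_dominant_responders(choices, attrs)

    stage <- "estimation"
    fits <- list()
    for (g in cfg$estimation$groups) {
      if (g != "all" && !any(choices$group == g)) next
      fits[[g]] <- fit_choice_model(choices, attrs, group = g,
                                    bootstrap = cfg$estimation$bootstrap,
                                    seed = cfg$estimation$seed)
    }
    if (length(fits) == 0L) stop_invalid("no group could be fitted")

    stage <- "welfare"
    wg <- cfg$welfare$group
    wfit <- fits[[wg]] %||% fits[[1L]]
    valuation <- scenario_valuation(wfit, fixture$scenarios$best,
                                    fixture$scenarios$worst,
                                    incremental_cost = cfg$welfare$incremental_cost,
                                    attrs = attrs)
    kr <- lapply(names(valuation$per_attribute), function(a) {
      lev <- paste(a, attrs[[a]]$levels[fixture$scenarios$best[match(a, names(attrs))]],
                   sep = ".")
      krinsky_robb_ci(wfit, lev, reps = cfg$welfare$kr_reps,
                      seed = cfg$welfare$seed, alpha = cfg$welfare$alpha)
    })
    names(kr) <- names(valuation$per_attribute)

    stage <- "report"
    caveats <- character(0)
    for (g in names(fits)) {
      pc <- fits[[g]]$p_values[.cost_coef_name(attrs)]
      if (is.finite(pc) && pc >= 0.05) {
        caveats <- c(caveats, sprintf(
          "group %s: cost coefficient not significant (p = %.3f); WTA ratios are fragile",
          g, pc))
      }
      if (!is.null(fits[[g]]$bootstrap) && fits[[g]]$bootstrap$n_failed > 0L) {
        caveats <- c(caveats, sprintf("group %s: %d bootstrap refits failed",
                                      g, fits[[g]]$bootstrap$n_failed))
      }
    }
    n_resp <- length(unique(choices$respondent_id))
    dom_counts <- vapply(dominance, length, integer(1))
    caveats <- c(caveats, sprintf(
      "dominant responders: %s (of %d respondents)",
      paste(sprintf("%s=%d", names(dom_counts), dom_counts), collapse = ", "),
      n_resp))

    results <- list(
      config_hash = .config_hash(cfg),
      seeds = list(design = cfg$design$seed, simulate = cfg$simulate$seed,
                   estimation = cfg$estimation$seed, welfare = cfg$welfare$seed),
      design = if (!is.null(design)) list(
        n_sets = length(unique(design$sets$set_id)),
        n_blocks = design$n_blocks,
        d_efficiency = design$d_efficiency),
      dominance = lapply(dominance, as.list),
      fits = lapply(fits, function(f) list(
        group = f$group, coefficients = as.list(f$coefficients),
        se = as.list(f$se), p_values = as.list(f$p_values),
        ll_full = f$ll_full, ll_null = f$ll_null,
        lr = f$lr, df = f$df, p_lr = f$p_lr,
        n_individuals = f$n_individuals, n_obs = f$n_obs,
        converged = f$converged,
        bootstrap_ci = if (!is.null(f$bootstrap))
          apply(f$bootstrap$ci, 1L, as.list, simplify = FALSE))),
      welfare = list(
        group = wfit$group,
        per_attribute_wta = as.list(valuation$per_attribute),
        kr_ci = lapply(kr, function(k) list(lower = k$ci[1L], upper = k$ci[2L])),
        total_wta = valuation$total_wta,
        compensating_variation = valuation$compensating_variation,
        incremental_cost = valuation$incremental_cost,
        net_benefit = valuation$net_benefit),
      caveats = as.list(caveats)
    )

    json_path <- file.path(cfg$out_dir, "results.json")
    jsonlite::write_json(results, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    written <- c(written, json_path)

    coef_tab <- do.call(rbind, lapply(names(fits), function(g) {
      f <- fits[[g]]
      data.frame(group = g, coefficient = names(f$coefficients),
                 beta = unname(f$coefficients), se = unname(f$se),
                 p = unname(f$p_values), stringsAsFactors = FALSE)
    }))
    utils::write.csv(coef_tab, file.path(cfg$out_dir, "coefficients.csv"),
                     row.names = FALSE)
    scen_tab <- data.frame(
      quantity = c(paste0("wta.", names(valuation$per_attribute)),
                   "total_wta", "compensating_variation",
                   "incremental_cost", "net_benefit"),
      euro_per_year = c(unname(valuation$per_attribute), valuation$total_wta,
                        valuation$compensating_variation,
                        valuation$incremental_cost, valuation$net_benefit),
      stringsAsFactors = FALSE)
    utils::write.csv(scen_tab, file.path(cfg$out_dir, "scenario.csv"),
                     row.names = FALSE)
    written <- c(written, file.path(cfg$out_dir,
                                    c("coefficients.csv", "scenario.csv")))

    rpt <- file.path(cfg$out_dir, "report.txt")
    con <- file(rpt, open = "wt")
    sink(con)
    cat("DCE valuation pipeline report\n")
    cat("config hash:", results$config_hash, "\n\n")
    if (!is.null(design)) print(design)
    cat("\n")
    for (g in names(fits)) { cat("== group:", g, "==\n"); print(fits[[g]]); cat("\n") }
    print(valuation)
    cat("\nCaveats:\n")
    for (cv in caveats) cat(" -", cv, "\n")
    sink()
    close(con)
    written <- c(written, rpt)
    results
  }, error = function(e) {
    unlink(written)
    stop_invalid("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e))
  })
  invisible(res)
}
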