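#' Validate long-format choice observations
#'
#' Choice data are long format: one row per alternative, with columns
#' `respondent_id`, `group` ("intervention"/"control"), `set_id`, `block`
#' (optional), `alternative` ("A"/"B"), one column of level indices per
#' attribute, and `chosen` (0/1). Each (respondent, set) pair must hold
#' exactly two alternatives of which exactly one is chosen; a respondent's
#' group must be constant.
#'
#' @param choices data frame of observations.
#' @param attrs a `dce_attributes` set.
#' @return `choices` invisibly (columns reordered canonically), or an error
#'   naming the offending rows.
#' @export
validate_choices <- function(choices, attrs) {
  required <- c("respondent_id", "group", "set_id", "alternative",
                names(attrs), "chosen")
  missing <- setdiff(required, names(choices))
  if (length(missing)) {
    stop_invalid("choice data missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyNA(choices[required])) {
    bad <- which(rowSums(is.na(choices[required])) > 0)
    stop_invalid("missing values in choice data at rows: ",
                 paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (!all(choices$chosen %in% c(0, 1))) {
    bad <- which(!choices$chosen %in% c(0, 1))
    stop_invalid("`chosen` must be 0/1; offending rows: ",
                 paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (!all(choices$group %in% c("intervention", "control"))) {
    stop_invalid("`group` must be 'intervention' or 'control'")
  }
  key <- interaction(choices$respondent_id, choices$set_id, drop = TRUE)
  dup <- duplicated(data.frame(key, choices$alternative))
  if (any(dup)) {
    stop_invalid("duplicated (respondent, set, alternative) at rows: ",
                 paste(utils::head(which(dup), 5L), collapse = ", "))
  }
  n_alt <- tapply(choices$chosen, key, length)
  if (any(n_alt != 2L)) {
    bad <- names(n_alt)[n_alt != 2L][1L]
    stop_invalid("choice set ", bad, " does not have exactly 2 alternatives")
  }
  n_chosen <- tapply(choices$chosen, key, sum)
  if (any(n_chosen != 1L)) {
    bad <- names(n_chosen)[n_chosen != 1L][1L]
    stop_invalid("choice set ", bad, " must have exactly 1 chosen alternative (has ",
                 n_chosen[bad], ")")
  }
  grp <- tapply(choices$group, choices$respondent_id,
                function(g) length(unique(g)))
  if (any(grp != 1L)) {
    stop_invalid("respondent ", names(grp)[grp != 1L][1L],
                 " appears in more than one group")
  }
  # level indices within range (delegated to the encoder's range checks)
  invisible(encode_profiles(choices[, names(attrs), drop = FALSE], attrs))
  invisible(choices)
}

#' Encode choice observations as a covariate design matrix
#'
#' One encoded row per alternative: dummy variables for every non-reference
#' level of each categorical attribute and the numeric level value for each
#' continuous attribute (the annual cost column, in euro per year). Column
#' order is deterministic: attribute order, then level order.
#'
#' @param choices validated long-format choice observations.
#' @param attrs a `dce_attributes` set.
#' @return data frame with `respondent_id`, `set_id`, `chosen` and one
#'   numeric column per covariate; covariate names in
#'   `attr(, "covariates")`.
#' @export
encode_design_matrix <- function(choices, attrs) {
  validate_choices(choices, attrs)
  X <- encode_profiles(choices[, names(attrs), drop = FALSE], attrs)
  out <- cbind(
    data.frame(respondent_id = as.character(choices$respondent_id),
               set_id = choices$set_id,
               chosen = as.integer(choices$chosen),
               stringsAsFactors = FALSE),
    as.data.frame(X)
  )
  # data.frame mangles "a.b" style names only if check.names; keep originals
  names(out)[-(1:3)] <- colnames(X)
  attr(out, "covariates") <- colnames(X)
  out
}

#' Read and write long-format choice data
#'
#' Comma-separated UTF-8 text with a header row; writing then reading
#' reproduces the observations exactly. Reading validates the choice-data
#' invariants and fails with row numbers on malformed input.
#'
#' @param choices data frame of observations.
#' @param path CSV file path.
#' @param attrs a `dce_attributes` set used for validation.
#' @return `read_choices` returns the validated data frame;
#'   `write_choices` returns `path` invisibly.
#' @export
write_choices <- function(choices, path, attrs = NULL) {
  if (!is.null(attrs)) validate_choices(choices, attrs)
  utils::write.csv(choices, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path, attrs) {
  if (!file.exists(path)) stop_invalid("choice file not found: ", path)
  choices <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(respondent_id = "character"))
  validate_choices(choices, attrs)
  choices
}

#' Screen for single-attribute dominant responders
#'
#' A dominant responder always chooses the alternative carrying the best
#' level of one attribute. For each attribute, a choice set is informative
#' when exactly one of its two alternatives carries the best level; sets
#' where both or neither alternative does are skipped. A respondent is
#' flagged for an attribute when they have at least one informative set and
#' chose the best-level alternative in every one of them.
#'
#' @param choices validated long-format choice observations.
#' @param attrs a `dce_attributes` set.
#' @param best named integer vector of best level indices per attribute
#'   (default [best_levels()]).
#' @return named list, one character vector of respondent ids per attribute.
#' @export
detect_dominant_responders <- function(choices, attrs, best = best_levels(attrs)) {
  validate_choices(choices, attrs)
  ord <- order(choices$respondent_id, choices$set_id, choices$alternative)
  ch <- choices[ord, ]
  key <- paste(ch$respondent_id, ch$set_id, sep = "\r")
  first <- !duplicated(key)          # alternating rows: alt 1, alt 2 per set
  i1 <- which(first)
  i2 <- i1 + 1L
  out <- vector("list", length(attrs))
  names(out) <- names(attrs)
  resp <- ch$respondent_id[i1]
  for (a in names(attrs)) {
    has_best1 <- ch[[a]][i1] == best[[a]]
    has_best2 <- ch[[a]][i2] == best[[a]]
    informative <- xor(has_best1, has_best2)
    picked_best <- ifelse(has_best1, ch$chosen[i1] == 1L, ch$chosen[i2] == 1L)
    n_inf <- tapply(informative, resp, sum)
    n_hit <- tapply(informative & picked_best, resp, sum)
    flagged <- names(n_inf)[n_inf > 0L & n_hit == n_inf]
    out[[a]] <- sort(flagged)
  }
  out
}
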