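#' Define a DCE attribute
#'
#' An attribute is one dimension of the service being valued (e.g. waiting
#' time to get a medical appointment) together with its ordered levels.
#' Categorical attributes enter the utility function as dummy variables
#' against a reference level; continuous attributes (typically the cost
#' attribute) enter as a single numeric column taking the level's value.
#'
#' @param name attribute name (unique within an attribute set).
#' @param levels character vector of level labels, ordered; at least two,
#'   unique. By convention level 1 is the "usual care" level.
#' @param coding `"categorical"` (dummy coded against `reference`) or
#'   `"continuous"` (single numeric column).
#' @param level_values numeric value per level; required when
#'   `coding = "continuous"` (e.g. annual cost levels 0, 30, 51, 76 euro).
#' @param reference index of the reference level (categorical only),
#'   default 1, the usual-care level.
#' @return an object of class `dce_attribute`.
#' @examples
#' dce_attribute("integration", c("weak", "partial", "full"))
#' dce_attribute("nhs_cost", c("0", "30", "51", "76"),
#'   coding = "continuous", level_values = c(0, 30, 51, 76))
#' @export
dce_attribute <- function(name, levels,
                          coding = c("categorical", "continuous"),
                          level_values = NULL, reference = 1L) {
  coding <- match.arg(coding)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_invalid("attribute `name` must be a non-empty string")
  }
  levels <- as.character(levels)
  if (length(levels) < 2L) {
    stop_invalid("attribute '", name, "' must have at least 2 levels")
  }
  if (anyDuplicated(levels)) {
    stop_invalid("attribute '", name, "' has duplicated level labels")
  }
  if (coding == "continuous") {
    if (is.null(level_values) || length(level_values) != length(levels) ||
        !is.numeric(level_values) || anyNA(level_values)) {
      stop_invalid("attribute '", name,
                   "' is continuous and needs one numeric value per level")
    }
  } else {
    reference <- as.integer(reference)
    if (is.na(reference) || reference < 1L || reference > length(levels)) {
      stop_invalid("attribute '", name, "': reference level index out of range")
    }
  }
  structure(
    list(name = name, levels = levels, coding = coding,
         level_values = if (coding == "continuous") as.numeric(level_values),
         reference = if (coding == "categorical") reference),
    class = "dce_attribute"
  )
}

#' Bundle attributes into an attribute set
#'
#' @param ... `dce_attribute` objects (or a single list of them).
#' @return an object of class `dce_attributes` (a named list).
#' @export
dce_attributes <- function(...) {
  attrs <- list(...)
  if (length(attrs) == 1L && is.list(attrs[[1L]]) &&
      !inherits(attrs[[1L]], "dce_attribute")) {
    attrs <- attrs[[1L]]
  }
  if (length(attrs) == 0L) stop_invalid("attribute set must be non-empty")
  ok <- vapply(attrs, inherits, logical(1), "dce_attribute")
  if (!all(ok)) stop_invalid("all elements must be `dce_attribute` objects")
  nm <- vapply(attrs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop_invalid("attribute names must be unique")
  names(attrs) <- nm
  structure(attrs, class = "dce_attributes")
}

#' @export
print.dce_attributes <- function(x, ...) {
  cat("DCE attribute set (", length(x), " attributes, ",
      prod(n_levels(x)), " full-factorial profiles)\n", sep = "")
  for (a in x) {
    cat(" -", a$name, paste0("[", a$coding, "]"), ":",
        paste(a$levels, collapse = " | "), "\n")
    if (a$coding == "continuous") {
      cat("   values:", paste(a$level_values, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

# level counts per attribute
n_levels <- function(attrs) {
  vapply(attrs, function(a) length(a$levels), integer(1))
}

# names of analysis-coding covariate columns, in attribute order then level
# order: one dummy per non-reference level, one numeric column per
# continuous attribute
covariate_names <- function(attrs) {
  unlist(lapply(attrs, function(a) {
    if (a$coding == "continuous") {
      a$name
    } else {
      paste(a$name, a$levels[-a$reference], sep = ".")
    }
  }), use.names = FALSE)
}

# the single continuous (cost) attribute; errors if absent or ambiguous
cost_attribute <- function(attrs) {
  cont <- Filter(function(a) a$coding == "continuous", attrs)
  if (length(cont) != 1L) {
    stop_invalid("expected exactly one continuous (cost) attribute, found ",
                 length(cont))
  }
  cont[[1L]]
}

#' Best level of each attribute
#'
#' The "best" level is the one a single-attribute (dominant) responder would
#' always chase: by convention the highest-index level for categorical
#' attributes (the fullest form of collaborative care) and the level with
#' the smallest numeric value for continuous attributes (least annual cost
#' to the NHS).
#'
#' @param attrs a `dce_attributes` set.
#' @param override named integer vector of level indices replacing the
#'   convention for specific attributes.
#' @return named integer vector of level indices.
#' @export
best_levels <- function(attrs, override = NULL) {
  best <- vapply(attrs, function(a) {
    if (a$coding == "continuous") which.min(a$level_values) else length(a$levels)
  }, integer(1))
  if (!is.null(override)) {
    bad <- setdiff(names(override), names(best))
    if (length(bad)) stop_invalid("unknown attribute in override: ",
                                  paste(bad, collapse = ", "))
    best[names(override)] <- as.integer(override)
  }
  best
}

#' Encode profiles as a numeric covariate matrix
#'
#' Profiles (rows of level indices, one column per attribute) are encoded
#' with the analysis coding used by the utility model: dummy variables for
#' every non-reference level of each categorical attribute (reference-level
#' profiles encode to all-zero dummies) and the level's numeric value for
#' each continuous attribute. With `all_categorical = TRUE` every attribute
#' is dummy coded against its first level — the factor coding used for
#' design construction and D-efficiency, where the metric of the cost levels
#' is irrelevant.
#'
#' @param profiles matrix or data frame of level indices, columns in
#'   attribute order.
#' @param attrs a `dce_attributes` set.
#' @param all_categorical logical; use design (all-factor) coding.
#' @return numeric matrix with named columns, one row per profile.
#' @export
encode_profiles <- function(profiles, attrs, all_categorical = FALSE) {
  P <- as.matrix(profiles)
  if (ncol(P) != length(attrs)) {
    stop_invalid("profiles have ", ncol(P), " columns but there are ",
                 length(attrs), " attributes")
  }
  storage.mode(P) <- "integer"
  cols <- list()
  for (j in seq_along(attrs)) {
    a <- attrs[[j]]
    L <- length(a$levels)
    lv <- P[, j]
    bad <- which(is.na(lv) | lv < 1L | lv > L)
    if (length(bad)) {
      stop_invalid("profile row ", bad[1L], " references unknown level '",
                   P[bad[1L], j], "' of attribute '", a$name, "'")
    }
    if (!all_categorical && a$coding == "continuous") {
      cols[[a$name]] <- a$level_values[lv]
    } else {
      ref <- if (all_categorical || is.null(a$reference)) 1L else a$reference
      for (l in setdiff(seq_len(L), ref)) {
        cols[[paste(a$name, a$levels[l], sep = ".")]] <- as.numeric(lv == l)
      }
    }
  }
  do.call(cbind, cols)
}

# reference profile (all attributes at their reference / first level)
profile_reference <- function(attrs) {
  p <- vapply(attrs, function(a) a$reference %||% 1L, integer(1))
  names(p) <- names(attrs)
  p
}

#' Read or write an attribute set as YAML
#'
#' @param attrs a `dce_attributes` set.
#' @param path file path.
#' @return `read_attributes` returns a `dce_attributes` set;
#'   `write_attributes` returns `path` invisibly.
#' @export
write_attributes <- function(attrs, path) {
  out <- lapply(unname(attrs), function(a) {
    x <- list(name = a$name, levels = as.list(a$levels), coding = a$coding)
    if (a$coding == "continuous") x$level_values <- as.list(a$level_values)
    if (a$coding == "categorical") x$reference <- a$reference
    x
  })
  yaml::write_yaml(list(attributes = out), path)
  invisible(path)
}

#' @rdname write_attributes
#' @export
read_attributes <- function(path) {
  if (!file.exists(path)) stop_invalid("attribute file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$attributes)) stop_invalid("no `attributes` section in ", path)
  dce_attributes(lapply(raw$attributes, function(a) {
    dce_attribute(a$name, unlist(a$levels), coding = a$coding,
                  level_values = if (!is.null(a$level_values)) unlist(a$level_values),
                  reference = a$reference %||% 1L)
  }))
}
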