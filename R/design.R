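#' Enumerate the full factorial profile space
#'
#' @param attrs a `dce_attributes` set.
#' @return integer matrix of level indices, one row per profile, one column
#'   per attribute; `prod(level counts)` rows, no duplicates.
#' @examples
#' attrs <- pharmacy_dce_attributes()
#' nrow(enumerate_full_factorial(attrs))  # 324 = 3^4 * 4
#' @export
enumerate_full_factorial <- function(attrs) {
  if (!inherits(attrs, "dce_attributes")) attrs <- dce_attributes(attrs)
  L <- n_levels(attrs)
  P <- as.matrix(expand.grid(lapply(L, seq_len), KEEP.OUT.ATTRS = FALSE))
  storage.mode(P) <- "integer"
  colnames(P) <- names(attrs)
  P
}

#' Number of unordered two-alternative choice sets
#'
#' The number of distinct pairwise choice sets that can be formed from
#' `n_profiles` profiles: n(n-1)/2.
#'
#' @param n_profiles number of profiles (>= 2).
#' @return integer count.
#' @examples
#' count_pairwise_choice_sets(324)  # 52326
#' @export
count_pairwise_choice_sets <- function(n_profiles) {
  if (!is.numeric(n_profiles) || length(n_profiles) != 1L ||
      is.na(n_profiles) || n_profiles < 2 || n_profiles != round(n_profiles)) {
    stop_invalid("`n_profiles` must be a single integer >= 2")
  }
  n <- as.double(n_profiles)
  n * (n - 1) / 2
}

#' Minimum DCE sample size (Johnson-Orme rule of thumb)
#'
#' The rule N > 500 c / (t a), with c the largest number of analysis cells
#' (level count), t the number of choice tasks per respondent, and a the
#' number of alternatives per task; the minimum sample size is the ceiling
#' of 500 c / (t a).
#'
#' @param c largest level count among the attributes.
#' @param t choice tasks per respondent.
#' @param a alternatives per task.
#' @return minimum number of respondents.
#' @examples
#' min_sample_size(c = 4, t = 4, a = 2)  # 250
#' @export
min_sample_size <- function(c, t, a) {
  for (arg in list(c = c, t = t, a = a)) {
    if (!is.numeric(arg) || length(arg) != 1L || is.na(arg) || arg <= 0) {
      stop_invalid("`c`, `t` and `a` must all be positive numbers")
    }
  }
  as.integer(ceiling(500 * c / (t * a)))
}

# ---- D-efficiency ----------------------------------------------------------

# Design-coding moment machinery. X is the all-factor dummy coding of the
# alternative profiles; the intercept is profiled out so the criterion is the
# determinant of the population covariance of the coded columns. Under this
# convention the level-balanced, mutually independent ("orthogonal") design
# maximizes the determinant, so relative efficiency lies in (0, 1].
.design_logdet_ideal <- function(attrs) {
  L <- n_levels(attrs)
  # per attribute, det of the multinomial covariance of its L-1 dummies is
  # the product of all L level frequencies; balanced gives L^-L
  sum(-L * log(L))
}

.design_ncols <- function(attrs) sum(n_levels(attrs) - 1L)

# population covariance log-determinant of the coded rows, or -Inf
.design_logdet <- function(X) {
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X))
  M <- crossprod(Xc) / n
  d <- determinant(M, logarithm = TRUE)
  if (d$sign <= 0) return(-Inf)
  as.numeric(d$modulus)
}

#' Relative D-efficiency of a choice design
#'
#' Computes the D-criterion of the design's coded alternatives relative to a
#' perfectly level-balanced orthogonal ideal. All attributes are treated as
#' factors (the coding under which the fractional design is constructed) and
#' the intercept is profiled out, i.e. the criterion is
#' `det(cov(X))^(1/p)` for the dummy-coded alternative matrix X with p
#' columns, divided by the same quantity for the balanced orthogonal ideal.
#' The result is invariant to the ordering of choice sets and lies in
#' (0, 1], with 1 attained exactly by balanced orthogonal designs.
#'
#' @param design a `dce_design`, or a matrix/data frame of profile level
#'   indices (rows = alternatives).
#' @param attrs a `dce_attributes` set (defaults to the design's own).
#' @return relative D-efficiency, a fraction in (0, 1].
#' @export
d_efficiency <- function(design, attrs = NULL) {
  if (inherits(design, "dce_design")) {
    attrs <- attrs %||% design$attributes
    P <- as.matrix(design$sets[, names(attrs), drop = FALSE])
  } else {
    if (is.null(attrs)) stop_invalid("`attrs` is required when `design` is a profile matrix")
    P <- as.matrix(design)
  }
  if (nrow(P) == 0L) stop_invalid("design is empty")
  X <- encode_profiles(P, attrs, all_categorical = TRUE)
  ld <- .design_logdet(X)
  if (!is.finite(ld)) {
    Xc <- sweep(X, 2L, colMeans(X))
    qrx <- qr(Xc)
    dropped <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    stop_invalid("design matrix is singular; collinear/constant columns: ",
                 paste(dropped, collapse = ", "))
  }
  p <- ncol(X)
  exp((ld - .design_logdet_ideal(attrs)) / p)
}

# Fedorov exchange on the profile fraction. Works on the intercept-augmented
# moment matrix A = Z'Z (Z = [1, X]) whose determinant equals n^(p+1) times
# the covariance determinant, so swaps are rank-one updates evaluated in
# closed form via the matrix determinant lemma. Returns selected row indices
# into `X_all` plus the monotone log-determinant trajectory.
.fedorov_exchange <- function(X_all, n_rows, max_iter = 10000L, tol = 1e-9) {
  n_cand <- nrow(X_all)
  Z <- cbind(1, X_all)
  if (n_rows < ncol(Z)) {
    stop_invalid("infeasible fraction: ", n_rows, " profiles cannot identify ",
                 ncol(X_all), " coded columns plus the intercept")
  }
  start_ok <- FALSE
  for (attempt in 1:50) {
    rows <- sample.int(n_cand, n_rows)
    if (qr(Z[rows, , drop = FALSE])$rank < ncol(Z)) next
    A <- crossprod(Z[rows, , drop = FALSE])
    d <- determinant(A, logarithm = TRUE)
    if (d$sign > 0 && is.finite(d$modulus)) { start_ok <- TRUE; break }
  }
  if (!start_ok) stop_invalid("could not find a non-singular starting fraction")
  logdet <- as.numeric(d$modulus)
  traj <- logdet
  in_design <- logical(n_cand)
  in_design[rows] <- TRUE
  for (iter in seq_len(max_iter)) {
    Ainv <- solve(A)
    B <- Z %*% Ainv                      # z' A^-1 for every candidate row
    s <- rowSums(B * Z)                  # z' A^-1 z
    best <- 1 + tol
    best_i <- 0L
    best_y <- 0L
    cand <- which(!in_design)
    for (i in seq_len(n_rows)) {
      zx <- Z[rows[i], ]
      alpha <- 1 - s[rows[i]]
      q <- B[cand, , drop = FALSE] %*% zx
      ratio <- alpha * (1 + s[cand]) + q^2
      k <- which.max(ratio)
      if (ratio[k] > best) {
        best <- ratio[k]
        best_i <- i
        best_y <- cand[k]
      }
    }
    if (best_i == 0L) break
    zx <- Z[rows[best_i], ]
    zy <- Z[best_y, ]
    A <- A - tcrossprod(zx) + tcrossprod(zy)
    in_design[rows[best_i]] <- FALSE
    in_design[best_y] <- TRUE
    rows[best_i] <- best_y
    logdet <- logdet + log(best)
    traj <- c(traj, logdet)
  }
  list(rows = rows, logdet = logdet, trajectory = traj)
}

#' Randomly pair profiles into two-alternative choice sets
#'
#' Pairs profiles without reuse (each profile appears in exactly one set),
#' re-drawing locally where a pairing would put two identical profiles in
#' the same set. Deterministic given `seed`.
#'
#' @param profiles matrix of profile level indices (even row count).
#' @param seed integer seed.
#' @param attrs optional `dce_attributes` set; when supplied with
#'   `avoid_dominated = TRUE`, pairings where one alternative is weakly
#'   better on every attribute (per [best_levels()] direction) are also
#'   re-drawn where possible.
#' @param avoid_dominated logical, default `FALSE` (orthogonal designs
#'   accept the risk of the occasional dominated pairing).
#' @return data frame of choice sets: `set_id`, `alternative` ("A"/"B") and
#'   one column per attribute.
#' @export
pair_profiles <- function(profiles, seed, attrs = NULL, avoid_dominated = FALSE) {
  P <- as.matrix(profiles)
  n <- nrow(P)
  if (n < 2L || n %% 2L != 0L) {
    stop_invalid("`profiles` must have a positive even number of rows")
  }
  bad_pair <- function(i, j) {
    if (all(P[i, ] == P[j, ])) return(TRUE)
    if (avoid_dominated && !is.null(attrs)) return(.dominates(P[i, ], P[j, ], attrs) ||
                                                   .dominates(P[j, ], P[i, ], attrs))
    FALSE
  }
  perm <- with_seed(seed, sample.int(n))
  # repair offending pairs by swapping their second member with any element
  # whose own pair stays valid after the exchange
  for (k in seq_len(n / 2L)) {
    a <- perm[2L * k - 1L]
    b <- perm[2L * k]
    if (!bad_pair(a, b)) next
    fixed <- FALSE
    for (m in setdiff(seq_len(n), c(2L * k - 1L, 2L * k))) {
      partner <- if (m %% 2L == 0L) m - 1L else m + 1L
      if (partner %in% c(2L * k - 1L, 2L * k)) next
      if (!bad_pair(a, perm[m]) && !bad_pair(perm[partner], b)) {
        tmp <- perm[2L * k]
        perm[2L * k] <- perm[m]
        perm[m] <- tmp
        fixed <- TRUE
        break
      }
    }
    if (!fixed) {
      stop_invalid("cannot pair profiles without an identical-profile set")
    }
  }
  idx <- matrix(perm, ncol = 2L, byrow = TRUE)
  sets <- data.frame(
    set_id = rep(seq_len(n / 2L), each = 2L),
    alternative = rep(c("A", "B"), n / 2L),
    stringsAsFactors = FALSE
  )
  cbind(sets, as.data.frame(P[as.vector(t(idx)), , drop = FALSE]))
}

# strict dominance of profile x over y under the best-level direction
.dominates <- function(x, y, attrs) {
  best <- best_levels(attrs)
  better <- FALSE
  for (j in seq_along(attrs)) {
    a <- attrs[[j]]
    if (a$coding == "continuous") {
      vx <- a$level_values[x[j]]; vy <- a$level_values[y[j]]
      sx <- if (a$level_values[best[j]] <= min(a$level_values)) -vx else vx
      sy <- if (a$level_values[best[j]] <= min(a$level_values)) -vy else vy
    } else {
      sx <- x[j]; sy <- y[j]
    }
    if (sx < sy) return(FALSE)
    if (sx > sy) better <- TRUE
  }
  better
}

#' Allocate choice sets into equal-sized blocks
#'
#' Blocks are the questionnaire versions: each respondent sees the sets of
#' one block only. Assignment is a seeded random partition into equal-sized
#' blocks.
#'
#' @param sets choice-set data frame as produced by [pair_profiles()].
#' @param n_blocks number of blocks; must divide the number of sets.
#' @param seed integer seed.
#' @param attrs optional `dce_attributes` set; when given, the returned
#'   design carries its D-efficiency.
#' @return a `dce_design`.
#' @export
block_design <- function(sets, n_blocks, seed, attrs = NULL) {
  ids <- unique(sets$set_id)
  n_sets <- length(ids)
  if (n_blocks < 1L || n_sets %% n_blocks != 0L) {
    stop_invalid(n_sets, " choice sets cannot be split into ", n_blocks,
                 " equal blocks")
  }
  shuffled <- with_seed(seed, sample(ids))
  block_of <- stats::setNames(rep(seq_len(n_blocks), each = n_sets / n_blocks),
                              shuffled)
  sets$block <- as.integer(block_of[as.character(sets$set_id)])
  sets <- sets[order(sets$block, sets$set_id, sets$alternative), ]
  rownames(sets) <- NULL
  front <- c("set_id", "block", "alternative")
  sets <- sets[, c(front, setdiff(names(sets), front))]
  design <- structure(
    list(attributes = attrs, sets = sets, n_blocks = as.integer(n_blocks),
         d_efficiency = NA_real_, seed = as.integer(seed)),
    class = "dce_design"
  )
  if (!is.null(attrs)) {
    # degenerate hand-built designs (too few sets for the coded columns)
    # are allowed through with an undefined efficiency
    design$d_efficiency <- tryCatch(d_efficiency(design),
                                    error = function(e) NA_real_)
  }
  design
}

#' Search for a D-efficient fractional choice design
#'
#' Selects a fraction of `2 * n_sets` distinct profiles from the full
#' factorial by Fedorov exchange (repeated single-profile swaps that improve
#' the D-criterion, from random starts), then randomly pairs the fraction
#' into two-alternative choice sets and blocks them into questionnaire
#' versions. With `pairing = "independent"` two fractions of `n_sets`
#' profiles are selected by independent exchanges and paired index-wise
#' instead. Deterministic given `seed`.
#'
#' @param attrs a `dce_attributes` set.
#' @param n_sets number of choice sets (divisible by `n_blocks`).
#' @param n_blocks number of questionnaire blocks.
#' @param seed integer seed.
#' @param restarts number of random exchange restarts (best design kept).
#' @param max_iter cap on exchange iterations per restart.
#' @param pairing `"within"` (pair one 2 n fraction) or `"independent"`.
#' @param avoid_dominated passed to [pair_profiles()].
#' @return a `dce_design` with `d_efficiency` filled in and the monotone
#'   exchange trajectory in `attr(design, "trajectory")`.
#' @examples
#' \donttest{
#' attrs <- pharmacy_dce_attributes()
#' des <- search_fractional_design(attrs, n_sets = 36, n_blocks = 9, seed = 1)
#' des$d_efficiency
#' }
#' @export
search_fractional_design <- function(attrs, n_sets, n_blocks, seed,
                                     restarts = 10L, max_iter = 10000L,
                                     pairing = c("within", "independent"),
                                     avoid_dominated = FALSE) {
  pairing <- match.arg(pairing)
  if (!inherits(attrs, "dce_attributes")) attrs <- dce_attributes(attrs)
  full <- enumerate_full_factorial(attrs)
  if (n_sets < 1L || n_blocks < 1L || n_sets %% n_blocks != 0L) {
    stop_invalid("`n_sets` must be a positive multiple of `n_blocks`")
  }
  if (2L * n_sets > nrow(full)) {
    stop_invalid("2 * n_sets = ", 2L * n_sets, " exceeds the full factorial (",
                 nrow(full), " profiles)")
  }
  X_all <- encode_profiles(full, attrs, all_categorical = TRUE)
  run_search <- function(n_rows, seed_offset) {
    best <- NULL
    for (r in seq_len(restarts)) {
      res <- with_seed(derive_seed(seed, seed_offset + r),
                       .fedorov_exchange(X_all, n_rows, max_iter = max_iter))
      if (is.null(best) || res$logdet > best$logdet) best <- res
    }
    best
  }
  if (pairing == "within") {
    sel <- run_search(2L * n_sets, 0L)
    sets <- pair_profiles(full[sel$rows, , drop = FALSE],
                          seed = derive_seed(seed, 101L),
                          attrs = attrs, avoid_dominated = avoid_dominated)
    traj <- sel$trajectory
  } else {
    sel_a <- run_search(n_sets, 0L)
    sel_b <- run_search(n_sets, 1000L)
    A <- full[sel_a$rows, , drop = FALSE]
    B <- full[with_seed(derive_seed(seed, 102L), sample(sel_b$rows)), ,
              drop = FALSE]
    # nudge index-wise identical pairs apart by rotating B
    for (i in seq_len(n_sets)) {
      if (all(A[i, ] == B[i, ])) {
        j <- which(!apply(B, 1L, function(b) all(b == A[i, ])))[1L]
        if (is.na(j)) stop_invalid("cannot pair fractions without identical sets")
        tmp <- B[i, ]; B[i, ] <- B[j, ]; B[j, ] <- tmp
      }
    }
    inter <- matrix(rbind(A, B)[rep(seq_len(n_sets), each = 2L) +
                                  c(0L, n_sets), ], ncol = ncol(A))
    colnames(inter) <- colnames(A)
    sets <- data.frame(set_id = rep(seq_len(n_sets), each = 2L),
                       alternative = rep(c("A", "B"), n_sets))
    sets <- cbind(sets, as.data.frame(inter))
    traj <- sel_a$trajectory
  }
  design <- block_design(sets, n_blocks, seed = derive_seed(seed, 202L),
                         attrs = attrs)
  design$seed <- as.integer(seed)
  attr(design, "trajectory") <- traj
  design
}

#' @export
print.dce_design <- function(x, ...) {
  n_sets <- length(unique(x$sets$set_id))
  cat("DCE design:", n_sets, "two-alternative choice sets in", x$n_blocks,
      "blocks of", n_sets / x$n_blocks, "\n")
  if (!is.na(x$d_efficiency)) {
    cat(sprintf("relative D-efficiency: %.1f%%\n", 100 * x$d_efficiency))
  }
  cat("seed:", x$seed, "\n")
  invisible(x)
}

#' Read or write a design as delimited text plus a sidecar config
#'
#' The design itself is a CSV (one row per alternative: set id, block,
#' alternative label, one column per attribute level index); the sidecar
#' YAML holds the attribute specification, seed and block count.
#'
#' @param design a `dce_design`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.attrs.yaml`.
#' @return `read_design` returns a `dce_design`; `write_design` returns
#'   `path` invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design$sets, path, row.names = FALSE, quote = FALSE)
  sidecar <- paste0(path, ".attrs.yaml")
  write_attributes(design$attributes, sidecar)
  meta <- yaml::read_yaml(sidecar)
  meta$n_blocks <- design$n_blocks
  meta$seed <- design$seed
  meta$d_efficiency <- design$d_efficiency
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  sets <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".attrs.yaml"))
  attrs <- dce_attributes(lapply(meta$attributes, function(a) {
    dce_attribute(a$name, unlist(a$levels), coding = a$coding,
                  level_values = if (!is.null(a$level_values)) unlist(a$level_values),
                  reference = a$reference %||% 1L)
  }))
  design <- structure(
    list(attributes = attrs, sets = sets,
         n_blocks = as.integer(meta$n_blocks),
         d_efficiency = NA_real_,
         seed = as.integer(meta$seed %||% NA_integer_)),
    class = "dce_design"
  )
  # recompute rather than trust the (precision-limited) sidecar value
  design$d_efficiency <- tryCatch(d_efficiency(design),
                                  error = function(e) NA_real_)
  design
}
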