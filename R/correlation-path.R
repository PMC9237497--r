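#' Trait correlation matrix with significance stars
#'
#' Computes the pairwise correlation matrix among traits at a chosen
#' aggregation level of the trial data: raw plot values, line means
#' (replicates averaged) or population (treatment) means. Spearman's rank
#' correlation (average ranks for ties) is the default, matching the
#' trial's reported analysis; Pearson is available and is the appropriate
#' input for [path_analysis()]. P-values use the t approximation with
#' n - 2 degrees of freedom; stars mark p < 0.001 (***), < 0.01 (**) and
#' < 0.05 (*).
#'
#' A trait with zero variance at the chosen level has no defined
#' correlation: its cells are returned as NA and the trait is listed in
#' the result's `degenerate` field (never silently set to 0).
#'
#' @param table A trait table.
#' @param traits Trait codes (default: all in the table).
#' @param method "spearman" (default) or "pearson".
#' @param level "line" (default), "plot" or "population".
#' @param variety,generation Optional cell filters.
#' @return An object of class `trait_correlations`: list with `r`, `p`,
#'   `stars` matrices, `n`, `method`, `level`, `degenerate`.
#' @export
trait_correlations <- function(table, traits = NULL,
                               method = c("spearman", "pearson"),
                               level = c("line", "plot", "population"),
                               variety = NULL, generation = NULL) {
  method <- match.arg(method)
  level <- match.arg(level)
  table <- as_tibble(table)
  if (!is.null(variety)) table <- filter(table, .data$variety %in% .env$variety)
  if (!is.null(generation)) table <- filter(table, .data$generation %in% .env$generation)
  traits <- traits %||% unique(table$trait)
  miss <- setdiff(traits, unique(table$trait))
  if (length(miss) > 0) {
    abort(paste0("traits not in table: ", paste(miss, collapse = ", "), "."))
  }
  table <- filter(table, .data$trait %in% traits)
  unit <- switch(level,
    plot = c("variety", "generation", "treatment", "line", "replicate"),
    line = c("variety", "generation", "treatment", "line"),
    population = c("variety", "generation", "treatment"))
  wide <- table |>
    summarise(value = mean(.data$value), .by = all_of(c(unit, "trait"))) |>
    pivot_wider(names_from = "trait", values_from = "value")
  x <- as.matrix(wide[, traits, drop = FALSE])
  n <- nrow(x)
  if (n < 3) abort("need at least 3 observations at the chosen level.")
  degenerate <- traits[apply(x, 2, function(col) var(col) == 0)]
  r <- suppressWarnings(cor(x, method = method))
  diag(r) <- 1
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  for (d in degenerate) r[d, d] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(p) <- NA_real_
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  structure(
    list(r = r, p = p, stars = stars, n = n, method = method, level = level,
         degenerate = degenerate),
    class = "trait_correlations"
  )
}

#' @export
print.trait_correlations <- function(x, digits = 3, ...) {
  cat("<trait_correlations> method =", x$method, " level =", x$level,
      " n =", x$n, "\n")
  disp <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
                 nrow(x$r), dimnames = dimnames(x$r))
  disp[is.na(x$r)] <- "NA"
  print(disp, quote = FALSE)
  if (length(x$degenerate) > 0) {
    cat("degenerate (zero-variance) traits:",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.trait_correlations <- function(x, ...) {
  labs <- rownames(x$r)
  expand_grid(trait1 = labs, trait2 = labs) |>
    filter(match(.data$trait1, labs) < match(.data$trait2, labs)) |>
    mutate(
      estimate = x$r[cbind(.data$trait1, .data$trait2)],
      p.value = x$p[cbind(.data$trait1, .data$trait2)],
      stars = x$stars[cbind(.data$trait1, .data$trait2)]
    )
}

#' Path-coefficient analysis of yield components
#'
#' Decomposes each component trait's total correlation with yield into a
#' direct effect (the path coefficient) and indirect effects routed
#' through the other components. The direct effects solve the normal
#' equations `Rxx b = rxy`; the indirect effect of predictor i via
#' predictor j is `r_ij * b_j`; the residual path is
#' `E1 = sqrt(1 - sum(b * rxy))`, clipped at 0 (and flagged) if the
#' explained share exceeds 1 numerically. By construction
#' `r_iy = b_i + sum_j indirect[i, j]` exactly.
#'
#' @param x Either a predictor correlation matrix `Rxx` (symmetric,
#'   positive definite) or a [trait_correlations()] object (Pearson
#'   recommended -- the decomposition identities hold for the matrix that
#'   generated `rxy`).
#' @param rxy Predictor-yield correlations (when `x` is a matrix).
#' @param yield Yield trait code (when `x` is a `trait_correlations`).
#' @param predictors Component traits to include; defaults to the
#'   standard yield components `PPP, BPP, SPP, SW, PL, HI` when present.
#' @param rcond_min Reciprocal-condition-number threshold below which the
#'   system is treated as singular.
#' @return An object of class `path_result`: `direct` (named vector),
#'   `indirect` (matrix, diagonal NA), `r_xy`, `residual_e1`, `clipped`,
#'   `ranking` (increasing direct effect).
#' @export
#' @examples
#' rxx <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' path_analysis(rxx, rxy = c(a = .7, b = .6))
path_analysis <- function(x, rxy = NULL, yield = "PY", predictors = NULL,
                          rcond_min = 1e-10) {
  if (inherits(x, "trait_correlations")) {
    labs <- rownames(x$r)
    predictors <- predictors %||%
      intersect(c("PPP", "BPP", "SPP", "SW", "PL", "HI"), labs)
    if (!yield %in% labs) abort(paste0("yield trait '", yield, "' not in the correlation matrix."))
    if (length(x$degenerate) > 0 &&
        any(c(yield, predictors) %in% x$degenerate)) {
      abort("degenerate traits among yield/predictors; remove them first.")
    }
    rxx <- x$r[predictors, predictors, drop = FALSE]
    rxy <- x$r[predictors, yield]
  } else {
    rxx <- as.matrix(x)
    if (is.null(rxy)) abort("`rxy` is required when `x` is a matrix.")
    if (is.null(rownames(rxx))) {
      rownames(rxx) <- colnames(rxx) <- names(rxy) %||%
        paste0("x", seq_len(nrow(rxx)))
    }
    if (is.null(names(rxy))) names(rxy) <- rownames(rxx)
    rxy <- rxy[rownames(rxx)]
  }
  if (nrow(rxx) != ncol(rxx) || length(rxy) != nrow(rxx)) {
    abort("dimension mismatch between Rxx and rxy.")
  }
  if (max(abs(rxx - t(rxx))) > 1e-8) abort("Rxx must be symmetric.")
  if (rcond(rxx) < rcond_min) {
    abort("Rxx is numerically singular; remove a collinear trait and retry.")
  }
  b <- solve(rxx, rxy)
  indirect <- sweep(rxx, 2, b, `*`)   # I[i, j] = r_ij * b_j
  diag(indirect) <- NA_real_
  explained <- sum(b * rxy)
  clipped <- explained > 1
  e1 <- sqrt(max(0, 1 - explained))
  ranking <- names(b)[order(b, names(b))]  # increasing direct effect, ties by label
  structure(
    list(direct = b, indirect = indirect, r_xy = rxy,
         residual_e1 = e1, clipped = clipped, ranking = ranking),
    class = "path_result"
  )
}

#' @export
print.path_result <- function(x, digits = 4, ...) {
  cat("<path_result>\n direct effects:\n")
  print(round(x$direct, digits))
  cat(" residual E1 =", round(x$residual_e1, digits),
      if (x$clipped) "(clipped: explained share exceeded 1)" else "", "\n")
  cat(" increasing contribution:", paste(x$ranking, collapse = " < "), "\n")
  invisible(x)
}

#' @export
tidy.path_result <- function(x, ...) {
  tibble(
    term = names(x$direct),
    direct = unname(x$direct),
    indirect_total = rowSums(x$indirect, na.rm = TRUE),
    r_total = unname(x$r_xy)
  )
}

#' @export
glance.path_result <- function(x, ...) {
  tibble(residual_e1 = x$residual_e1, clipped = x$clipped,
         n_predictors = length(x$direct))
}

#' Order predictors by their contribution to yield
#'
#' Reproduces the "increasing trend" chains of a path analysis report:
#' predictors ordered by direct effect, either signed (default, matching
#' the `<` chains) or by absolute magnitude; ties break lexicographically.
#'
#' @param path A [path_analysis()] result.
#' @param by "signed" (default) or "absolute".
#' @return Character vector of predictor labels in increasing order.
#' @export
contribution_ranking <- function(path, by = c("signed", "absolute")) {
  stopifnot(inherits(path, "path_result"))
  by <- match.arg(by)
  key <- if (by == "signed") path$direct else abs(path$direct)
  names(key)[order(key, names(key))]
}
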