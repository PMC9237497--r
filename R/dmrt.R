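#' Duncan least significant range
#'
#' The least significant range for comparing the extremes of `p` ordered
#' means in Duncan's multiple range test:
#' `LSR(p) = q(p, df_e, alpha_p) * se_mean`, where `q` is the studentized
#' range quantile evaluated at Duncan's protected level
#' `alpha_p = 1 - (1 - alpha)^(p - 1)`. Critical values are computed from
#' the studentized range distribution ([stats::qtukey()]) rather than
#' historical tables, so any error degrees of freedom are supported.
#'
#' @param p Span (number of ordered means between and including the pair
#'   compared), `p >= 2`; vectorized.
#' @param df_e Error degrees of freedom (>= 1).
#' @param alpha Nominal per-comparison significance level in (0, 1).
#' @param se_mean Standard error of a group mean (> 0).
#' @return Numeric vector of least significant ranges, non-decreasing in
#'   `p`.
#' @export
#' @examples
#' duncan_lsr(2:4, df_e = 20, alpha = 0.05, se_mean = 1)
duncan_lsr <- function(p, df_e, alpha, se_mean) {
  check_finite(p, "p")
  if (any(p < 2) || any(p != trunc(p))) abort("`p` must be integers >= 2.")
  check_finite(df_e, "df_e")
  if (df_e < 1) abort("`df_e` must be >= 1.")
  check_finite(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  check_positive(se_mean, "se_mean")
  alpha_p <- 1 - (1 - alpha)^(p - 1)
  qtukey(1 - alpha_p, nmeans = p, df = df_e) * se_mean
}

# Stepwise Duncan span acceptance: spans of sorted (descending) means are
# visited widest first; a span is declared homogeneous when it is
# contained in an already-accepted span (protection) or its range does
# not exceed LSR(span width). Returns the accepted spans as a logical
# "sharing" matrix plus the maximal homogeneous spans.
duncan_spans <- function(means_sorted, lsr) {
  m <- length(means_sorted)
  accepted <- list()
  contained <- function(i, j) {
    any(vapply(accepted, function(s) s[1] <= i && j <= s[2], TRUE))
  }
  if (m >= 2) {
    for (width in seq(m, 2)) {
      for (i in seq_len(m - width + 1)) {
        j <- i + width - 1
        if (contained(i, j)) next
        if (means_sorted[i] - means_sorted[j] <= lsr[width - 1]) {
          accepted <- c(accepted, list(c(i, j)))
        }
      }
    }
  }
  # every index not inside any accepted span forms its own (singleton) span
  covered <- rep(FALSE, m)
  for (s in accepted) covered[s[1]:s[2]] <- TRUE
  spans <- c(accepted, lapply(which(!covered), function(i) c(i, i)))
  spans[order(vapply(spans, `[`, 0, 1), vapply(spans, `[`, 0, 2))]
}

#' Duncan's multiple range test with compact letter display
#'
#' Orders the group means descending, applies Duncan's stepwise multiple
#' range procedure (a span of ordered means is homogeneous when its range
#' does not exceed the least significant range for its width, and spans
#' inside an already-accepted homogeneous span are not retested), and
#' converts the resulting maximal homogeneous spans into the familiar
#' superscript letters: groups share a letter exactly when the procedure
#' does not separate them, and the group with the largest mean always
#' carries "a".
#'
#' @param means Named numeric vector of group means (names = group
#'   labels).
#' @param n Observations per group (balanced; a single number or a vector
#'   of identical values).
#' @param mse Error mean square from the ANOVA the means came from
#'   (>= 0).
#' @param df_e Error degrees of freedom.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `dmrt`: tibble of groups (descending mean,
#'   ties broken by label) with letter strings, plus the LSR table,
#'   `alpha`, `df_e` and `se_mean`.
#' @export
#' @examples
#' dm <- dmrt_letters(c(A = 10, B = 10.2, C = 14), n = 5, mse = 0.5,
#'                    df_e = 12)
#' tidy(dm)
dmrt_letters <- function(means, n, mse, df_e, alpha = 0.05) {
  if (is.null(names(means)) || anyDuplicated(names(means))) {
    abort("`means` must have unique names.")
  }
  check_finite(means, "means")
  check_positive(mse, "mse", strict = FALSE)
  if (length(unique(n)) != 1) {
    abort("unbalanced group sizes; Duncan's test here requires equal n per group.")
  }
  n <- n[1]
  check_positive(n, "n")
  m <- length(means)
  # ties in means broken by label so output is deterministic
  ord <- order(-means, names(means))
  ms <- means[ord]
  se_mean <- sqrt(mse / n)
  lsr <- if (m >= 2) {
    if (se_mean > 0) {
      duncan_lsr(2:m, df_e = df_e, alpha = alpha, se_mean = se_mean)
    } else {
      rep(0, m - 1)
    }
  } else {
    numeric(0)
  }
  spans <- duncan_spans(unname(ms), lsr)
  letter_strings <- rep("", m)
  for (s in seq_along(spans)) {
    idx <- spans[[s]][1]:spans[[s]][2]
    letter_strings[idx] <- paste0(letter_strings[idx], letters[s])
  }
  groups <- tibble(
    group = names(ms), mean = unname(ms), letters = letter_strings
  )
  structure(
    list(groups = groups, lsr = lsr, spans = spans, alpha = alpha,
         df_e = df_e, se_mean = se_mean),
    class = "dmrt"
  )
}

#' @export
print.dmrt <- function(x, ...) {
  cat("<dmrt> alpha =", x$alpha, " df_e =", x$df_e,
      " se(mean) =", signif(x$se_mean, 4), "\n")
  print(as.data.frame(x$groups), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.dmrt <- function(x, ...) x$groups

#' @export
glance.dmrt <- function(x, ...) {
  tibble(n_groups = nrow(x$groups), alpha = x$alpha, df_e = x$df_e,
         se_mean = x$se_mean)
}

#' Letter-sharing relation of a Duncan test
#'
#' Two groups are "not separated" by the test when they share at least
#' one letter. Exposed as a symmetric logical matrix because letter
#' strings themselves are representation-dependent while the sharing
#' relation is the statistical content.
#'
#' @param x A [dmrt_letters()] result.
#' @return Symmetric logical matrix over the groups (TRUE = share a
#'   letter).
#' @export
dmrt_sharing <- function(x) {
  stopifnot(inherits(x, "dmrt"))
  g <- x$groups
  m <- nrow(g)
  out <- matrix(FALSE, m, m, dimnames = list(g$group, g$group))
  for (s in x$spans) {
    idx <- s[1]:s[2]
    out[idx, idx] <- TRUE
  }
  diag(out) <- TRUE
  out
}
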