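#' One-way ANOVA among lines within a trial cell
#'
#' Fits the balanced one-way analysis of variance among the lines of one
#' (variety, generation, treatment, trait) cell. The among-line mean
#' square (MSG) and the pooled within-line error mean square (MSE) are
#' the moment inputs for [genetic_parameters()]:
#' `MSG = r * sum((line mean - grand mean)^2) / (g - 1)` and MSE pools
#' the within-line replicate variance.
#'
#' @param table A trait table (see [simulate_trait_table()]).
#' @param variety,generation,treatment,trait Cell selectors.
#' @return An object of class `lines_anova`: a list with `msg`, `mse`,
#'   `df_g`, `df_e`, `f` (NA when MSE is 0), `p`, `r` (replications per
#'   line), `n_lines`, `grand_mean`, `se_mean` and the cell selectors.
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   variety = "V", generation = "M2", treatment = "C",
#'   line = rep(c("A", "B", "C"), each = 2), replicate = rep(1:2, 3),
#'   trait = "y", value = c(10, 12, 14, 16, 18, 20))
#' a <- anova_lines(tab, "V", "M2", "C", "y")
#' c(a$msg, a$mse)  # 32, 2
anova_lines <- function(table, variety, generation, treatment, trait) {
  cell <- as_tibble(table) |>
    filter(.data$variety == .env$variety,
           .data$generation == .env$generation,
           .data$treatment == .env$treatment,
           .data$trait == .env$trait)
  if (nrow(cell) == 0) abort("requested cell is empty.")
  counts <- cell |> count(.data$line)
  if (nrow(counts) < 2) abort("cell must contain at least 2 lines.")
  if (length(unique(counts$n)) != 1) {
    bad <- counts$line[counts$n != stats::median(counts$n)]
    abort(paste0("unbalanced cell: lines with deviant replicate counts: ",
                 paste(bad, collapse = ", "), "."))
  }
  r <- counts$n[1]
  if (r < 2) abort("each line needs at least 2 replicates.")
  fit <- suppressWarnings(anova(lm(value ~ factor(line), data = cell)))
  msg <- fit$`Mean Sq`[1]
  mse <- fit$`Mean Sq`[2]
  grand_mean <- mean(cell$value)
  # zap numerical dust from an exact fit (all values identical)
  eps <- 1e-12 * max(1, mean(cell$value^2))
  if (msg < eps) msg <- 0
  if (mse < eps) mse <- 0
  structure(
    list(
      msg = msg, mse = mse,
      df_g = fit$Df[1], df_e = fit$Df[2],
      f = if (mse > 0) msg / mse else NA_real_,
      p = if (mse > 0) fit$`Pr(>F)`[1] else NA_real_,
      r = r, n_lines = nrow(counts),
      grand_mean = grand_mean,
      se_mean = sd(cell$value) / sqrt(nrow(cell)),
      variety = variety, generation = generation,
      treatment = treatment, trait = trait
    ),
    class = "lines_anova"
  )
}

#' @export
print.lines_anova <- function(x, ...) {
  cat("<lines_anova> ", x$variety, "/", x$generation, "/", x$treatment, "/",
      x$trait, "\n", sep = "")
  cat(sprintf("  MSG %.4g (df %d)  MSE %.4g (df %d)  F %.4g  p %.4g  r %d\n",
              x$msg, x$df_g, x$mse, x$df_e, x$f, x$p, x$r))
  invisible(x)
}

#' @export
tidy.lines_anova <- function(x, ...) {
  tibble(term = c("line", "residual"),
         df = c(x$df_g, x$df_e),
         meansq = c(x$msg, x$mse),
         statistic = c(x$f, NA_real_),
         p.value = c(x$p, NA_real_))
}

#' Genetic advance as percent of the mean
#'
#' The expected gain from truncation selection expressed as a percentage
#' of the population mean, `GA = k * GCV * sqrt(h2/100)`, algebraically
#' identical to `100 * k * sigma_p * h2 / mean` with `h2` as a fraction.
#' The constant `k` is the standardized selection differential; 2.64
#' corresponds to a 1% selection intensity.
#'
#' @param gcv_pct Genotypic coefficient of variation, percent (>= 0).
#' @param h2_pct Broad-sense heritability, percent, in [0, 100].
#' @param k Selection-intensity constant (default 2.64).
#' @return Numeric vector of GA as percent of the mean (full precision;
#'   round only for presentation).
#' @export
#' @examples
#' genetic_advance_percent(7.43, 82.46)  # ~17.81
genetic_advance_percent <- function(gcv_pct, h2_pct, k = 2.64) {
  check_positive(gcv_pct, "gcv_pct", strict = FALSE)
  check_finite(h2_pct, "h2_pct")
  if (any(h2_pct < 0 | h2_pct > 100)) abort("`h2_pct` must lie in [0, 100].")
  check_positive(k, "k")
  k * gcv_pct * sqrt(h2_pct / 100)
}

#' Genetic parameters from ANOVA mean squares
#'
#' Moment estimation of the genetic parameters from a balanced one-way
#' ANOVA among lines: genotypic variance `sigma2_g = (MSG - MSE) / r`
#' (truncated at zero with a warning when negative), phenotypic variance
#' on a plot basis `sigma2_p = sigma2_g + MSE`, genotypic coefficient of
#' variation `GCV = 100 * sqrt(sigma2_g) / mean`, broad-sense
#' heritability `h2 = 100 * sigma2_g / sigma2_p` (0 when `sigma2_p` is
#' 0), and genetic advance `GA = 100 * k * sigma_p * (h2/100) / mean`,
#' equal to `k * GCV * sqrt(h2/100)`.
#'
#' @param anova A [anova_lines()] result.
#' @param grand_mean Population mean (> 0); defaults to the mean of the
#'   cell the ANOVA was fitted on.
#' @param k Selection-intensity constant (default 2.64).
#' @return A one-row tibble: `mean`, `se_mean`, `sigma2_g`, `sigma2_p`,
#'   `gcv_pct`, `h2_pct`, `ga_pct`, `k` plus the cell selectors.
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   variety = "V", generation = "M2", treatment = "C",
#'   line = rep(c("A", "B", "C"), each = 2), replicate = rep(1:2, 3),
#'   trait = "y", value = c(10, 12, 14, 16, 18, 20))
#' genetic_parameters(anova_lines(tab, "V", "M2", "C", "y"))
genetic_parameters <- function(anova, grand_mean = NULL, k = 2.64) {
  stopifnot(inherits(anova, "lines_anova"))
  grand_mean <- grand_mean %||% anova$grand_mean
  check_finite(grand_mean, "grand_mean")
  if (grand_mean <= 0) abort("`grand_mean` must be > 0.")
  raw <- (anova$msg - anova$mse) / anova$r
  if (raw < 0) {
    warn(sprintf(
      "negative genotypic variance estimate (%.4g) truncated to 0 [%s/%s/%s/%s]",
      raw, anova$variety, anova$generation, anova$treatment, anova$trait),
      class = "mutbreedr_negative_sigma_g")
  }
  sigma2_g <- max(0, raw)
  sigma2_p <- sigma2_g + anova$mse
  gcv <- 100 * sqrt(sigma2_g) / grand_mean
  h2 <- if (sigma2_p > 0) 100 * sigma2_g / sigma2_p else 0
  ga <- 100 * k * sqrt(sigma2_p) * (h2 / 100) / grand_mean
  tibble(
    variety = anova$variety, generation = anova$generation,
    treatment = anova$treatment, trait = anova$trait,
    mean = grand_mean, se_mean = anova$se_mean,
    sigma2_g = sigma2_g, sigma2_p = sigma2_p,
    gcv_pct = gcv, h2_pct = h2, ga_pct = ga, k = k
  )
}

#' Per-population genetic parameters with Duncan letter groupings
#'
#' The workhorse summary behind the trial's printed tables: for every
#' (treatment, trait) cell of one variety and generation it estimates the
#' genetic parameters from the among-line ANOVA ([anova_lines()] +
#' [genetic_parameters()]), and, per trait, compares treatment means with
#' Duncan's multiple range test ([dmrt_letters()]), whose error term is
#' the pooled within-treatment mean square across lines and replicates.
#'
#' @inheritParams anova_lines
#' @param traits Trait codes to summarise (default: all in the table).
#' @param treatments Treatments to include (default: all present).
#' @param alpha Significance level of the Duncan test.
#' @param k Selection-intensity constant for genetic advance.
#' @return A tibble with one row per (treatment, trait): mean, SE,
#'   Duncan `letters`, `sigma2_g`, `sigma2_p`, `gcv_pct`, `h2_pct`,
#'   `ga_pct`.
#' @export
population_summary <- function(table, variety, generation, traits = NULL,
                               treatments = NULL, alpha = 0.05, k = 2.64) {
  table <- as_tibble(table) |>
    filter(.data$variety == .env$variety,
           .data$generation == .env$generation)
  if (nrow(table) == 0) abort("no rows for the requested variety/generation.")
  traits <- traits %||% unique(table$trait)
  treatments <- treatments %||% unique(table$treatment)
  table <- table |> filter(.data$trait %in% traits,
                           .data$treatment %in% treatments)

  params <- expand_grid(treatment = treatments, trait = traits) |>
    purrr::pmap(function(treatment, trait) {
      genetic_parameters(
        anova_lines(table, variety, generation, treatment, trait), k = k)
    }) |>
    list_rbind()

  letters_tab <- purrr::map(traits, function(t) {
    sub <- table |> filter(.data$trait == t)
    n_per <- sub |> count(.data$treatment)
    if (length(unique(n_per$n)) != 1) {
      abort(paste0("unequal observations per treatment for trait ", t,
                   "; Duncan grouping needs a balanced layout."))
    }
    means <- sub |> summarise(m = mean(.data$value), .by = "treatment")
    if (nrow(means) == 1) {
      return(tibble(treatment = means$treatment, trait = t, letters = "a"))
    }
    fit <- suppressWarnings(anova(lm(value ~ factor(treatment), data = sub)))
    dm <- dmrt_letters(setNames(means$m, means$treatment),
                       n = n_per$n[1], mse = fit$`Mean Sq`[2],
                       df_e = fit$Df[2], alpha = alpha)
    tidy(dm) |>
      transmute(treatment = .data$group, trait = t, letters = .data$letters)
  }) |> list_rbind()

  params |>
    left_join(letters_tab, by = c("treatment", "trait")) |>
    relocate("letters", .after = "se_mean")
}
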