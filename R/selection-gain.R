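#' Select the top lines per treatment
#'
#' Truncation selection: within each treatment of one variety and
#' generation, lines are ranked by their mean value of the selection
#' trait over replicates and the top `n` are returned (ties broken by
#' line id). Asking for more lines than exist returns all of them with a
#' warning.
#'
#' @inheritParams anova_lines
#' @param trait Selection trait (default the yield trait "PY").
#' @param n Lines to keep per treatment (> 0).
#' @param treatments Treatments to select within (default: all present).
#' @param direction "high" (default) or "low".
#' @return A tibble of class `selection_result`: `variety`, `generation`,
#'   `treatment`, `rank`, `line`, `line_mean`.
#' @export
select_top <- function(table, variety, generation, trait = "PY", n = 30,
                       treatments = NULL, direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (!is.numeric(n) || length(n) != 1 || n <= 0) abort("`n` must be > 0.")
  table <- as_tibble(table) |>
    filter(.data$variety == .env$variety,
           .data$generation == .env$generation,
           .data$trait == .env$trait)
  if (nrow(table) == 0) abort("no rows for the requested cell/trait.")
  treatments <- treatments %||% unique(table$treatment)
  miss <- setdiff(treatments, unique(table$treatment))
  if (length(miss) > 0) abort(paste0("treatments not present: ",
                                     paste(miss, collapse = ", "), "."))
  out <- table |>
    filter(.data$treatment %in% treatments) |>
    summarise(line_mean = mean(.data$value),
              .by = c("variety", "generation", "treatment", "line")) |>
    arrange(.data$treatment,
            if (direction == "high") desc(.data$line_mean) else .data$line_mean,
            .data$line) |>
    mutate(rank = row_number(), .by = "treatment") |>
    filter(.data$rank <= n) |>
    relocate("rank", .before = "line")
  short <- out |> count(.data$treatment) |> filter(.data$n < .env$n)
  if (nrow(short) > 0) {
    warn(paste0("fewer than n = ", n, " lines available in: ",
                paste(short$treatment, collapse = ", "),
                "; returning all of them."))
  }
  class(out) <- c("selection_result", class(out))
  out
}

#' Realized genetic gain over the control
#'
#' Genetic gain of each treated population, operationalized as the
#' percent advantage of its mean over the same-generation control:
#' `gain_pct = 100 * (treatment mean - control mean) / control mean`.
#' Accepts either a replicate-level trait table (means are computed) or a
#' ready-made summary with one mean per treatment.
#'
#' @param x A trait table, or a tibble with columns `treatment` and
#'   `mean` (e.g. printed report tables).
#' @param variety,generation Cell selectors (trait-table input).
#' @param trait Yield trait code (trait-table input; default "PY").
#' @param control Label of the control treatment.
#' @return A tibble of class `gain_report`: `treatment`, `mean`,
#'   `control_mean`, `gain_pct` (full precision; round for display).
#' @export
#' @examples
#' printed <- tibble::tibble(treatment = c("C", "G1"), mean = c(92.64, 119.27))
#' genetic_gain(printed)  # 28.75 % for G1
genetic_gain <- function(x, variety = NULL, generation = NULL, trait = "PY",
                         control = "C") {
  x <- as_tibble(x)
  if (all(c("treatment", "mean") %in% names(x)) && !"value" %in% names(x)) {
    means <- x |> select("treatment", "mean")
    if (!is.null(variety)) means <- mutate(means, variety = variety, .before = 1)
  } else {
    if (is.null(variety) || is.null(generation)) {
      abort("`variety` and `generation` are required for trait-table input.")
    }
    means <- x |>
      filter(.data$variety == .env$variety,
             .data$generation == .env$generation,
             .data$trait == .env$trait) |>
      summarise(mean = mean(.data$value), .by = c("variety", "generation",
                                                  "treatment"))
    if (nrow(means) == 0) abort("no yield rows for the requested cell.")
  }
  if (!control %in% means$treatment) {
    abort(paste0("control '", control, "' not present."))
  }
  cm <- means$mean[means$treatment == control]
  if (cm <= 0) abort("control mean must be > 0.")
  out <- means |>
    mutate(control_mean = cm,
           gain_pct = 100 * (.data$mean - cm) / cm)
  class(out) <- c("gain_report", class(out))
  out
}

#' Change in genetic gain between generations
#'
#' Per-treatment difference in realized gain between an earlier and a
#' later generation, `delta = gain(later) - gain(earlier)`; the treatment
#' with the largest increase is reported as an attribute.
#'
#' @param earlier,later [genetic_gain()] reports over the same treatment
#'   set.
#' @return A tibble: `treatment`, `gain_earlier`, `gain_later`,
#'   `delta_gain_pct`, with `attr(, "argmax")` naming the treatment with
#'   the largest delta.
#' @export
gain_delta <- function(earlier, later) {
  stopifnot(inherits(earlier, "gain_report"), inherits(later, "gain_report"))
  shared <- intersect(earlier$treatment, later$treatment)
  only <- c(setdiff(earlier$treatment, later$treatment),
            setdiff(later$treatment, earlier$treatment))
  if (!setequal(earlier$treatment, later$treatment)) {
    abort(paste0("treatment sets differ between reports: ",
                 paste(only, collapse = ", "), "."))
  }
  out <- tibble(treatment = shared) |>
    left_join(earlier |> select("treatment", gain_earlier = "gain_pct"),
              by = "treatment") |>
    left_join(later |> select("treatment", gain_later = "gain_pct"),
              by = "treatment") |>
    mutate(delta_gain_pct = .data$gain_later - .data$gain_earlier)
  treated <- out |> filter(.data$delta_gain_pct == max(.data$delta_gain_pct))
  attr(out, "argmax") <- treated$treatment[1]
  out
}
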