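#' Germination dose-response parameters
#'
#' Parameters of the logistic germination decline used by
#' [simulate_germination()]. Germination probability at composite dose d
#' is `g0 * plogis(-slope * (d - d50)) / plogis(slope * d50)`, i.e. the
#' curve is rescaled so the control (d = 0) germinates at exactly `g0`.
#'
#' Defaults place the 50%-of-control point at 450 Gy-equivalents with a
#' moderately steep slope, so every dose level up to the fourth (400
#' Gy-equivalents for single mutagens, 440 for the combined series under
#' the saturating [composite_dose()]) survives the published "more than a
#' 50% reduction in seed germination" screen while the fifth and higher
#' levels fail it.
#'
#' @param g0 Baseline germination rate of untreated seed, in (0, 1].
#' @param slope Logistic slope per Gy-equivalent (> 0).
#' @param d50 Dose at which expected germination halves relative to a
#'   saturated baseline (Gy-equivalents).
#' @param sa_scale,combo_weight Passed to [composite_dose()].
#' @return A list of class `germination_params`.
#' @export
germination_params <- function(g0 = 0.9, slope = 0.03, d50 = 450,
                               sa_scale = 1, combo_weight = 0.1) {
  check_finite(g0, "g0"); check_finite(slope, "slope")
  check_finite(d50, "d50"); check_finite(sa_scale, "sa_scale")
  check_finite(combo_weight, "combo_weight")
  if (g0 <= 0 || g0 > 1) abort("`g0` must be in (0, 1].")
  check_positive(slope, "slope")
  structure(list(g0 = g0, slope = slope, d50 = d50, sa_scale = sa_scale,
                 combo_weight = combo_weight),
            class = "germination_params")
}

#' Simulation parameters for a synthetic trial
#'
#' Encodes the statistical ground truth the downstream estimators are
#' meant to recover: per-trait grand means, per-treatment mean shifts,
#' genotypic variance among lines (`sigma_g`), plot-error variance
#' (`sigma_e`), a standardized linear path structure generating the yield
#' trait from its component traits, and the germination dose response.
#'
#' Trait values are generated as grand mean + treatment shift + line
#' effect + plot error, with line effects N(0, sigma_g) drawn once per
#' line (persisting across generations) and plot errors N(0, sigma_e)
#' redrawn per plot. If `path_coefficients` is non-NULL, the yield trait
#' is instead built from the standardized component traits:
#' `PY = mean + shift + scale * (sum(b * z) + eps)` with
#' `scale = sqrt(sigma_g[yield] + sigma_e[yield])` and
#' `eps ~ N(0, yield_residual_sd^2)`, so yield heritability is induced by
#' the components rather than parameterized directly.
#'
#' @param means Named numeric vector of grand (control) means per trait.
#' @param shifts Long tibble with columns `treatment`, `trait`, `shift`
#'   (trait units, relative to the control mean), or NULL for no shifts.
#'   Treatments absent from `shifts` get shift 0.
#' @param sigma_g Named numeric vector of genotypic variances per trait
#'   (>= 0); recycled if length 1.
#' @param sigma_e Named numeric vector of plot-error variances (>= 0);
#'   recycled if length 1.
#' @param path_coefficients Named numeric vector of standardized path
#'   coefficients of yield on component traits, or NULL to treat yield as
#'   an ordinary trait.
#' @param yield_residual_sd Residual SD of the standardized yield
#'   equation; default `sqrt(1 - sum(b^2))` (unit total variance when the
#'   components are uncorrelated), floored at 0.
#' @param yield_trait Trait code of the yield trait (default "PY").
#' @param germination A [germination_params()] object.
#' @return An object of class `sim_params`.
#' @seealso [cowpea_sim_params()] for defaults drawn from the published
#'   trait tables.
#' @export
sim_params <- function(means, shifts = NULL, sigma_g = 0, sigma_e = 0,
                       path_coefficients = NULL, yield_residual_sd = NULL,
                       yield_trait = "PY",
                       germination = germination_params()) {
  if (is.null(names(means)) || anyDuplicated(names(means))) {
    abort("`means` must be a uniquely named numeric vector (one per trait).")
  }
  check_finite(means, "means")
  traits <- names(means)
  expand <- function(x, name) {
    check_positive(x, name, strict = FALSE)
    if (length(x) == 1 && is.null(names(x))) x <- setNames(rep(x, length(traits)), traits)
    if (!all(traits %in% names(x))) {
      abort(paste0("`", name, "` must name every trait in `means`."))
    }
    x[traits]
  }
  sigma_g <- expand(sigma_g, "sigma_g")
  sigma_e <- expand(sigma_e, "sigma_e")
  if (!is.null(shifts)) {
    shifts <- as_tibble(shifts)
    if (!all(c("treatment", "trait", "shift") %in% names(shifts))) {
      abort("`shifts` needs columns treatment, trait, shift.")
    }
    check_finite(shifts$shift, "shift")
    if (!all(shifts$trait %in% traits)) {
      abort("`shifts` refers to traits absent from `means`.")
    }
  }
  if (!is.null(path_coefficients)) {
    check_finite(path_coefficients, "path_coefficients")
    b <- path_coefficients
    if (is.null(names(b)) || !all(names(b) %in% setdiff(traits, yield_trait))) {
      abort("`path_coefficients` must be named after non-yield traits in `means`.")
    }
    if (!yield_trait %in% traits) {
      abort("`yield_trait` must be one of the traits in `means`.")
    }
    if (is.null(yield_residual_sd)) {
      yield_residual_sd <- sqrt(max(0, 1 - sum(b^2)))
    }
    check_positive(yield_residual_sd, "yield_residual_sd", strict = FALSE)
  }
  if (!inherits(germination, "germination_params")) {
    abort("`germination` must be built with germination_params().")
  }
  structure(
    list(means = means, shifts = shifts, sigma_g = sigma_g, sigma_e = sigma_e,
         path_coefficients = path_coefficients,
         yield_residual_sd = yield_residual_sd,
         yield_trait = yield_trait, germination = germination),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>", length(x$means), "traits:",
      paste(names(x$means), collapse = " "), "\n")
  if (!is.null(x$path_coefficients)) {
    cat("  yield", x$yield_trait, "<-",
        paste(names(x$path_coefficients), round(x$path_coefficients, 3),
              sep = "=", collapse = " "),
        " residual sd", round(x$yield_residual_sd, 3), "\n")
  }
  cat("  germination: g0", x$germination$g0, "d50", x$germination$d50,
      "slope", x$germination$slope, "\n")
  invisible(x)
}

#' Simulation parameters calibrated to the published cowpea trial
#'
#' Builds [sim_params()] defaults from the printed per-population tables:
#' grand means are the control means of the chosen variety and
#' generation, treatment shifts are the printed treated-minus-control
#' mean differences, and per-trait genotypic variance is set from the
#' median printed GCV of the treated populations
#' (`sigma_g = (GCV/100 * control mean)^2`), with plot-error variance
#' chosen to give a nominal plot-level heritability `h2_nominal`.
#'
#' @param variety Variety name as printed.
#' @param generation "M2" (default) or "M3".
#' @param h2_nominal Nominal plot-basis heritability
#'   sigma_g / (sigma_g + sigma_e) for directly parameterized traits.
#' @param path_coefficients Standardized yield path structure; defaults
#'   put most direct effect on seed weight and seeds per pod, a small
#'   negative direct effect of pod length, consistent with the reported
#'   ordering of trait contributions.
#' @param reference Reference table, see [cowpea_reference()].
#' @inheritParams sim_params
#' @return An object of class `sim_params`.
#' @export
#' @examples
#' p <- cowpea_sim_params("Gomati VU-89")
#' round(p$means["PY"], 2)
cowpea_sim_params <- function(variety = "Gomati VU-89", generation = "M2",
                              h2_nominal = 0.8,
                              path_coefficients = c(PPP = 0.2, BPP = 0.05,
                                                    SPP = 0.4, SW = 0.6,
                                                    PL = -0.1, HI = 0.15),
                              germination = germination_params(),
                              reference = cowpea_reference()) {
  if (h2_nominal <= 0 || h2_nominal >= 1) abort("`h2_nominal` must be in (0, 1).")
  ref <- reference |>
    filter(.data$variety == .env$variety,
           .data$generation == .env$generation)
  if (nrow(ref) == 0) abort("variety/generation not present in the reference table.")
  ctrl <- ref |> filter(.data$treatment == "C")
  means <- setNames(ctrl$mean, ctrl$trait)[names(cowpea_traits())]
  shifts <- ref |>
    filter(.data$treatment != "C") |>
    left_join(ctrl |> select("trait", control_mean = "mean"), by = "trait") |>
    transmute(.data$treatment, .data$trait,
              shift = .data$mean - .data$control_mean)
  gcv_med <- ref |>
    filter(.data$treatment != "C") |>
    summarise(g = stats::median(.data$gcv_pct), .by = "trait")
  sg <- setNames((gcv_med$g / 100)^2, gcv_med$trait) * means[gcv_med$trait]^2
  sg <- sg[names(means)]
  se <- sg * (1 - h2_nominal) / h2_nominal
  sim_params(means = means, shifts = shifts, sigma_g = sg, sigma_e = se,
             path_coefficients = path_coefficients,
             germination = germination)
}
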