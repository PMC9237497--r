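#' Simulate the germination dose screen
#'
#' Draws seeds germinated per treatment from a binomial whose success
#' probability follows the logistic decline of [germination_params()]
#' evaluated at each treatment's [composite_dose()]. The control (dose 0)
#' germinates at the baseline rate `g0` in expectation.
#'
#' @param design A [trial_design()].
#' @param params A [sim_params()] (its `germination` component is used).
#' @param seed Integer seed; identical inputs give identical output.
#' @return A tibble with one row per treatment: `treatment`, `gamma_gy`,
#'   `sa_pct`, `composite_dose`, `sown`, `germinated`, `germination_pct`.
#' @export
#' @examples
#' g <- simulate_germination(trial_design(), cowpea_sim_params(), seed = 1)
#' head(g, 3)
simulate_germination <- function(design, params, seed) {
  stopifnot(inherits(design, "trial_design"), inherits(params, "sim_params"))
  gp <- params$germination
  dose <- composite_dose(design$treatments$gamma_gy, design$treatments$sa_pct,
                         sa_scale = gp$sa_scale, combo_weight = gp$combo_weight)
  p <- gp$g0 * plogis(-gp$slope * (dose - gp$d50)) / plogis(gp$slope * gp$d50)
  sown <- design$seeds_per_treatment
  germinated <- with_preserved_seed(seed, rbinom(length(p), sown, p))
  tibble(
    treatment = design$treatments$label,
    gamma_gy = design$treatments$gamma_gy,
    sa_pct = design$treatments$sa_pct,
    composite_dose = dose,
    sown = sown,
    germinated = germinated,
    germination_pct = 100 * germinated / sown
  )
}

#' Exclude treatments by germination loss
#'
#' Applies the dose screen used to decide which treated populations
#' advance: a treatment is retained when its germination percentage is at
#' least `threshold_fraction` of the control's (i.e. a reduction of
#' strictly more than 50% excludes, at the default threshold). Order is
#' preserved.
#'
#' @param germ Germination table as produced by [simulate_germination()]
#'   (columns `treatment`, `germination_pct`).
#' @param control_label Label of the control row.
#' @param threshold_fraction Retention threshold as a fraction of the
#'   control's germination percentage (default 0.5).
#' @return Character vector of retained treatment labels (control first
#'   if it is first in `germ`).
#' @export
#' @examples
#' g <- tibble::tibble(treatment = c("C", "T1", "T2"),
#'                     germination_pct = c(90, 46, 44))
#' apply_dose_exclusion(g)  # T1 retained (46 >= 45), T2 excluded
apply_dose_exclusion <- function(germ, control_label = "C",
                                 threshold_fraction = 0.5) {
  germ <- as_tibble(germ)
  if (!all(c("treatment", "germination_pct") %in% names(germ))) {
    abort("`germ` needs columns treatment and germination_pct.")
  }
  idx <- match(control_label, germ$treatment)
  if (is.na(idx)) {
    abort(paste0("control label '", control_label,
                 "' not found in the germination table."))
  }
  cutoff <- threshold_fraction * germ$germination_pct[idx]
  keep <- germ$germination_pct >= cutoff | germ$treatment == control_label
  germ$treatment[keep]
}

# Draw persistent line effects for each (variety, treatment, line, trait).
# Yield gets no own line effect when a path structure is present: its
# heritable component is induced through the component traits.
draw_line_effects <- function(design, params, treatments, lines) {
  traits <- design$traits
  own <- if (is.null(params$path_coefficients)) traits else
    setdiff(traits, params$yield_trait)
  out <- vector("list", length(design$varieties) * length(treatments))
  i <- 0L
  for (v in design$varieties) {
    for (trt in treatments) {
      L <- length(lines)
      eff <- matrix(0, L, length(own), dimnames = list(lines, own))
      for (t in own) {
        s <- params$sigma_g[[t]]
        if (s > 0) eff[, t] <- rnorm(L, 0, sqrt(s))
      }
      i <- i + 1L
      out[[i]] <- tibble(
        variety = v, treatment = trt,
        line = rep(lines, times = length(own)),
        trait = rep(own, each = L),
        effect = as.vector(eff)
      )
    }
  }
  list_rbind(out)
}

# Simulate one (variety, treatment) cell for the lines given, reusing the
# supplied line effects; called inside an already-seeded RNG stream.
sim_cell <- function(params, traits, shift_for, eff_wide, lines, r) {
  L <- length(lines)
  n <- L * r
  b <- params$path_coefficients
  yield <- params$yield_trait
  plain <- if (is.null(b)) traits else setdiff(traits, yield)
  vals <- matrix(NA_real_, n, length(traits),
                 dimnames = list(NULL, traits))
  for (t in plain) {
    se <- params$sigma_e[[t]]
    err <- if (se > 0) rnorm(n, 0, sqrt(se)) else 0
    vals[, t] <- params$means[[t]] + shift_for(t) +
      rep(eff_wide[lines, t], each = r) + err
  }
  if (!is.null(b)) {
    z <- matrix(0, n, length(b), dimnames = list(NULL, names(b)))
    for (t in names(b)) {
      tot <- params$sigma_g[[t]] + params$sigma_e[[t]]
      if (tot > 0) {
        z[, t] <- (vals[, t] - params$means[[t]] - shift_for(t)) / sqrt(tot)
      }
    }
    scale_y <- sqrt(params$sigma_g[[yield]] + params$sigma_e[[yield]])
    eps <- if (params$yield_residual_sd > 0) {
      rnorm(n, 0, params$yield_residual_sd)
    } else 0
    vals[, yield] <- params$means[[yield]] + shift_for(yield) +
      scale_y * (as.vector(z %*% b) + eps)
  }
  tibble(
    line = rep(rep(lines, each = r), times = length(traits)),
    replicate = rep(rep(seq_len(r), times = L), times = length(traits)),
    trait = rep(traits, each = n),
    value = as.vector(vals)
  )
}

line_ids <- function(n) sprintf("L%03d", seq_len(n))

#' Simulate a replicate-level trait table for one generation
#'
#' Generates the long-format trait table the whole analysis pipeline
#' consumes: for each variety, treatment, line, replicate and trait,
#' `value = grand mean + treatment shift + line effect + plot error`,
#' with the yield trait assembled from the standardized component traits
#' when the parameters carry a path structure (see [sim_params()]). The
#' table is balanced: every (line, replicate, trait) cell is present.
#'
#' @inheritParams simulate_germination
#' @param generation Generation label stored in the output.
#' @param treatments Treatment labels to simulate (default: all in the
#'   design), e.g. the retained set from [apply_dose_exclusion()].
#' @param line_effects Optional long tibble of pre-drawn line effects
#'   (columns `variety`, `treatment`, `line`, `trait`, `effect`), used by
#'   [simulate_generations()] to persist genotypes across generations.
#' @param lines Optional character vector (or named list keyed by
#'   "variety.treatment") of line ids to include; default
#'   `L001..L<lines_per_treatment>`.
#' @return A tibble with columns `variety`, `generation`, `treatment`,
#'   `line`, `replicate`, `trait`, `value`, carrying the drawn line
#'   effects in `attr(, "line_effects")`.
#' @export
#' @examples
#' d <- trial_design(varieties = "V1", lines_per_treatment = 4,
#'                   replications = 2,
#'                   treatments = default_treatments(1),
#'                   traits = c("PY"))
#' p <- sim_params(means = c(PY = 100), sigma_g = 4, sigma_e = 1)
#' simulate_trait_table(d, p, "M2", seed = 1)
simulate_trait_table <- function(design, params, generation = "M2", seed,
                                 treatments = NULL, line_effects = NULL,
                                 lines = NULL) {
  stopifnot(inherits(design, "trial_design"), inherits(params, "sim_params"))
  if (design$lines_per_treatment < 1 || design$replications < 1) {
    abort("design must have at least one line and one replication.")
  }
  if (!all(design$traits %in% names(params$means))) {
    abort("`params` must provide a mean for every design trait.")
  }
  treatments <- treatments %||% design$treatments$label
  if (!all(treatments %in% design$treatments$label)) {
    abort("unknown treatment labels requested.")
  }
  default_lines <- line_ids(design$lines_per_treatment)

  shift_tab <- params$shifts
  shift_lookup <- function(trt) {
    if (is.null(shift_tab)) return(function(t) 0)
    rows <- shift_tab[shift_tab$treatment == trt, ]
    s <- setNames(rows$shift, rows$trait)
    function(t) if (t %in% names(s)) s[[t]] else 0
  }
  cell_lines <- function(v, trt) {
    if (is.null(lines)) return(default_lines)
    if (is.list(lines)) return(lines[[paste(v, trt, sep = ".")]] %||% default_lines)
    lines
  }

  with_preserved_seed(seed, {
    if (is.null(line_effects)) {
      all_lines <- unique(unlist(lapply(design$varieties, function(v)
        lapply(treatments, function(trt) cell_lines(v, trt)))))
      line_effects <- draw_line_effects(design, params, treatments,
                                        sort(all_lines))
    }
    out <- vector("list", length(design$varieties) * length(treatments))
    i <- 0L
    for (v in design$varieties) {
      for (trt in treatments) {
        ls <- cell_lines(v, trt)
        eff <- line_effects |>
          filter(.data$variety == v, .data$treatment == trt) |>
          pivot_wider(names_from = "trait", values_from = "effect")
        eff_wide <- as.matrix(eff[, setdiff(names(eff),
                                            c("variety", "treatment", "line")),
                                  drop = FALSE])
        rownames(eff_wide) <- eff$line
        # traits with no own line effect (yield under a path structure)
        missing <- setdiff(design$traits, colnames(eff_wide))
        if (length(missing) > 0) {
          eff_wide <- cbind(eff_wide,
                            matrix(0, nrow(eff_wide), length(missing),
                                   dimnames = list(eff$line, missing)))
        }
        if (!all(ls %in% rownames(eff_wide))) {
          abort("line effects missing for some requested lines.")
        }
        cell <- sim_cell(params, design$traits, shift_lookup(trt),
                         eff_wide, ls, design$replications)
        i <- i + 1L
        out[[i]] <- cell |>
          mutate(variety = v, generation = generation, treatment = trt,
                 .before = 1)
      }
    }
    res <- list_rbind(out)
    attr(res, "line_effects") <- line_effects
    res
  })
}

#' Truncation-selection rule for advancing lines between generations
#'
#' @param trait Trait whose line means rank the lines (default the yield
#'   trait "PY").
#' @param n Lines kept per treatment per generation; `NULL` keeps all.
#' @param direction "high" (default) keeps the largest means.
#' @param treatments Treated populations that advance beyond the first
#'   generation; `NULL` advances all. The control always advances, by a
#'   seeded random draw of `n` lines (no trait-based selection is applied
#'   to it, which keeps the design balanced without selecting the check).
#' @return A list of class `selection_rule`.
#' @export
selection_rule <- function(trait = "PY", n = 30,
                           direction = c("high", "low"), treatments = NULL) {
  direction <- match.arg(direction)
  if (!is.null(n)) {
    if (!is.numeric(n) || length(n) != 1 || n < 1) abort("`n` must be a positive count or NULL.")
    n <- as.integer(n)
  }
  structure(list(trait = trait, n = n, direction = direction,
                 treatments = treatments),
            class = "selection_rule")
}

#' Simulate successive generations under selection
#'
#' Simulates the generation chain of a mutation-breeding programme: the
#' first generation draws line effects once; each later generation keeps
#' only the selected subset of the previous generation's lines per the
#' [selection_rule()] (their line effects persist -- the heritable
#' component -- while plot errors are redrawn), and treated populations
#' outside the rule's `treatments` set are dropped.
#'
#' @inheritParams simulate_trait_table
#' @param selection A [selection_rule()].
#' @param generations Ordered generation labels (default:
#'   `design$generations`).
#' @return A trait table spanning all generations, with the first
#'   generation's line effects in `attr(, "line_effects")`.
#' @export
simulate_generations <- function(design, params, selection = selection_rule(),
                                 seed, generations = NULL) {
  stopifnot(inherits(design, "trial_design"), inherits(selection, "selection_rule"))
  generations <- generations %||% design$generations
  if (length(generations) < 1) abort("need at least one generation label.")
  ctrl <- design$control

  with_preserved_seed(seed, {
    treatments1 <- design$treatments$label
    tab <- simulate_trait_table(design, params, generations[1],
                                seed = floor(stats::runif(1, 1, 2^30)),
                                treatments = treatments1)
    effects <- attr(tab, "line_effects")
    out <- list(tab)
    prev <- tab
    keep_trts <- if (is.null(selection$treatments)) {
      treatments1
    } else {
      unique(c(ctrl, selection$treatments))
    }
    for (g in generations[-1]) {
      sel_lines <- list()
      for (v in design$varieties) {
        for (trt in intersect(keep_trts, unique(prev$treatment))) {
          cell <- prev |>
            filter(.data$variety == v, .data$treatment == trt,
                   .data$trait == selection$trait)
          avail <- sort(unique(cell$line))
          key <- paste(v, trt, sep = ".")
          if (is.null(selection$n)) {
            sel_lines[[key]] <- avail
          } else {
            if (selection$n > length(avail)) {
              abort(paste0("selection n = ", selection$n, " exceeds the ",
                           length(avail), " available lines in ", key, "."))
            }
            if (trt == ctrl) {
              sel_lines[[key]] <- sort(sample(avail, selection$n))
            } else {
              lm_ <- cell |>
                summarise(m = mean(.data$value), .by = "line") |>
                arrange(if (selection$direction == "high") desc(.data$m) else .data$m,
                        .data$line)
              sel_lines[[key]] <- sort(lm_$line[seq_len(selection$n)])
            }
          }
        }
      }
      tab_g <- simulate_trait_table(design, params, g,
                                    seed = floor(stats::runif(1, 1, 2^30)),
                                    treatments = intersect(keep_trts, unique(prev$treatment)),
                                    line_effects = effects,
                                    lines = sel_lines)
      out <- c(out, list(tab_g))
      prev <- tab_g
    }
    res <- list_rbind(out)
    attr(res, "line_effects") <- effects
    res
  })
}
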