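#' Default configuration of the full analysis pipeline
#'
#' Every option of [run_pipeline()] with its default. Defaults mirror the
#' published trial: both cowpea varieties, 300 seeds per treatment, 30
#' replications, selection of the 30 highest-yielding lines in the six
#' advanced treated populations, M2 and M3 generations analysed,
#' alpha = 0.05 and k = 2.64.
#'
#' @return A nested named list (class `run_config`).
#' @export
default_run_config <- function() {
  structure(list(
    seed = 20140401L,
    varieties = c("Gomati VU-89", "Pusa-578"),
    generations = c("M2", "M3"),
    design = list(
      seeds_per_treatment = 300L,
      replications = 30L,
      lines_per_treatment = 100L
    ),
    h2_nominal = 0.8,
    germination = list(g0 = 0.9, slope = 0.03, d50 = 450,
                       sa_scale = 1, combo_weight = 0.1),
    selection = list(trait = "PY", n = 30L,
                     treatments = c("G1", "G2", "S1", "S2",
                                    "G1+S1", "G2+S2")),
    analysis = list(alpha = 0.05, k = 2.64, cluster_k = 5L,
                    standardize_distances = FALSE,
                    path_predictors = c("PPP", "BPP", "SPP", "SW",
                                        "PL", "HI")),
    verbose = TRUE
  ), class = "run_config")
}

merge_config <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ",
                 paste(paste(c(path, ""), collapse = "."),
                       unknown, sep = "", collapse = ", "), "."))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) abort(paste0("key '", k, "' must be a mapping."))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' Reads a (possibly partial) YAML configuration, fills unset options
#' from [default_run_config()], and rejects unknown keys outright.
#'
#' @param path YAML file path.
#' @return A complete `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(unclass(default_run_config()), user)
  structure(cfg, class = "run_config")
}

stage <- function(name, verbose, expr) {
  if (verbose) inform(paste0("[", name, "] ..."))
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full trial analysis pipeline
#'
#' Orchestrates the whole workflow on synthetic data: simulate the
#' germination dose screen, exclude treatments losing more than half the
#' control's germination, simulate the retained populations across
#' generations under truncation selection, then per variety and
#' generation compute the genetic-parameter summaries with Duncan
#' letters, realized genetic gains and their between-generation deltas,
#' trait correlations and the yield path decomposition, and the
#' multivariate population profile (Euclidean distances, UPGMA dendrogram
#' with Newick export, cluster profiles, correlation PCA). All artifacts
#' are written to `out_dir` as CSV/Newick/plain text plus a `manifest.csv`
#' of MD5 content hashes; reruns with the same configuration and seed
#' produce identical artifacts.
#'
#' @param config A `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Invisibly, the manifest tibble (`file`, `md5`, `bytes`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         seed = config$seed) {
  if (!inherits(config, "run_config")) {
    config <- merge_config(unclass(default_run_config()), config)
  }
  verbose <- isTRUE(config$verbose)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(out_dir, paste0(...))
  written <- character(0)
  emit <- function(x, file) {
    readr::write_csv(x, out(file), progress = FALSE)
    written <<- c(written, out(file))
  }

  germ_p <- do.call(germination_params, config$germination)
  design <- trial_design(
    varieties = config$varieties,
    seeds_per_treatment = config$design$seeds_per_treatment,
    replications = config$design$replications,
    lines_per_treatment = config$design$lines_per_treatment,
    generations = config$generations
  )

  retained <- list()
  tables <- list()
  for (i in seq_along(config$varieties)) {
    v <- config$varieties[i]
    params <- stage(paste0("params:", v), verbose,
                    cowpea_sim_params(v, generation = "M2",
                                      h2_nominal = config$h2_nominal,
                                      germination = germ_p))
    germ <- stage(paste0("germination:", v), verbose,
                  simulate_germination(design, params, seed = seed + i))
    emit(germ, paste0("germination_", i, ".csv"))
    keep <- stage(paste0("dose-exclusion:", v), verbose,
                  apply_dose_exclusion(germ, control_label = design$control))
    retained[[v]] <- keep
    vdesign <- trial_design(
      varieties = v,
      treatments = design$treatments |> filter(.data$label %in% keep),
      seeds_per_treatment = design$seeds_per_treatment,
      replications = design$replications,
      lines_per_treatment = design$lines_per_treatment,
      generations = config$generations
    )
    rule <- selection_rule(trait = config$selection$trait,
                           n = config$selection$n,
                           treatments = intersect(config$selection$treatments,
                                                  keep))
    tables[[v]] <- stage(paste0("simulate:", v), verbose,
                         simulate_generations(vdesign, params, rule,
                                              seed = seed + 100 + i))
  }
  tab <- list_rbind(unname(tables))
  stage("write-trait-table", verbose, {
    write_trait_csv(tab, out("trait_table.csv"))
    written <- c(written, out("trait_table.csv"))
  })
  written <- c(written, out("trait_table.csv"))

  gains <- list()
  for (v in config$varieties) {
    slug <- gsub("[^A-Za-z0-9]+", "_", v)
    for (g in config$generations) {
      summ <- stage(paste0("genetics:", v, ":", g), verbose,
                    population_summary(tab, v, g,
                                       alpha = config$analysis$alpha,
                                       k = config$analysis$k))
      emit(summ, paste0("summary_", slug, "_", g, ".csv"))
      writeLines(render_summary(summ), out("summary_", slug, "_", g, ".txt"))
      written <- c(written, out("summary_", slug, "_", g, ".txt"))
      gains[[paste(v, g)]] <- stage(paste0("gain:", v, ":", g), verbose,
        genetic_gain(tab, v, g, trait = config$selection$trait,
                     control = design$control))
      emit(gains[[paste(v, g)]], paste0("gain_", slug, "_", g, ".csv"))
    }
    sel <- stage(paste0("selection:", v), verbose,
                 select_top(tab, v, config$generations[1],
                            trait = config$selection$trait,
                            n = config$selection$n))
    emit(sel, paste0("selection_", slug, "_", config$generations[1], ".csv"))
    if (length(config$generations) >= 2) {
      g1 <- config$generations[1]; g2 <- config$generations[2]
      shared <- intersect(gains[[paste(v, g1)]]$treatment,
                          gains[[paste(v, g2)]]$treatment)
      dl <- stage(paste0("gain-delta:", v), verbose, gain_delta(
        gains[[paste(v, g1)]] |> filter(.data$treatment %in% shared),
        gains[[paste(v, g2)]] |> filter(.data$treatment %in% shared)))
      emit(dl, paste0("gain_delta_", slug, ".csv"))
      if (verbose) {
        inform(paste0(v, ": largest gain increase ", g1, "->", g2, " in ",
                      attr(dl, "argmax")))
      }
    }

    gen_last <- tail(config$generations, 1)
    corr <- stage(paste0("correlation:", v), verbose,
                  trait_correlations(tab, variety = v,
                                     generation = gen_last,
                                     method = "spearman", level = "line"))
    emit(as_tibble(corr$r, rownames = "trait"), paste0("spearman_", slug, ".csv"))
    emit(as_tibble(corr$stars, rownames = "trait"),
         paste0("spearman_stars_", slug, ".csv"))
    pcorr <- trait_correlations(tab, variety = v, generation = gen_last,
                                method = "pearson", level = "plot")
    pa <- stage(paste0("path:", v), verbose,
                path_analysis(pcorr,
                              predictors = intersect(
                                config$analysis$path_predictors,
                                rownames(pcorr$r))))
    emit(tidy(pa), paste0("path_", slug, ".csv"))

    mm <- stage(paste0("means:", v), verbose,
                population_means(tab, v, config$generations[1]))
    emit(mm, paste0("population_means_", slug, ".csv"))
    dmat <- euclidean_matrix(mm,
                             standardize = config$analysis$standardize_distances)
    emit(as_tibble(as.matrix(dmat), rownames = "treatment"),
         paste0("distances_", slug, ".csv"))
    dend <- stage(paste0("upgma:", v), verbose, upgma(dmat))
    write_newick(dend, out("dendrogram_", slug, ".nwk"))
    written <- c(written, out("dendrogram_", slug, ".nwk"))
    k <- min(config$analysis$cluster_k, length(dend$labels))
    cp <- cluster_profiles(dend, k, mm, dmat)
    emit(cp$membership, paste0("clusters_", slug, ".csv"))
    emit(cp$profiles, paste0("cluster_profiles_", slug, ".csv"))
    pca <- stage(paste0("pca:", v), verbose, pca_populations(mm))
    emit(tidy(pca, "eigenvalues"), paste0("pca_eigenvalues_", slug, ".csv"))
    emit(tidy(pca, "cos2"), paste0("pca_cos2_", slug, ".csv"))
    emit(tidy(pca, "contrib"), paste0("pca_contrib_", slug, ".csv"))
    emit(pca$scores, paste0("pca_scores_", slug, ".csv"))
  }

  cfg_out <- out("run_config.yaml")
  yaml::write_yaml(c(unclass(config),
                     list(retained = retained)), cfg_out)
  written <- c(written, cfg_out)
  files <- sort(unique(written))
  manifest <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files)
  )
  readr::write_csv(manifest, out("manifest.csv"), progress = FALSE)
  if (verbose) inform(paste0("wrote ", nrow(manifest), " artifacts to ", out_dir))
  invisible(manifest)
}
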