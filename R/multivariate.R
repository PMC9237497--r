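#' Population-by-trait mean matrix
#'
#' Collapses a trait table to the treatment-level trait means of one
#' variety and generation -- the input of the multivariate profiling
#' steps (distances, clustering, PCA).
#'
#' @inheritParams anova_lines
#' @param traits Trait codes (default: all in the table).
#' @return A tibble with a `treatment` column followed by one numeric
#'   column per trait; complete (an informative error lists any missing
#'   cell).
#' @export
population_means <- function(table, variety, generation, traits = NULL) {
  table <- as_tibble(table) |>
    filter(.data$variety == .env$variety,
           .data$generation == .env$generation)
  if (nrow(table) == 0) abort("no rows for the requested variety/generation.")
  traits <- traits %||% unique(table$trait)
  m <- table |>
    filter(.data$trait %in% traits) |>
    summarise(mean = mean(.data$value), .by = c("treatment", "trait"))
  full <- expand_grid(treatment = unique(m$treatment), trait = traits)
  missing <- anti_join(full, m, by = c("treatment", "trait"))
  if (nrow(missing) > 0) {
    abort(paste0("missing cells: ",
                 paste(paste(missing$treatment, missing$trait, sep = "/"),
                       collapse = ", "), "."))
  }
  m |> pivot_wider(names_from = "trait", values_from = "mean")
}

as_mean_matrix <- function(m) {
  if (is.matrix(m)) return(m)
  m <- as_tibble(m)
  if (!"treatment" %in% names(m)) abort("mean matrix needs a `treatment` column.")
  x <- as.matrix(m[, setdiff(names(m), "treatment"), drop = FALSE])
  rownames(x) <- m$treatment
  if (anyDuplicated(rownames(x))) abort("population labels must be unique.")
  if (any(!is.finite(x))) abort("mean matrix must be complete and finite.")
  x
}

#' Euclidean inter-population distance matrix
#'
#' Pairwise Euclidean distances between population trait-mean vectors,
#' on the raw trait scales by default (which is how the trial's printed
#' proximity matrix is reproducible to within rounding) or on z-scored
#' columns.
#'
#' @param m Mean matrix from [population_means()] (or a plain matrix with
#'   population rownames).
#' @param standardize If TRUE, columns are centred and scaled first; a
#'   zero-variance column is then an error.
#' @return A [stats::dist] object with population labels.
#' @export
#' @examples
#' euclidean_matrix(reference_mean_matrix())
euclidean_matrix <- function(m, standardize = FALSE) {
  x <- as_mean_matrix(m)
  if (standardize) {
    s <- apply(x, 2, sd)
    if (any(s == 0)) {
      abort(paste0("zero-variance trait(s) under standardization: ",
                   paste(colnames(x)[s == 0], collapse = ", "), "."))
    }
    x <- scale(x)
  }
  dist(x, method = "euclidean")
}

#' UPGMA (average linkage) dendrogram
#'
#' Agglomerative clustering with unweighted average linkage: at each step
#' the two closest clusters merge, and the distance between clusters is
#' the arithmetic mean of all member-pair distances. Heights are
#' monotone non-decreasing. Labels are sorted before clustering so the
#' output is reproducible regardless of input row order.
#'
#' @param d A [stats::dist] object (e.g. from [euclidean_matrix()]) or a
#'   square symmetric matrix.
#' @return An [stats::hclust] object (n - 1 merges for n leaves).
#' @export
upgma <- function(d) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12) {
      abort("`d` must be a symmetric square matrix or a dist object.")
    }
    d <- stats::as.dist(d)
  }
  if (!inherits(d, "dist")) abort("`d` must be a dist object or symmetric matrix.")
  n <- attr(d, "Size")
  if (n < 2) abort("need at least 2 populations to cluster.")
  labs <- attr(d, "Labels") %||% as.character(seq_len(n))
  dm <- as.matrix(d)
  ord <- order(labs)
  hclust(stats::as.dist(dm[ord, ord]), method = "average")
}

#' Export a dendrogram as Newick
#'
#' @param dend An [stats::hclust] object (e.g. from [upgma()]).
#' @param path File path; branch lengths derive from merge heights.
#' @return The path, invisibly.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "hclust"))
  phy <- ape::as.phylo(dend)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Flat clusters with trait profiles and inter-cluster distances
#'
#' Cuts a dendrogram into `k` flat clusters and summarises each cluster
#' by its mean trait profile; inter-cluster distances are the average of
#' all member-pair distances (consistent with the average-linkage
#' criterion).
#'
#' @param dend An [stats::hclust] object.
#' @param k Number of clusters, `1 <= k <=` number of leaves.
#' @param m The mean matrix the dendrogram was built from.
#' @param d The distance matrix (dist object or square matrix).
#' @return An object of class `cluster_profiles`: `membership` (tibble
#'   treatment/cluster), `profiles` (tibble cluster x trait means),
#'   `intercluster` (matrix of average between-cluster distances).
#' @export
cluster_profiles <- function(dend, k, m, d) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$labels)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n || k != trunc(k)) {
    abort(paste0("`k` must be an integer in [1, ", n, "]."))
  }
  x <- as_mean_matrix(m)
  dm <- as.matrix(d)
  cl <- cutree(dend, k = k)
  x <- x[names(cl), , drop = FALSE]
  dm <- dm[names(cl), names(cl)]
  membership <- tibble(treatment = names(cl), cluster = unname(cl))
  profiles <- membership |>
    left_join(as_tibble(x, rownames = "treatment"), by = "treatment") |>
    summarise(across(-"treatment", mean), .by = "cluster") |>
    arrange(.data$cluster)
  inter <- matrix(0, k, k, dimnames = list(seq_len(k), seq_len(k)))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (a == b) next
      ia <- which(cl == a); ib <- which(cl == b)
      inter[a, b] <- mean(dm[ia, ib, drop = FALSE])
    }
  }
  structure(list(membership = membership, profiles = profiles,
                 intercluster = inter, k = k),
            class = "cluster_profiles")
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat("<cluster_profiles> k =", x$k, "\n")
  print(as.data.frame(x$profiles), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Principal component analysis of population trait means
#'
#' PCA by eigendecomposition of the correlation matrix of the traits
#' (default; the covariance matrix is available for same-unit traits).
#' Scores are the centred (and scaled, in correlation mode) data
#' projected on the eigenvectors. For each variable, `cos2` is its
#' squared correlation with each component's scores (quality of
#' representation; rows sum to 1 over all components in correlation
#' mode), and `contrib` is the percent share of a component's variance
#' carried by the variable (columns sum to 100). Eigenvector signs are
#' fixed so each component's largest-|loading| variable loads
#' positively, making output platform-reproducible.
#'
#' @param m Mean matrix from [population_means()] (or a plain matrix).
#' @param standardize TRUE (default) for correlation PCA; FALSE for
#'   covariance PCA.
#' @return An object of class `population_pca`: `eigenvalues`,
#'   `pct_variance`, `scores` (tibble), `loadings` (eigenvectors),
#'   `cos2`, `contrib`, `standardize`.
#' @export
#' @examples
#' p <- pca_populations(reference_mean_matrix())
#' round(p$pct_variance[1:2], 1)
pca_populations <- function(m, standardize = TRUE) {
  x <- as_mean_matrix(m)
  if (nrow(x) < 2 || ncol(x) < 2) abort("need >= 2 populations and >= 2 traits.")
  s <- apply(x, 2, sd)
  if (standardize && any(s == 0)) {
    abort(paste0("zero-variance trait(s) under correlation PCA: ",
                 paste(colnames(x)[s == 0], collapse = ", "), "."))
  }
  xc <- scale(x, center = TRUE, scale = standardize)
  cm <- if (standardize) cor(x) else stats::cov(x)
  eig <- eigen(cm, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # deterministic sign: largest-|loading| variable positive per component
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(x), paste0("PC", seq_len(ncol(vecs))))
  scores <- xc %*% vecs
  # variable coordinate on PC j = loading * sqrt(eigenvalue); in
  # correlation mode this is the variable-component correlation
  coord <- sweep(vecs, 2, sqrt(vals), `*`)
  cos2 <- if (standardize) coord^2 else {
    sweep(coord^2, 1, rowSums(coord^2), `/`)
  }
  contrib <- 100 * sweep(vecs^2, 2, colSums(vecs^2), `/`)
  structure(
    list(
      eigenvalues = vals,
      pct_variance = 100 * vals / sum(vals),
      scores = as_tibble(scores, rownames = "treatment"),
      loadings = vecs,
      coord = coord,
      cos2 = cos2,
      contrib = contrib,
      standardize = standardize
    ),
    class = "population_pca"
  )
}

#' @export
print.population_pca <- function(x, ...) {
  cat("<population_pca>", if (x$standardize) "correlation" else "covariance",
      "PCA,", length(x$eigenvalues), "components\n")
  cat(" variance explained (%):",
      paste(round(x$pct_variance, 1), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.population_pca <- function(x, matrix = c("eigenvalues", "scores",
                                              "loadings", "cos2", "contrib"),
                                ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    eigenvalues = tibble(
      component = seq_along(x$eigenvalues),
      eigenvalue = x$eigenvalues,
      pct_variance = x$pct_variance,
      cum_pct = cumsum(x$pct_variance)
    ),
    scores = x$scores,
    loadings = as_tibble(x$loadings, rownames = "trait"),
    cos2 = as_tibble(x$cos2, rownames = "trait"),
    contrib = as_tibble(x$contrib, rownames = "trait")
  )
}
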