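test_that("anova_lines reproduces hand-computed sums of squares", {
  a <- anova_lines(hand_anova_table(), "V", "M2", "C", "y")
  expect_equal(a$msg, 32)
  expect_equal(a$mse, 2)
  expect_equal(a$df_g, 2L)
  expect_equal(a$df_e, 3L)
  expect_equal(a$f, 16)
  expect_equal(a$r, 2)
})

test_that("anova_lines matches the moment formulas on random data", {
  set.seed(421)
  for (i in 1:5) {
    L <- sample(3:8, 1); r <- sample(2:5, 1)
    tab <- tidyr::expand_grid(line = sprintf("L%02d", 1:L),
                              replicate = 1:r) |>
      dplyr::mutate(variety = "V", generation = "M2", treatment = "T",
                    trait = "y", value = rnorm(L * r, 50, 4))
    a <- anova_lines(tab, "V", "M2", "T", "y")
    lm_ <- tab |> dplyr::summarise(m = mean(value), .by = line)
    msg_hand <- r * sum((lm_$m - mean(tab$value))^2) / (L - 1)
    sse <- tab |>
      dplyr::mutate(m = ave(value, line), d2 = (value - m)^2) |>
      dplyr::summarise(s = sum(d2)) |> dplyr::pull(s)
    expect_equal(a$msg, msg_hand, tolerance = 1e-10)
    expect_equal(a$mse, sse / (L * (r - 1)), tolerance = 1e-10)
  }
})

test_that("anova_lines flags degenerate and malformed cells", {
  tab <- hand_anova_table()
  const <- dplyr::mutate(tab, value = 5)
  a <- anova_lines(const, "V", "M2", "C", "y")
  expect_equal(a$msg, 0)
  expect_equal(a$mse, 0)
  expect_true(is.na(a$f))
  # permutation invariance: shuffling replicates within lines changes nothing
  shuf <- tab[c(2, 1, 4, 3, 6, 5), ]
  b <- anova_lines(shuf, "V", "M2", "C", "y")
  expect_equal(b$msg, 32)
  expect_equal(b$mse, 2)
  # error paths
  expect_error(anova_lines(tab[-1, ], "V", "M2", "C", "y"), "unbalanced.*A")
  expect_error(anova_lines(tab[1:2, ], "V", "M2", "C", "y"), "2 lines")
  expect_error(anova_lines(tab, "V", "M2", "X", "y"), "empty")
})

test_that("genetic parameters follow the moment definitions", {
  a <- anova_lines(hand_anova_table(), "V", "M2", "C", "y")
  gp <- genetic_parameters(a, grand_mean = 15)
  expect_equal(gp$sigma2_g, 15)
  expect_equal(gp$sigma2_p, 17)
  expect_equal(gp$gcv_pct, 100 * sqrt(15) / 15, tolerance = 1e-12)
  expect_equal(round(gp$gcv_pct, 2), 25.82)
  expect_equal(round(gp$h2_pct, 2), 88.24)
  expect_equal(round(gp$ga_pct, 2), 64.03)
  expect_error(genetic_parameters(a, grand_mean = -3), "grand_mean")
  # MSG = MSE collapses everything to zero
  flat <- a
  flat$msg <- flat$mse <- 4
  gp0 <- genetic_parameters(flat, grand_mean = 10)
  expect_equal(gp0$sigma2_g, 0)
  expect_equal(gp0$gcv_pct, 0)
  expect_equal(gp0$h2_pct, 0)
  expect_equal(gp0$ga_pct, 0)
  # negative raw sigma2_g warns and truncates, never errors
  neg <- a
  neg$msg <- 1; neg$mse <- 3
  expect_warning(gpn <- genetic_parameters(neg, grand_mean = 10),
                 class = "mutbreedr_negative_sigma_g")
  expect_equal(gpn$sigma2_g, 0)
})

test_that("GA identity holds for every emitted row and printed anchor cells", {
  # printed anchors
  expect_equal(genetic_advance_percent(9.41, 96.01), 24.34, tolerance = 1e-3)
  expect_equal(genetic_advance_percent(13.64, 90.39), 34.24, tolerance = 2e-4)
  expect_equal(genetic_advance_percent(0, 50), 0)
  expect_equal(genetic_advance_percent(12, 0), 0)
  expect_error(genetic_advance_percent(5, 120), "0, 100")
  # identity on simulated summaries
  d <- tiny_design(lines = 8, reps = 3, treatments = default_treatments(2))
  tab <- simulate_trait_table(d, tiny_params(), "M2", seed = 31)
  summ <- population_summary(tab, "V1", "M2")
  expect_equal(summ$ga_pct,
               summ$k * summ$gcv_pct * sqrt(summ$h2_pct / 100),
               tolerance = 1e-9)
  expect_true(all(summ$sigma2_p >= summ$sigma2_g))
  expect_true(all(summ$h2_pct >= 0 & summ$h2_pct <= 100))
})

test_that("GCV, h2 and GA are scale equivariant", {
  d <- tiny_design(lines = 8, reps = 3, treatments = default_treatments(1))
  tab <- simulate_trait_table(d, tiny_params(), "M2", seed = 77)
  scaled <- dplyr::mutate(tab, value = value * 3.7)
  g1 <- genetic_parameters(anova_lines(tab, "V1", "M2", "G1", "y"))
  g2 <- genetic_parameters(anova_lines(scaled, "V1", "M2", "G1", "y"))
  expect_equal(g2$gcv_pct, g1$gcv_pct, tolerance = 1e-10)
  expect_equal(g2$h2_pct, g1$h2_pct, tolerance = 1e-10)
  expect_equal(g2$ga_pct, g1$ga_pct, tolerance = 1e-10)
  expect_equal(g2$mean, 3.7 * g1$mean, tolerance = 1e-10)
  expect_equal(sqrt(g2$sigma2_p), 3.7 * sqrt(g1$sigma2_p), tolerance = 1e-10)
})

test_that("expected MSG decomposes as sigma_e + r sigma_g across simulations", {
  d <- trial_design(varieties = "V", treatments = default_treatments(1)[1, ],
                    lines_per_treatment = 12, replications = 4, traits = "y")
  p <- sim_params(means = c(y = 50), sigma_g = 6, sigma_e = 3)
  est <- vapply(1:300, function(s) {
    a <- anova_lines(simulate_trait_table(d, p, "M2", seed = 5000 + s),
                     "V", "M2", "C", "y")
    (a$msg - a$mse) / a$r
  }, 0)
  expect_lt(abs(mean(est) / 6 - 1), 0.05)
})

test_that("population_summary letters respond to real shifts and degenerate cases", {
  # a single treatment gets letter "a" everywhere
  d1 <- tiny_design(lines = 5, reps = 3,
                    treatments = default_treatments(1)[1, ])
  t1 <- simulate_trait_table(d1, tiny_params(), "M2", seed = 5)
  s1 <- population_summary(t1, "V1", "M2")
  expect_true(all(s1$letters == "a"))
  # a +20% yield shift with tiny variances separates G1 from control
  d2 <- tiny_design(lines = 5, reps = 3, treatments = default_treatments(1))
  shifted <- sim_params(
    means = c(y = 50, PY = 100),
    shifts = tibble::tibble(treatment = "G1", trait = "PY", shift = 20),
    sigma_g = c(y = 0.01, PY = 0.01), sigma_e = c(y = 0.01, PY = 0.01))
  t2 <- simulate_trait_table(d2, shifted, "M2", seed = 6)
  s2 <- population_summary(t2, "V1", "M2", traits = "PY")
  lg1 <- s2$letters[s2$treatment == "G1"]
  lc <- s2$letters[s2$treatment == "C"]
  expect_false(any(strsplit(lg1, "")[[1]] %in% strsplit(lc, "")[[1]]))
})

test_that("null treatment effects share letters at Duncan's protected type-I rate", {
  # With no shifts and m treatments, the full span is homogeneous with
  # probability (1 - alpha)^(m - 1) (protected level), ~0.857 for m = 4.
  # iid null (no line effects): the plot-level MSE is then the correct
  # error term for the treatment means, so the protected rate applies
  d <- tiny_design(lines = 4, reps = 3, traits = "y",
                   treatments = default_treatments(1)[1:4, ])
  p <- sim_params(means = c(y = 50), sigma_g = 0, sigma_e = 4)
  n_seeds <- 200
  all_share <- vapply(seq_len(n_seeds), function(s) {
    tab <- simulate_trait_table(d, p, "M2", seed = 20000 + s)
    summ <- suppressWarnings(population_summary(tab, "V1", "M2",
                                                traits = "y"))
    any(vapply(letters[1:8], function(l) {
      all(grepl(l, summ$letters))
    }, TRUE))
  }, TRUE)
  p_expect <- (1 - 0.05)^(4 - 1)
  se3 <- 3 * sqrt(p_expect * (1 - p_expect) / n_seeds)
  expect_gt(mean(all_share), p_expect - se3)
})
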