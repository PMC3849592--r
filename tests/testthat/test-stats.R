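make_summaries <- function(n_control = 10, n_pad = 10, f = function(g) 0,
                           seed = 1) {
  set.seed(seed)
  g <- rep(c("control", "pad"), c(n_control, n_pad))
  data.frame(
    patient_id = sprintf("S%02d", seq_along(g)), group = g,
    fontaine_stage = ifelse(g == "pad", sample(2:4, length(g), TRUE), NA),
    abi = ifelse(g == "pad", runif(length(g), 0.1, 0.8),
                 runif(length(g), 0.95, 1.3)),
    cad = rbinom(length(g), 1, 0.5) == 1,
    htn = rbinom(length(g), 1, 0.5) == 1,
    n_fibers = 500L,
    mean_carbonyl_gsu = vapply(g, f, numeric(1)) + rnorm(length(g), 500, 1),
    mean_hne_gsu = rnorm(length(g), 300, 1),
    mean_csa_um2 = rnorm(length(g), 4000, 1),
    stringsAsFactors = FALSE)
}

test_that("group comparison: null case, t-squared identity, orthogonal covariates", {
  s <- make_summaries(seed = 2)
  null <- adjusted_group_comparison(s, "carbonyl", covariates = character())
  expect_lt(abs(null$percent_difference), 1)
  expect_gt(null$p_value, 0.001)

  # with no covariates and a two-level factor, F is the squared pooled t
  s2 <- make_summaries(12, 12, f = function(g) ifelse(g == "pad", 30, 0),
                       seed = 3)
  g <- adjusted_group_comparison(s2, "carbonyl", covariates = character())
  tt <- t.test(mean_carbonyl_gsu ~ group, s2, var.equal = TRUE)
  expect_equal(g$F_stat, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(g$df, c(1, 22))

  # covariates orthogonal to group leave the group difference unchanged
  s3 <- make_summaries(8, 8, f = function(g) ifelse(g == "pad", 50, 0), seed = 4)
  s3$cad <- rep(c(TRUE, FALSE), 8)  # balanced within group
  s3$htn <- rep(c(TRUE, TRUE, FALSE, FALSE), 4)
  d_adj <- with(adjusted_group_comparison(s3, "carbonyl", c("cad", "htn")),
                adjusted_mean_pad - adjusted_mean_control)
  d_raw <- with(adjusted_group_comparison(s3, "carbonyl", character()),
                adjusted_mean_pad - adjusted_mean_control)
  expect_equal(d_adj, d_raw, tolerance = 1e-8)

  # constant covariate is dropped with a warning, not a failure
  s3$htn <- TRUE
  expect_warning(g2 <- adjusted_group_comparison(s3, "carbonyl", c("cad", "htn")),
                 "htn")
  expect_equal(g2$covariates, "cad")
})

test_that("percent differences reproduce the published group contrasts", {
  expect_equal(percent_difference(486, 695, "vs_larger"), 30.07, tolerance = 1e-3)
  expect_equal(percent_difference(261, 436, "vs_larger"), 40.14, tolerance = 1e-3)
  expect_equal(percent_difference(5324, 3760, "vs_control"), -29.38,
               tolerance = 1e-3)
  expect_equal(percent_difference(100, 50, "vs_larger"), -50)
  expect_error(percent_difference(0, 10, "vs_control"), "denominator")
})

test_that("stage trend: perfect fit, error handling", {
  s <- make_summaries(0, 12, seed = 5)
  s$mean_carbonyl_gsu <- 100 + 140 * s$fontaine_stage
  tr <- suppressWarnings(stage_trend(s, "carbonyl", covariates = character()))
  expect_equal(tr$slope, 140, tolerance = 1e-8)
  expect_equal(tr$r_squared, 1, tolerance = 1e-8)

  s$fontaine_stage <- 2L
  expect_error(stage_trend(s, "carbonyl"), "distinct")
})

test_that("stage trend keeps its nominal type-I error under the null", {
  set.seed(11)
  reps <- 1000
  stages <- rep(2:4, c(13, 9, 12))
  p <- replicate(reps, {
    s <- data.frame(patient_id = sprintf("P%02d", 1:34), group = "pad",
                    fontaine_stage = stages,
                    abi = runif(34, 0.1, 0.8),
                    cad = rbinom(34, 1, 0.6) == 1,
                    htn = rbinom(34, 1, 0.8) == 1,
                    n_fibers = 500L,
                    mean_carbonyl_gsu = rnorm(34, 600, 120),
                    mean_hne_gsu = 0, mean_csa_um2 = 0)
    stage_trend(s, "carbonyl")$p_value
  })
  hits <- sum(p < 0.05)
  bounds <- qbinom(c(0.005, 0.995), reps, 0.05)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})

test_that("partial correlation: reductions, extremes, and the normal-equations oracle", {
  s <- make_summaries(0, 12, seed = 6)
  plain <- abi_partial_correlation(s, "carbonyl", covariates = character())
  expect_equal(plain$r, cor(s$abi, s$mean_carbonyl_gsu), tolerance = 1e-10)
  expect_gt(plain$ci_high, plain$r)
  expect_lt(plain$ci_low, plain$r)

  s$mean_carbonyl_gsu <- -s$abi
  perfect <- abi_partial_correlation(s, "carbonyl", covariates = character())
  expect_equal(perfect$r, -1, tolerance = 1e-10)

  # fixed 6-row table vs the independent oracle
  d <- data.frame(patient_id = paste0("P", 1:6), group = "pad",
                  fontaine_stage = c(2, 2, 3, 3, 4, 4),
                  abi = c(0.61, 0.48, 0.41, 0.37, 0.22, 0.15),
                  cad = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
                  htn = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
                  n_fibers = 100L,
                  mean_carbonyl_gsu = c(512, 570, 655, 702, 801, 830),
                  mean_hne_gsu = 0, mean_csa_um2 = 0)
  got <- abi_partial_correlation(d, "carbonyl", covariates = c("cad", "htn"))
  want <- oracle_partial_r(d$mean_carbonyl_gsu, d$abi,
                           cbind(as.numeric(d$cad), as.numeric(d$htn)))
  expect_equal(got$r, want, tolerance = 1e-10)

  expect_error(abi_partial_correlation(d[1:4, ], "carbonyl"), "insufficient")
})

test_that("repeated-measures quartile model: null and effect behaviour", {
  qt <- expand.grid(patient_id = sprintf("P%02d", 1:8),
                    class = c("Q1", "Q2", "Q3", "Q4"),
                    stringsAsFactors = FALSE)
  qt$marker <- "carbonyl"; qt$group <- "pad"; qt$n_fibers <- 50L
  base <- rep(rnorm(8, 4000, 500), 4)

  flat <- qt; flat$mean_csa_um2 <- base
  res <- suppressWarnings(quartile_repeated_measures(flat, "carbonyl", "pad"))
  expect_gt(res$overall_p, 0.9)
  expect_null(res$contrasts)

  set.seed(3)
  eff <- qt
  eff$mean_csa_um2 <- base + ifelse(qt$class == "Q4", -600, 0) + rnorm(32, 0, 60)
  res2 <- quartile_repeated_measures(eff, "carbonyl", "pad")
  expect_lt(res2$overall_p, 0.01)
  expect_equal(nrow(res2$contrasts), 3L)
  q4row <- res2$contrasts[grepl("Q1", res2$contrasts$contrast), ]
  expect_gt(q4row$estimate, 0)  # Q1 - Q4 positive: Q4 smaller

  # missing classes are dropped, not treated as zero
  holey <- eff[!(eff$patient_id == "P01" & eff$class == "Q3"), ]
  expect_silent(quartile_repeated_measures(holey, "carbonyl", "pad"))
})

test_that("quartile model keeps its nominal type-I error under the null", {
  set.seed(13)
  reps <- 1000
  grid <- expand.grid(patient_id = sprintf("P%02d", 1:8),
                      class = c("Q1", "Q2", "Q3", "Q4"),
                      stringsAsFactors = FALSE)
  grid$marker <- "carbonyl"; grid$group <- "pad"; grid$n_fibers <- 50L
  p <- replicate(reps, {
    grid$mean_csa_um2 <- rep(rnorm(8, 4000, 500), 4) + rnorm(32, 0, 150)
    quartile_repeated_measures(grid, "carbonyl", "pad")$overall_p
  })
  hits <- sum(p < 0.05)
  bounds <- qbinom(c(0.005, 0.995), reps, 0.05)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})

test_that("marker agreement behaves at the extremes and under independence", {
  s <- make_summaries(0, 20, seed = 8)
  s$mean_hne_gsu <- 0.6 * s$mean_carbonyl_gsu
  expect_equal(marker_agreement(s)$r, 1, tolerance = 1e-10)

  set.seed(9)
  s$mean_hne_gsu <- rnorm(20, 300, 50)
  expect_lt(abs(marker_agreement(s)$r), qnorm(0.995) / sqrt(17))

  expect_error(marker_agreement(s[1:2, ]), "3 specimens")
})

test_that("shared patient-level damage makes the two markers agree across specimens", {
  coh <- generate_cohort(cohort_config(seed = 19), render_images = FALSE)
  summ <- summarize_cohort(truth_as_measurements(coh$fibers), coh$patients)
  expect_gt(marker_agreement(summ[summ$group == "pad", ])$r, 0.7)
})

test_that("demographics tests reproduce the published chi-square values", {
  md <- data.frame(
    patient_id = sprintf("S%02d", 1:55),
    group = rep(c("control", "pad"), c(21, 34)),
    fontaine_stage = NA,
    cad = c(rep(c(TRUE, FALSE), c(5, 16)), rep(c(TRUE, FALSE), c(21, 13))),
    htn = c(rep(c(TRUE, FALSE), c(12, 9)), rep(c(TRUE, FALSE), c(28, 6))),
    abi = c(runif(21, 0.94, 1.34), runif(34, 0.01, 0.81)))
  tab <- demographics_table(md, variables = c("cad", "htn", "abi"))
  cad_row <- tab[tab$variable == "cad", ]
  expect_equal(cad_row$statistic, 7.50, tolerance = 0.01)
  expect_true(cad_row$covariate_candidate)
  htn_row <- tab[tab$variable == "htn", ]
  expect_equal(htn_row$statistic, 4.15, tolerance = 0.01)
  expect_equal(tab[tab$variable == "abi", "test"], "linear_model_F")

  # identical proportions give a zero statistic
  md2 <- data.frame(patient_id = sprintf("T%02d", 1:54),
                    group = rep(c("control", "pad"), c(20, 34)),
                    cad = c(rep(c(TRUE, FALSE), c(10, 10)),
                            rep(c(TRUE, FALSE), c(17, 17))))
  tab2 <- demographics_table(md2, variables = "cad")
  expect_equal(tab2$statistic, 0, tolerance = 1e-12)

  # hand-built 2x2 table vs the textbook formula
  a <- 5; b <- 16; c_ <- 21; d <- 13; n <- a + b + c_ + d
  chi_formula <- n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_equal(cad_row$statistic, chi_formula, tolerance = 1e-10)
})

test_that("p-values and intervals are internally coherent", {
  coh <- generate_cohort(cohort_config(seed = 29), render_images = FALSE)
  summ <- summarize_cohort(truth_as_measurements(coh$fibers), coh$patients)
  for (o in c("carbonyl", "hne", "csa")) {
    g <- adjusted_group_comparison(summ, o)
    expect_gte(g$p_value, 0)
    expect_lte(g$p_value, 1)
  }
  pr <- abi_partial_correlation(summ, "carbonyl")
  expect_true(pr$ci_low <= pr$r && pr$r <= pr$ci_high)
  expect_gte(pr$p_value, 0); expect_lte(pr$p_value, 1)
})
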