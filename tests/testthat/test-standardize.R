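test_that("mean/SD standardization matches the closed form and applies polarity", {
  ctrl <- cbind(c(8, 8, 12, 12), c(8, 8, 12, 12))   # mean 10
  sd_ctrl <- sd(c(8, 8, 12, 12))   # 2.3094...
  case <- cbind(c(14, 10), c(14, 10))
  tab <- toy_cohort(case, ctrl, polarity = c(1L, -1L))
  std <- standardize_against_controls(tab, "case_a", "control_a")
  expect_equal(std$values[1, 1], (14 - 10) / sd_ctrl)
  expect_equal(std$values[2, 1], 0)
  # polarity -1 stores the negated z
  expect_equal(std$values[, 2], -std$values[, 1])
})

test_that("a literal control mean 10 / SD 2 gives z = 2 for raw 14", {
  ctrl <- matrix(c(7, 9, 11, 13), ncol = 1)   # mean 10
  ctrl <- ctrl * (2 / sd(ctrl))               # rescale to SD exactly 2
  ctrl <- ctrl - mean(ctrl) + 10              # recenter to mean exactly 10
  tab <- toy_cohort(matrix(14, 1, 1), ctrl)
  std <- standardize_against_controls(tab, "case_a", "control_a")
  expect_equal(unname(std$values[1, 1]), 2.0)
})

test_that("age-residual standardization uses the control fit and n-2 residual scale", {
  # controls on score = 1 + 2*age plus residuals orthogonal to age
  ages <- c(1, 2, 3, 4)
  resid <- c(1, -1, -1, 1)                     # sum 0, sum(resid*age) = 0
  ctrl <- matrix(1 + 2 * ages + resid, ncol = 1)
  rse <- sqrt(sum(resid^2) / (4 - 2))          # sqrt(2)
  tab <- toy_cohort(matrix(25, 1, 1), ctrl, ages_case = 10, ages_ctrl = ages)
  methods <- data.frame(scale_id = "sc01", method = "age_residual",
                        interaction_p = NA_real_)
  std <- standardize_against_controls(tab, "case_a", "control_a", methods)
  expect_equal(unname(std$values[1, 1]), (25 - (1 + 2 * 10)) / rse)
})

test_that("controls standardized against themselves have mean 0 and SD 1", {
  set.seed(42)
  spec <- preset_null(p = 5, sizes = c(case_a = 30, case_b = 30,
                                       control_a = 40, control_b = 40), seed = 8)
  tab <- generate_cohort(spec)
  ctrl_std <- standardize_against_controls(tab, "case_a", "control_a",
                                           subjects = "control")
  expect_equal(unname(colMeans(ctrl_std$values)), rep(0, 5))
  expect_equal(unname(apply(ctrl_std$values, 2, sd)), rep(1, 5))
})

test_that("age-residual z reduces to scaled mean/SD z when the sample age slope is zero", {
  # symmetric scores over symmetric ages: sample cov(score, age) = 0
  ages <- c(-2, -1, 1, 2) + 10
  ctrl <- matrix(c(5, 7, 7, 5), ncol = 1)
  tab <- toy_cohort(matrix(8, 1, 1), ctrl, ages_case = 10, ages_ctrl = ages)
  z_ms <- standardize_against_controls(tab, "case_a", "control_a")$values[1, 1]
  methods <- data.frame(scale_id = "sc01", method = "age_residual",
                        interaction_p = NA_real_)
  z_ar <- standardize_against_controls(tab, "case_a", "control_a",
                                       methods)$values[1, 1]
  n <- length(ages)
  # rse uses n-2, sd uses n-1: z_ar = z_ms * sd/rse = z_ms * sqrt((n-2)/(n-1))
  expect_equal(z_ar, z_ms * sqrt((n - 2) / (n - 1)))
})

test_that("effect size equals the difference in standardized group means", {
  set.seed(7)
  spec <- preset_null(p = 3, sizes = c(case_a = 25, case_b = 25,
                                       control_a = 30, control_b = 30), seed = 7)
  tab <- generate_cohort(spec)
  std_a <- standardize_against_controls(tab, "case_a", "control_a")
  std_b <- standardize_against_controls(tab, "case_b", "control_b")
  ctrl_a <- standardize_against_controls(tab, "case_a", "control_a",
                                         subjects = "control")
  ctrl_b <- standardize_against_controls(tab, "case_b", "control_b",
                                         subjects = "control")
  es <- effect_sizes(std_a, std_b, ctrl_a, ctrl_b)
  # OLS group coefficient = difference of group means
  expect_equal(es$effect_a, unname(colMeans(std_a$values) - colMeans(ctrl_a$values)))
  expect_equal(es$effect_b, unname(colMeans(std_b$values) - colMeans(ctrl_b$values)))
})

test_that("a planted shift of 0.8 control-SD units is recovered within 0.1", {
  spec <- preset_null(p = 4, sizes = c(case_a = 500, case_b = 500,
                                       control_a = 500, control_b = 500),
                      seed = 12)
  spec$mean_shift <- matrix(0.8, 4, 2) *
    matrix(sqrt(spec$loadings[1:4]^2 + spec$noise_sd[1:4]^2), 4, 2)
  tab <- generate_cohort(spec)
  std_a <- standardize_against_controls(tab, "case_a", "control_a")
  ctrl_a <- standardize_against_controls(tab, "case_a", "control_a",
                                         subjects = "control")
  std_b <- standardize_against_controls(tab, "case_b", "control_b")
  ctrl_b <- standardize_against_controls(tab, "case_b", "control_b",
                                         subjects = "control")
  es <- effect_sizes(std_a, std_b, ctrl_a, ctrl_b)
  expect_true(all(abs(es$effect_a - 0.8) < 0.1))
})

test_that("interaction screen keeps mean_sd under the null and flags a real interaction", {
  # null: no age-by-group interaction; per-scale type-I ~ alpha
  n_rep <- 100
  picks <- vapply(seq_len(n_rep), function(i) {
    set.seed(1000 + i)
    n <- 100
    ages <- runif(2 * n, 5, 25)
    scores <- matrix(rnorm(2 * n), ncol = 1)
    tab <- toy_cohort(matrix(scores[1:n], ncol = 1),
                      matrix(scores[(n + 1):(2 * n)], ncol = 1),
                      ages_case = ages[1:n], ages_ctrl = ages[(n + 1):(2 * n)])
    detect_age_interaction(tab, "I1", "case_a", "control_a")$method[1]
  }, character(1))
  expect_gte(mean(picks == "mean_sd"), 0.90)

  # strong interaction: case slope differs by 0.5 SD units
  set.seed(99)
  n <- 100
  age_c <- runif(n, 5, 25); age_t <- runif(n, 5, 25)
  case <- matrix(0.5 * scale(age_c)[, 1] + rnorm(n, 0, 1), ncol = 1)
  ctrl <- matrix(rnorm(n), ncol = 1)
  tab <- toy_cohort(case, ctrl, ages_case = age_c, ages_ctrl = age_t)
  det <- detect_age_interaction(tab, "I1", "case_a", "control_a")
  expect_equal(det$method[1], "age_residual")
  expect_lt(det$interaction_p[1], 0.05)
})

test_that("degenerate all-equal ages are rejected by the interaction screen", {
  tab <- toy_cohort(matrix(rnorm(12), ncol = 1), matrix(rnorm(12), ncol = 1),
                    ages_case = rep(10, 12), ages_ctrl = rep(10, 12))
  expect_error(detect_age_interaction(tab, "I1", "case_a", "control_a"),
               "degenerate")
})

test_that("zero control variance names the offending scale", {
  ctrl <- cbind(rnorm(5), rep(3, 5))
  case <- cbind(rnorm(3), rnorm(3))
  tab <- toy_cohort(case, ctrl)
  expect_error(standardize_against_controls(tab, "case_a", "control_a"), "sc02")
})
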