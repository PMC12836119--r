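test_that("coefficient-to-load conversion matches published values", {
  expect_equal(round(unname(beta_to_load(1.517, -0.219)), 3), c(0.198, 0.043))
  expect_equal(round(unname(beta_to_load(2.730, -1.974)), 3), c(0.063, 0.322))
  expect_equal(round(unname(beta_to_load(4.403, -2.798)), 3), c(0.012, 0.171))
  expect_equal(beta_to_load(-2.7, 0)[["B_R"]], 0)    # no slope, no concealed load
  expect_equal(beta_to_load(5, 0)[["B_R"]], 0)
  expect_error(beta_to_load(Inf, 0), "finite")
})

test_that("load-to-coefficient conversion inverts the forward map", {
  fog2 <- beta_to_load(1.517, -0.219)
  b <- beta_from_load(fog2[["A_R"]], fog2[["B_R"]])
  expect_equal(unname(b), c(1.517, -0.219), tolerance = 1e-8)
  expect_equal(unname(beta_from_load(-log(0.5), 0)), c(0, 0))
  expect_error(beta_from_load(-0.5, 0), "outside")
  set.seed(42)
  for (i in 1:1000) {
    b0 <- runif(1, -4, 6); b1 <- runif(1, -5, 5)
    load <- beta_to_load(b0, b1)
    back <- beta_from_load(load[["A_R"]], load[["B_R"]])
    expect_equal(unname(back), c(b0, b1), tolerance = 1e-10)
  }
})

test_that("pair-scale loads halve to the per-individual Morton scale", {
  expect_equal(unname(individual_scale(0.322, 0.322)), c(0.161, 0.161))
  expect_equal(unname(individual_scale(0, 0)), c(0, 0))
  expect_equal(individual_scale(0.063, 0.322)[["B"]], 0.161)
})

test_that("concealed load decreases strictly in the slope at fixed intercept", {
  b1_grid <- seq(-4, 4, by = 0.25)
  B <- vapply(b1_grid, function(b1) beta_to_load(2, b1)[["B_R"]], 0)
  expect_true(all(diff(B) < 0))
  expect_true(all(sign(B) == -sign(b1_grid)))
})

make_fit <- function(beta0, beta1) {
  # minimal well-posed fit object for prediction/curve tests
  rec <- data.frame(line_id = "L", generation = c(1, 1, 3, 3),
                    F_parents = c(0, 0, 0.25, 0.25),
                    copulated = NA, fertile = NA, developed = NA,
                    success = c(TRUE, FALSE, TRUE, FALSE))
  f <- fit_load_model(rec)
  f$coefficients <- c(beta0 = beta0, beta1 = beta1)
  f
}

test_that("predicted success reproduces the published endpoint values", {
  expect_equal(round(predicted_success(make_fit(4.038, -1.320), 1), 2), 0.94)
  expect_equal(1 - predicted_success(make_fit(1.517, -0.219), 0), 0.18,
               tolerance = 0.002)
  f0 <- make_fit(1.2, 0)
  expect_equal(predicted_success(f0, c(0, 0.5, 1)), rep(plogis(1.2), 3))
  expect_error(predicted_success(f0, 1.2), "0, 1")
})

test_that("maximum-likelihood fit matches brute-force likelihood search", {
  toy <- data.frame(
    line_id = letters[1:8], generation = c(1, 1, 3, 3, 4, 4, 5, 5),
    F_parents = c(0, 0, 0.25, 0.25, 0.375, 0.375, 0.5, 0.5),
    copulated = NA, fertile = NA, developed = NA,
    success = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  fit <- fit_load_model(toy)
  oracle <- bf_logistic(toy$success, toy$F_parents)
  expect_equal(unname(coef(fit)), oracle, tolerance = 1e-4)

  toy2 <- toy[1:6, ]
  toy2$success <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  fit2 <- fit_load_model(toy2)
  expect_equal(unname(coef(fit2)), bf_logistic(toy2$success, toy2$F_parents),
               tolerance = 1e-4)
})

test_that("the fit recovers simulated truth within 3 standard errors", {
  cfg <- sim_config(n_lines = 108, max_generations = 20,
                    betas = c(3.5, -1.0), seed = 2024)
  fit <- fit_load_model(simulate_line_extinction(cfg))
  expect_lt(abs(coef(fit)[[1]] - 3.5), 3 * fit$se[[1]])
  expect_lt(abs(coef(fit)[[2]] + 1.0), 3 * fit$se[[2]])
  expect_identical(fit$stage, "overall")
  expect_identical(fit$method, "ml")
})

test_that("degenerate and ill-posed designs raise classed errors", {
  rec <- data.frame(line_id = "L", generation = c(1, 1, 3, 3),
                    F_parents = c(0, 0, 0.25, 0.25),
                    copulated = NA, fertile = NA, developed = NA,
                    success = c(TRUE, TRUE, TRUE, TRUE))
  expect_error(fit_load_model(rec), class = "nemaload_degenerate_fit")
  rec$success <- rep(FALSE, 4)
  expect_error(fit_load_model(rec), class = "nemaload_degenerate_fit")
  rec$success <- c(TRUE, FALSE, TRUE, FALSE)
  rec$F_parents <- rep(0, 4)
  expect_error(fit_load_model(rec), class = "nemaload_design_error")
  # perfectly separated on F
  sep <- data.frame(line_id = "L", generation = c(1, 1, 4, 4),
                    F_parents = c(0, 0, 0.375, 0.375),
                    copulated = NA, fertile = NA, developed = NA,
                    success = c(TRUE, TRUE, FALSE, FALSE))
  expect_error(fit_load_model(sep), class = "nemaload_degenerate_fit")
  firth <- fit_load_model(sep, firth = TRUE)
  expect_identical(firth$method, "firth")
  expect_true(all(is.finite(coef(firth))))
  expect_true(all(is.finite(firth$se)))
})

test_that("Wald test keeps its nominal type-I error rate under the null", {
  n_rep <- 200
  n <- 800
  sched <- sib_mating_F(18)
  rejections <- 0L
  set.seed(99)
  for (i in seq_len(n_rep)) {
    F <- parental_F(sample(1:20, n, replace = TRUE), sched)
    y <- runif(n) < plogis(1.0)   # success independent of F
    rec <- data.frame(line_id = "L", generation = 1L, F_parents = F,
                      copulated = NA, fertile = NA, developed = NA,
                      success = y)
    fit <- fit_load_model(rec)
    if (fit$p_beta1 < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("delta-method load standard errors are exposed as an extension", {
  cfg <- sim_config(n_lines = 108, betas = c(3.3, -1.8), seed = 5)
  s <- summary(fit_load_model(simulate_line_extinction(cfg)), load_se = TRUE)
  expect_true(is.finite(s$se_A_R) && s$se_A_R > 0)
  expect_true(is.finite(s$se_B_R) && s$se_B_R > 0)
})

test_that("expected survival curves match their closed forms and bounds", {
  fog2 <- make_fit(1.517, -0.219)
  s_const <- expected_survival_curve(fog2, 20, mode = "constant")
  expect_equal(s_const[20], plogis(1.517)^20, tolerance = 1e-12)
  expect_equal(round(s_const[20], 3), 0.019)
  expect_true(all(diff(s_const) < 0))

  flat <- make_fit(2.1, 0)
  expect_equal(expected_survival_curve(flat, 15, mode = "constant"),
               expected_survival_curve(flat, 15, mode = "inbreeding"))

  qg704 <- make_fit(3.513, -0.899)
  s_in <- expected_survival_curve(qg704, 20, mode = "inbreeding")
  expect_true(all(diff(s_in) < 0))
  R0 <- plogis(3.513); R1 <- plogis(3.513 - 0.899)
  expect_gt(s_in[20], R1^20)   # bounded by the worst per-cross rate
  expect_lt(s_in[20], R0^20)   # and by the best
})

test_that("stage-wise conditional fits recover their own slopes", {
  sb <- list(copulation = c(3.0, -1.5), fertility = c(3.5, -1.0),
             development = c(4.0, -0.5))
  rec <- make_stage_records(10000, sb, seed = 314)
  fits <- stagewise_fits(rec)
  for (s in names(sb)) {
    expect_s3_class(fits[[s]], "load_fit")
    expect_identical(fits[[s]]$stage, sub("copulation", "copulation", s))
    expect_lt(abs(coef(fits[[s]])[[2]] - sb[[s]][2]), 3 * fits[[s]]$se[[2]])
  }
  # conditional-probability identity at F = 0
  overall <- fit_load_model(rec)
  p_prod <- prod(vapply(sb, function(b) plogis(b[1]), 0))
  expect_equal(predicted_success(overall, 0), p_prod, tolerance = 0.03)
})

test_that("a degenerate stage does not poison the other stage fits", {
  sb <- list(copulation = c(30, 0), fertility = c(30, 0),
             development = c(2.0, -1.0))
  rec <- make_stage_records(2000, sb, seed = 11)
  fits <- stagewise_fits(rec)
  expect_s3_class(fits$copulation, "nemaload_degenerate_fit")
  expect_s3_class(fits$fertility, "nemaload_degenerate_fit")
  expect_s3_class(fits$development, "load_fit")
  expect_lt(abs(coef(fits$development)[[2]] + 1.0),
            3 * fits$development$se[[2]])
})

test_that("load_fit methods behave like a standard model object", {
  cfg <- sim_config(n_lines = 80, betas = c(3.0, -1.2), seed = 8)
  fit <- fit_load_model(simulate_line_extinction(cfg))
  expect_named(coef(fit), c("beta0", "beta1"))
  expect_equal(dim(vcov(fit)), c(2L, 2L))
  expect_equal(predict(fit, data.frame(F = 0.5)),
               predicted_success(fit, 0.5))
  expect_equal(length(residuals(fit)), fit$n_crosses)
  expect_output(print(fit), "beta0")
  expect_output(print(summary(fit)), "Concealed load")
  sims <- simulate(fit, nsim = 2, seed = 3, n_lines = 10,
                   max_generations = 5)
  expect_length(sims, 2)
  expect_true(all(c("line_id", "success") %in% names(sims[[1]])))
})
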