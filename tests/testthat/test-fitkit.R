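fast_conc <- 10^seq(0, log10(50), length.out = 12)

test_that("noise-free synthetic curves equal the model exactly and are deterministic", {
  pa <- params_asyn(); ea <- asyn_ensemble()
  d0 <- generate_synthetic_curve(pa, ea, fast_conc, "mean_length",
                                 noise_sd = 0, seed = 3)
  expect_equal(d0$value,
               amyloidtm:::.predict_curve(ea, pa, fast_conc, "mean_length"),
               tolerance = 1e-12)
  d1 <- generate_synthetic_curve(pa, ea, fast_conc, "mean_length",
                                 noise_sd = 0.05, seed = 8)
  d2 <- generate_synthetic_curve(pa, ea, fast_conc, "mean_length",
                                 noise_sd = 0.05, seed = 8)
  expect_identical(d1$value, d2$value)
  d3 <- generate_synthetic_curve(pa, ea, fast_conc, "mean_length",
                                 noise_sd = 0.05, seed = 9)
  expect_false(identical(d1$value, d3$value))
  expect_error(generate_synthetic_curve(pa, ea, fast_conc, noise_sd = 0.1),
               "seed")
})

test_that("noise model has the declared standard deviation and respects bounds", {
  pa <- params_asyn(); ea <- asyn_ensemble()
  ## a grid where the sheet fraction stays well inside (0, 1), so the
  ## clipping never truncates the Gaussian noise
  conc <- 10^seq(log10(10), log10(50), length.out = 12)
  mu <- amyloidtm:::.predict_curve(ea, pa, conc, "sheet_fraction")
  resid <- unlist(lapply(1:50, function(i) {
    d <- generate_synthetic_curve(pa, ea, conc, "sheet_fraction",
                                  noise_sd = 0.02, seed = 100 + i)
    d$value - mu
  }))
  expect_lt(abs(sd(resid) - 0.02) / 0.02, 0.10)
  dl <- generate_synthetic_curve(pa, ea, fast_conc, "mean_length",
                                 noise_sd = 5, seed = 4)
  expect_true(all(dl$value >= 1))
  ds <- generate_synthetic_curve(pa, ea, fast_conc, "sheet_fraction",
                                 noise_sd = 0.5, seed = 4)
  expect_true(all(ds$value >= 0 & ds$value <= 1))
})

test_that("a noise-free curve is refit to its generating parameters", {
  pa <- params_asyn(); ea <- asyn_ensemble()
  d0 <- generate_synthetic_curve(pa, ea, fast_conc, "mean_length",
                                 noise_sd = 0, seed = 3)
  init <- update_params(pa, P2 = 2.7 * 1.15, B = 1.95 * 0.85, R2 = -1.64 * 1.2)
  f <- fit_observable_curve(d0, ea, init = init, free = c("P2", "B", "R2"),
                            ties = c(K = "P2"), n_restarts = 2, seed = 1)
  expect_true(f$converged)
  expect_equal(unname(f$estimates["P2"]), 2.7, tolerance = 1e-4)
  expect_equal(unname(f$estimates["B"]), 1.95, tolerance = 1e-4)
  expect_equal(unname(f$estimates["R2"]), -1.64, tolerance = 1e-3)
  ## refitting from the optimum is a fixed point
  f2 <- fit_observable_curve(d0, ea, init = f$params, free = c("P2", "B", "R2"),
                             ties = c(K = "P2"), n_restarts = 1,
                             warmup = FALSE, seed = 1)
  expect_lt(max(abs(f2$estimates - f$estimates)), 1e-5)
})

test_that("duplicating every data point leaves the fitted parameters unchanged", {
  pa <- params_asyn(); ea <- asyn_ensemble()
  d <- generate_synthetic_curve(pa, ea, fast_conc, "mean_length",
                                noise_sd = 0.05, seed = 21)
  dd <- dplyr::bind_rows(d, d)
  init <- update_params(pa, P2 = 2.6, B = 2.1, R2 = -1.5)
  f1 <- fit_observable_curve(d, ea, init = init, free = c("P2", "B", "R2"),
                             ties = c(K = "P2"), n_restarts = 1, seed = 2)
  f2 <- fit_observable_curve(dd, ea, init = init, free = c("P2", "B", "R2"),
                             ties = c(K = "P2"), n_restarts = 1, seed = 2)
  ## same optimum up to the optimizer's termination scatter, far below the
  ## statistical uncertainty of the parameters
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-3)
  expect_lt(max(abs(f1$estimates - f2$estimates) / f1$std_errors), 0.25)
})

test_that("bias of the fitted parameters shrinks as the noise vanishes", {
  pa <- params_asyn(); ea <- asyn_ensemble()
  truth <- c(P2 = 2.7, B = 1.95, R2 = -1.64)
  mean_abs_err <- vapply(c(0.5, 0.05, 0), function(sd) {
    errs <- vapply(1:3, function(i) {
      d <- generate_synthetic_curve(pa, ea, fast_conc, "mean_length",
                                    noise_sd = sd, seed = 400 + i)
      f <- fit_observable_curve(d, ea,
                                init = update_params(pa, P2 = 2.55, B = 2.05,
                                                     R2 = -1.8),
                                free = c("P2", "B", "R2"), ties = c(K = "P2"),
                                n_restarts = 1, seed = i)
      max(abs(f$estimates - truth))
    }, 0)
    mean(errs)
  }, 0)
  expect_lt(mean_abs_err[3], 1e-3)
  expect_lt(mean_abs_err[3], mean_abs_err[1])
})

test_that("tidy and glance expose the fit summary", {
  pa <- params_asyn(); ea <- asyn_ensemble()
  d <- generate_synthetic_curve(pa, ea, fast_conc, "mean_length",
                                noise_sd = 0.02, seed = 77)
  f <- fit_observable_curve(d, ea, init = pa, free = c("P2", "B"),
                            ties = c(K = "P2"), n_restarts = 1, seed = 3)
  td <- generics::tidy(f)
  expect_identical(td$term, c("P2", "B"))
  expect_true(all(is.finite(td$estimate)))
  gl <- generics::glance(f)
  expect_identical(gl$nobs, 12L)
  expect_true(gl$n_eval > 0)
  p <- ggplot2::autoplot(f)
  expect_s3_class(p, "ggplot")
})
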