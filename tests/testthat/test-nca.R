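test_that("Cmax/Tmax pick the maximum and the earliest tying time, in hours", {
  peak <- compute_cmax_tmax(c(0, 60, 120), c(0, 10, 5))
  expect_equal(peak$cmax, 10)
  expect_equal(peak$tmax_h, 1)
  tie <- compute_cmax_tmax(c(0, 30, 60, 90), c(1, 8, 8, 2))
  expect_equal(tie$tmax_h, 0.5) # earliest of the tied maxima
  flat <- compute_cmax_tmax(c(0, 10, 20), c(0, 0, 0))
  expect_false(flat$quantifiable)
  expect_error(compute_cmax_tmax(c(0, 10), c(1, 2)), "3 points")
})

test_that("the sampled peak of a noiseless absorption curve sits at the closed-form tmax", {
  tr <- pk_truth(ka = 0.05, ke = 0.005, noise_cv = 0)
  prof <- gen_concentration_profiles(tr, 1, seed = 1L)
  peak <- compute_cmax_tmax(prof$time_min, prof$conc)
  # analytic argmax ln(10)/0.045 = 51.2 min; nearest sampled time is 60 min
  tm <- true_tmax(tr)
  grid <- tr$sample_times
  expect_equal(peak$tmax_h * 60, grid[which.max(conc_curve(tr, grid))])
  expect_equal(grid[which.min(abs(grid - tm))],
               peak$tmax_h * 60)
})

test_that("trapezoidal AUC matches simple closed forms and the analytic integral", {
  expect_equal(compute_auc_trapezoid(c(0, 60, 120), c(10, 10, 10)), 20)
  expect_equal(compute_auc_trapezoid(c(0, 60, 120), c(0, 0, 0)), 0)
  # C(t) = 100 exp(-0.5 t/h) on [0, 12] h every 0.25 h
  th <- seq(0, 12, by = 0.25)
  cc <- 100 * exp(-0.5 * th)
  got <- compute_auc_trapezoid(th * 60, cc)
  exact <- 200 * (1 - exp(-6))
  # trapezoid on exp decay overestimates by <= h^2/12 * max|f''| * span
  expect_lt(abs(got - exact), 0.25^2 / 12 * 0.25 * 100 * length(th))
  expect_equal(got, exact, tolerance = 3e-3)
  # log-down is exact on exponential decline
  expect_equal(compute_auc_trapezoid(th * 60, cc, method = "log-down"), exact,
               tolerance = 1e-10)
  expect_error(compute_auc_trapezoid(c(0), c(1)), "2 points")
})

test_that("appending nonnegative segments never decreases AUC", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    t <- sort(sample(1:500, n))
    c <- runif(n, 0, 50)
    base <- compute_auc_trapezoid(t, c)
    ext <- compute_auc_trapezoid(c(t, max(t) + 30), c(c, runif(1, 0, 50)))
    expect_gte(ext, base - 1e-12)
  }
})

test_that("the terminal fit recovers an exact exponential tail", {
  # ke = 0.1/h, sampled hourly: lambda_z = 0.1, t1/2 = 6.931 h, r2 = 1
  th <- 0:12
  cc <- 50 * exp(-0.1 * th)
  cc[1] <- 10 # rising point so tmax = 1 h and the tail starts after it
  fit <- fit_terminal_slope(th * 60, cc)
  expect_equal(fit$lambda_z, 0.1, tolerance = 1e-10)
  expect_equal(fit$t_half_h, log(2) / 0.1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("too few post-peak points or a flat tail are not estimable", {
  expect_error(fit_terminal_slope(c(0, 60, 120, 180), c(1, 10, 8, 6)),
               "fewer than 3")
  expect_error(fit_terminal_slope(c(0, 60, 120, 180, 240), c(1, 10, 5, 5, 5)),
               "not estimable")
  expect_error(fit_terminal_slope(c(0, 60, 120), c(0, 0, 0)), "not estimable")
})

test_that("leading absorption points do not disturb the selected terminal window", {
  tr <- pk_truth(ka = 0.06, ke = 0.008, noise_cv = 0)
  tail_times <- c(120, 180, 240, 360, 480, 720)
  full_times <- c(5, 10, 20, 40, 60, 90, tail_times)
  conc_full <- conc_curve(tr, full_times)
  fit_full <- fit_terminal_slope(full_times, conc_full)
  # exhaustive suffix oracle over the post-peak points
  peak_i <- which.max(conc_full)
  cand <- (peak_i + 1):length(full_times)
  best <- NULL
  for (s in cand[seq_len(length(cand) - 2)]) {
    idx <- which(full_times >= full_times[s])
    f <- lm(log(conc_full[idx]) ~ I(full_times[idx] / 60))
    r2 <- summary(f)$r.squared
    adj <- 1 - (1 - r2) * (length(idx) - 1) / (length(idx) - 2)
    if (is.null(best) || adj > best$adj + 1e-10)
      best <- list(adj = adj, lambda = -coef(f)[[2]])
  }
  expect_equal(fit_full$lambda_z, best$lambda, tolerance = 1e-12)
})

test_that("AUC extrapolation follows Clast over lambda_z", {
  expect_equal(extrapolate_auc_inf(100, 5, 0.5), 110)
  expect_equal(extrapolate_auc_inf(40, 0, 0.2), 40)
  expect_error(extrapolate_auc_inf(100, 5, 0), "positive")
  # pure exponential from t=0, dense sampling: AUCinf ~ C0/ke
  th <- seq(0, 48, by = 0.05)
  cc <- 80 * exp(-0.25 * th)
  cc[1] <- 1 # nominal rise for a defined post-peak phase
  auc <- compute_auc_trapezoid(th * 60, cc)
  fit <- fit_terminal_slope(th * 60, cc)
  inf <- extrapolate_auc_inf(auc, cc[length(cc)], fit$lambda_z)
  expect_equal(inf, 80 / 0.25, tolerance = 1e-2)
})

test_that("rescaling time rescales lambda_z inversely and t1/2 proportionally", {
  th <- c(1, 2, 4, 6, 8, 12)
  cc <- c(5, 40, 25, 16, 10, 4)
  f1 <- fit_terminal_slope(th * 60, cc)
  f2 <- fit_terminal_slope(th * 60 * 3, cc)
  expect_equal(f2$lambda_z, f1$lambda_z / 3, tolerance = 1e-10)
  expect_equal(f2$t_half_h, f1$t_half_h * 3, tolerance = 1e-10)
})

test_that("the per-compound summary has the reporting shape and SD conventions", {
  tr <- pk_truth(noise_cv = 0)
  prof <- gen_concentration_profiles(tr, 2, seed = 1L)
  prof$compound <- "cpd1"
  out <- summarize_pk(prof)
  expect_equal(out$n_subjects, 2)
  # column order mirrors the report: Cmax, Tmax, t1/2, AUC0-t, AUC0-inf
  expect_equal(grep("_mean$", names(out), value = TRUE),
               c("cmax_mean", "tmax_h_mean", "t_half_h_mean", "auc_0_t_mean",
                 "auc_0_inf_mean"))
  expect_equal(out$cmax_sd, 0) # identical subjects
  single <- summarize_pk(prof[prof$subject == "S01", ])
  expect_true(is.na(single$cmax_sd)) # absent, not zero
  expect_true(out$auc_0_inf_mean >= out$auc_0_t_mean)
})

test_that("NCA on noiseless synthetic subjects recovers the true parameters", {
  tr <- pk_truth(noise_cv = 0)
  prof <- gen_concentration_profiles(tr, 20, seed = 3L)
  out <- summarize_pk(prof)
  true_thalf_h <- log(2) / tr$ke / 60
  true_auc_inf <- tr$dose / (tr$V_F * tr$ke) / 60
  expect_lt(abs(out$t_half_h_mean - true_thalf_h) / true_thalf_h, 0.02)
  expect_lt(abs(out$auc_0_inf_mean - true_auc_inf) / true_auc_inf, 0.05)
})
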