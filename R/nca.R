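#' @name netpharm-nca
#' @title Non-compartmental pharmacokinetic analysis
#'
#' @description Model-free estimation of the five standard exposure
#' parameters from a plasma concentration-time profile: Cmax, Tmax,
#' terminal half-life, AUC to the last observation and AUC extrapolated
#' to infinity. Times are supplied in minutes (the sampling unit) and all
#' reported time-based quantities are in hours, the conventional
#' reporting unit (a 40-min peak reports as Tmax 0.67 h).
NULL

validate_profile <- function(times, concs) {
  if (length(times) != length(concs))
    stop("times and concentrations differ in length", call. = FALSE)
  if (length(times) < 3L)
    stop("a profile needs at least 3 points", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(concs < 0) || any(!is.finite(concs)))
    stop("concentrations must be finite and nonnegative", call. = FALSE)
  invisible(TRUE)
}

#' Peak concentration and its time
#'
#' `cmax` is the maximum observed concentration; `tmax` the earliest time
#' achieving it, reported in hours. A profile of all zeros carries no
#' quantifiable exposure and is flagged with `quantifiable = FALSE`.
#'
#' @param times sampling times in minutes, strictly increasing.
#' @param concs nonnegative concentrations, same length.
#' @return list with `cmax`, `tmax_h`, `quantifiable`.
#' @export
compute_cmax_tmax <- function(times, concs) {
  validate_profile(times, concs)
  if (all(concs == 0))
    return(list(cmax = 0, tmax_h = NA_real_, quantifiable = FALSE))
  i <- which.max(concs) # ties: which.max takes the first, i.e. earliest
  list(cmax = concs[i], tmax_h = times[i] / 60, quantifiable = TRUE)
}

#' Area under the curve to the last observation
#'
#' Trapezoidal integration over the observed span, in concentration-hours.
#' The default is the linear trapezoid on every interval; `"log-down"`
#' uses the log-trapezoid on intervals where the concentration declines
#' between two positive values (the usual alternative for the
#' post-absorption phase) and falls back to linear elsewhere.
#'
#' @param times minutes, strictly increasing (>= 2 points).
#' @param concs nonnegative concentrations.
#' @param method `"linear"` or `"log-down"`.
#' @return AUC(0-t) in conc * hours.
#' @export
compute_auc_trapezoid <- function(times, concs, method = c("linear", "log-down")) {
  method <- match.arg(method)
  if (length(times) < 2L) stop("AUC needs at least 2 points", call. = FALSE)
  if (length(times) != length(concs) || any(diff(times) <= 0) || any(concs < 0))
    stop("invalid profile", call. = FALSE)
  th <- times / 60
  dt <- diff(th)
  c1 <- concs[-length(concs)]
  c2 <- concs[-1]
  seg <- (c1 + c2) / 2 * dt
  if (method == "log-down") {
    logdown <- c2 < c1 & c2 > 0
    seg[logdown] <- (c1[logdown] - c2[logdown]) /
      log(c1[logdown] / c2[logdown]) * dt[logdown]
  }
  sum(seg)
}

#' Terminal-phase log-linear regression
#'
#' Estimates the terminal elimination rate `lambda_z` (1/h) by
#' least-squares on log concentration over a terminal point run. The run
#' is chosen automatically, the standard NCA convention: among candidate
#' suffixes of the positive-concentration points strictly after Tmax,
#' with at least `min_points` points, the one maximizing adjusted r^2
#' wins (ties go to the longer run). Zero concentrations are excluded
#' from the regression. `t_half = ln 2 / lambda_z` in hours.
#'
#' @param times minutes, strictly increasing.
#' @param concs nonnegative concentrations.
#' @param min_points minimum points in the regression (default 3).
#' @return list with `lambda_z` (1/h), `t_half_h`, `r_squared`,
#'   `adj_r_squared`, `points_used` (times in minutes of the points).
#' @export
fit_terminal_slope <- function(times, concs, min_points = 3) {
  validate_profile(times, concs)
  peak <- compute_cmax_tmax(times, concs)
  if (!peak$quantifiable)
    stop("terminal phase not estimable: no quantifiable exposure", call. = FALSE)
  after <- times / 60 > peak$tmax_h & concs > 0
  t_el <- times[after] / 60
  c_el <- concs[after]
  m <- length(t_el)
  if (m < min_points)
    stop("terminal phase not estimable: fewer than ", min_points,
         " positive points after Tmax", call. = FALSE)
  best <- NULL
  for (start in seq_len(m - min_points + 1L)) {
    tt <- t_el[start:m]
    cc <- c_el[start:m]
    fit <- lm(log(cc) ~ tt)
    slope <- coef(fit)[[2]]
    # a slope indistinguishable from zero at double precision is a flat
    # tail, not an elimination phase
    if (!is.finite(slope) || slope >= -1e-9) next
    y <- log(cc)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    nn <- length(tt)
    adj <- 1 - (1 - r2) * (nn - 1) / (nn - 2)
    # prefer higher adjusted r^2; on (near-exact) ties keep the longer run,
    # which is the earlier candidate
    if (is.null(best) || adj > best$adj + 1e-10) {
      best <- list(lambda = -slope, r2 = r2, adj = adj,
                   pts = times[after][start:m])
    }
  }
  if (is.null(best))
    stop("terminal phase not estimable: no declining terminal segment",
         call. = FALSE)
  list(lambda_z = best$lambda, t_half_h = log(2) / best$lambda,
       r_squared = best$r2, adj_r_squared = best$adj,
       points_used = best$pts)
}

#' Extrapolate AUC to infinity
#'
#' `AUC(0-inf) = AUC(0-t) + Clast / lambda_z`, with `Clast` the last
#' quantifiable concentration and `lambda_z` the terminal rate (1/h).
#'
#' @param auc_0_t AUC to the last observation (conc * h).
#' @param c_last last quantifiable concentration.
#' @param lambda_z terminal elimination rate, must be positive.
#' @return AUC(0-inf) in conc * hours.
#' @export
extrapolate_auc_inf <- function(auc_0_t, c_last, lambda_z) {
  if (!is.finite(lambda_z) || lambda_z <= 0)
    stop("lambda_z must be positive", call. = FALSE)
  auc_0_t + c_last / lambda_z
}

#' Full NCA for one profile
#'
#' Runs the component estimators and assembles the five reported
#' parameters (Cmax; Tmax, t1/2 in hours; AUC0-t, AUC0-inf in
#' conc-hours) plus the terminal-fit diagnostics.
#'
#' @param times minutes, strictly increasing.
#' @param concs nonnegative concentrations.
#' @param auc_method passed to [compute_auc_trapezoid()].
#' @param min_points passed to [fit_terminal_slope()].
#' @return one-row data frame with columns `cmax`, `tmax_h`, `t_half_h`,
#'   `auc_0_t`, `auc_0_inf`, `lambda_z`, `r_squared_terminal`.
#' @export
nca_profile <- function(times, concs, auc_method = "linear", min_points = 3) {
  peak <- compute_cmax_tmax(times, concs)
  auc <- compute_auc_trapezoid(times, concs, method = auc_method)
  term <- tryCatch(fit_terminal_slope(times, concs, min_points),
                   error = function(e) NULL)
  c_last <- {
    pos <- which(concs > 0)
    if (length(pos)) concs[max(pos)] else 0
  }
  data.frame(
    cmax = peak$cmax,
    tmax_h = peak$tmax_h,
    t_half_h = if (is.null(term)) NA_real_ else term$t_half_h,
    auc_0_t = auc,
    auc_0_inf = if (is.null(term)) NA_real_
                else extrapolate_auc_inf(auc, c_last, term$lambda_z),
    lambda_z = if (is.null(term)) NA_real_ else term$lambda_z,
    r_squared_terminal = if (is.null(term)) NA_real_ else term$r_squared)
}

#' Per-compound mean and SD of the NCA parameters
#'
#' Applies [nca_profile()] per subject and summarizes each parameter as
#' mean and sample SD per compound, the conventional "mean +/- SD" table
#' shape with columns ordered Cmax, Tmax, t1/2, AUC0-t, AUC0-inf. With a
#' single subject the SD is reported as NA, not zero.
#'
#' @param profiles data frame with columns `subject`, `time_min`, `conc`
#'   and optionally `compound` (a single unnamed compound is assumed
#'   otherwise).
#' @param auc_method,min_points passed through to the per-profile NCA.
#' @return data frame, one row per compound: `compound`, `n_subjects`,
#'   then `<param>_mean` / `<param>_sd` for `cmax`, `tmax_h`, `t_half_h`,
#'   `auc_0_t`, `auc_0_inf`.
#' @export
summarize_pk <- function(profiles, auc_method = "linear", min_points = 3) {
  stopifnot(all(c("subject", "time_min", "conc") %in% names(profiles)))
  if (!"compound" %in% names(profiles)) profiles$compound <- "compound"
  params <- c("cmax", "tmax_h", "t_half_h", "auc_0_t", "auc_0_inf")
  rows <- lapply(split(profiles, profiles$compound), function(d) {
    per_subj <- do.call(rbind, lapply(split(d, d$subject), function(s) {
      s <- s[order(s$time_min), ]
      nca_profile(s$time_min, s$conc, auc_method, min_points)
    }))
    n <- nrow(per_subj)
    row <- data.frame(compound = d$compound[1], n_subjects = n,
                      stringsAsFactors = FALSE)
    for (p in params) {
      row[[paste0(p, "_mean")]] <- mean(per_subj[[p]], na.rm = TRUE)
      row[[paste0(p, "_sd")]] <- if (n < 2) NA_real_ else sd(per_subj[[p]],
                                                             na.rm = TRUE)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
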