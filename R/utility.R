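# Survival-based utility distances: do analyses on the synthetic control arm
# reach the same treatment-effect conclusions as on the original arm?

#' Kaplan-Meier product-limit estimate
#'
#' @param times Non-negative event/censoring times.
#' @param events 0/1 vector (1 = event observed) of the same length.
#' @return An object of class `survival_curve`: `times` (ascending distinct
#'   event times), `survival` (non-increasing, S(0) = 1 implicit),
#'   `censor_times`, `max_followup`, `n`.
#' @export
km_estimate <- function(times, events) {
  check_(length(times) == length(events), "times and events differ in length")
  check_(is.numeric(times) && all(times >= 0), "times must be non-negative")
  events <- as.numeric(events)
  check_(all(events %in% c(0, 1)), "events must be 0/1")
  ut <- sort(unique(times[events == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  structure(list(times = ut, survival = surv,
                 censor_times = sort(times[events == 0]),
                 max_followup = if (length(times)) max(times) else 0,
                 n = length(times)),
            class = "survival_curve")
}

#' Evaluate a survival curve at arbitrary times
#'
#' Right-continuous step function; `S(t) = 1` before the first event time.
#'
#' @param curve A `survival_curve`.
#' @param t Numeric times.
#' @export
surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$times)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1L)])
}

#' Median survival time of a curve
#'
#' First time at which the survival estimate drops to 0.5 or below. A curve
#' that never reaches 0.5 has no defined median and raises a
#' `synarm_undefined_median` error.
#'
#' @param curve A `survival_curve`.
#' @export
km_median <- function(curve) {
  hit <- which(curve$survival <= 0.5)
  if (!length(hit))
    abort_("survival curve never reaches 0.5: median undefined",
           "synarm_undefined_median")
  curve$times[hit[1L]]
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> n=%d, %d event times, max follow-up %.3g\n",
              x$n, length(x$times), x$max_followup))
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, add = FALSE, col = 1, lwd = 1, ...) {
  tt <- c(0, rep(x$times, each = 2), x$max_followup)
  ss <- c(1, 1, rep(x$survival, each = 2))[seq_along(tt)]
  if (!add) plot(tt, ss, type = "l", ylim = c(0, 1), xlab = "time",
                 ylab = "survival", col = col, lwd = lwd, ...)
  else graphics::lines(tt, ss, col = col, lwd = lwd, ...)
  invisible(x)
}

#' Export a survival curve as a (time, survival) table
#' @param curve A `survival_curve`.
#' @export
as.data.frame.survival_curve <- function(x, ...) {
  data.frame(time = c(0, x$times), survival = c(1, x$survival))
}

km_from_dataset_ <- function(d) {
  sch <- d$schema
  km_estimate(d$data[[surv_col_(sch)]],
              as.numeric(d$data[[event_col_(sch)]] == "1"))
}

#' Cox proportional-hazards fit on a trial dataset
#'
#' Partial-likelihood maximization with Efron handling of ties. Categorical
#' covariates are expanded against the shared schema levels so coefficient
#' vectors from datasets with the same schema align. Non-convergence (no
#' events, complete separation, vanished categories) is flagged, never
#' silent.
#'
#' @param d A `trial_dataset`.
#' @param covariates Covariate names (>= 1); default: all schema covariates.
#' @return An object of class `cox_fit`: `coefficients`, `se`, `converged`,
#'   `n`, `n_events`.
#' @export
fit_cox <- function(d, covariates = covariate_names(d$schema)) {
  check_(length(covariates) >= 1L, "need at least one covariate")
  sch <- d$schema
  tt <- d$data[[surv_col_(sch)]]
  ev <- as.numeric(d$data[[event_col_(sch)]] == "1")
  if (sum(ev) == 0)
    abort_("no events: partial likelihood undefined", "synarm_convergence_error")
  X <- encode_features_(d, covariates)
  keep <- apply(X, 2L, function(col) stats::var(col) > 0)
  df <- data.frame(.time = tt, .event = ev, X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(X)[keep]), collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- setNames(rep(0, ncol(X)), colnames(X))
  beta[names(coef(fit))] <- coef(fit)
  se <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  se[names(coef(fit))] <- sqrt(diag(fit$var))
  converged <- !warned && all(is.finite(coef(fit)))
  structure(list(coefficients = beta, se = se, converged = converged,
                 n = nrow(X), n_events = sum(ev), dropped = colnames(X)[!keep]),
            class = "cox_fit")
}

#' Cox beta distance
#'
#' Euclidean norm of the difference between the log-hazard-ratio vectors
#' fitted on the original and the synthetic data.
#'
#' @param original,synthetic `trial_dataset`s sharing a schema.
#' @param covariates Covariate names used in both fits.
#' @return A non-negative real.
#' @export
cox_beta_distance <- function(original, synthetic,
                              covariates = covariate_names(original$schema)) {
  f1 <- fit_cox(original, covariates)
  f2 <- fit_cox(synthetic, covariates)
  if (!f1$converged || !f2$converged)
    abort_(sprintf("Cox fit failed to converge (original: %s, synthetic: %s)",
                   f1$converged, f2$converged), "synarm_convergence_error")
  sqrt(sum((f1$coefficients - f2$coefficients)^2))
}

rmst_ <- function(curve, horizon) {
  tt <- c(0, curve$times[curve$times <= horizon], horizon)
  ss <- c(1, curve$survival[curve$times <= horizon])
  sum(diff(tt) * ss)
}

#' Median survival distance
#'
#' Absolute difference between the Kaplan-Meier median survival estimates of
#' the two datasets. If a median is undefined (curve never crosses 0.5) the
#' default policy is an error; `fallback = "rmst"` substitutes the absolute
#' difference in restricted mean survival time over the common follow-up,
#' with a warning.
#'
#' @param original,synthetic `trial_dataset`s sharing a schema.
#' @param fallback `"error"` (default) or `"rmst"`.
#' @return A non-negative real.
#' @export
median_survival_distance <- function(original, synthetic,
                                     fallback = c("error", "rmst")) {
  fallback <- match.arg(fallback)
  c1 <- km_from_dataset_(original)
  c2 <- km_from_dataset_(synthetic)
  med <- tryCatch(abs(km_median(c1) - km_median(c2)),
                  synarm_undefined_median = function(e) e)
  if (!inherits(med, "condition")) return(med)
  if (fallback == "error") stop(med)
  warning("KM median undefined; falling back to restricted-mean distance")
  horizon <- min(c1$max_followup, c2$max_followup)
  abs(rmst_(c1, horizon) - rmst_(c2, horizon))
}

#' Survival curve distance
#'
#' Integrated absolute difference between the two Kaplan-Meier curves over
#' `[0, T]`, `T` = the shorter of the two maximum follow-ups, evaluated
#' exactly on the merged step grid.
#'
#' @param original,synthetic `trial_dataset`s sharing a schema.
#' @return A non-negative real (time units).
#' @export
survival_curve_distance <- function(original, synthetic) {
  check_(n_patients(original) > 0 && n_patients(synthetic) > 0,
         "datasets must be non-empty")
  c1 <- km_from_dataset_(original)
  c2 <- km_from_dataset_(synthetic)
  horizon <- min(c1$max_followup, c2$max_followup)
  grid <- sort(unique(c(0, c1$times[c1$times <= horizon],
                        c2$times[c2$times <= horizon], horizon)))
  if (length(grid) < 2L) return(0)
  lo <- grid[-length(grid)]
  sum(diff(grid) * abs(surv_at(c1, lo) - surv_at(c2, lo)))
}

# ---- flexible parametric (spline-on-log-cumulative-hazard) survival model --

ns_basis_ <- function(y, knots, boundary) {
  cbind(1, splines::ns(y, knots = knots, Boundary.knots = boundary))
}

ns_basis_deriv_ <- function(y, knots, boundary, h = 1e-5) {
  (ns_basis_(y + h, knots, boundary) - ns_basis_(y - h, knots, boundary)) / (2 * h)
}

#' Fit a spline-based proportional-hazards survival model
#'
#' Models the log cumulative hazard as a natural cubic spline in log time
#' (2 internal knots at the 33rd/67th percentiles of event log-times,
#' boundary knots at the extreme event log-times) plus a linear covariate
#' term, maximizing the full likelihood. This is the flexible parametric
#' form used by the predicted-survival distance.
#'
#' @param times,events Follow-up times (> 0 after flooring) and 0/1 event
#'   indicators.
#' @param X Numeric covariate matrix (may have zero columns).
#' @param n_internal_knots Number of internal spline knots (default 2).
#' @return An object of class `spline_ph_fit`.
#' @export
fit_spline_ph <- function(times, events, X, n_internal_knots = 2L) {
  events <- as.numeric(events)
  check_(sum(events) >= 5, "too few events to fit the spline hazard model")
  tfloor <- max(min(times[times > 0]), 1e-8) / 2
  y <- log(pmax(times, tfloor))
  ye <- y[events == 1]
  boundary <- range(ye)
  knots <- unique(stats::quantile(ye, probs = seq_len(n_internal_knots) /
                                    (n_internal_knots + 1L), type = 7))
  knots <- knots[knots > boundary[1L] & knots < boundary[2L]]
  B <- ns_basis_(y, knots, boundary)
  Bp <- ns_basis_deriv_(y, knots, boundary)
  X <- as.matrix(X)
  keep <- if (ncol(X)) apply(X, 2L, function(c) stats::var(c) > 0) else logical(0)
  Xk <- X[, keep, drop = FALSE]
  np <- ncol(B); nb <- ncol(Xk)

  # init: regress log Nelson-Aalen cumulative hazard on the basis
  ut <- sort(unique(times[events == 1]))
  na_h <- cumsum(vapply(ut, function(t)
    sum(times == t & events == 1) / sum(times >= t), numeric(1L)))
  Bu <- ns_basis_(log(ut), knots, boundary)
  g0 <- tryCatch(stats::lm.fit(Bu, log(pmax(na_h, 1e-8)))$coefficients,
                 error = function(e) NULL)
  if (is.null(g0) || any(!is.finite(g0))) g0 <- c(0, rep(1, np - 1L))
  par0 <- c(g0, rep(0, nb))

  negll <- function(par) {
    g <- par[seq_len(np)]
    b <- par[np + seq_len(nb)]
    eta <- drop(B %*% g) + if (nb) drop(Xk %*% b) else 0
    ds <- drop(Bp %*% g)
    ev <- events == 1
    if (any(ds[ev] <= 1e-10)) return(1e10 + sum(pmax(0, -ds[ev])) * 1e6)
    H <- exp(pmin(eta, 50))
    -(sum(log(ds[ev]) - y[ev] + eta[ev]) - sum(H))
  }
  opt <- stats::optim(par0, negll, method = "BFGS",
                      control = list(maxit = 500))
  if (!is.finite(opt$value) || opt$value >= 1e9)
    abort_("spline hazard fit failed: no feasible monotone solution",
           "synarm_fit_error")
  structure(list(gamma = opt$par[seq_len(np)],
                 beta = setNames(opt$par[np + seq_len(nb)], colnames(Xk)),
                 keep = keep, knots = knots, boundary = boundary,
                 tfloor = tfloor, convergence = opt$convergence,
                 loglik = -opt$value),
            class = "spline_ph_fit")
}

#' Predicted survival probabilities from a spline hazard fit
#'
#' @param fit A [fit_spline_ph()] result.
#' @param X Covariate matrix (full schema encoding; the fit selects its
#'   retained columns).
#' @param t Positive time grid.
#' @return Matrix `length(t)` x `nrow(X)` of survival probabilities.
#' @export
predict_spline_ph <- function(fit, X, t) {
  X <- as.matrix(X)
  Xk <- X[, fit$keep, drop = FALSE]
  y <- log(pmax(t, fit$tfloor))
  B <- ns_basis_(y, fit$knots, fit$boundary)
  base <- drop(B %*% fit$gamma)
  lp <- if (ncol(Xk)) drop(Xk %*% fit$beta) else rep(0, nrow(X))
  S <- exp(-exp(outer(base, lp, `+`)))
  S[t <= 0, ] <- 1
  S
}

#' Predicted survival distance
#'
#' Fits one flexible parametric survival model per dataset, predicts a
#' patient-specific survival curve for every original patient under each
#' model over a common time grid, and returns the mean over patients of the
#' mean absolute difference between the paired curves. Bounded in \[0, 1\].
#'
#' @param original,synthetic `trial_dataset`s sharing a schema.
#' @param covariates Covariate names; default all schema covariates.
#' @param grid Positive time grid; default 24 evenly spaced points up to the
#'   0.95 quantile of the original follow-up times.
#' @return A value in \[0, 1\].
#' @export
predicted_survival_distance <- function(original, synthetic,
                                        covariates = covariate_names(original$schema),
                                        grid = NULL) {
  sch <- original$schema
  get_ <- function(d) list(t = d$data[[surv_col_(sch)]],
                           e = as.numeric(d$data[[event_col_(sch)]] == "1"),
                           X = encode_features_(d, covariates))
  o <- get_(original); s <- get_(synthetic)
  if (is.null(grid)) {
    horizon <- unname(stats::quantile(o$t, 0.95, type = 7))
    grid <- seq(horizon / 24, horizon, length.out = 24)
  }
  f1 <- fit_spline_ph(o$t, o$e, o$X)
  f2 <- fit_spline_ph(s$t, s$e, s$X)
  S1 <- predict_spline_ph(f1, o$X, grid)
  S2 <- predict_spline_ph(f2, o$X, grid)
  mean(colMeans(abs(S1 - S2)))
}
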