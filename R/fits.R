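## Dose-response and kinetics fitting.

# bounded least squares: nls/port first (its scaleOffset makes zero-residual
# problems well-posed), Levenberg-Marquardt as fallback on rough starts
.fit_ls <- function(formula, start, lower, upper, weights = NULL,
                    maxiter = 300, env = parent.frame()) {
  environment(formula) <- env
  # warnOnly: port's "singular convergence" report frequently accompanies a
  # numerically excellent rank-deficient optimum; candidates are compared by
  # residual sum of squares upstream, so a genuinely poor fit is discarded
  args <- list(formula, data = env, start = start, algorithm = "port",
               lower = lower, upper = upper,
               control = stats::nls.control(maxiter = maxiter,
                                            scaleOffset = 1,
                                            warnOnly = TRUE))
  if (!is.null(weights)) args$weights <- weights
  f <- tryCatch(suppressWarnings(do.call(stats::nls, args)),
                error = function(e) NULL)
  if (is.null(f)) {
    args2 <- list(formula, data = env, start = start, lower = lower,
                  upper = upper,
                  control = minpack.lm::nls.lm.control(maxiter = maxiter))
    if (!is.null(weights)) args2$weights <- weights
    f <- tryCatch(do.call(minpack.lm::nlsLM, args2),
                  error = function(e) NULL)
  }
  f
}

#' Hill dose-response model
#'
#' `y = START + (END - START) / (1 + (IC50 / S)^n)`, where START and END
#' are the response plateaus at low and high concentration, IC50 the
#' midpoint concentration and n the Hill (cooperativity) coefficient.
#'
#' @param S Concentrations.
#' @param start,end,ic50,n Hill parameters.
#' @return Response values.
#' @export
hill_response <- function(S, start, end, ic50, n) {
  start + (end - start) / (1 + (ic50 / S)^n)
}

#' Fit the Hill equation to dose-response data
#'
#' Bounded Levenberg-Marquardt least squares with multistart: five
#' log-spaced IC50 initialisations across the concentration range (with a
#' fixed seed for reproducible initialisation jitter), best residual wins.
#' IC50 is constrained to `[min(S)/100, max(S)*100]` and n to `[0.3, 6]`;
#' START and END are free.  If the fitted curve does not explain
#' significantly more variance than a constant (F-test, p > 0.01) or its
#' dynamic range `|END - START|` does not exceed three residual standard
#' deviations, the IC50 is flagged unidentifiable and reported as `NA`.
#'
#' @param concentrations Concentrations (>= 4 distinct values spanning at
#'   least one decade).
#' @param responses Responses, same length.
#' @param weights Optional per-point weights (e.g. replicate counts).
#' @return An object of class `hill_fit` with coefficients `START`, `END`,
#'   `IC50`, `n`, standard errors, residual norm and `flag`
#'   (`"ok"` or `"unidentifiable"`).
#' @examples
#' S <- 10^seq(-1, 2, length.out = 8)
#' y <- hill_response(S, 1, 0, 1.6, 1.5)
#' coef(hill_fit(S, y))
#' @export
hill_fit <- function(concentrations, responses, weights = NULL) {
  S <- as.numeric(concentrations); y <- as.numeric(responses)
  if (length(unique(S)) < 4) stop("need >= 4 distinct concentrations")
  if (max(S) / min(S) < 10) stop("concentrations must span >= 1 decade")
  if (is.null(weights)) weights <- rep(1, length(y))
  lower <- c(START = -Inf, END = -Inf, IC50 = min(S) / 100, n = 0.3)
  upper <- c(START = Inf, END = Inf, IC50 = max(S) * 100, n = 6)
  ic50_grid <- 10^seq(log10(min(S)), log10(max(S)), length.out = 5)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(20321L)  # reproducible multistart jitter
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  best <- NULL
  for (ic0 in ic50_grid) {
    st <- c(START = y[which.min(S)], END = y[which.max(S)],
            IC50 = ic0 * exp(runif(1, -0.1, 0.1)), n = 1)
    fit <- .fit_ls(y ~ hill_response(S, START, END, IC50, n),
                   start = as.list(st), lower = lower, upper = upper,
                   weights = if (all(weights == 1)) NULL else weights,
                   maxiter = 200)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("Hill fit failed to converge from any start")
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e)
    rep(NA_real_, 4))
  sigma_res <- sqrt(best$rss / max(1, length(y) - 4))
  # identifiability: the Hill curve must explain significantly more variance
  # than a constant (F-test) and have a dynamic range above the noise floor
  rss0 <- sum((y - mean(y))^2)
  f_stat <- ((rss0 - best$rss) / 3) / (best$rss / max(1, length(y) - 4))
  p_curve <- stats::pf(f_stat, 3, max(1, length(y) - 4), lower.tail = FALSE)
  flag <- if (p_curve > 0.01 || abs(cf["END"] - cf["START"]) <= 3 * sigma_res)
    "unidentifiable" else "ok"
  coefs <- cf
  if (flag == "unidentifiable") coefs["IC50"] <- NA_real_
  structure(list(coefficients = coefs, se = se,
                 residual_norm = sqrt(best$rss), flag = flag,
                 data = data.frame(S = S, y = y), fit = best$fit),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
print.hill_fit <- function(x, ...) {
  cf <- x$coefficients
  if (x$flag == "unidentifiable") {
    cat("Hill fit: IC50 unidentifiable (dynamic range below noise floor)\n")
  } else {
    cat(sprintf(
      "Hill fit: START %.4g, END %.4g, IC50 %.4g (n = %.3g), resid %.3g\n",
      cf["START"], cf["END"], cf["IC50"], cf["n"], x$residual_norm))
  }
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$S else newdata$S %||% newdata
  cf <- object$coefficients
  hill_response(S, cf["START"], cf["END"], cf["IC50"], cf["n"])
}

#' @export
plot.hill_fit <- function(x, ...) {
  graphics::plot(x$data$S, x$data$y, log = "x",
                 xlab = "concentration", ylab = "response", ...)
  ss <- 10^seq(log10(min(x$data$S)), log10(max(x$data$S)), length.out = 100)
  graphics::lines(ss, predict(x, ss))
  invisible(x)
}

#' Kv4.3 kinetic model curves
#'
#' Activation: `i(t) = a * (1 - exp(-t/tau_act))^4 + b`.
#' Inactivation: `i(t) = a * exp(-t/tau_fast) + b * exp(-t/tau_slow) + c`.
#'
#' @param t Time (ms).
#' @param a,b,c Amplitudes/offset (current units).
#' @param tau_act,tau_fast,tau_slow Time constants (ms).
#' @return Current values.
#' @export
kv43_activation_curve <- function(t, a, b, tau_act) {
  a * (1 - exp(-t / tau_act))^4 + b
}

#' @rdname kv43_activation_curve
#' @export
kv43_inactivation_curve <- function(t, a, b, c, tau_fast, tau_slow) {
  a * exp(-t / tau_fast) + b * exp(-t / tau_slow) + c
}

.kinetic_fit_obj <- function(kind, cf, se, rss, flag = "ok") {
  structure(list(kind = kind, coefficients = cf, se = se,
                 residual_norm = sqrt(rss), flag = flag),
            class = "kinetic_fit")
}

#' @export
coef.kinetic_fit <- function(object, ...) object$coefficients

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Kv4.3 %s fit%s: %s (resid %.3g)\n", x$kind,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else "",
              paste(names(x$coefficients),
                    signif(x$coefficients, 4), sep = "=", collapse = ", "),
              x$residual_norm))
  invisible(x)
}

#' Fit Kv4.3 activation kinetics
#'
#' Nonlinear least squares of the fourth-power activation model
#' `i(t) = a (1 - e^(-t/tau_act))^4 + b` to a current segment starting at
#' the voltage-step onset, with multistart over log-spaced time constants.
#'
#' @param times Time since step onset (ms).
#' @param current Current samples (same length).
#' @return A `kinetic_fit` with coefficients `a`, `b`, `tau_act`.
#' @examples
#' t <- seq(0, 10, 0.01)
#' i <- kv43_activation_curve(t, 218, 0, 0.69)
#' coef(fit_kv43_activation(t, i))["tau_act"]
#' @export
fit_kv43_activation <- function(times, current) {
  t <- as.numeric(times); y <- as.numeric(current)
  b0 <- y[1]; a0 <- max(y) - b0
  if (a0 == 0) stop("flat activation segment")
  tau_grid <- 10^seq(log10(max(t[2], 1e-3)), log10(max(t) / 2),
                     length.out = 5)
  best <- NULL
  for (tau0 in tau_grid) {
    fit <- .fit_ls(y ~ kv43_activation_curve(t, a, b, tau_act),
                   start = list(a = a0, b = b0, tau_act = tau0),
                   lower = c(-Inf, -Inf, 1e-6), upper = rep(Inf, 3))
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("activation fit failed to converge")
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e)
    rep(NA_real_, 3))
  .kinetic_fit_obj("activation", cf, se, best$rss)
}

#' Fit Kv4.3 inactivation kinetics
#'
#' Double-exponential decay `i(t) = a e^(-t/tau_fast) + b e^(-t/tau_slow)
#' + c` fitted to a current segment starting at the peak.  Initialised by a
#' two-segment log-linear peel (slow component from the trace tail, fast
#' component from the residual), then refined by bounded
#' Levenberg-Marquardt.  Components are ordered so `tau_fast < tau_slow`;
#' fits collapsing to a single exponential (near-equal time constants or a
#' vanishing amplitude) are flagged `"degenerate"`.
#'
#' @param times Time since the current peak (ms).
#' @param current Current samples.
#' @return A `kinetic_fit` with coefficients `a`, `b`, `c`, `tau_fast`,
#'   `tau_slow`.
#' @export
fit_kv43_inactivation <- function(times, current) {
  t <- as.numeric(times); y <- as.numeric(current)
  n <- length(t)
  c0 <- mean(y[t >= stats::quantile(t, 0.9)])
  # log-linear peel: slow component from the late third of the decay
  late <- t >= stats::quantile(t, 0.45) & t <= stats::quantile(t, 0.85) &
    y - c0 > 0
  slow <- if (sum(late) > 2)
    stats::lm(log(y[late] - c0) ~ t[late]) else NULL
  tau_s0 <- if (!is.null(slow) && coef(slow)[2] < 0)
    -1 / coef(slow)[2] else max(t) / 3
  b0 <- if (!is.null(slow)) exp(coef(slow)[1]) else (y[1] - c0) / 2
  resid_early <- y - c0 - b0 * exp(-t / tau_s0)
  early <- t <= stats::quantile(t, 0.15) & resid_early > 0
  fast <- if (sum(early) > 2)
    stats::lm(log(resid_early[early]) ~ t[early]) else NULL
  tau_f0 <- if (!is.null(fast) && coef(fast)[2] < 0)
    -1 / coef(fast)[2] else tau_s0 / 8
  a0 <- max(y[1] - c0 - b0, b0 / 4)

  best <- NULL
  for (mult in c(1, 0.3, 3)) {
    fit <- .fit_ls(y ~ kv43_inactivation_curve(t, a, b, c, tau_fast, tau_slow),
                   start = list(a = a0, b = b0, c = c0,
                                tau_fast = tau_f0 * mult, tau_slow = tau_s0),
                   lower = c(-Inf, -Inf, -Inf, 1e-6, 1e-6),
                   upper = rep(Inf, 5), maxiter = 500)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop(sprintf(
    "inactivation fit failed to converge (peel residual %.3g)",
    sum(resid_early^2)))
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit))), error = function(e)
    rep(NA_real_, 5))
  if (cf["tau_fast"] > cf["tau_slow"]) {   # enforce component order
    cf[c("a", "b", "tau_fast", "tau_slow")] <-
      cf[c("b", "a", "tau_slow", "tau_fast")]
    se[c(1, 2, 4, 5)] <- se[c(2, 1, 5, 4)]
  }
  flag <- if (cf["tau_slow"] / cf["tau_fast"] < 1.25 ||
                min(abs(cf[c("a", "b")])) <
                  0.01 * max(abs(cf[c("a", "b")])))
    "degenerate" else "ok"
  .kinetic_fit_obj("inactivation", cf, se, best$rss, flag)
}
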