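#' @title Logistic genetic-load model for cross success
#' @description
#' The core model of the package: cross success is Bernoulli with
#' probability R following a logistic regression on the parental inbreeding
#' coefficient,
#' \deqn{\ln(R / (1 - R)) = \beta_0 + \beta_1 F,}
#' and the fitted coefficients convert to Morton-style load parameters on
#' the reproducing-pair scale,
#' \deqn{A_R = -\ln R_{F=0}, \qquad B_R = -\ln(R_{F=1} / R_{F=0}).}
#' \eqn{A_R} is the expressed load (log reduction in success of a
#' non-inbred pair) and \eqn{B_R} the concealed load (slope of the decline
#' of log success with F, due to recessive deleterious variants homozygosed
#' by inbreeding). Because a reproduction event requires two individuals,
#' both parameters are approximately twice the per-individual Morton scale;
#' see [individual_scale()].
#' @name load_model
NULL

stop_design <- function(...) {
  stop(errorCondition(paste0(...), class = c("nemaload_design_error", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("nemaload_degenerate_fit", "error")))
}

# Pull the (y, F) vectors for one analysis stage out of a cross table,
# applying the conditional subsetting the staged phenotypes require.
stage_outcome <- function(records, stage) {
  if (!is.data.frame(records)) {
    stop("`records` must be a data frame of cross records", call. = FALSE)
  }
  fcol <- if ("F_parents" %in% names(records)) "F_parents" else "F"
  if (!fcol %in% names(records)) {
    stop("`records` must carry an F_parents column (see read_cross_table)",
         call. = FALSE)
  }
  keep <- switch(stage,
    overall     = rep(TRUE, nrow(records)),
    copulation  = !is.na(records$copulated),
    fertility   = !is.na(records$copulated) & records$copulated,
    development = !is.na(records$fertile) & records$fertile
  )
  y <- switch(stage,
    overall     = records$success,
    copulation  = records$copulated,
    fertility   = records$fertile,
    development = records$developed
  )
  keep <- keep & !is.na(y)
  list(y = as.logical(y[keep]), F = as.numeric(records[[fcol]][keep]))
}

# Complete/quasi-complete separation with a single continuous covariate:
# the MLE does not exist when the F ranges of successes and failures do
# not interleave.
is_separated <- function(y, F) {
  f1 <- F[y]
  f0 <- F[!y]
  max(f1) <= min(f0) || max(f0) <= min(f1)
}

#' Fit the logistic load model to cross records
#'
#' Maximum-likelihood logistic regression of a binary cross outcome on the
#' parental inbreeding coefficient F, with Wald standard errors and a
#' two-sided z-test of \eqn{\beta_1 = 0}. Coefficients are converted to
#' expressed and concealed load via [beta_to_load()].
#'
#' @param records data frame of cross records with columns
#'   \code{F_parents} (or \code{F}) and \code{success}, plus
#'   \code{copulated} / \code{fertile} / \code{developed} for the staged
#'   phenotypes. See [read_cross_table()] for the file layout.
#' @param stage which binary phenotype to model. \code{"overall"} models
#'   \code{success} on all records; \code{"copulation"} models
#'   \code{copulated}; \code{"fertility"} models \code{fertile} on crosses
#'   that copulated; \code{"development"} models \code{developed} on
#'   fertile crosses.
#' @param firth if \code{TRUE}, fall back to Firth's penalized likelihood
#'   when the plain ML fit is degenerate (complete or quasi-complete
#'   separation). Off by default: degenerate fits are reported as errors
#'   rather than silently regularized.
#' @return An object of class \code{"load_fit"}: fitted \code{coefficients}
#'   (\code{beta0}, \code{beta1}), standard errors, covariance matrix,
#'   Wald \code{z} and \code{p_beta1}, derived \code{A_R} and \code{B_R},
#'   \code{n_crosses}, \code{stage} and \code{method}.
#' @section Errors:
#' All outcomes identical, or complete/quasi-complete separation (with
#' \code{firth = FALSE}), signal a condition of class
#' \code{"nemaload_degenerate_fit"}; fewer than two distinct F values
#' signal \code{"nemaload_design_error"}.
#' @examples
#' cfg <- sim_config(n_lines = 60, betas = c(3.5, -1.8), seed = 7)
#' rec <- simulate_line_extinction(cfg)
#' fit <- fit_load_model(rec)
#' fit
#' coef(fit)
#' @export
fit_load_model <- function(records,
                           stage = c("overall", "copulation", "fertility",
                                     "development"),
                           firth = FALSE) {
  stage <- match.arg(stage)
  d <- stage_outcome(records, stage)
  y <- d$y
  F <- d$F
  if (length(y) < 2L) {
    stop_design("stage '", stage, "': fewer than 2 usable records")
  }
  if (length(unique(F)) < 2L) {
    stop_design("stage '", stage,
                "': fewer than 2 distinct F values; slope not identifiable")
  }
  if (all(y)) {
    stop_degenerate("stage '", stage, "': all outcomes are successes")
  }
  if (!any(y)) {
    stop_degenerate("stage '", stage, "': all outcomes are failures")
  }

  if (is_separated(y, F) && !firth) {
    stop_degenerate("stage '", stage,
                    "': complete or quasi-complete separation on F; ",
                    "ML estimates do not exist (consider firth = TRUE)")
  }

  method <- "ml"
  if (is_separated(y, F)) {
    fit <- firth_logistic(y, F)
    method <- "firth"
  } else {
    g <- stats::glm(y ~ F, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
    if (!g$converged) {
      if (firth) {
        fit <- firth_logistic(y, F)
        method <- "firth"
      } else {
        stop_degenerate("stage '", stage, "': IRLS failed to converge")
      }
    } else {
      V <- stats::summary.glm(g)$cov.unscaled
      fit <- list(coef = stats::coef(g), vcov = V,
                  loglik = as.numeric(stats::logLik(g)))
    }
  }

  beta <- unname(fit$coef)
  se <- sqrt(diag(fit$vcov))
  z <- beta[2] / se[2]
  load <- beta_to_load(beta[1], beta[2])
  structure(
    list(
      coefficients = c(beta0 = beta[1], beta1 = beta[2]),
      se = c(beta0 = unname(se[1]), beta1 = unname(se[2])),
      vcov = unname(fit$vcov),
      z = unname(z),
      p_beta1 = unname(2 * stats::pnorm(-abs(z))),
      A_R = load[["A_R"]],
      B_R = load[["B_R"]],
      n_crosses = length(y),
      stage = stage,
      method = method,
      loglik = fit$loglik,
      data = data.frame(y = y, F = F)
    ),
    class = "load_fit"
  )
}

# Firth (1993) penalized logistic regression via Newton iteration with the
# hat-diagonal score adjustment; used only behind the `firth` flag.
firth_logistic <- function(y, F, tol = 1e-8, maxit = 200) {
  X <- cbind(1, F)
  beta <- c(stats::qlogis(mean(y)), 0)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XtWX <- crossprod(X * w, X)
    Vinv <- solve(XtWX)
    # hat diagonal of W^(1/2) X (X'WX)^-1 X' W^(1/2)
    h <- rowSums((X %*% Vinv) * X) * w
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(Vinv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  ll <- sum(stats::dbinom(as.integer(y), 1, p, log = TRUE))
  XtWX <- crossprod(X * (p * (1 - p)), X)
  list(coef = c(`(Intercept)` = beta[1], F = beta[2]),
       vcov = solve(XtWX),
       loglik = ll + 0.5 * determinant(XtWX)$modulus[1])
}

#' Convert logistic coefficients to expressed and concealed load
#'
#' \eqn{A_R = -\ln(e^{\beta_0} / (1 + e^{\beta_0}))} and
#' \eqn{B_R = -\ln(R_{F=1} / R_{F=0})} with
#' \eqn{R_F = \mathrm{logistic}(\beta_0 + \beta_1 F)}.
#'
#' @param beta0,beta1 finite logistic intercept and slope on F.
#' @return Named numeric vector \code{c(A_R = , B_R = )}. \code{A_R} is
#'   always non-negative; \code{B_R} has the opposite sign of \code{beta1}.
#' @examples
#' beta_to_load(1.517, -0.219)  # A_R = 0.198, B_R = 0.043 at 3 decimals
#' @export
beta_to_load <- function(beta0, beta1) {
  if (!is.finite(beta0) || !is.finite(beta1)) {
    stop("`beta0` and `beta1` must be finite", call. = FALSE)
  }
  # -log(plogis(x)) computed stably as log(1 + exp(-x))
  A_R <- log1p(exp(-beta0))
  B_R <- log1p(exp(-(beta0 + beta1))) - A_R
  c(A_R = A_R, B_R = B_R)
}

#' Recover logistic coefficients from load parameters
#'
#' Analytic inverse of [beta_to_load()]: \eqn{\beta_0 =
#' \mathrm{logit}(e^{-A_R})} and \eqn{\beta_1 =
#' \mathrm{logit}(e^{-A_R-B_R}) - \beta_0}.
#'
#' @param A_R expressed load, must imply \eqn{R_{F=0} = e^{-A_R} \in (0,1)}.
#' @param B_R concealed load, must imply \eqn{R_{F=1} \in (0,1)}.
#' @return Named numeric vector \code{c(beta0 = , beta1 = )}.
#' @export
beta_from_load <- function(A_R, B_R) {
  if (!is.finite(A_R) || !is.finite(B_R)) {
    stop("`A_R` and `B_R` must be finite", call. = FALSE)
  }
  R0 <- exp(-A_R)
  R1 <- exp(-A_R - B_R)
  if (R0 <= 0 || R0 >= 1 || R1 <= 0 || R1 >= 1) {
    stop("loads imply success probabilities outside (0, 1)", call. = FALSE)
  }
  beta0 <- stats::qlogis(R0)
  c(beta0 = beta0, beta1 = stats::qlogis(R1) - beta0)
}

#' Per-individual Morton-scale load
#'
#' A reproduction event requires both parents to succeed, so the
#' pair-scale loads are approximately twice the per-individual survival
#' loads of the classical Morton-Crow-Muller regression; this helper halves
#' them.
#'
#' @param A_R,B_R pair-scale loads.
#' @return Named numeric vector \code{c(A = A_R/2, B = B_R/2)}.
#' @export
individual_scale <- function(A_R, B_R) {
  if (!is.finite(A_R) || !is.finite(B_R)) {
    stop("`A_R` and `B_R` must be finite", call. = FALSE)
  }
  c(A = A_R / 2, B = B_R / 2)
}

#' Predicted cross success probability at a given F
#'
#' @param fit a \code{"load_fit"}.
#' @param F inbreeding coefficient(s) in \[0, 1\].
#' @return \eqn{\mathrm{logistic}(\beta_0 + \beta_1 F)}.
#' @export
predicted_success <- function(fit, F) {
  stopifnot(inherits(fit, "load_fit"))
  if (any(!is.finite(F)) || any(F < 0) || any(F > 1)) {
    stop("`F` must lie in [0, 1]", call. = FALSE)
  }
  b <- fit$coefficients
  unname(stats::plogis(b[1] + b[2] * F))
}

#' Expected line-survival curve
#'
#' Probability that a line is still extant after each of its first
#' \code{n_generations} crosses. In \code{"constant"} mode the per-cross
#' success rate is held at its F = 0 value, giving the exponential-decay
#' null expected in the absence of inbreeding depression,
#' \eqn{S_g = R_{F=0}^g}. In \code{"inbreeding"} mode each cross uses the
#' parental F of its generation:
#' \eqn{S_g = \prod_{t=1}^{g} \mathrm{logistic}(\beta_0 + \beta_1
#' F_{\mathrm{par}}(t))}.
#'
#' @param fit a \code{"load_fit"}.
#' @param n_generations number of experiment generations (>= 1).
#' @param mode \code{"inbreeding"} or \code{"constant"}.
#' @param schedule optional \code{"inbreeding_schedule"}; computed from
#'   \code{n_generations} when missing.
#' @return Numeric vector of length \code{n_generations}, non-increasing,
#'   all values in (0, 1\].
#' @export
expected_survival_curve <- function(fit, n_generations,
                                    mode = c("inbreeding", "constant"),
                                    schedule = NULL) {
  stopifnot(inherits(fit, "load_fit"))
  mode <- match.arg(mode)
  if (length(n_generations) != 1L || n_generations < 1 ||
      n_generations != floor(n_generations)) {
    stop("`n_generations` must be a single positive integer", call. = FALSE)
  }
  b <- fit$coefficients
  if (mode == "constant") {
    R0 <- stats::plogis(b[1])
    return(unname(R0 ^ seq_len(n_generations)))
  }
  Fpar <- parental_F_curve(n_generations, schedule)
  unname(cumprod(stats::plogis(b[1] + b[2] * Fpar)))
}

#' Stage-wise load fits
#'
#' Fits the logistic load model separately to the three sequential
#' sub-phenotypes: copulation (all crosses), fertility (conditional on
#' copulation) and development (conditional on fertility). A stage whose
#' fit is degenerate (no outcome variation, separation) is returned as the
#' condition object rather than aborting the other stages.
#'
#' @param records cross-record data frame carrying the stage columns.
#' @param firth passed through to [fit_load_model()].
#' @return Named list \code{list(copulation =, fertility =, development =)}
#'   of \code{"load_fit"} objects (or condition objects for degenerate
#'   stages).
#' @export
stagewise_fits <- function(records, firth = FALSE) {
  stages <- c("copulation", "fertility", "development")
  fits <- lapply(stages, function(s) {
    tryCatch(fit_load_model(records, stage = s, firth = firth),
             nemaload_degenerate_fit = function(e) e,
             nemaload_design_error = function(e) e)
  })
  names(fits) <- stages
  fits
}

#' @export
print.load_fit <- function(x, digits = 3, ...) {
  cat("Logistic genetic-load fit (stage: ", x$stage,
      if (x$method == "firth") ", Firth-penalized", ")\n", sep = "")
  cat("  n crosses:", x$n_crosses, "\n")
  b <- x$coefficients
  cat(sprintf("  beta0 = %.*f (SE %.*f)   beta1 = %.*f (SE %.*f)\n",
              digits, b[1], digits, x$se[1], digits, b[2], digits, x$se[2]))
  cat(sprintf("  A_R = %.*f   B_R = %.*f\n", digits, x$A_R, digits, x$B_R))
  cat("  P(beta1 = 0):", format.pval(x$p_beta1, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.load_fit <- function(object, ...) object$coefficients

#' @export
vcov.load_fit <- function(object, ...) object$vcov

#' @export
logLik.load_fit <- function(object, ...) {
  structure(object$loglik, df = 2, nobs = object$n_crosses, class = "logLik")
}

#' Summarize a load fit
#'
#' @param object a \code{"load_fit"}.
#' @param load_se if \code{TRUE}, also report delta-method standard errors
#'   for \code{A_R} and \code{B_R}. These are an extension of the
#'   coefficient-level Wald errors, provided for convenience.
#' @param ... unused.
#' @export
summary.load_fit <- function(object, load_se = FALSE, ...) {
  b <- object$coefficients
  tab <- cbind(Estimate = b, `Std. Error` = object$se,
               `z value` = b / object$se,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(b / object$se)))
  out <- list(coefficients = tab, A_R = object$A_R, B_R = object$B_R,
              p_beta1 = object$p_beta1, n_crosses = object$n_crosses,
              stage = object$stage, method = object$method)
  if (load_se) {
    p0 <- stats::plogis(b[1])
    p1 <- stats::plogis(b[1] + b[2])
    gA <- c(-(1 - p0), 0)              # dA_R/dbeta
    gB <- c(p1 - p0, p1 - 1)           # dB_R/dbeta
    out$se_A_R <- sqrt(drop(gA %*% object$vcov %*% gA))
    out$se_B_R <- sqrt(drop(gB %*% object$vcov %*% gB))
  }
  class(out) <- "summary.load_fit"
  out
}

#' @export
print.summary.load_fit <- function(x, digits = 3, ...) {
  cat("Logistic genetic-load fit, stage:", x$stage, "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nExpressed load  A_R = %.*f", digits, x$A_R))
  if (!is.null(x$se_A_R)) cat(sprintf(" (delta-method SE %.*f)", digits, x$se_A_R))
  cat(sprintf("\nConcealed load  B_R = %.*f", digits, x$B_R))
  if (!is.null(x$se_B_R)) cat(sprintf(" (delta-method SE %.*f)", digits, x$se_B_R))
  cat("\nn =", x$n_crosses, "crosses\n")
  invisible(x)
}

#' @export
predict.load_fit <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  F <- if (is.null(newdata)) object$data$F else {
    if (is.data.frame(newdata)) {
      if ("F_parents" %in% names(newdata)) newdata$F_parents else newdata$F
    } else as.numeric(newdata)
  }
  b <- object$coefficients
  eta <- unname(b[1] + b[2] * F)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.load_fit <- function(object,
                               type = c("deviance", "pearson", "response"),
                               ...) {
  type <- match.arg(type)
  y <- as.numeric(object$data$y)
  p <- predict.load_fit(object)
  switch(type,
    response = y - p,
    pearson  = (y - p) / sqrt(p * (1 - p)),
    deviance = sign(y - p) *
      sqrt(-2 * (y * log(p) + (1 - y) * log1p(-p)))
  )
}

#' Plot a load fit
#'
#' Draws the fitted success-probability curve over F with observed success
#' fractions at each distinct F level (point area proportional to the
#' number of crosses), or the expected line-survival curves under the
#' inbreeding model and the constant-rate null.
#'
#' @param x a \code{"load_fit"}.
#' @param which \code{"fit"} or \code{"survival"}.
#' @param n_generations generations for the survival curves.
#' @param ... passed to the underlying plot call.
#' @export
plot.load_fit <- function(x, which = c("fit", "survival"),
                          n_generations = 20, ...) {
  which <- match.arg(which)
  if (which == "fit") {
    Fgrid <- seq(0, 1, length.out = 101)
    graphics::plot(Fgrid, predicted_success(x, Fgrid), type = "l",
                   ylim = c(0, 1), xlab = "inbreeding coefficient F",
                   ylab = "P(cross success)", ...)
    agg <- stats::aggregate(y ~ F, data = x$data,
                            FUN = function(v) c(mean(v), length(v)))
    graphics::points(agg$F, agg$y[, 1], cex = sqrt(agg$y[, 2] / pi) / 3,
                     pch = 16, col = grDevices::grey(0.3, 0.6))
  } else {
    g <- seq_len(n_generations)
    S_in <- expected_survival_curve(x, n_generations, "inbreeding")
    S_c <- expected_survival_curve(x, n_generations, "constant")
    graphics::plot(g, S_in, type = "s", ylim = c(0, 1),
                   xlab = "generation", ylab = "P(line extant)", ...)
    graphics::lines(g, S_c, type = "s", lty = 2)
    graphics::legend("topright", lty = c(1, 2),
                     legend = c("inbreeding model", "constant-rate null"),
                     bty = "n")
  }
  invisible(x)
}

#' Simulate experiments from a fitted load model
#'
#' Uses the fitted \eqn{(\beta_0, \beta_1)} as generative truth for
#' [simulate_line_extinction()], a parametric-bootstrap convenience.
#'
#' @param object a \code{"load_fit"}.
#' @param nsim number of replicate experiments.
#' @param seed integer seed for the simulator.
#' @param n_lines,max_generations experiment dimensions.
#' @param ... unused.
#' @return A list of \code{nsim} cross-record data frames.
#' @export
simulate.load_fit <- function(object, nsim = 1, seed = 1,
                              n_lines = 108, max_generations = 20, ...) {
  b <- object$coefficients
  lapply(seq_len(nsim), function(i) {
    cfg <- sim_config(n_lines = n_lines, max_generations = max_generations,
                      betas = unname(b), seed = seed + i - 1L)
    simulate_line_extinction(cfg)
  })
}
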