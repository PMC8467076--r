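#' Four-parameter logistic reporter kinetics
#'
#' Reporter-enzyme kinetic curves (fluorescence vs time from substrate
#' cleavage) are summarised by fitting the four-parameter logistic (4PL)
#' model
#' \deqn{F(t) = d + \frac{a - d}{1 + (t/c)^b}}
#' with lower asymptote `a` (RFU), upper asymptote `d` (RFU), inflection
#' time `c` (min, > 0) and slope exponent `b` (> 0). The steepest slope of
#' the fitted curve estimates the maximal reaction velocity, which is
#' proportional to enzyme concentration and hence to promoter activity.
#'
#' @name fourpl
#' @keywords internal
NULL

#' Construct a 4PL parameter object
#' @param a,d lower and upper asymptote (RFU).
#' @param c inflection time (min), > 0.
#' @param b slope exponent, > 0.
#' @return An object of class `four_pl`.
#' @export
four_pl <- function(a, d, c, b) {
  stopifnot(c > 0, b > 0)
  structure(list(a = a, d = d, c = c, b = b), class = "four_pl")
}

#' Evaluate a 4PL curve
#' @param fp a [four_pl()].
#' @param t times (min), >= 0.
#' @export
predict_four_pl <- function(fp, t) {
  fp$d + (fp$a - fp$d) / (1 + (t / fp$c)^fp$b)
}

#' @export
print.four_pl <- function(x, ...) {
  cat(sprintf("4PL: a=%.4g d=%.4g c=%.4g b=%.4g", x$a, x$d, x$c, x$b))
  if (!is.null(x$rss)) cat(sprintf("  (RSS %.4g, %s)", x$rss,
                                   if (isTRUE(x$converged)) "converged" else "NOT converged"))
  cat("\n")
  invisible(x)
}

#' Fit a 4PL model to a kinetic curve
#'
#' Levenberg-Marquardt least squares with data-driven initialisation:
#' `a0 = min(signal)`, `d0 = max(signal)`, `c0` the time at which the signal
#' first crosses half its range, `b0 = 1`. Convergence is tracked by
#' relative RSS change (`< 1e-10`) within 500 iterations; non-convergence is
#' flagged on the result, not raised.
#'
#' @param times time points (min), strictly increasing, >= 8 points.
#' @param signal fluorescence (RFU), same length as `times`.
#' @return A [four_pl()] with extra fields `rss`, `converged`, `times`,
#'   `signal`.
#' @export
fit_4pl <- function(times, signal) {
  if (is.list(times) && !is.null(times$times)) {
    signal <- times$signal
    times <- times$times
  }
  stopifnot(length(times) == length(signal), length(times) >= 8L,
            all(diff(times) > 0))
  if (max(signal) == min(signal)) stop("constant signal cannot be fitted")
  a0 <- min(signal)
  d0 <- max(signal)
  half <- (a0 + d0) / 2
  rising <- signal[length(signal)] >= signal[1]
  cross <- if (rising) which(signal >= half)[1] else which(signal <= half)[1]
  c0 <- max(times[cross], min(times[times > 0]), na.rm = TRUE)
  dat <- data.frame(t = times, y = signal)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ d + (a - d) / (1 + (t / c)^b),
      data = dat,
      start = list(a = a0, d = d0, c = c0, b = 1),
      lower = c(a = -Inf, d = -Inf, c = 1e-9, b = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- four_pl(a0, d0, c0, 1)
    out$rss <- sum((signal - predict_four_pl(out, times))^2)
    out$converged <- FALSE
  } else {
    p <- as.list(stats::coef(fit))
    out <- four_pl(p$a, p$d, p$c, p$b)
    out$rss <- sum(stats::resid(fit)^2)
    out$converged <- fit$convInfo$isConv
  }
  out$times <- times
  out$signal <- signal
  out
}

#' Maximal slope of a 4PL curve
#'
#' The derivative of the 4PL model is
#' \deqn{F'(t) = (d - a)\, b\, (t/c)^b / \left(t\,(1 + (t/c)^b)^2\right).}
#' Substituting \eqn{u = (t/c)^b}, \eqn{|F'|} is maximised where
#' \eqn{(1 - 1/b)(1+u) = 2u}, i.e. at \eqn{u^\ast = (b-1)/(b+1)}, so for
#' `b > 1` the steepest point is \eqn{t^\ast = c\,((b-1)/(b+1))^{1/b}}, in
#' closed form. For `b <= 1` the supremum lies at `t -> 0+` and the slope is
#' evaluated at the start of the observed time range instead.
#'
#' @param fp a [four_pl()] (fitted objects carry their time range).
#' @param t_range observed time range, needed only when `b <= 1` and `fp`
#'   does not carry one.
#' @return The maximal absolute slope (RFU/min), with attributes `t_max`
#'   (argmax) and `sign` (+1 rising, -1 falling).
#' @export
max_slope <- function(fp, t_range = NULL) {
  stopifnot(inherits(fp, "four_pl"))
  amp <- fp$d - fp$a
  if (amp == 0) {
    return(structure(0, t_max = NA_real_, sign = 0))
  }
  deriv <- function(t) {
    u <- (t / fp$c)^fp$b
    amp * fp$b * u / (t * (1 + u)^2)
  }
  if (fp$b > 1) {
    t_star <- fp$c * ((fp$b - 1) / (fp$b + 1))^(1 / fp$b)
  } else {
    if (is.null(t_range) && !is.null(fp$times)) t_range <- range(fp$times)
    if (is.null(t_range)) {
      stop("b <= 1: supply t_range to bound the slope evaluation")
    }
    t_star <- max(min(t_range), 1e-9)
  }
  s <- deriv(t_star)
  structure(abs(s), t_max = t_star, sign = sign(s))
}

#' Subtract background from kinetic signals
#'
#' Pointwise subtraction of the mean of the control wells (no-cell and
#' no-substrate); negative values are floored at 0.
#'
#' @param signal RFU vector.
#' @param controls matrix or list of control RFU vectors on the same grid.
#' @export
subtract_background <- function(signal, controls) {
  bg <- if (is.list(controls)) {
    rowMeans(do.call(cbind, controls))
  } else if (is.matrix(controls)) {
    rowMeans(controls)
  } else {
    controls
  }
  pmax(signal - bg, 0)
}

#' Relative promoter activity from replicate kinetic curves
#'
#' Fits a 4PL per replicate curve, takes the maximal slope as the
#' replicate's Vmax, and reports each strain's mean Vmax relative to the
#' reference strain's mean Vmax. Strains whose relative activity drops
#' strictly below `threshold` (default 0.5, i.e. "less than half" of the
#' reference) are flagged — the repressed-mutant screening filter.
#'
#' @param curves long-format `data.frame` with columns `strain`,
#'   `replicate`, `time_min`, `rfu`.
#' @param reference name of the reference strain (must be present).
#' @param threshold relative-activity flag threshold (strict `<`).
#' @return A `data.frame`, one row per strain: `strain`, `n_replicates`,
#'   `vmax_mean`, `vmax_sd`, `relative_activity`, `flag_low` (reference row
#'   has relative activity 1).
#' @export
relative_activity <- function(curves, reference, threshold = 0.5) {
  stopifnot(all(c("strain", "replicate", "time_min", "rfu") %in% names(curves)))
  if (!(reference %in% curves$strain)) {
    stop("reference strain '", reference, "' not found")
  }
  per_rep <- lapply(split(curves, list(curves$strain, curves$replicate),
                          drop = TRUE), function(d) {
    d <- d[order(d$time_min), ]
    fp <- fit_4pl(d$time_min, d$rfu)
    data.frame(strain = d$strain[1], replicate = d$replicate[1],
               vmax = as.numeric(max_slope(fp)), stringsAsFactors = FALSE)
  })
  vm <- do.call(rbind, per_rep)
  agg <- do.call(rbind, lapply(split(vm, vm$strain), function(d) {
    if (nrow(d) < 3L) {
      warning("strain ", d$strain[1], ": fewer than 3 replicates")
    }
    data.frame(strain = d$strain[1], n_replicates = nrow(d),
               vmax_mean = mean(d$vmax), vmax_sd = stats::sd(d$vmax),
               stringsAsFactors = FALSE)
  }))
  ref_mean <- agg$vmax_mean[agg$strain == reference]
  agg$relative_activity <- agg$vmax_mean / ref_mean
  agg$flag_low <- agg$relative_activity < threshold
  rownames(agg) <- NULL
  agg
}

#' Compare Vmax between two strains
#'
#' Unpaired two-tailed Student's t-test (pooled variance by default; Welch
#' as option) on per-replicate maximal velocities. Two constant groups with
#' equal means return `t = 0`, `p = 1`.
#'
#' @param group_a,group_b numeric vectors of per-replicate Vmax, `n >= 2`.
#' @param var_equal pooled-variance Student form (default `TRUE`).
#' @return List with `t`, `df`, `p`.
#' @export
compare_activity <- function(group_a, group_b, var_equal = TRUE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1))
    }
    stop("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
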