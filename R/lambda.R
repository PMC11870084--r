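# Space-constant estimation: the subthreshold depolarization at the
# recording site is modeled as the convolution of the illumination
# profile f with an electrotonic weight function g(x, lambda); lambda is
# obtained by least squares over an illumination-size series.  A
# power-law fit with F-test confidence intervals relates relative changes
# in input resistance and space constant.

#' Electrotonic weight function
#'
#' `g(x, lambda) = (1/lambda) (2 - exp(-x/lambda)) exp(-|x|/lambda)` as
#' printed (`variant = "printed"`), or with `|x|` in both exponentials
#' (`variant = "symmetric"`).  The printed form is asymmetric and becomes
#' negative for `x < -lambda log 2`; both variants integrate to 3/2 over
#' the positive half-line.
#'
#' @param x distance from the recording site (mm).
#' @param lambda space constant (mm), > 0.
#' @param variant `"printed"` (default) or `"symmetric"`.
#' @return weight (1/mm), vectorized over `x`.
#' @export
weight_g <- function(x, lambda, variant = c("printed", "symmetric")) {
  variant <- match.arg(variant)
  if (!is.numeric(lambda) || lambda <= 0) stop("lambda must be > 0")
  inner <- if (variant == "printed") exp(-x / lambda)
           else exp(-abs(x) / lambda)
  (1 / lambda) * (2 - inner) * exp(-abs(x) / lambda)
}

#' Illumination profile
#'
#' Indicator of the illuminated region: the interval
#' `[far_edge, b]` relative to the recording site, or the literal
#' half-line `x <= b` when `far_edge = -Inf`.
#'
#' @param x position (mm).
#' @param b near-edge position of the illuminated region (mm).
#' @param far_edge far-edge position (mm), `-Inf` for half-line mode.
#' @return 0/1, vectorized over `x`.
#' @export
light_f <- function(x, b, far_edge = -Inf) {
  if (is.finite(far_edge) && far_edge >= b)
    stop("far_edge must be < b")
  as.numeric(x >= far_edge & x <= b)
}

# cumulative integral I(u) = int_0^u g(s) ds, closed form, continuous
weight_g_cumint <- function(u, lambda, variant = "printed") {
  pos <- -2 * exp(-pmax(u, 0) / lambda) +
    0.5 * exp(-2 * pmax(u, 0) / lambda) + 1.5
  neg <- if (variant == "printed")
    2 * exp(pmin(u, 0) / lambda) - pmin(u, 0) / lambda - 2
  else
    2 * exp(pmin(u, 0) / lambda) -
      0.5 * exp(2 * pmin(u, 0) / lambda) - 1.5
  ifelse(u >= 0, pos, neg)
}

#' Convolution of the illumination profile with the weight function
#'
#' Closed-form evaluation of `(f * g)(x) = int f(tau) g(x - tau) dtau`
#' for an interval (or half-line) illumination profile; the dimensionless
#' electrotonic response at position `x`.
#'
#' @param x evaluation position (mm), typically 0 (the recording site).
#' @param b near-edge position (mm).
#' @param far_edge far-edge position (mm), `-Inf` for the half-line mode.
#' @param lambda space constant (mm), > 0.
#' @param variant weight-function variant, see [weight_g()].
#' @return dimensionless response, vectorized over `b`.
#' @export
convolve_fg <- function(x, b, far_edge = -Inf, lambda,
                        variant = c("printed", "symmetric")) {
  variant <- match.arg(variant)
  if (lambda <= 0) stop("lambda must be > 0")
  upper <- if (is.finite(far_edge)) {
    weight_g_cumint(x - far_edge, lambda, variant)
  } else 1.5  # I(+Inf)
  upper - weight_g_cumint(x - b, lambda, variant)
}

#' Build an illumination-size series
#'
#' @param b edge positions of the illuminated region relative to the
#'   recording site (mm); at least 4 distinct values.
#' @param delta_e subthreshold membrane-potential changes (mV).
#' @param far_edge common far edge (mm) or `-Inf`.
#' @param direction `"longitudinal"` or `"transverse"` (fiber
#'   orientation).
#' @param phase AP phase tag: `"diastole"`, `"APD70"` or `"plateau"`.
#' @return object of class `illumination_series`.
#' @export
illumination_series <- function(b, delta_e, far_edge = -Inf,
                                direction = c("longitudinal",
                                              "transverse"),
                                phase = c("diastole", "APD70",
                                          "plateau")) {
  direction <- match.arg(direction)
  phase <- match.arg(phase)
  stopifnot(length(b) == length(delta_e))
  if (length(unique(b)) < 4L)
    stop("an illumination series needs >= 4 distinct edge positions")
  structure(list(b = b, delta_e = delta_e, far_edge = far_edge,
                 direction = direction, phase = phase),
            class = "illumination_series")
}

#' Convert illumination areas to edge positions
#'
#' Maps the area of a centered illumination pattern to the position of
#' its near edge along the axis through the recording site: for a square
#' pattern of side `sqrt(area)` shrunk towards the far side, and for a
#' circle of radius `sqrt(area/pi)`. The experimental pattern sizes
#' (11.2, 6.2 and ~1 mm^2) are typical inputs.
#'
#' @param area_mm2 illumination areas (mm^2).
#' @param shape `"square"` or `"circle"`.
#' @param offset_mm distance from the recording site to the pattern's far
#'   edge (mm); the near edge is at `offset + extent`.
#' @return near-edge positions `b` (mm).
#' @export
area_to_edge <- function(area_mm2, shape = c("square", "circle"),
                         offset_mm = 0) {
  shape <- match.arg(shape)
  extent <- switch(shape, square = sqrt(area_mm2),
                   circle = 2 * sqrt(area_mm2 / pi))
  offset_mm + extent
}

#' Fit the space constant to an illumination-size series
#'
#' Least-squares fit of `delta_e ~ A * (f * g)(0; b, lambda)` over the
#' amplitude `A` (mV) and the space constant `lambda` (mm). `A` is
#' profiled exactly (the model is linear in `A`), leaving a 1-D
#' minimization in `lambda`. The mean squared error is computed on the
#' amplitude-normalized scale (`delta_e / A` against the dimensionless
#' response) and the fit is accepted when it does not exceed
#' `mse_threshold`.
#'
#' @param series an [illumination_series()].
#' @param variant weight-function variant, see [weight_g()].
#' @param lambda_range search interval for lambda (mm).
#' @param mse_threshold acceptance threshold on the normalized mean
#'   squared error (default 0.3).
#' @return object of class `lambda_fit`: list with `lambda_mm`,
#'   `amplitude_mV`, `mse`, `accepted`, `direction`, `phase`, `variant`,
#'   plus the data and fitted values.
#' @export
fit_lambda <- function(series, variant = c("printed", "symmetric"),
                       lambda_range = c(0.02, 10), mse_threshold = 0.3) {
  variant <- match.arg(variant)
  stopifnot(inherits(series, "illumination_series"))
  y <- series$delta_e
  resp <- function(lambda)
    convolve_fg(0, series$b, series$far_edge, lambda, variant)
  sse <- function(loglam) {
    r <- resp(exp(loglam))
    a <- sum(r * y) / sum(r * r)
    sum((y - a * r)^2)
  }
  opt <- optimize(sse, log(lambda_range), tol = 1e-10)
  lambda <- exp(opt$minimum)
  r <- resp(lambda)
  a <- sum(r * y) / sum(r * r)
  if (!is.finite(a) || a == 0)
    stop("fit failure: degenerate amplitude")
  mse <- mean((y / a - r)^2)
  out <- list(lambda_mm = lambda, amplitude_mV = a, mse = mse,
              accepted = mse <= mse_threshold,
              mse_threshold = mse_threshold,
              direction = series$direction, phase = series$phase,
              variant = variant, b = series$b, delta_e = y,
              far_edge = series$far_edge, fitted = a * r)
  class(out) <- "lambda_fit"
  out
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf(
    "Space-constant fit (%s, %s, %s weight): lambda = %.4g mm\n",
    x$direction, x$phase, x$variant, x$lambda_mm))
  cat(sprintf("  amplitude %.4g mV, normalized MSE %.4g (%s)\n",
              x$amplitude_mV, x$mse,
              if (x$accepted) "accepted" else
                sprintf("excluded: MSE > %g", x$mse_threshold)))
  invisible(x)
}

#' @export
coef.lambda_fit <- function(object, ...) {
  c(lambda_mm = object$lambda_mm, amplitude_mV = object$amplitude_mV)
}

#' @export
predict.lambda_fit <- function(object, b = object$b, ...) {
  object$amplitude_mV *
    convolve_fg(0, b, object$far_edge, object$lambda_mm, object$variant)
}

#' @export
plot.lambda_fit <- function(x, ...) {
  graphics::plot(x$b, x$delta_e, xlab = "illumination edge b (mm)",
                 ylab = expression(Delta * E ~ "(mV)"), ...)
  bb <- seq(min(x$b), max(x$b), length.out = 200)
  graphics::lines(bb, predict(x, bb), col = "firebrick")
  invisible(x)
}

#' Power-law relation with F-test confidence intervals
#'
#' Fits `y = a * x^b` by nonlinear least squares (starting values from the
#' log-log regression) and derives confidence intervals for each
#' parameter by F-statistic profiling: the bound is where the residual
#' sum of squares of the constrained fit reaches
#' `RSS_min * (1 + qf(level, 1, n-2) / (n-2))`.
#'
#' @param x,y positive paired observations (e.g. relative R_m and
#'   relative lambda), at least 5 pairs.
#' @param level confidence level, default 0.99.
#' @return object of class `power_fit`: list with `a`, `b`, `ci_a`,
#'   `ci_b`, `rss`, `level`, `n`.
#' @export
fit_power_relation <- function(x, y, level = 0.99) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("need at least 5 paired points")
  if (any(x <= 0) || any(y <= 0)) stop("inputs must be positive")
  n <- length(x)
  lf <- stats::lm(log(y) ~ log(x))
  start <- c(a = exp(unname(coef(lf)[1L])), b = unname(coef(lf)[2L]))
  rss_b_fixed <- function(b) {
    # conditionally linear in a
    xb <- x^b
    a <- sum(xb * y) / sum(xb * xb)
    c(a = a, rss = sum((y - a * xb)^2))
  }
  opt <- optimize(function(b) rss_b_fixed(b)["rss"],
                  interval = start["b"] + c(-3, 3), tol = 1e-12)
  b_hat <- opt$minimum
  fit0 <- rss_b_fixed(b_hat)
  a_hat <- unname(fit0["a"])
  rss0 <- unname(fit0["rss"])
  crit <- rss0 * (1 + stats::qf(level, 1, n - 2) / (n - 2))
  near_exact <- rss0 < 1e-12 * sum(y^2)
  profile_ci <- function(par) {
    if (near_exact) {
      est <- if (par == "a") a_hat else b_hat
      return(c(est, est))
    }
    rss_at <- function(val) {
      if (par == "b") {
        unname(rss_b_fixed(val)["rss"])
      } else {
        # a fixed, minimize over b
        optimize(function(b) sum((y - val * x^b)^2),
                 interval = b_hat + c(-4, 4), tol = 1e-12)$objective
      }
    }
    est <- if (par == "a") a_hat else b_hat
    bound <- function(dir) {
      step <- max(abs(est), 0.1) * 0.05
      hi <- est + dir * step
      it <- 0L
      while (rss_at(hi) < crit && it < 60L) {
        step <- step * 2; hi <- est + dir * step; it <- it + 1L
      }
      if (rss_at(hi) < crit) return(dir * Inf)
      uniroot(function(v) rss_at(v) - crit,
              sort(c(est, hi)), tol = 1e-9)$root
    }
    c(bound(-1), bound(1))
  }
  out <- list(a = a_hat, b = b_hat,
              ci_a = profile_ci("a"), ci_b = profile_ci("b"),
              rss = rss0, level = level, n = n,
              fitted = a_hat * x^b_hat, x = x, y = y)
  class(out) <- "power_fit"
  out
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("Power-law fit y = a x^b (n = %d)\n", x$n))
  cat(sprintf("  a = %.4g, %d%% CI [%.4g, %.4g]\n", x$a,
              round(100 * x$level), x$ci_a[1L], x$ci_a[2L]))
  cat(sprintf("  b = %.4g, %d%% CI [%.4g, %.4g]\n", x$b,
              round(100 * x$level), x$ci_b[1L], x$ci_b[2L]))
  invisible(x)
}

#' @export
coef.power_fit <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' @export
predict.power_fit <- function(object, x = object$x, ...) {
  object$a * x^object$b
}

#' Read / write an illumination-size series as delimited text
#'
#' Two tab-separated columns `b_mm` and `delta_e_mV`, with the far edge,
#' direction and phase carried in `#`-prefixed header lines.
#'
#' @param series an [illumination_series()].
#' @param path file path.
#' @return `write_illumination_series` returns `path` invisibly;
#'   `read_illumination_series` returns an `illumination_series`.
#' @export
write_illumination_series <- function(series, path) {
  stopifnot(inherits(series, "illumination_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# optoclamp illumination series v1",
               sprintf("# far_edge_mm: %s", series$far_edge),
               sprintf("# direction: %s", series$direction),
               sprintf("# phase: %s", series$phase),
               "b_mm\tdelta_e_mV"), con)
  utils::write.table(data.frame(series$b, series$delta_e), con,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_illumination_series
#' @export
read_illumination_series <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  field <- function(name, default) {
    ln <- grep(paste0("^# ", name, ": "), hdr, value = TRUE)
    if (!length(ln)) default else sub(paste0("^# ", name, ": "), "", ln)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  illumination_series(tab$b_mm, tab$delta_e_mV,
                      far_edge = as.numeric(field("far_edge_mm", "-Inf")),
                      direction = field("direction", "longitudinal"),
                      phase = field("phase", "diastole"))
}
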