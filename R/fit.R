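#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

tac_fit_window <- function(tac, window) {
  if (is.null(window)) window <- c(0, Inf)
  stopifnot(is.numeric(window), length(window) == 2L, window[1] < window[2])
  keep <- tac$t_mid >= window[1] & tac$t_mid <= window[2]
  list(data = tac[keep, , drop = FALSE], window = window)
}

#' Fit a single-exponential decay to a time-activity curve
#'
#' Least-squares fit of \eqn{A e^{-\lambda t}} to a TAC. The model value
#' for a frame is the time-AVERAGE of the exponential over the frame (the
#' quantity a histogramming scanner reports), not a point evaluation at the
#' frame midpoint; this removes a systematic bias of order
#' \eqn{(\lambda \Delta t)^2 / 24} on long frames. The fit is initialized
#' from the log-linear regression slope over the positive frame values and
#' refined by Levenberg-Marquardt.
#'
#' @param tac A `tac` tibble (columns `t_start`, `t_mid`, `duration`,
#'   `value`).
#' @param window Optional `c(t_min, t_max)` fit window in seconds applied
#'   to frame midpoints; default uses the full acquisition.
#' @param weighting `"none"` (default, unweighted) or `"poisson"`
#'   (inverse-variance weights for counting statistics, proportional to
#'   frame duration over value).
#'
#' @return An object of class `washout_fit` with fields `lambda`,
#'   `halflife` (`Inf` when the rate is not positive), `amplitude`,
#'   `std_errors`, `residual_rms`, `n_points`, `window`, `converged`,
#'   `weighting` and the fitted data. Supports [tidy()] and [glance()].
#' @export
fit_single_exponential <- function(tac, window = NULL,
                                   weighting = c("none", "poisson")) {
  weighting <- match.arg(weighting)
  fw <- tac_fit_window(tac, window)
  d <- fw$data
  usable <- d$value > 0
  if (sum(usable) < 3L) {
    stop("need at least 3 frames with positive values in the fit window",
         call. = FALSE)
  }
  dpos <- d[usable, , drop = FALSE]

  # log-linear initialization: exact for noiseless single exponentials
  init <- stats::lm(log(value) ~ t_mid, data = dpos)
  lambda0 <- max(-unname(stats::coef(init)[2]), 0)
  A0 <- exp(unname(stats::coef(init)[1]))

  w <- if (weighting == "poisson") {
    dpos$duration / pmax(dpos$value, max(dpos$value) * 1e-9)
  } else {
    rep(1, nrow(dpos))
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      value ~ A * frame_mean_exp(lambda, t_start, duration),
      data = dpos,
      start = list(A = A0, lambda = lambda0),
      weights = w,
      lower = c(A = 0, lambda = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    est <- c(A = A0, lambda = lambda0)
    se <- c(A = NA_real_, lambda = NA_real_)
    resid <- dpos$value - est["A"] *
      frame_mean_exp(est["lambda"], dpos$t_start, dpos$duration)
    converged <- FALSE
  } else {
    est <- stats::coef(fit)
    se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                   error = function(e) c(A = NA_real_, lambda = NA_real_))
    resid <- stats::residuals(fit)
    converged <- isTRUE(fit$convInfo$isConv)
  }

  # a rate producing < 1e-9 relative decay across the fitted window is
  # indistinguishable from zero: report no decay rather than a huge number
  lambda_hat <- unname(est["lambda"])
  t_span <- diff(range(dpos$t_mid))
  structure(
    list(
      lambda = lambda_hat,
      halflife = if (lambda_hat * t_span > 1e-9) log(2) / lambda_hat else Inf,
      amplitude = unname(est["A"]),
      std_errors = c(amplitude = unname(se["A"]), lambda = unname(se["lambda"])),
      residual_rms = sqrt(mean(resid^2)),
      n_points = nrow(dpos),
      window = fw$window,
      converged = converged,
      weighting = weighting,
      data = dpos
    ),
    class = "washout_fit"
  )
}

#' @export
print.washout_fit <- function(x, ...) {
  cat(sprintf(
    "<washout_fit> lambda = %.4e 1/s (T1/2 = %.4g s), A = %.4g Bq, %d frames%s\n",
    x$lambda, x$halflife, x$amplitude, x$n_points,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
tidy.washout_fit <- function(x, ...) {
  se_hl <- if (is.finite(x$halflife) && is.finite(x$std_errors["lambda"])) {
    x$std_errors[["lambda"]] * log(2) / x$lambda^2
  } else {
    NA_real_
  }
  tibble::tibble(
    term = c("amplitude", "lambda", "halflife"),
    estimate = c(x$amplitude, x$lambda, x$halflife),
    std.error = c(x$std_errors[["amplitude"]], x$std_errors[["lambda"]], se_hl)
  )
}

#' @export
glance.washout_fit <- function(x, ...) {
  tibble::tibble(
    halflife = x$halflife,
    lambda = x$lambda,
    residual_rms = x$residual_rms,
    n_points = x$n_points,
    t_min = x$window[1],
    t_max = x$window[2],
    converged = x$converged
  )
}

#' Decompose alive/dead fits into tissular and washout components
#'
#' The dead-condition fit estimates the tissular (passive diffusion) decay
#' constant directly. In the alive condition the biological curve is the
#' product of the tissular and washout exponentials, so its fitted decay
#' constant is the sum of the two rates; the default `"subtraction"` mode
#' therefore computes \eqn{\lambda_{wash} = \lambda_{alive} -
#' \lambda_{tiss}}. The `"direct"` mode instead reports the alive-condition
#' rate as the washout rate unmodified.
#'
#' @param fit_alive,fit_dead `washout_fit` objects for the alive and dead
#'   acquisitions of the same tissue.
#' @param mode `"subtraction"` (default) or `"direct"`.
#'
#' @return An object of class `washout_decomposition` with tissular, alive
#'   and washout rates and half-lives. When the alive rate does not exceed
#'   the dead rate in subtraction mode the result is flagged
#'   `no_washout = TRUE` with an infinite washout half-life (not an error).
#' @export
decompose_washout <- function(fit_alive, fit_dead,
                              mode = c("subtraction", "direct")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit_alive, "washout_fit"),
            inherits(fit_dead, "washout_fit"))
  if (!fit_alive$converged || !fit_dead$converged) {
    stop("both condition fits must have converged", call. = FALSE)
  }
  lambda_tiss <- fit_dead$lambda
  lambda_alive <- fit_alive$lambda
  if (mode == "subtraction") {
    lambda_wash <- lambda_alive - lambda_tiss
    no_washout <- lambda_wash <= 0
    if (no_washout) lambda_wash <- 0
  } else {
    lambda_wash <- lambda_alive
    no_washout <- lambda_wash <= 0
  }
  structure(
    list(
      mode = mode,
      lambda_tiss = lambda_tiss,
      lambda_alive = lambda_alive,
      lambda_wash = lambda_wash,
      halflife_tiss = lambda_to_halflife(lambda_tiss),
      halflife_alive = lambda_to_halflife(lambda_alive),
      halflife_wash = lambda_to_halflife(lambda_wash),
      no_washout = no_washout,
      fit_alive = fit_alive,
      fit_dead = fit_dead
    ),
    class = "washout_decomposition"
  )
}

#' @export
print.washout_decomposition <- function(x, ...) {
  cat(sprintf("<washout_decomposition> mode = %s\n", x$mode))
  cat(sprintf("  tissular: T1/2 = %.4g s\n", x$halflife_tiss))
  cat(sprintf("  washout:  T1/2 = %.4g s%s\n", x$halflife_wash,
              if (x$no_washout) " [no detectable washout]" else ""))
  invisible(x)
}

#' @export
tidy.washout_decomposition <- function(x, ...) {
  tibble::tibble(
    component = c("tissular", "alive_total", "washout"),
    lambda = c(x$lambda_tiss, x$lambda_alive, x$lambda_wash),
    halflife = c(x$halflife_tiss, x$halflife_alive, x$halflife_wash),
    mode = x$mode,
    no_washout = c(FALSE, FALSE, x$no_washout)
  )
}

# Basis matrix of frame-averaged exponentials, one column per component.
mizuno_basis <- function(lambdas, t_start, duration) {
  vapply(lambdas, function(l) frame_mean_exp(l, t_start, duration),
         numeric(length(t_start)))
}

mizuno_rss <- function(log_lambdas, d) {
  lam <- sort(exp(log_lambdas), decreasing = TRUE)
  phi <- mizuno_basis(lam, d$t_start, d$duration)
  b <- pracma::lsqnonneg(phi, d$value)$x
  sum((phi %*% b - d$value)^2)
}

#' Fit the multi-exponential (fast/medium/slow) washout model
#'
#' Constrained least squares for the three-exponential biological washout
#' parameterization: amplitudes are kept non-negative (so the fractions lie
#' on the simplex and sum to one by construction) and the decay constants
#' ordered fast to slow. Uses variable projection: the outer optimization
#' runs over the log decay constants while the amplitudes are solved by
#' non-negative least squares. With `n_components = 1` the model reduces
#' to the single-exponential fit.
#'
#' @param tac A `tac` tibble.
#' @param n_components Number of exponential components, 1 to 3.
#' @param window Optional `c(t_min, t_max)` fit window in seconds.
#'
#' @return An object of class `mizuno_fit`: a [mizuno_params()] in
#'   `params` (unused components have zero fraction), total amplitude
#'   `A0`, `residual_rms`, `n_points`, `converged`, and a `collapsed` flag
#'   with a `lambda_gap` diagnostic when components became
#'   non-identifiable and were merged.
#' @export
fit_mizuno <- function(tac, n_components = 3L, window = NULL) {
  stopifnot(n_components %in% 1:3)
  fw <- tac_fit_window(tac, window)
  d <- fw$data[fw$data$value > 0, , drop = FALSE]
  if (nrow(d) < 2L * n_components + 1L) {
    stop(sprintf("need at least %d positive frames for %d components",
                 2L * n_components + 1L, n_components), call. = FALSE)
  }

  init <- stats::lm(log(value) ~ t_mid, data = d)
  l0 <- max(-unname(stats::coef(init)[2]), 1e-8)
  spread <- switch(n_components, 1, c(3, 1 / 3), c(10, 1, 0.1))
  start <- log(l0 * spread)

  if (n_components == 1L) {
    opt <- stats::optim(start, mizuno_rss, d = d, method = "Brent",
                        lower = start - 12, upper = start + 6,
                        control = list(reltol = 1e-15))
  } else {
    opt <- stats::optim(start, mizuno_rss, d = d, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-15))
    # one polish pass from the first solution
    opt2 <- stats::optim(opt$par, mizuno_rss, d = d, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-15))
    if (opt2$value <= opt$value) opt <- opt2
  }

  lam <- sort(exp(opt$par), decreasing = TRUE)
  phi <- mizuno_basis(lam, d$t_start, d$duration)
  b <- pracma::lsqnonneg(phi, d$value)$x
  A0 <- sum(b)
  if (A0 <= 0) stop("degenerate fit: zero total amplitude", call. = FALSE)
  frac <- b / A0

  # merge components whose rates collapsed onto each other
  lambda_gap <- if (length(lam) > 1L) {
    min(abs(diff(log(pmax(lam, 1e-300)))))
  } else {
    Inf
  }
  collapsed <- is.finite(lambda_gap) && lambda_gap < 1e-3
  if (collapsed) {
    keep <- c(TRUE, abs(diff(log(pmax(lam, 1e-300)))) >= 1e-3)
    grp <- cumsum(keep)
    lam <- as.numeric(tapply(lam * frac, grp, sum) /
                        tapply(frac, grp, sum))
    frac <- as.numeric(tapply(frac, grp, sum))
  }

  pad <- 3L - length(lam)
  params <- mizuno_params(
    fractions = c(frac, rep(0, pad)),
    lambdas = c(lam, rep(0, pad))
  )
  resid <- d$value - A0 * as.numeric(
    mizuno_basis(params$lambdas[params$fractions > 0],
                 d$t_start, d$duration) %*%
      (params$fractions[params$fractions > 0]))

  structure(
    list(
      params = params,
      A0 = A0,
      n_components = as.integer(n_components),
      residual_rms = sqrt(mean(resid^2)),
      n_points = nrow(d),
      window = fw$window,
      converged = opt$convergence == 0,
      collapsed = collapsed,
      lambda_gap = lambda_gap,
      data = d
    ),
    class = "mizuno_fit"
  )
}

#' @export
print.mizuno_fit <- function(x, ...) {
  cat(sprintf("<mizuno_fit> %d component(s), A0 = %.4g Bq%s\n",
              x$n_components, x$A0,
              if (x$collapsed) " [components collapsed]" else ""))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.mizuno_fit <- function(x, ...) {
  tibble::tibble(
    component = c("fast", "medium", "slow"),
    fraction = x$params$fractions,
    lambda = x$params$lambdas,
    halflife = ifelse(x$params$lambdas > 0,
                      log(2) / x$params$lambdas, Inf)
  )
}

#' @export
glance.mizuno_fit <- function(x, ...) {
  tibble::tibble(
    A0 = x$A0,
    n_components = x$n_components,
    residual_rms = x$residual_rms,
    n_points = x$n_points,
    converged = x$converged,
    collapsed = x$collapsed
  )
}

#' Group summary of recovered half-lives
#'
#' Across-animal arithmetic mean and sample standard deviation (n - 1
#' denominator) of half-life estimates for one tissue and model component,
#' the per-tissue summary format of washout studies.
#'
#' @param halflives Numeric vector of per-animal half-lives in seconds, or
#'   a data frame with a `halflife` column.
#' @param tissue Tissue label.
#' @param component Component label, e.g. `"tissular"` or `"washout"`.
#'
#' @return A one-row tibble with `tissue`, `component`, `n`,
#'   `mean_halflife`, `sd_halflife` (0 when n = 1).
#' @export
#' @examples
#' summarize_group(c(300, 360), "brain", "washout")
summarize_group <- function(halflives, tissue, component) {
  if (is.data.frame(halflives)) {
    if (!"halflife" %in% names(halflives)) {
      stop("data frame input must have a `halflife` column", call. = FALSE)
    }
    halflives <- halflives$halflife
  }
  if (length(halflives) < 1L) stop("no half-lives supplied", call. = FALSE)
  tibble::tibble(
    tissue = tissue,
    component = component,
    n = length(halflives),
    mean_halflife = mean(halflives),
    sd_halflife = if (length(halflives) == 1L) 0 else stats::sd(halflives)
  )
}
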