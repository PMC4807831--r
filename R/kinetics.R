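#' Convert a half-life to a decay constant
#'
#' @param t_half Half-life in seconds. Must be strictly positive.
#'
#' @return Decay constant \eqn{\lambda = \ln 2 / T_{1/2}} in 1/s.
#' @seealso [lambda_to_halflife()]
#' @export
#' @examples
#' halflife_to_lambda(1223.4) # 11C physical decay constant
halflife_to_lambda <- function(t_half) {
  if (any(!is.finite(t_half)) || any(t_half <= 0)) {
    stop("`t_half` must be finite and > 0", call. = FALSE)
  }
  log(2) / t_half
}

#' Convert a decay constant to a half-life
#'
#' @param lambda Decay constant in 1/s. Must be non-negative; a zero rate
#'   maps to an infinite half-life (no decay).
#'
#' @return Half-life in seconds (`Inf` when `lambda` is 0).
#' @export
lambda_to_halflife <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    stop("`lambda` must be finite and >= 0", call. = FALSE)
  }
  ifelse(lambda == 0, Inf, log(2) / lambda)
}

#' Isotope specification
#'
#' @param name Isotope label.
#' @param half_life Physical half-life in seconds (> 0).
#'
#' @return An object of class `isotope_spec` with fields `name`,
#'   `half_life` and the derived decay constant `lambda`.
#' @export
#' @examples
#' isotope_spec("18F", 6586.2)
isotope_spec <- function(name, half_life) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life) || length(half_life) != 1L ||
      !is.finite(half_life) || half_life <= 0) {
    stop("`half_life` must be a single finite value > 0", call. = FALSE)
  }
  structure(
    list(name = name, half_life = half_life,
         lambda = halflife_to_lambda(half_life)),
    class = "isotope_spec"
  )
}

#' Carbon-11 isotope specification
#'
#' The default isotope of the package: 11C with a physical half-life of
#' 1223.4 s (20.39 min, standard nuclear data).
#'
#' @return An `isotope_spec` for 11C.
#' @export
isotope_11c <- function() isotope_spec("11C", 1223.4)

#' @export
print.isotope_spec <- function(x, ...) {
  cat(sprintf("<isotope_spec> %s: T1/2 = %.1f s (lambda = %.4e 1/s)\n",
              x$name, x$half_life, x$lambda))
  invisible(x)
}

#' Two-component biological washout parameters
#'
#' Parameters of the two-component biological decay model. The biological
#' signal at a point-like injection site is the product of a tissular
#' (passive diffusion) exponential, present in both alive and dead tissue,
#' and a vascular washout exponential present only while the tissue is
#' perfused:
#' \deqn{C_{bio,alive}(t) = e^{-\lambda_{wash} t} e^{-\lambda_{tiss} t},
#'       \quad C_{bio,dead}(t) = e^{-\lambda_{tiss} t}.}
#'
#' @param lambda_tiss Tissular (diffusion) decay constant, 1/s, >= 0.
#' @param lambda_wash Vascular washout decay constant, 1/s, >= 0. Zero
#'   means no perfusion, i.e. the alive curve collapses onto the dead one.
#' @param A0 Activity at injection time in Bq (> 0). Defaults to 1 so that
#'   curves are relative unless an absolute scale is requested.
#'
#' @return An object of class `two_component_params`.
#' @export
#' @examples
#' two_component_params(lambda_tiss = halflife_to_lambda(2878),
#'                      lambda_wash = halflife_to_lambda(330))
two_component_params <- function(lambda_tiss, lambda_wash, A0 = 1) {
  vals <- c(lambda_tiss = lambda_tiss, lambda_wash = lambda_wash, A0 = A0)
  if (!all(is.finite(vals))) stop("all parameters must be finite", call. = FALSE)
  if (lambda_tiss < 0 || lambda_wash < 0) {
    stop("decay constants must be >= 0", call. = FALSE)
  }
  if (A0 <= 0) stop("`A0` must be > 0", call. = FALSE)
  structure(
    list(A0 = A0, lambda_tiss = lambda_tiss, lambda_wash = lambda_wash),
    class = "two_component_params"
  )
}

#' @export
print.two_component_params <- function(x, ...) {
  cat("<two_component_params>\n")
  cat(sprintf("  A0          = %.4g Bq\n", x$A0))
  cat(sprintf("  lambda_tiss = %.4e 1/s (T1/2 = %.4g s)\n",
              x$lambda_tiss, lambda_to_halflife(x$lambda_tiss)))
  cat(sprintf("  lambda_wash = %.4e 1/s (T1/2 = %.4g s)\n",
              x$lambda_wash, lambda_to_halflife(x$lambda_wash)))
  invisible(x)
}

check_condition <- function(condition) {
  match.arg(condition, c("alive", "dead"))
}

#' Evaluate the two-component biological decay curve
#'
#' In the alive condition both the tissular and the washout exponential act,
#' so the decay constant is the sum \eqn{\lambda_{tiss} + \lambda_{wash}};
#' in the dead condition there is no perfusion and only the tissular
#' component remains.
#'
#' @param params A [two_component_params()] object.
#' @param t Time(s) since injection, seconds, >= 0.
#' @param condition `"alive"` or `"dead"`.
#' @param absolute If `TRUE`, multiply by `A0` to return activity in Bq;
#'   otherwise return the relative curve in (0, 1].
#'
#' @return Numeric vector, same length as `t`.
#' @export
#' @examples
#' p <- two_component_params(halflife_to_lambda(2878), halflife_to_lambda(330))
#' eval_two_component(p, c(0, 300, 3600), "alive")
eval_two_component <- function(params, t, condition = c("alive", "dead"),
                               absolute = FALSE) {
  stopifnot(inherits(params, "two_component_params"))
  condition <- check_condition(condition)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  lambda <- params$lambda_tiss +
    if (condition == "alive") params$lambda_wash else 0
  out <- exp(-lambda * t)
  if (absolute) out <- params$A0 * out
  out
}

#' Three-exponential washout parameters (Mizuno model)
#'
#' The reference biological washout parameterization from radioactive-beam
#' rabbit experiments: a weighted sum of fast, medium and slow exponentials
#' with fractions summing to one,
#' \deqn{C_{bio}(t) = M_f e^{-\lambda_f t} + M_m e^{-\lambda_m t}
#'       + M_s e^{-\lambda_s t}.}
#'
#' @param fractions Numeric vector of three fractions in \[0, 1\] summing to
#'   1 (tolerance 1e-9), ordered fast/medium/slow.
#' @param lambdas Numeric vector of three decay constants in 1/s, >= 0,
#'   non-increasing (fast >= medium >= slow).
#'
#' @return An object of class `mizuno_params`.
#' @export
#' @examples
#' mizuno_params(c(0.3, 0.3, 0.4), c(0.01, 0.001, 0.0001))
mizuno_params <- function(fractions, lambdas) {
  if (length(fractions) != 3L || length(lambdas) != 3L) {
    stop("`fractions` and `lambdas` must have length 3", call. = FALSE)
  }
  if (any(!is.finite(fractions)) || any(fractions < 0) || any(fractions > 1)) {
    stop("fractions must be finite and within [0, 1]", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (any(!is.finite(lambdas)) || any(lambdas < 0)) {
    stop("decay constants must be finite and >= 0", call. = FALSE)
  }
  if (is.unsorted(rev(lambdas))) {
    stop("decay constants must be ordered fast >= medium >= slow", call. = FALSE)
  }
  structure(
    list(fractions = as.numeric(fractions), lambdas = as.numeric(lambdas)),
    class = "mizuno_params"
  )
}

#' Evaluate the three-exponential washout curve
#'
#' @param params A [mizuno_params()] object.
#' @param t Time(s) since injection, seconds, >= 0.
#'
#' @return Numeric vector in (0, 1], same length as `t`.
#' @export
eval_mizuno <- function(params, t) {
  stopifnot(inherits(params, "mizuno_params"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  vapply(t, function(ti) sum(params$fractions * exp(-params$lambdas * ti)),
         numeric(1))
}

#' Physical radioactive decay factor
#'
#' Fraction of the injected activity surviving physical decay at time `t`,
#' \eqn{A_{phys}(t)/A_{phys}(0) = e^{-\ln 2 \, t / T_{1/2}}}. The measured
#' activity is the product of this factor and the biological curve; decay
#' correction divides it back out.
#'
#' @param t Time(s) since injection, seconds, >= 0.
#' @param isotope An [isotope_spec()]; defaults to 11C.
#'
#' @return Numeric vector in (0, 1].
#' @export
#' @examples
#' physical_decay_factor(1223.4) # one half-life -> 0.5
physical_decay_factor <- function(t, isotope = isotope_11c()) {
  stopifnot(inherits(isotope, "isotope_spec"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  exp(-isotope$lambda * t)
}

#' Time-averaged exponential over an interval
#'
#' Mean of exp(-lambda t) over \[t_start, t_start + duration\], the exact
#' value a scanner histogramming counts into that frame reports for a
#' mono-exponential source. Closed form, with the lambda -> 0 limit handled.
#'
#' @param lambda Decay constant, 1/s (>= 0). Vectorized.
#' @param t_start Frame start time, s.
#' @param duration Frame duration, s (> 0).
#'
#' @return Mean relative activity over the frame.
#' @keywords internal
frame_mean_exp <- function(lambda, t_start, duration) {
  n <- max(length(lambda), length(t_start), length(duration))
  lambda <- rep_len(lambda, n)
  t_start <- rep_len(t_start, n)
  duration <- rep_len(duration, n)
  x <- lambda * duration
  out <- numeric(n)
  small <- abs(x) < 1e-9
  # (1 - exp(-x))/x -> 1 - x/2 as x -> 0
  out[small] <- exp(-lambda[small] * t_start[small]) * (1 - x[small] / 2)
  out[!small] <- exp(-lambda[!small] * t_start[!small]) *
    (1 - exp(-x[!small])) / x[!small]
  out
}
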