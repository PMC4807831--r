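#' Dynamic acquisition protocol
#'
#' Frame binning of a dynamic PET acquisition. The default reproduces the
#' 25-frame preclinical sequence 10 x 30 s, 5 x 60 s, 10 x 300 s (3600 s
#' total) used for point-source washout studies.
#'
#' @param frame_durations Ordered frame durations in seconds, all > 0.
#'
#' @return A tibble with one row per frame and columns `frame`, `t_start`,
#'   `duration`, `t_mid`, `t_end` (seconds from acquisition start =
#'   injection time).
#' @export
#' @examples
#' acquisition_protocol()
acquisition_protocol <- function(
    frame_durations = c(rep(30, 10), rep(60, 5), rep(300, 10))) {
  if (length(frame_durations) < 1L || any(!is.finite(frame_durations)) ||
      any(frame_durations <= 0)) {
    stop("`frame_durations` must be positive and finite", call. = FALSE)
  }
  t_end <- cumsum(frame_durations)
  t_start <- t_end - frame_durations
  tibble::tibble(
    frame = seq_along(frame_durations),
    t_start = t_start,
    duration = as.numeric(frame_durations),
    t_mid = t_start + frame_durations / 2,
    t_end = t_end
  )
}

check_protocol <- function(protocol) {
  req <- c("frame", "t_start", "duration", "t_mid", "t_end")
  if (!is.data.frame(protocol) || !all(req %in% names(protocol))) {
    stop("`protocol` must be a frame table from acquisition_protocol()",
         call. = FALSE)
  }
  invisible(protocol)
}

#' Frame-averaged activity of a two-component source
#'
#' Expected activity reported in each frame of a dynamic protocol for a
#' point source decaying with the two-component biological model,
#' optionally multiplied by physical radioactive decay. The frame value is
#' the time average of the instantaneous activity over the frame (how a
#' scanner histogramming counts sees an exponential source), computed in
#' closed form.
#'
#' @param params A [two_component_params()] object.
#' @param condition `"alive"` (tissular + washout) or `"dead"` (tissular
#'   only).
#' @param protocol Frame table from [acquisition_protocol()].
#' @param isotope An [isotope_spec()]; used when
#'   `include_physical_decay = TRUE`.
#' @param include_physical_decay If `TRUE` (default) the source also decays
#'   physically, i.e. the frames contain measured (uncorrected) activity.
#'
#' @return Numeric vector of per-frame mean activities in Bq (length =
#'   number of frames).
#' @export
#' @examples
#' p <- two_component_params(halflife_to_lambda(2878), halflife_to_lambda(330),
#'                           A0 = 0.9e6)
#' frame_average_activity(p, "alive", acquisition_protocol())
frame_average_activity <- function(params, condition = c("alive", "dead"),
                                   protocol = acquisition_protocol(),
                                   isotope = isotope_11c(),
                                   include_physical_decay = TRUE) {
  stopifnot(inherits(params, "two_component_params"))
  condition <- check_condition(condition)
  check_protocol(protocol)
  lambda <- params$lambda_tiss +
    (if (condition == "alive") params$lambda_wash else 0) +
    (if (include_physical_decay) {
      stopifnot(inherits(isotope, "isotope_spec"))
      isotope$lambda
    } else 0)
  params$A0 * frame_mean_exp(lambda, protocol$t_start, protocol$duration)
}
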