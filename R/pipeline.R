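#' Tissue parameter presets
#'
#' Group-mean half-lives measured for a point-like 11C source in rat
#' tissues, used as generative defaults for simulated studies: tissular
#' (passive diffusion, dead condition) and vascular washout (alive
#' condition) components. The two tumor metabolic states share the tumor
#' tissular half-life and differ in washout.
#'
#' @return A tibble with columns `tissue`, `halflife_tiss` (s) and
#'   `halflife_wash` (s).
#' @export
#' @examples
#' tissue_presets()
tissue_presets <- function() {
  tibble::tribble(
    ~tissue,          ~halflife_tiss, ~halflife_wash,
    "brain",          2878,           330,
    "muscle",         2132,           361,
    "tumor",          2019,           621,
    "tumor_necrotic", 2019,           613,
    "tumor_active",   2019,           418
  )
}

#' Generative parameters for a tissue preset
#'
#' @param tissue One of the `tissue` labels of [tissue_presets()].
#' @param A0 Injected activity in Bq for the parameter set (default 1,
#'   i.e. a relative curve; simulations draw the actual activity from the
#'   injection spec).
#'
#' @return A [two_component_params()] with the preset's decay constants.
#' @export
#' @examples
#' preset_params("brain")
preset_params <- function(tissue, A0 = 1) {
  presets <- tissue_presets()
  row <- presets[presets$tissue == tissue, ]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown tissue preset '%s' (available: %s)", tissue,
                 paste(presets$tissue, collapse = ", ")), call. = FALSE)
  }
  two_component_params(
    lambda_tiss = halflife_to_lambda(row$halflife_tiss),
    lambda_wash = halflife_to_lambda(row$halflife_wash),
    A0 = A0
  )
}

#' Extract TACs for every series of a simulated study
#'
#' Applies the first-frame threshold ROI and decay-corrected TAC
#' extraction to each acquisition of a study tibble.
#'
#' @param study Study tibble from [simulate_study()] (needs the `series`
#'   list-column).
#' @param threshold_fraction ROI threshold passed to [select_roi()].
#' @param isotope An [isotope_spec()] for decay correction.
#' @param decay_correct Passed to [extract_tac()].
#'
#' @return The study tibble with `roi` and `tac` list-columns added.
#' @export
extract_study_tacs <- function(study, threshold_fraction = 0.5,
                               isotope = isotope_11c(),
                               decay_correct = TRUE) {
  stopifnot(is.data.frame(study), "series" %in% names(study))
  study$roi <- purrr::map(study$series, select_roi,
                          threshold_fraction = threshold_fraction)
  study$tac <- purrr::map2(study$series, study$roi, extract_tac,
                           isotope = isotope, decay_correct = decay_correct)
  study
}

#' Fit a single exponential to every TAC of a study
#'
#' @param study Study tibble with a `tac` list-column (from
#'   [extract_study_tacs()]).
#' @param window,weighting Passed to [fit_single_exponential()]. The dead
#'   condition of tumors may need `window = c(600, Inf)` to skip the
#'   post-mortem pressure-equilibration transient.
#'
#' @return The study tibble with a `fit` list-column of `washout_fit`
#'   objects added.
#' @export
fit_study_tacs <- function(study, window = NULL, weighting = "none") {
  stopifnot(is.data.frame(study), "tac" %in% names(study))
  study$fit <- purrr::map(study$tac, fit_single_exponential,
                          window = window, weighting = weighting)
  study
}

#' Per-animal alive/dead decomposition of a fitted study
#'
#' Pairs each animal's alive and dead fits and decomposes them into
#' tissular and washout half-lives.
#'
#' @param study Study tibble with `fit` list-column (from
#'   [fit_study_tacs()]) and `animal_id`/`condition` columns.
#' @param mode Decomposition mode, see [decompose_washout()].
#'
#' @return A tibble with one row per animal: ground-truth decay constants
#'   (when present in the study), recovered `halflife_tiss_hat`,
#'   `halflife_wash_hat`, the underlying rates and the `no_washout` flag.
#' @export
decompose_study <- function(study, mode = "subtraction") {
  stopifnot(is.data.frame(study),
            all(c("animal_id", "condition", "fit") %in% names(study)))
  ids <- unique(study$animal_id)
  purrr::map_dfr(ids, function(id) {
    rows <- study[study$animal_id == id, ]
    fa <- rows$fit[[match("alive", rows$condition)]]
    fd <- rows$fit[[match("dead", rows$condition)]]
    dec <- decompose_washout(fa, fd, mode = mode)
    out <- tibble::tibble(
      animal_id = id,
      lambda_tiss_hat = dec$lambda_tiss,
      lambda_wash_hat = dec$lambda_wash,
      halflife_tiss_hat = dec$halflife_tiss,
      halflife_wash_hat = dec$halflife_wash,
      mode = dec$mode,
      no_washout = dec$no_washout
    )
    if (all(c("lambda_tiss", "lambda_wash") %in% names(rows))) {
      out$lambda_tiss_true <- rows$lambda_tiss[1]
      out$lambda_wash_true <- rows$lambda_wash[1]
    }
    out
  })
}

#' Run simulate-extract-fit-decompose for one tissue preset
#'
#' Convenience wrapper chaining [simulate_study()],
#' [extract_study_tacs()], [fit_study_tacs()] and [decompose_study()].
#'
#' @param params_mean Group-mean [two_component_params()], e.g. from
#'   [preset_params()].
#' @param n_animals,inter_animal_cv,seed Study design, see
#'   [study_design()].
#' @param noise Poisson counting noise?
#' @param scanner,injection,protocol,isotope Acquisition set-up.
#' @param threshold_fraction ROI threshold.
#' @param window,weighting,mode Fit and decomposition options.
#'
#' @return A list with `study` (the full tibble including series, TACs and
#'   fits) and `animals` (the per-animal decomposition tibble).
#' @export
#' @examples
#' \donttest{
#' res <- recover_tissue(preset_params("brain"), n_animals = 2,
#'                       inter_animal_cv = 0, seed = 1)
#' res$animals[, c("halflife_tiss_hat", "halflife_wash_hat")]
#' }
recover_tissue <- function(params_mean, n_animals = 4L,
                           inter_animal_cv = 0.1, seed = 1L, noise = FALSE,
                           scanner = scanner_model(),
                           injection = injection_spec(),
                           protocol = acquisition_protocol(),
                           isotope = isotope_11c(),
                           threshold_fraction = 0.5,
                           window = NULL, weighting = "none",
                           mode = "subtraction") {
  design <- study_design(params_mean, n_animals = n_animals,
                         inter_animal_cv = inter_animal_cv, seed = seed)
  study <- simulate_study(design, scanner, injection, protocol, isotope,
                          noise = noise) |>
    extract_study_tacs(threshold_fraction = threshold_fraction,
                       isotope = isotope) |>
    fit_study_tacs(window = window, weighting = weighting)
  list(study = study, animals = decompose_study(study, mode = mode))
}
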