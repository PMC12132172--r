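# Synthetic two-electrode voltage clamp recordings.
#
# Stimulus protocol emulated: a heat pulse (>40 C, 30 s), a 120 s wash,
# then a single 90 s AITC application at one dose. Inward currents are
# stored as negative values; all reported amplitudes are magnitudes of
# deflection from the relevant baseline.

trace_windows <- function() {
  list(baseline = c(0, 10),
       heat     = c(10, 40),
       wash     = c(40, 160),
       aitc     = c(160, 250))
}

#' Generate one synthetic TEVC trace
#'
#' Simulates a clamped-current recording of a single oocyte expressing one
#' TRPA1 isoform: flat baseline, a heat-evoked inward current whose
#' amplitude equals the oocyte's expression scale, a wash during which the
#' heat response relaxes, and a covalent-agonist (AITC) response that
#' rises mono-exponentially towards a plateau and does not return to
#' baseline within the record. The plateau amplitude is
#' `expression_scale * f(dose)` times a multiplicative log-normal noise
#' factor, where `f` is the isoform's saturating dose-response curve.
#'
#' @param isoform_params list with elements `d`, `e`, `h` (see
#'   [hill_response()]).
#' @param dose AITC concentration (mM), `>= 0`.
#' @param expression_scale heat-evoked current magnitude of this oocyte
#'   (uA), `> 0`.
#' @param config a [sim_config()]; its seed makes the trace reproducible.
#' @param isoform_label identifier stored on the trace.
#'
#' @return a `tevc_trace` object: time (s), current (uA, signed, inward
#'   negative), temperature (C), the labelled stimulus windows, the dose,
#'   and a `truth` list with the noiseless amplitudes.
#' @examples
#' tr <- gen_tevc_trace(list(d = 2, e = 0.1, h = 1), dose = 0.1,
#'                      expression_scale = 2, config = sim_config(seed = 1))
#' extract_heat_amplitude(tr)
#' @export
gen_tevc_trace <- function(isoform_params, dose, expression_scale, config,
                           isoform_label = "isoform") {
  if (!is.numeric(expression_scale) || length(expression_scale) != 1L ||
      !is.finite(expression_scale) || expression_scale <= 0) {
    stop("`expression_scale` must be a single positive number (uA)",
         call. = FALSE)
  }
  stop_if_not_number(dose, "dose", nonneg = TRUE)
  stopifnot(inherits(config, "sim_config"))
  d <- isoform_params$d; e <- isoform_params$e; h <- isoform_params$h

  with_seed(config$seed, {
    win <- trace_windows()
    dt <- 1 / config$sampling_hz
    time <- seq(0, win$aitc[2], by = dt)
    n <- length(time)

    # heat response: fast logistic onset inside the heat window, exponential
    # relaxation during the wash (heat activation is reversible)
    heat_amp <- expression_scale
    heat_shape <- numeric(n)
    in_heat <- time >= win$heat[1] & time < win$heat[2]
    heat_shape[in_heat] <- 1 / (1 + exp(-(time[in_heat] - win$heat[1] - 5)))
    after <- time >= win$heat[2]
    peak <- 1 / (1 + exp(-25))
    heat_shape[after] <- peak * exp(-(time[after] - win$heat[2]) / 15)

    # covalent AITC response: mono-exponential rise to plateau, no decay;
    # rate increases with dose relative to the isoform's EC50
    f <- hill_response(dose, d, e, h)
    aitc_amp <- expression_scale * f * lognormal_factor(1, config$noise_cv)
    k <- 0.08 + 0.4 * if (dose > 0) dose / (dose + e) else 0
    aitc_shape <- numeric(n)
    in_aitc <- time >= win$aitc[1]
    aitc_shape[in_aitc] <- 1 - exp(-k * (time[in_aitc] - win$aitc[1]))

    temperature <- 22 + 23 * heat_shape
    leak <- -0.05
    current <- leak - heat_amp * heat_shape - aitc_amp * aitc_shape +
      rnorm(n, 0, config$trace_noise_sd)

    structure(
      list(time = time, current = current, temperature = temperature,
           windows = win, dose = dose, isoform_label = isoform_label,
           truth = list(i_heat = heat_amp, i_aitc = aitc_amp,
                        normalized = aitc_amp / heat_amp,
                        params = list(d = d, e = e, h = h))),
      class = "tevc_trace"
    )
  })
}

#' @export
print.tevc_trace <- function(x, ...) {
  cat("TEVC trace:", x$isoform_label, "at", x$dose, "mM,",
      length(x$time), "samples over", max(x$time), "s\n")
  invisible(x)
}

#' Generate a set of recording summaries for a dose-response design
#'
#' Draws one summary row per oocyte for each isoform x dose x replicate
#' cell of the design. Expression scales are log-normal across oocytes
#' (positive support, realistic oocyte-to-oocyte spread), so the raw
#' heat- and AITC-evoked currents are positively correlated. The heat
#' current equals the oocyte's expression scale; the AITC current is
#' `scale * f(dose)` times mean-one log-normal noise with CV
#' `config$noise_cv`, so the normalized response is `f(dose)` times that
#' same noise factor.
#'
#' @param isoform_params named list of parameter lists (`d`, `e`, `h`),
#'   one per isoform; a single unnamed parameter list is also accepted.
#' @param config a [sim_config()]; supplies doses, replicates, noise and
#'   the seed.
#'
#' @return data.frame with columns `isoform`, `dose`, `oocyte`,
#'   `expression_scale`, `i_heat`, `i_aitc`, `normalized`, and the true
#'   parameters as attribute `"params"`.
#' @examples
#' cfg <- sim_config(seed = 1, n_oocytes_per_dose = 4)
#' rec <- gen_recording_set(list(CL = list(d = 3, e = 0.03, h = 1)), cfg)
#' head(rec)
#' @export
gen_recording_set <- function(isoform_params, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.list(isoform_params) || length(isoform_params) == 0L) {
    stop("`isoform_params` must be a non-empty list", call. = FALSE)
  }
  if (!is.null(isoform_params$d)) {
    isoform_params <- list(isoform = isoform_params)
  }
  if (is.null(names(isoform_params))) {
    names(isoform_params) <- paste0("isoform", seq_along(isoform_params))
  }

  with_seed(config$seed, {
    rows <- lapply(names(isoform_params), function(id) {
      p <- isoform_params[[id]]
      per_dose <- lapply(config$dose_series, function(dose) {
        nrep <- config$n_oocytes_per_dose
        scale <- rlnorm(nrep, log(config$expression_median),
                        config$expression_sdlog)
        f <- hill_response(dose, p$d, p$e, p$h)
        i_aitc <- scale * f * lognormal_factor(nrep, config$noise_cv)
        data.frame(isoform = id, dose = dose, oocyte = seq_len(nrep),
                   expression_scale = scale, i_heat = scale,
                   i_aitc = i_aitc, normalized = i_aitc / scale,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, per_dose)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "params") <- isoform_params
    out
  })
}
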