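#' Simulation configuration for all synthetic-data generators
#'
#' One object holds every knob of the synthetic study: the TEVC recording
#' design (dose series, oocytes per dose, multiplicative noise), the
#' amplicon read simulator (read count, per-base error, length jitter,
#' junk fraction) and the behavioral arm (flies per group). The defaults
#' are the study conditions used throughout: the seven applied AITC doses
#' 0.001-3 mM, 8 oocytes per dose, 20% multiplicative noise on responses,
#' and a log-normal expression-scale distribution across oocytes.
#'
#' @param seed integer RNG seed; a fixed seed makes every generator
#'   byte-reproducible.
#' @param n_oocytes_per_dose recordings per dose and isoform.
#' @param dose_series applied agonist concentrations (mM), strictly
#'   positive and strictly increasing.
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal noise on evoked responses (dimensionless, in `[0, 1]`).
#' @param read_count number of amplicon reads to simulate.
#' @param per_base_error per-base error rate of the read simulator
#'   (substitutions + indels), must be `< 0.3`.
#' @param length_jitter_sd standard deviation (bp) of random end-trimming
#'   applied to reads.
#' @param junk_fraction fraction of reads replaced by off-target junk
#'   (half truncated fragments, half composition-shuffled sequences).
#' @param n_flies_per_group flies per group and dose in the PER generator.
#' @param sampling_hz trace sampling rate (Hz). Recordings are digitized
#'   at kHz rates in the rig; traces here default to 100 Hz, which fully
#'   resolves the second-scale kinetics being modelled.
#' @param expression_median median of the log-normal expression scale
#'   across oocytes (uA).
#' @param expression_sdlog log-scale SD of the expression distribution.
#' @param trace_noise_sd additive recording noise on traces (uA).
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$dose_series
#' @export
sim_config <- function(seed = 1L,
                       n_oocytes_per_dose = 8L,
                       dose_series = c(0.001, 0.01, 0.03, 0.1, 0.3, 1, 3),
                       noise_cv = 0.2,
                       read_count = 2000L,
                       per_base_error = 0.05,
                       length_jitter_sd = 20,
                       junk_fraction = 0,
                       n_flies_per_group = 30L,
                       sampling_hz = 100,
                       expression_median = 2,
                       expression_sdlog = 0.4,
                       trace_noise_sd = 0.02) {
  stop_if_not_number(seed, "seed")
  stop_if_not_number(n_oocytes_per_dose, "n_oocytes_per_dose", positive = TRUE)
  if (!is.numeric(dose_series) || length(dose_series) < 1L ||
      any(dose_series <= 0) || any(diff(dose_series) <= 0)) {
    stop("`dose_series` must be strictly positive and strictly increasing",
         call. = FALSE)
  }
  stop_if_not_fraction(noise_cv, "noise_cv")
  stop_if_not_number(read_count, "read_count", positive = TRUE)
  stop_if_not_fraction(per_base_error, "per_base_error")
  if (per_base_error >= 0.3) {
    stop("`per_base_error` must be < 0.3", call. = FALSE)
  }
  stop_if_not_number(length_jitter_sd, "length_jitter_sd", nonneg = TRUE)
  stop_if_not_fraction(junk_fraction, "junk_fraction")
  stop_if_not_number(n_flies_per_group, "n_flies_per_group", positive = TRUE)
  stop_if_not_number(sampling_hz, "sampling_hz", positive = TRUE)
  stop_if_not_number(expression_median, "expression_median", positive = TRUE)
  stop_if_not_number(expression_sdlog, "expression_sdlog", nonneg = TRUE)
  stop_if_not_number(trace_noise_sd, "trace_noise_sd", nonneg = TRUE)

  structure(
    list(seed = as.integer(seed),
         n_oocytes_per_dose = as.integer(n_oocytes_per_dose),
         dose_series = as.numeric(dose_series),
         noise_cv = noise_cv,
         read_count = as.integer(read_count),
         per_base_error = per_base_error,
         length_jitter_sd = length_jitter_sd,
         junk_fraction = junk_fraction,
         n_flies_per_group = as.integer(n_flies_per_group),
         sampling_hz = sampling_hz,
         expression_median = expression_median,
         expression_sdlog = expression_sdlog,
         trace_noise_sd = trace_noise_sd),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  cat("  TEVC: ", x$n_oocytes_per_dose, " oocytes/dose at doses [",
      paste(x$dose_series, collapse = ", "), "] mM, noise CV ",
      x$noise_cv, "\n", sep = "")
  cat("  Reads: ", x$read_count, " reads, per-base error ",
      x$per_base_error, ", junk fraction ", x$junk_fraction, "\n", sep = "")
  cat("  PER: ", x$n_flies_per_group, " flies/group\n", sep = "")
  invisible(x)
}
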