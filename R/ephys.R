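# Amplitude extraction from TEVC traces and dose-response estimation.

window_idx <- function(trace, name) {
  w <- trace$windows[[name]]
  if (is.null(w)) {
    stop(sprintf("trace has no \"%s\" window annotation", name),
         call. = FALSE)
  }
  idx <- which(trace$time >= w[1] & trace$time < w[2])
  if (length(idx) == 0L) {
    stop(sprintf("\"%s\" window contains no samples", name), call. = FALSE)
  }
  idx
}

#' Extract the heat-evoked current amplitude from a trace
#'
#' Returns the maximum absolute deflection of the clamped current from
#' the pre-stimulus baseline mean within the heat window (uA magnitude).
#'
#' @param trace a `tevc_trace` (or any list with `time`, `current` and a
#'   `windows` annotation containing `baseline` and `heat`).
#' @return heat-evoked amplitude (uA, magnitude).
#' @export
extract_heat_amplitude <- function(trace) {
  base_idx <- window_idx(trace, "baseline")
  w <- trace$windows$baseline
  if (diff(w) < 1) {
    stop("baseline window must span at least 1 s", call. = FALSE)
  }
  heat_idx <- window_idx(trace, "heat")
  base <- mean(trace$current[base_idx])
  max(abs(trace$current[heat_idx] - base))
}

#' Extract the AITC-evoked amplitude and saturation flag
#'
#' The local baseline is the mean current over the 5 s preceding AITC
#' onset. Because covalent activation does not reverse, the response is
#' reported at the end of the 90 s window unless it saturates inside it:
#' the response is called saturated when the peak deflection occurs at
#' least 2 s before the window end and the mean deflection over the final
#' 2 s is at most 98% of that peak, in which case the peak deflection is
#' returned instead.
#'
#' @param trace a `tevc_trace` with an `aitc` window.
#' @return list with `amplitude` (uA magnitude) and `saturated` (flag).
#' @export
extract_aitc_amplitude <- function(trace) {
  aitc_idx <- window_idx(trace, "aitc")
  w <- trace$windows$aitc
  pre_idx <- which(trace$time >= w[1] - 5 & trace$time < w[1])
  if (length(pre_idx) == 0L) {
    stop("no samples in the 5 s preceding AITC onset", call. = FALSE)
  }
  base <- mean(trace$current[pre_idx])
  defl <- abs(trace$current[aitc_idx] - base)
  peak <- max(defl)
  t_peak <- trace$time[aitc_idx][which.max(defl)]
  tail_idx <- aitc_idx[trace$time[aitc_idx] >= w[2] - 2]
  tail_mean <- mean(defl[match(tail_idx, aitc_idx)])
  saturated <- (t_peak <= w[2] - 2) && peak > 0 && (tail_mean <= 0.98 * peak)
  amplitude <- if (saturated) peak else defl[length(defl)]
  list(amplitude = amplitude, saturated = saturated)
}

#' Heat-normalize an AITC-evoked current
#'
#' The expression level of an oocyte is proxied by its heat-evoked
#' current, so dividing the AITC amplitude by the heat amplitude removes
#' the expression scale and makes recordings comparable.
#'
#' @param i_aitc AITC-evoked amplitude (uA magnitude, `>= 0`).
#' @param i_heat heat-evoked amplitude (uA magnitude, `> 0`).
#' @return dimensionless normalized response `i_aitc / i_heat`.
#' @examples
#' normalize_response(1, 2)
#' @export
normalize_response <- function(i_aitc, i_heat) {
  if (any(i_heat <= 0)) {
    stop("i_heat must be > 0; for weakly heat-responsive (inactive) ",
         "isoforms analyse raw AITC currents instead ",
         "(fit_dose_response(use_raw = TRUE))", call. = FALSE)
  }
  if (any(i_aitc < 0)) stop("i_aitc must be >= 0", call. = FALSE)
  i_aitc / i_heat
}

#' Fit a three-parameter log-logistic dose-response curve
#'
#' Least-squares fit of `f(c) = d / (1 + (e/c)^h)` (lower asymptote fixed
#' at 0) to per-recording responses, via Levenberg-Marquardt nonlinear
#' least squares with multi-start over the slope (`h` in 0.5, 1, 2), the
#' EC50 initialized at the half-max crossing of the per-dose means, and
#' the maximum initialized at the largest observed response. Zero-dose
#' recordings are excluded: they carry no information about `e` or `h`.
#'
#' @param summaries data.frame with columns `dose` and `normalized` (or
#'   `i_aitc` when `use_raw = TRUE`); at least 3 distinct positive doses.
#' @param use_raw fit raw AITC currents instead of normalized responses
#'   (the pathway for weakly heat-responsive isoforms).
#'
#' @return a `dose_response_fit`: coefficients `d`, `e`, `h`, asymptotic
#'   standard errors, residual sum of squares, counts, and a convergence
#'   flag. `predict()` evaluates the fitted curve.
#' @examples
#' cfg <- sim_config(seed = 1, noise_cv = 0)
#' rec <- gen_recording_set(list(d = 2, e = 0.1, h = 1), cfg)
#' coef(fit_dose_response(rec))
#' @export
fit_dose_response <- function(summaries, use_raw = FALSE) {
  ycol <- if (use_raw) "i_aitc" else "normalized"
  if (!all(c("dose", ycol) %in% names(summaries))) {
    stop(sprintf("`summaries` needs columns dose and %s", ycol),
         call. = FALSE)
  }
  keep <- summaries$dose > 0 & is.finite(summaries[[ycol]])
  dose <- summaries$dose[keep]
  y <- summaries[[ycol]][keep]
  if (length(unique(dose)) < 3L) {
    stop("at least 3 distinct positive doses are required", call. = FALSE)
  }
  if (any(y < 0)) stop("responses must be >= 0", call. = FALSE)

  d0 <- max(y)
  if (d0 <= 0) d0 <- 1e-6
  means <- tapply(y, dose, mean)
  ds <- as.numeric(names(means))
  e0 <- {
    half <- max(means) / 2
    above <- which(means >= half)
    if (length(above) == 0L || above[1] == 1L) {
      ds[1]
    } else {
      i <- above[1]
      # linear interpolation of the half-max crossing on log-dose
      frac <- (half - means[i - 1]) / (means[i] - means[i - 1])
      exp(log(ds[i - 1]) + frac * (log(ds[i]) - log(ds[i - 1])))
    }
  }
  e0 <- unname(as.numeric(e0))
  if (!is.finite(e0) || e0 <= 0) e0 <- exp(mean(log(ds)))

  dat <- data.frame(dose = dose, y = y)
  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ d / (1 + (e / dose)^h), data = dat,
        start = list(d = d0, e = e0, h = h0),
        lower = c(d = 1e-8, e = 1e-10, h = 1e-3),
        upper = c(d = Inf, e = Inf, h = 50),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }

  if (is.null(best)) {
    return(structure(
      list(coefficients = c(d = NA_real_, e = NA_real_, h = NA_real_),
           se = c(d = NA_real_, e = NA_real_, h = NA_real_),
           rss = NA_real_, n_recordings = length(y),
           n_doses = length(unique(dose)), converged = FALSE,
           use_raw = use_raw, data = dat),
      class = "dose_response_fit"))
  }

  cf <- coef(best$fit)[c("d", "e", "h")]
  se <- tryCatch(summary(best$fit)$coefficients[c("d", "e", "h"), 2],
                 error = function(e) c(d = NA_real_, e = NA_real_,
                                       h = NA_real_))
  structure(
    list(coefficients = cf, se = setNames(as.numeric(se), c("d", "e", "h")),
         rss = best$rss, n_recordings = length(y),
         n_doses = length(unique(dose)), converged = TRUE,
         use_raw = use_raw, data = dat),
    class = "dose_response_fit")
}

#' @export
coef.dose_response_fit <- function(object, ...) object$coefficients

#' @export
predict.dose_response_fit <- function(object, doses, ...) {
  cf <- object$coefficients
  if (anyNA(cf)) stop("fit did not converge; no predictions available",
                      call. = FALSE)
  hill_response(doses, cf[["d"]], cf[["e"]], cf[["h"]])
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Dose-response fit (", if (x$use_raw) "raw currents" else
    "heat-normalized responses", ")\n", sep = "")
  if (!x$converged) {
    cat("  ** optimizer did not converge **\n")
  } else {
    cf <- x$coefficients; se <- x$se
    cat(sprintf("  max response d = %.4g (SE %.3g)\n", cf[["d"]], se[["d"]]))
    cat(sprintf("  EC50         e = %.4g mM (SE %.3g)\n", cf[["e"]],
                se[["e"]]))
    cat(sprintf("  slope        h = %.4g (SE %.3g)\n", cf[["h"]], se[["h"]]))
    cat(sprintf("  RSS %.4g over %d recordings at %d doses\n", x$rss,
                x$n_recordings, x$n_doses))
  }
  invisible(x)
}

#' Rank correlation between raw AITC and heat currents
#'
#' The heat-normalization strategy assumes both raw currents scale with
#' channel expression; a positive rank correlation between them at a
#' fixed dose supports that assumption.
#'
#' @param summaries data.frame with columns `i_aitc` and `i_heat`,
#'   typically restricted to one dose; `n >= 3`.
#' @return a `phys_test` with Spearman's rho and a two-sided p-value, or
#'   an NA statistic with a note when an input is constant.
#' @export
raw_current_correlation <- function(summaries) {
  if (!all(c("i_aitc", "i_heat") %in% names(summaries))) {
    stop("`summaries` needs columns i_aitc and i_heat", call. = FALSE)
  }
  if (nrow(summaries) < 3L) stop("n >= 3 recordings required", call. = FALSE)
  tryCatch(
    correlation(summaries$i_aitc, summaries$i_heat, method = "spearman"),
    error = function(e) {
      phys_test(statistic = NA_real_, p_raw = NA_real_,
                method = "Spearman rank correlation",
                n = nrow(summaries),
                notes = "constant input: correlation undefined")
    })
}

#' Write a trace to CSV with a JSON window sidecar / read it back
#'
#' The CSV holds `time_s`, `current_uA`, `temp_C`; window annotations,
#' dose and isoform label go to `<path>.json`.
#'
#' @param trace a `tevc_trace`.
#' @param path CSV output path.
#' @return `write_trace_csv()` returns `path` invisibly;
#'   `read_trace_csv()` returns a `tevc_trace` (without generator truth).
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = trace$time, current_uA = trace$current,
               temp_C = trace$temperature),
    path, row.names = FALSE)
  jsonlite::write_json(
    list(windows = trace$windows, dose = trace$dose,
         isoform_label = trace$isoform_label),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(time = df$time_s, current = df$current_uA,
         temperature = df$temp_C,
         windows = lapply(meta$windows, as.numeric),
         dose = meta$dose, isoform_label = meta$isoform_label,
         truth = NULL),
    class = "tevc_trace")
}
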