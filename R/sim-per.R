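# Synthetic proboscis extension reflex (PER) trial tables.

#' Generate a PER trial dataset with known aversion curves
#'
#' Each fly performs 5 trials at a single tastant dose; each trial is
#' scored 1 (full extension and sustained drinking), 0.5 (partial) or 0.
#' The generative model: a trial elicits a response with probability
#' `baseline * aversion(dose)` (clamped to `[0, 1]`); a response is full
#' with probability 0.9, otherwise partial. Under this model the
#' group-mean PER score normalized to the 0 mM mean equals
#' `aversion(dose)` exactly, independent of the baseline response rate,
#' so the aversion curve is the ground truth for the normalized readout.
#'
#' @param group_params named list of groups, each a list with `baseline`
#'   (response probability per trial at dose 0, in `(0, 1]`) and
#'   `aversion` (function of dose returning the relative response, 1 at
#'   dose 0; values slightly above 1 are allowed, mirroring real assays).
#' @param config a [sim_config()]; supplies `n_flies_per_group` and seed.
#' @param doses tastant concentrations (mM) including 0 (the
#'   normalization anchor).
#'
#' @return list with `trials` (data.frame: `fly_id`, `group`, `dose`,
#'   `t1`..`t5`) and `truth` (data.frame of true normalized means per
#'   group and dose).
#' @examples
#' gp <- list(wt = list(baseline = 0.5, aversion = function(d) 1 / (1 + d)))
#' per <- gen_per_dataset(gp, sim_config(seed = 1, n_flies_per_group = 5),
#'                        doses = c(0, 5))
#' head(per$trials)
#' @export
gen_per_dataset <- function(group_params, config, doses = c(0, 2, 5, 10)) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.list(group_params) || is.null(names(group_params))) {
    stop("`group_params` must be a named list of groups", call. = FALSE)
  }
  if (!0 %in% doses) {
    stop("`doses` must include 0 (the normalization anchor)", call. = FALSE)
  }
  for (g in names(group_params)) {
    b <- group_params[[g]]$baseline
    if (!is.numeric(b) || length(b) != 1L || b <= 0 || b > 1) {
      stop(sprintf("group \"%s\": `baseline` must lie in (0, 1]", g),
           call. = FALSE)
    }
    if (!is.function(group_params[[g]]$aversion)) {
      stop(sprintf("group \"%s\": `aversion` must be a function of dose", g),
           call. = FALSE)
    }
  }

  with_seed(config$seed, {
    n <- config$n_flies_per_group
    rows <- list()
    truth <- list()
    for (g in names(group_params)) {
      p <- group_params[[g]]
      for (dose in doses) {
        pr <- min(1, p$baseline * p$aversion(dose))
        trials <- matrix(0, nrow = n, ncol = 5)
        responded <- matrix(runif(n * 5) < pr, nrow = n)
        full <- matrix(runif(n * 5) < 0.9, nrow = n)
        trials[responded & full] <- 1
        trials[responded & !full] <- 0.5
        df <- data.frame(
          fly_id = sprintf("%s_d%g_f%03d", g, dose, seq_len(n)),
          group = g, dose = dose, stringsAsFactors = FALSE)
        colnames(trials) <- paste0("t", 1:5)
        rows[[length(rows) + 1L]] <- cbind(df, as.data.frame(trials))
        truth[[length(truth) + 1L]] <- data.frame(
          group = g, dose = dose,
          true_normalized = p$aversion(dose) / p$aversion(0),
          stringsAsFactors = FALSE)
      }
    }
    list(trials = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}
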