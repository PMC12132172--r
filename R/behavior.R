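# Proboscis extension reflex (PER) scoring, zero-dose normalization,
# dose contrasts and test/control genotype ratios.

per_allowed <- c(0, 0.5, 1)

#' Total PER score of one fly
#'
#' Five presentations, each scored 1 (extended proboscis, sustained
#' drinking), 0.5 (partial/brief contact) or 0 (no extension); the total
#' ranges 0-5 in steps of 0.5.
#'
#' @param trials numeric vector of exactly 5 outcomes in `{0, 0.5, 1}`.
#' @return the total score.
#' @examples
#' score_trials(c(1, 0.5, 0, 0, 0))
#' @export
score_trials <- function(trials) {
  if (!is.numeric(trials) || length(trials) != 5L) {
    stop("exactly 5 trial outcomes are required", call. = FALSE)
  }
  if (!all(trials %in% per_allowed)) {
    stop("trial outcomes must be 0, 0.5 or 1", call. = FALSE)
  }
  sum(trials)
}

#' Score a PER trial table
#'
#' @param trials data.frame with columns `t1`..`t5` (plus any metadata
#'   columns, carried through).
#' @return the input with a `score` column appended.
#' @export
score_trial_table <- function(trials) {
  tcols <- paste0("t", 1:5)
  if (!all(tcols %in% names(trials))) {
    stop("`trials` needs columns t1..t5", call. = FALSE)
  }
  trials$score <- apply(as.matrix(trials[tcols]), 1, score_trials)
  trials
}

#' Normalize PER scores to the within-group zero-dose mean
#'
#' Every score is divided by its group's mean score at dose 0, so the
#' group-level mean at dose 0 maps to exactly 1 and smaller values mean
#' stronger feeding inhibition. Normalized scores may exceed 1; no
#' clipping is applied.
#'
#' @param df data.frame with columns `group`, `dose`, `score`.
#' @return the input with a `normalized` column appended.
#' @export
normalize_per <- function(df) {
  if (!all(c("group", "dose", "score") %in% names(df))) {
    stop("`df` needs columns group, dose, score", call. = FALSE)
  }
  df$normalized <- NA_real_
  for (g in unique(df$group)) {
    at0 <- df$group == g & df$dose == 0
    if (!any(at0)) {
      stop(sprintf("group \"%s\" has no flies at dose 0", g), call. = FALSE)
    }
    m0 <- mean(df$score[at0])
    if (m0 <= 0) {
      stop(sprintf("group \"%s\" has zero mean score at dose 0: cannot normalize",
                   g), call. = FALSE)
    }
    sel <- df$group == g
    df$normalized[sel] <- df$score[sel] / m0
  }
  df
}

#' Mean normalized PER per group and dose
#'
#' @param df normalized data.frame (see [normalize_per()]).
#' @return data.frame with `group`, `dose`, `mean_normalized`, `n`.
#' @export
summarize_aversion <- function(df) {
  if (!all(c("group", "dose", "normalized") %in% names(df))) {
    stop("`df` needs columns group, dose, normalized (run normalize_per)",
         call. = FALSE)
  }
  agg <- aggregate(normalized ~ group + dose, data = df, FUN = mean)
  ns <- aggregate(normalized ~ group + dose, data = df, FUN = length)
  out <- data.frame(group = agg$group, dose = agg$dose,
                    mean_normalized = agg$normalized, n = ns$normalized,
                    stringsAsFactors = FALSE)
  out[order(out$group, out$dose), , drop = FALSE]
}

#' Pairwise dose contrasts within one group
#'
#' All dose-pair Wilcoxon rank-sum tests on normalized scores, BH
#' adjusted within the group's family of contrasts.
#'
#' @param df normalized data.frame for a single group (columns `dose`,
#'   `normalized`); >= 2 doses with >= 3 flies each.
#' @return data.frame: `dose1`, `dose2`, `statistic`, `p_raw`,
#'   `p_adjusted`.
#' @export
dose_contrasts <- function(df) {
  if (!all(c("dose", "normalized") %in% names(df))) {
    stop("`df` needs columns dose and normalized", call. = FALSE)
  }
  by_dose <- split(df$normalized, df$dose)
  if (length(by_dose) < 2L) stop("at least 2 doses required", call. = FALSE)
  if (any(lengths(by_dose) < 3L)) {
    stop("every dose needs >= 3 flies", call. = FALSE)
  }
  doses <- names(by_dose)
  pairs <- combn(doses, 2)
  stat <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    res <- wilcoxon_rank_sum(by_dose[[pairs[1, j]]],
                             by_dose[[pairs[2, j]]])
    stat[j] <- res$statistic
    p_raw[j] <- res$p_raw
  }
  data.frame(dose1 = as.numeric(pairs[1, ]), dose2 = as.numeric(pairs[2, ]),
             statistic = stat, p_raw = p_raw,
             p_adjusted = benjamini_hochberg(p_raw),
             stringsAsFactors = FALSE)
}

#' Test/control genotype ratio of mean normalized PER per dose
#'
#' For the transgenic arm: the ratio of the test genotype's mean
#' normalized PER to the control genotype's, at each shared dose.
#'
#' @param test,control data.frames with columns `dose` and
#'   `mean_normalized` (e.g. from [summarize_aversion()]).
#' @return data.frame: `dose`, `test_mean`, `control_mean`, `ratio`.
#' @export
genotype_ratio <- function(test, control) {
  for (nm in list(test, control)) {
    if (!all(c("dose", "mean_normalized") %in% names(nm))) {
      stop("both inputs need columns dose and mean_normalized",
           call. = FALSE)
    }
  }
  m <- merge(test[, c("dose", "mean_normalized")],
             control[, c("dose", "mean_normalized")],
             by = "dose", suffixes = c("_test", "_control"))
  if (any(m$mean_normalized_control <= 0)) {
    stop("control mean must be > 0 at every dose", call. = FALSE)
  }
  data.frame(dose = m$dose,
             test_mean = m$mean_normalized_test,
             control_mean = m$mean_normalized_control,
             ratio = m$mean_normalized_test / m$mean_normalized_control,
             stringsAsFactors = FALSE)
}
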