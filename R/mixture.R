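# Additive modelling of isoform mixtures: a cell co-expressing several
# TRPA1 isoforms responds as the weighted sum of the per-isoform
# dose-response curves, with weights given by the mRNA composition.

#' Define an isoform mixture
#'
#' @param isoforms component isoform ids.
#' @param weights simplex weights (non-negative, summing to 1 within
#'   1e-6; renormalized to machine precision).
#' @param provenance where the weights came from: a measured
#'   composition, an integer-ratio approximation of one, or manual.
#' @return an object of class `mixture_spec`.
#' @examples
#' mixture_spec(c("CL", "DL"), c(7, 6) / 13)
#' @export
mixture_spec <- function(isoforms, weights,
                         provenance = c("manual", "measured",
                                        "integer_ratio")) {
  provenance <- match.arg(provenance)
  if (length(isoforms) != length(weights) || length(weights) == 0L) {
    stop("`isoforms` and `weights` must be non-empty and equal length",
         call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6) {
    stop("`weights` must be non-negative and sum to 1", call. = FALSE)
  }
  weights <- weights / sum(weights)
  structure(list(isoforms = as.character(isoforms),
                 weights = setNames(as.numeric(weights),
                                    as.character(isoforms)),
                 provenance = provenance),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("Isoform mixture (", x$provenance, "): ",
      paste(sprintf("%s=%.3f", x$isoforms, x$weights), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Derive mixture weights from a measured composition
#'
#' Weights are the estimated proportions, optionally snapped to the
#' closest small-integer ratio (two-component case) as done when
#' designing cRNA co-injection mixtures.
#'
#' @param composition a `composition_estimate` or a named simplex
#'   vector of proportions.
#' @param models optional named list of per-isoform dose-response models;
#'   when given, every component must have one (missing ids raise an
#'   error listing them).
#' @param use_integer_ratio snap two-component weights to the closest
#'   integer ratio before renormalization.
#' @param max_part see [integer_ratio()].
#' @return a `mixture_spec`.
#' @export
mixture_from_composition <- function(composition, models = NULL,
                                     use_integer_ratio = FALSE,
                                     max_part = 9L) {
  props <- if (inherits(composition, "composition_estimate")) {
    composition$proportions
  } else {
    composition
  }
  if (is.null(names(props))) {
    stop("composition proportions must be named by isoform", call. = FALSE)
  }
  if (!is.null(models)) {
    missing <- setdiff(names(props), names(models))
    if (length(missing) > 0L) {
      stop("no fitted model for isoform(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  provenance <- "measured"
  if (use_integer_ratio) {
    if (length(props) != 2L) {
      stop("integer-ratio snapping is defined for two components",
           call. = FALSE)
    }
    ab <- integer_ratio(as.numeric(props) / sum(props), max_part = max_part)
    props <- setNames(c(ab[["a"]], ab[["b"]]) / sum(ab), names(props))
    provenance <- "integer_ratio"
  }
  mixture_spec(names(props), as.numeric(props) / sum(props),
               provenance = provenance)
}

component_curve <- function(model, doses) {
  if (inherits(model, "dose_response_fit")) {
    predict(model, doses)
  } else if (is.character(model) && identical(model, "inactive")) {
    numeric(length(doses))
  } else if (is.list(model) && all(c("d", "e", "h") %in% names(model))) {
    hill_response(doses, model$d, model$e, model$h)
  } else {
    stop("each model must be a dose_response_fit, a list(d, e, h), or ",
         "the string \"inactive\"", call. = FALSE)
  }
}

#' Predict the response of an isoform mixture
#'
#' Additive model: the predicted normalized response at dose `c` is
#' `sum_i w_i f_i(c)`, a convex combination of the component curves, so
#' it always lies between the component extremes. Inactive isoforms
#' contribute their own fitted small-response curve, or exactly zero
#' when flagged `"inactive"`.
#'
#' @param spec a `mixture_spec`.
#' @param models named list of per-isoform models (`dose_response_fit`,
#'   `list(d, e, h)`, or `"inactive"`), covering every component.
#' @param doses positive concentrations (mM).
#' @return a `mixture_prediction`: `doses`, `predicted`, and the
#'   per-component `contributions` matrix (`w_i f_i(c)`).
#' @export
predict_mixture_response <- function(spec, models, doses) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  missing <- setdiff(spec$isoforms, names(models))
  if (length(missing) > 0L) {
    stop("no model for isoform(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  contrib <- sapply(spec$isoforms, function(id) {
    spec$weights[[id]] * component_curve(models[[id]], doses)
  })
  contrib <- matrix(contrib, nrow = length(doses),
                    dimnames = list(NULL, spec$isoforms))
  structure(list(doses = doses, predicted = rowSums(contrib),
                 contributions = contrib, spec = spec),
            class = "mixture_prediction")
}

#' @export
print.mixture_prediction <- function(x, ...) {
  df <- data.frame(dose = x$doses, predicted = round(x$predicted, 4))
  cat("Additive mixture prediction\n")
  print(df, row.names = FALSE)
  invisible(x)
}

project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  tau <- (1 - css[rho]) / rho
  pmax(v + tau, 0)
}

#' Recover mixture weights from mixture recordings
#'
#' Solves the simplex-constrained least-squares problem
#' `min_w ||F w - y||^2` where `F[i, j] = f_j(dose_i)` evaluates each
#' component curve at the recorded doses, by projected gradient descent
#' with multi-start (each vertex plus the barycenter). Emits an
#' identifiability warning when component curves are near-collinear
#' over the recorded dose grid.
#'
#' @param recordings data.frame with columns `dose` and `normalized`;
#'   at least as many distinct doses as components.
#' @param models named list of component models (see
#'   [predict_mixture_response()]).
#' @return list with `weights` (simplex, named), `rss`, and
#'   `diagnostics` (`identifiable`, `condition`).
#' @export
recover_weights <- function(recordings, models) {
  if (!all(c("dose", "normalized") %in% names(recordings))) {
    stop("`recordings` needs columns dose and normalized", call. = FALSE)
  }
  K <- length(models)
  if (K < 1L || is.null(names(models))) {
    stop("`models` must be a non-empty named list", call. = FALSE)
  }
  doses <- recordings$dose
  y <- recordings$normalized
  if (length(unique(doses)) < K) {
    stop("under-determined design: need at least as many distinct doses ",
         "as mixture components", call. = FALSE)
  }
  Fm <- sapply(names(models), function(id) {
    component_curve(models[[id]], doses)
  })
  Fm <- matrix(Fm, nrow = length(doses), dimnames = list(NULL, names(models)))

  sv <- svd(Fm)$d
  condition <- if (min(sv) <= 0) Inf else max(sv) / min(sv)
  identifiable <- is.finite(condition) && condition < 1e6
  if (!identifiable) {
    warning("component curves are near-collinear over the dose grid: ",
            "weights are poorly identifiable", call. = FALSE)
  }

  step <- 1 / (2 * max(sv)^2 + 1e-12)
  starts <- c(lapply(seq_len(K), function(j) {
    w <- rep(0, K); w[j] <- 1; w
  }), list(rep(1 / K, K)))
  best <- NULL
  for (w in starts) {
    ss_old <- Inf
    for (it in seq_len(20000L)) {
      resid <- Fm %*% w - y
      g <- 2 * crossprod(Fm, resid)
      w <- project_simplex(as.numeric(w - step * g))
      ss <- sum((Fm %*% w - y)^2)
      if (ss_old - ss < 1e-10 * (1 + ss)) break
      ss_old <- ss
    }
    ss <- sum((Fm %*% w - y)^2)
    if (is.null(best) || ss < best$rss) {
      best <- list(weights = w, rss = ss)
    }
  }
  # polish on the active support: equality-constrained least squares via
  # the KKT system, kept only when it stays feasible and improves the fit
  supp <- which(best$weights > 1e-9)
  if (length(supp) >= 1L) {
    Fs <- Fm[, supp, drop = FALSE]
    ks <- length(supp)
    kkt <- tryCatch({
      A <- rbind(cbind(2 * crossprod(Fs), rep(1, ks)),
                 c(rep(1, ks), 0))
      sol <- solve(A, c(2 * crossprod(Fs, y), 1))
      sol[seq_len(ks)]
    }, error = function(e) NULL)
    if (!is.null(kkt) && all(kkt >= -1e-12)) {
      w2 <- rep(0, K)
      w2[supp] <- pmax(kkt, 0)
      w2 <- w2 / sum(w2)
      ss2 <- sum((Fm %*% w2 - y)^2)
      if (ss2 <= best$rss) best <- list(weights = w2, rss = ss2)
    }
  }
  list(weights = setNames(best$weights, names(models)),
       rss = best$rss,
       diagnostics = list(identifiable = identifiable,
                          condition = condition))
}

#' Compare mixture responses between two groups at one dose
#'
#' A variance-ratio F test at alpha = 0.05 selects the pooled (Student)
#' or unpooled (Welch) two-sided t-test; the method actually used is
#' recorded in the result.
#'
#' @param x,y normalized responses of the two groups (`n >= 3` each).
#' @param paired unused placeholder for interface symmetry (only
#'   unpaired designs arise here); must be FALSE.
#' @return a `phys_test` with the t statistic and method label.
#' @export
compare_mixture_groups <- function(x, y, paired = FALSE) {
  if (isTRUE(paired)) stop("only unpaired comparisons are supported",
                           call. = FALSE)
  if (length(x) < 3L || length(y) < 3L) {
    stop("n >= 3 per group required", call. = FALSE)
  }
  if (var(x) == 0 && var(y) == 0) {
    stop("zero variance in both groups: t-test undefined", call. = FALSE)
  }
  vt_p <- tryCatch(var.test(x, y)$p.value, error = function(e) 1)
  welch <- is.finite(vt_p) && vt_p < 0.05
  tt <- t.test(x, y, var.equal = !welch)
  phys_test(unname(tt$statistic), tt$p.value,
            method = if (welch) "Welch t-test" else "Student t-test",
            n = c(length(x), length(y)),
            notes = sprintf("variance-ratio F p = %.3g", vt_p))
}
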