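# shared internal helpers

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  code
}

# Multiplicative log-normal noise factors with mean exactly 1 and the
# requested coefficient of variation.
lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

stop_if_not_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

stop_if_not_fraction <- function(x, name) {
  stop_if_not_number(x, name)
  if (x < 0 || x > 1) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

check_dna <- function(x, name = "sequence") {
  if (!is.character(x) || length(x) != 1L || !nzchar(x)) {
    stop(sprintf("`%s` must be a non-empty character scalar", name),
         call. = FALSE)
  }
  if (grepl("[^ACGTN]", x)) {
    stop(sprintf("`%s` contains characters outside ACGTN", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Saturating log-logistic (Hill) dose-response function
#'
#' `hill_response()` evaluates `f(c) = d / (1 + (e/c)^h)` with the
#' convention `f(0) = 0` (the limit for `h > 0`). This is the
#' three-parameter log-logistic curve with lower asymptote fixed at zero:
#' `d` is the maximum response, `e` the EC50 (the curve passes exactly
#' through `d/2` at `c = e`), and `h > 0` the slope.
#'
#' @param dose concentrations (mM), `>= 0`.
#' @param d maximum response (upper asymptote), `> 0`.
#' @param e half-maximal effective concentration (mM), `> 0`.
#' @param h Hill slope, `> 0`.
#' @return numeric vector of responses.
#' @examples
#' hill_response(c(0, 0.1, 1), d = 2, e = 0.1, h = 1)
#' @export
hill_response <- function(dose, d, e, h) {
  stop_if_not_number(d, "d", positive = TRUE)
  stop_if_not_number(e, "e", positive = TRUE)
  stop_if_not_number(h, "h", positive = TRUE)
  out <- numeric(length(dose))
  pos <- dose > 0
  out[pos] <- d / (1 + (e / dose[pos])^h)
  out
}
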