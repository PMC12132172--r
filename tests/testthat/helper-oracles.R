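# Independent oracles and small fixture builders used across the suite.

# Full (unbanded) semi-global edit distance: query aligned end-to-end,
# reference end gaps free. Row-wise dynamic program; the horizontal
# dependency is resolved with the cummin trick so each row is vectorized.
dp_semiglobal_dist <- function(query, ref) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(ref, "")[[1]]
  m <- length(q); n <- length(s)
  prev <- rep(0L, n + 1L)            # D[0, j] = 0 (free start in ref)
  for (i in seq_len(m)) {
    sub <- prev[1:n] + (q[i] != s)   # diagonal + substitution cost
    up <- prev[2:(n + 1)] + 1L       # gap in reference consumption
    cand <- pmin(sub, up)
    # left moves: D[i, j] = min(cand[j], min_{k<j}(D[i,k]) + (j-k))
    run <- cummin(c(i, cand) - 0:n) + 0:n
    prev <- c(i, pmin(cand, run[1:n] + 1L))
  }
  min(prev)
}

# Exhaustive integer-ratio search over ALL pairs (including non-coprime,
# reduced afterwards) — an independent route to the same optimum.
brute_integer_ratio <- function(p1, max_part = 9L) {
  grid <- expand.grid(a = seq_len(max_part), b = seq_len(max_part))
  red <- t(apply(grid, 1, function(ab) {
    g <- ab[1]; h <- ab[2]
    while (h != 0) { t <- h; h <- g %% h; g <- t }
    c(ab[1] / g, ab[2] / g)
  }))
  red <- unique(red[red[, 1] <= max_part & red[, 2] <= max_part, ,
                    drop = FALSE])
  err <- abs(p1 - red[, 1] / (red[, 1] + red[, 2]))
  ord <- order(err, red[, 1] + red[, 2], red[, 1])
  red[ord[1], ]
}

# Reference parameters used as simulation truth (slope fixed at 1).
ref_params <- function(isoform) {
  tab <- trpa1_reference_params()
  row <- tab[tab$isoform == isoform, ]
  list(d = row$max_norm, e = row$ec50, h = 1)
}

# Direct sums-of-squares one-way ANOVA F statistic.
direct_anova_F <- function(groups) {
  values <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  grand <- mean(values)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  k <- length(groups); N <- length(values)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# Grid-search oracle for the three-parameter log-logistic fit: (e, h) on
# 1%-spaced log grids, optimal d in closed form for each node (the model
# is linear in d given (e, h)).
grid_fit_oracle <- function(dose, y, e_range = c(5e-4, 6),
                            h_range = c(0.2, 5)) {
  stepf <- 1.01
  e_grid <- exp(seq(log(e_range[1]), log(e_range[2]), by = log(stepf)))
  h_grid <- exp(seq(log(h_range[1]), log(h_range[2]), by = log(stepf)))
  best <- list(ss = Inf)
  yy <- sum(y^2)
  for (h in h_grid) {
    G <- 1 / (1 + outer(e_grid, dose, function(e, c) (e / c)^h))
    num <- as.numeric(G %*% y)
    den <- rowSums(G * G)
    ss <- yy - num^2 / den  # profile SS over d (linear parameter)
    i <- which.min(ss)
    if (ss[i] < best$ss) {
      best <- list(ss = ss[i], d = num[i] / den[i], e = e_grid[i], h = h)
    }
  }
  best$step <- log(stepf)
  best
}

rand_simplex2 <- function(n, min_comp = 0.02) {
  p1 <- runif(n, min_comp, 1 - min_comp)
  cbind(p1, 1 - p1)
}
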