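# Additive isoform-mixture predictions and weight recovery.

test_that("mixture specs validate simplex weights and map compositions", {
  sp <- mixture_spec(c("CL", "DL"), c(0.5, 0.5))
  expect_equal(sum(sp$weights), 1, tolerance = 1e-12)
  expect_error(mixture_spec(c("a", "b"), c(0.7, 0.6)), "sum to 1")
  expect_error(mixture_spec(c("a", "b"), c(1.2, -0.2)), "non-negative")
  est <- structure(list(proportions = c(CL = 0.714, DL = 0.286)),
                   class = "composition_estimate")
  m <- mixture_from_composition(est)
  expect_equal(unname(m$weights), c(0.714, 0.286), tolerance = 1e-9)
  snap <- mixture_from_composition(est, use_integer_ratio = TRUE)
  expect_equal(unname(snap$weights), c(5, 2) / 7, tolerance = 1e-12)
  expect_identical(snap$provenance, "integer_ratio")
  models <- list(CL = list(d = 1, e = 0.1, h = 1))
  expect_error(mixture_from_composition(est, models = models), "DL")
})

test_that("predictions are the weighted sum of component curves", {
  mA <- list(d = 2, e = 0.1, h = 1)
  mB <- list(d = 4, e = 1, h = 1)
  models <- list(A = mA, B = mB)
  doses <- c(0.01, 0.1, 1, 3)
  # w = (1, 0): component A exactly
  p1 <- predict_mixture_response(mixture_spec(c("A", "B"), c(1, 0)),
                                 models, doses)
  expect_equal(p1$predicted, hill_response(doses, 2, 0.1, 1),
               tolerance = 1e-12)
  # half/half average
  p2 <- predict_mixture_response(mixture_spec(c("A", "B"), c(0.5, 0.5)),
                                 models, doses)
  expect_equal(p2$predicted,
               0.5 * hill_response(doses, 2, 0.1, 1) +
                 0.5 * hill_response(doses, 4, 1, 1), tolerance = 1e-12)
  # inactive component contributes exactly zero when flagged
  p3 <- predict_mixture_response(
    mixture_spec(c("A", "B"), c(0.5, 0.5)),
    list(A = mA, B = "inactive"), doses)
  expect_equal(p3$predicted, 0.5 * hill_response(doses, 2, 0.1, 1),
               tolerance = 1e-12)
  expect_error(predict_mixture_response(
    mixture_spec(c("A", "C"), c(0.5, 0.5)), models, doses), "C")
})

test_that("a 1:1 canonical+inactive mixture falls between the pure
           responses", {
  canonical <- ref_params("SfTRPA1-CL")
  inactive <- list(d = 0.15, e = 0.5, h = 1) # weakly responsive isoform
  models <- list(CL = canonical, CS = inactive)
  doses <- exp(seq(log(0.001), log(3), length.out = 30))
  mix <- predict_mixture_response(
    mixture_spec(c("CL", "CS"), c(0.5, 0.5)), models, doses)
  lo <- pmin(hill_response(doses, canonical$d, canonical$e, canonical$h),
             hill_response(doses, inactive$d, inactive$e, inactive$h))
  hi <- pmax(hill_response(doses, canonical$d, canonical$e, canonical$h),
             hill_response(doses, inactive$d, inactive$e, inactive$h))
  expect_true(all(mix$predicted > lo & mix$predicted < hi))
})

test_that("mixture predictions are convex combinations for random
           specs", {
  set.seed(31)
  doses <- exp(seq(log(0.001), log(3), length.out = 40))
  for (i in 1:200) {
    k <- sample(2:4, 1)
    w <- as.numeric(rmultinom(1, 100, rep(1, k))) / 100
    models <- lapply(seq_len(k), function(j) {
      list(d = runif(1, 0.1, 5), e = exp(runif(1, log(0.005), log(1))),
           h = runif(1, 0.5, 3))
    })
    names(models) <- paste0("m", seq_len(k))
    sp <- mixture_spec(names(models), w)
    pred <- predict_mixture_response(sp, models, doses)
    comp <- sapply(models, function(m) {
      hill_response(doses, m$d, m$e, m$h)
    })
    expect_true(all(pred$predicted >= apply(comp, 1, min) - 1e-12))
    expect_true(all(pred$predicted <= apply(comp, 1, max) + 1e-12))
  }
})

test_that("shifting weight to the more sensitive component never lowers
           the prediction", {
  sens <- list(d = 3, e = 0.03, h = 1)   # lower EC50, also higher max
  dull <- list(d = 3, e = 0.5, h = 1)
  models <- list(s = sens, u = dull)
  doses <- exp(seq(log(0.001), log(3), length.out = 50))
  prev <- rep(-Inf, length(doses))
  for (ws in seq(0, 1, by = 0.1)) {
    p <- predict_mixture_response(
      mixture_spec(c("s", "u"), c(ws, 1 - ws)), models, doses)
    expect_true(all(p$predicted >= prev - 1e-12))
    prev <- p$predicted
  }
})

test_that("species-mimicking mixtures reproduce the labellar contrast at
           low dose", {
  # labellar mixtures built from reported parameters and printed ratios:
  # S. pallida CL:DL = 5:2, S. flava CL:DL = 7:6
  sp_models <- list(CL = ref_params("SpTRPA1-CL"),
                    DL = ref_params("SpTRPA1-DL"))
  sf_models <- list(CL = ref_params("SfTRPA1-CL"),
                    DL = ref_params("SfTRPA1-DL"))
  ratios <- tissue_isoform_ratios()
  sp_lab <- ratios[ratios$species == "S. pallida" &
                     ratios$tissue == "labella", ]
  sf_lab <- ratios[ratios$species == "S. flava" &
                     ratios$tissue == "labella", ]
  p_sp <- predict_mixture_response(
    mixture_spec(c("CL", "DL"), c(sp_lab$cl, sp_lab$dl) /
                   (sp_lab$cl + sp_lab$dl)), sp_models, 0.01)
  p_sf <- predict_mixture_response(
    mixture_spec(c("CL", "DL"), c(sf_lab$cl, sf_lab$dl) /
                   (sf_lab$cl + sf_lab$dl)), sf_models, 0.01)
  expect_gt(p_sp$predicted, p_sf$predicted)
})

test_that("weights are recovered from mixture recordings", {
  mA <- list(d = 2, e = 0.03, h = 1)
  mB <- list(d = 4, e = 0.5, h = 1)
  models <- list(A = mA, B = mB)
  doses <- rep(c(0.001, 0.01, 0.03, 0.1, 0.3, 1, 3), each = 4)
  w <- c(0.7, 0.3)
  y <- 0.7 * hill_response(doses, 2, 0.03, 1) +
    0.3 * hill_response(doses, 4, 0.5, 1)
  rec <- data.frame(dose = doses, normalized = y)
  out <- recover_weights(rec, models)
  expect_equal(unname(out$weights), w, tolerance = 1e-6)
  expect_lt(out$rss, 1e-12)
  # noisy Monte-Carlo: mean absolute error < 0.1 at 20% CV
  set.seed(32)
  errs <- replicate(60, {
    yn <- y * exp(rnorm(length(y), -0.5 * log(1.04), sqrt(log(1.04))))
    got <- recover_weights(data.frame(dose = doses, normalized = yn),
                           models)$weights
    mean(abs(got - w))
  })
  expect_lt(mean(errs), 0.1)
  # identical component curves are flagged as unidentifiable
  expect_warning(
    recover_weights(rec, list(A = mA, B = mA)), "collinear")
  expect_error(recover_weights(data.frame(dose = rep(0.1, 5),
                                          normalized = rep(1, 5)), models),
               "under-determined")
})

test_that("the two-group comparison picks Student vs Welch by the
           variance-ratio test", {
  set.seed(33)
  x <- rnorm(10)
  res <- compare_mixture_groups(x, x + 1e-9 * rnorm(10))
  expect_match(res$method, "Student")
  expect_gt(res$p_raw, 0.9)
  y <- rnorm(30, sd = sqrt(10))
  res2 <- compare_mixture_groups(rnorm(30), y)
  expect_match(res2$method, "Welch")
  expect_error(compare_mixture_groups(rep(1, 5), rep(2, 5)), "variance")
  expect_error(compare_mixture_groups(1:2, 1:5), "n >= 3")
})

test_that("the two-group comparison keeps its nominal size under the
           null", {
  set.seed(34)
  rej <- mean(replicate(2000, {
    compare_mixture_groups(rnorm(8), rnorm(8))$p_raw < 0.05
  }))
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rej - 0.05), 3 * se)
})
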