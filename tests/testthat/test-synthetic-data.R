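# Synthetic-data generators: determinism, stimulus protocol, noise and
# sampling contracts.

test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(noise_cv = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(per_base_error = 0.35), "< 0.3")
  expect_error(sim_config(dose_series = c(0.1, 0.1)), "increasing")
  expect_error(sim_config(dose_series = c(-1, 1)), "increasing|positive")
  expect_error(sim_config(junk_fraction = -0.1), "\\[0, 1\\]")
})

test_that("identical configs give byte-identical generator output", {
  cfg <- sim_config(seed = 42, read_count = 20, junk_fraction = 0.2,
                    n_flies_per_group = 5)
  p <- list(d = 2, e = 0.1, h = 1)
  expect_identical(serialize(gen_tevc_trace(p, 0.1, 2, cfg), NULL),
                   serialize(gen_tevc_trace(p, 0.1, 2, cfg), NULL))
  expect_identical(serialize(gen_recording_set(list(a = p), cfg), NULL),
                   serialize(gen_recording_set(list(a = p), cfg), NULL))
  refs <- gen_isoform_references(cfg)
  expect_identical(refs, gen_isoform_references(cfg))
  expect_identical(
    serialize(gen_amplicon_reads(refs[1:2], c(0.5, 0.5), cfg), NULL),
    serialize(gen_amplicon_reads(refs[1:2], c(0.5, 0.5), cfg), NULL))
  gp <- list(g = list(baseline = 0.5, aversion = function(d) 1 / (1 + d)))
  expect_identical(serialize(gen_per_dataset(gp, cfg), NULL),
                   serialize(gen_per_dataset(gp, cfg), NULL))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(7)
  a <- runif(1)
  set.seed(7)
  invisible(gen_recording_set(list(d = 1, e = 0.1, h = 1),
                              sim_config(seed = 1)))
  expect_identical(runif(1), a)
})

test_that("TEVC traces encode the stimulus protocol and amplitudes", {
  cfg <- sim_config(seed = 1, noise_cv = 0, trace_noise_sd = 0)
  p <- list(d = 2, e = 0.1, h = 1)
  tr <- gen_tevc_trace(p, dose = 0.1, expression_scale = 2, cfg)
  # window ordering and coverage
  w <- tr$windows
  expect_true(w$baseline[2] <= w$heat[1] && w$heat[2] <= w$wash[1] &&
                w$wash[2] <= w$aitc[1])
  expect_gte(diff(w$heat), 30 - 1e-9)
  expect_gte(diff(w$wash), 120 - 1e-9)
  expect_gte(diff(w$aitc), 90 - 1e-9)
  expect_gt(max(tr$temperature), 40)
  # heat amplitude proportional to expression scale; noiseless round-trip
  expect_equal(extract_heat_amplitude(tr), 2, tolerance = 1e-6)
  # half-maximal at EC50 by construction: plateau = scale * d/2 = 2
  aitc <- extract_aitc_amplitude(tr)
  expect_equal(aitc$amplitude, 2, tolerance = 1e-2)
  expect_false(aitc$saturated)
  # covalent activation: current does not return to baseline at record end
  base <- mean(tr$current[tr$time < w$baseline[2]])
  expect_gt(abs(tr$current[length(tr$current)] - base), 0.5 * aitc$amplitude)
  # inward currents are negative-going
  expect_lt(tr$current[length(tr$current)], base)
  expect_error(gen_tevc_trace(p, 0.1, expression_scale = 0, cfg),
               "positive")
})

test_that("doubling the expression scale leaves the normalized response
           distribution unchanged", {
  p <- list(d = 2, e = 0.1, h = 1)
  cfg1 <- sim_config(seed = 11, n_oocytes_per_dose = 150,
                     dose_series = 0.1, expression_median = 1)
  cfg2 <- sim_config(seed = 12, n_oocytes_per_dose = 150,
                     dose_series = 0.1, expression_median = 7)
  r1 <- gen_recording_set(list(a = p), cfg1)$normalized
  r2 <- gen_recording_set(list(a = p), cfg2)$normalized
  ks <- suppressWarnings(stats::ks.test(r1, r2))
  expect_gt(ks$p.value, 0.01)
  # per-trace Monte-Carlo version of the same contract
  rat <- vapply(1:400, function(i) {
    tr <- gen_tevc_trace(p, 0.1, if (i %% 2) 1 else 2,
                         sim_config(seed = 1000 + i))
    extract_aitc_amplitude(tr)$amplitude / extract_heat_amplitude(tr)
  }, numeric(1))
  m1 <- rat[seq(1, 400, 2)]; m2 <- rat[seq(2, 400, 2)]
  se <- sqrt(var(m1) / length(m1) + var(m2) / length(m2))
  expect_lt(abs(mean(m1) - mean(m2)), 2 * se + 1e-12)
})

test_that("recording sets have the designed shape and raw-current
           correlation", {
  p <- list(d = 3, e = 0.1, h = 1)
  cfg <- sim_config(seed = 5, n_oocytes_per_dose = 8)
  rec <- gen_recording_set(list(a = p, b = p), cfg)
  expect_equal(nrow(rec), 2 * 7 * 8)
  # positive correlation between raw currents at a fixed dose
  cfg2 <- sim_config(seed = 6, n_oocytes_per_dose = 200, dose_series = 0.3)
  rec2 <- gen_recording_set(list(a = p), cfg2)
  res <- raw_current_correlation(rec2)
  expect_gt(res$statistic, 0)
  expect_lt(res$p_raw, 0.01)
  # zero noise makes all normalized responses at one dose identical
  cfg0 <- sim_config(seed = 7, noise_cv = 0)
  rec0 <- gen_recording_set(list(a = p), cfg0)
  spread <- tapply(rec0$normalized, rec0$dose, function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
})

test_that("toy references share a backbone but differ at two distant
           blocks", {
  cfg <- sim_config(seed = 8)
  refs <- gen_isoform_references(cfg)
  expect_named(refs, c("CL", "CS", "DL", "DS", "EL"))
  expect_true(all(nchar(refs) >= 3800 & nchar(refs) <= 4500))
  pairs <- combn(names(refs), 2)
  for (j in seq_len(ncol(pairs))) {
    id <- percent_identity(refs[[pairs[1, j]]], refs[[pairs[2, j]]])
    expect_gt(id, 0.9)
    expect_lt(id, 1)
  }
  # CL and CS differ only at the 5' block: their distal halves align
  tail_cl <- substr(refs[["CL"]], nchar(refs[["CL"]]) - 1999,
                    nchar(refs[["CL"]]))
  tail_cs <- substr(refs[["CS"]], nchar(refs[["CS"]]) - 1999,
                    nchar(refs[["CS"]]))
  expect_identical(tail_cl, tail_cs)
  expect_error(gen_isoform_references(cfg, isoforms = "CL"), "at least 2")
})

test_that("amplicon reads follow the composition, error and junk
           contracts", {
  cfg0 <- sim_config(seed = 9, read_count = 20, per_base_error = 0,
                     length_jitter_sd = 0, junk_fraction = 0)
  refs <- gen_isoform_references(cfg0, c("CL", "DL"))
  rd <- gen_amplicon_reads(refs, c(1, 0), cfg0)
  fwd <- ifelse(rd$truth$strand == "-",
                vapply(rd$reads, function(s) {
                  as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(s)))
                }, character(1)),
                rd$reads)
  expect_true(all(fwd == refs[["CL"]]))
  # multinomial sampling: empirical fraction near 0.5 at n = 10000
  cfgm <- sim_config(seed = 10, read_count = 10000)
  rdm <- gen_amplicon_reads(refs, c(0.5, 0.5), cfgm)
  frac <- mean(rdm$truth$isoform == "CL")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(gen_amplicon_reads(refs, c(0.7, 0.4), cfg0), "sum to 1")
})

test_that("junk reads are rejected by the downstream filters", {
  cfg <- sim_config(seed = 13, read_count = 300, per_base_error = 0.05,
                    junk_fraction = 0.1)
  refs <- gen_isoform_references(cfg, c("CL", "DL"))
  rd <- gen_amplicon_reads(refs, c(0.5, 0.5), cfg)
  asn <- filter_reads(classify_reads(rd$reads, refs))
  fail_frac <- mean(asn$status != "passed")
  n_junk <- sum(rd$truth$is_junk)
  expect_equal(sum(asn$status != "passed"), n_junk)
  expect_lt(abs(fail_frac - 0.1), 3 * sqrt(0.1 * 0.9 / 300) + 1e-9)
  # junk splits across both filter branches
  expect_true(any(asn$status == "failed_length"))
  expect_true(any(asn$status == "failed_identity"))
})

test_that("PER generator recovers its aversion curve", {
  # flat curve: normalized means stay at 1
  gp <- list(flat = list(baseline = 0.6, aversion = function(d) 1))
  per <- gen_per_dataset(gp, sim_config(seed = 14, n_flies_per_group = 300))
  df <- normalize_per(score_trial_table(per$trials))
  s <- summarize_aversion(df)
  expect_true(all(abs(s$mean_normalized - 1) < 0.15))
  # full aversion at high dose: all scores zero
  gp2 <- list(avert = list(baseline = 0.8,
                           aversion = function(d) as.numeric(d == 0)))
  per2 <- gen_per_dataset(gp2, sim_config(seed = 15, n_flies_per_group = 20))
  sc <- score_trial_table(per2$trials)
  expect_true(all(sc$score[sc$dose > 0] == 0))
  # Monte-Carlo: large-n normalized means within 2 SE of the truth curve
  curve <- function(d) 1 / (1 + (d / 8)^1.5)
  gp3 <- list(mc = list(baseline = 0.5, aversion = curve))
  per3 <- gen_per_dataset(gp3, sim_config(seed = 16,
                                          n_flies_per_group = 500))
  df3 <- normalize_per(score_trial_table(per3$trials))
  m0 <- mean(df3$score[df3$dose == 0])
  for (dose in c(2, 5, 10)) {
    sel <- df3$dose == dose
    est <- mean(df3$normalized[sel])
    se <- sqrt(var(df3$normalized[sel]) / sum(sel) +
                 est^2 * var(df3$score[df3$dose == 0]) /
                 (sum(df3$dose == 0) * m0^2))
    expect_lt(abs(est - curve(dose)), 2 * se + 0.02)
  }
  expect_error(
    gen_per_dataset(list(bad = list(baseline = 0, aversion = curve)),
                    sim_config(seed = 1)),
    "\\(0, 1\\]")
})

test_that("FASTA/FASTQ/JSON round trips preserve sequences", {
  cfg <- sim_config(seed = 17, read_count = 5)
  refs <- gen_isoform_references(cfg, c("CL", "DL"))
  fa <- tempfile(fileext = ".fasta")
  write_isoform_fasta(refs, fa)
  expect_identical(read_isoform_fasta(fa), refs)
  rd <- gen_amplicon_reads(refs, c(0.5, 0.5), cfg)
  fq <- tempfile(fileext = ".fastq")
  write_reads_fastq(rd$reads, fq, per_base_error = cfg$per_base_error)
  expect_identical(read_reads_fastq(fq), rd$reads)
  js <- tempfile(fileext = ".json")
  write_ground_truth_json(rd$truth, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(back$isoform, rd$truth$isoform)
  tr <- gen_tevc_trace(list(d = 2, e = 0.1, h = 1), 0.1, 2, cfg)
  csv <- tempfile(fileext = ".csv")
  write_trace_csv(tr, csv)
  tr2 <- read_trace_csv(csv)
  expect_equal(tr2$current, tr$current, tolerance = 1e-12)
  expect_equal(tr2$windows$aitc, tr$windows$aitc)
})
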