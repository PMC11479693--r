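test_that("a flat noisy trace yields no spikes", {
  set.seed(42)
  times <- seq(0, 7199, by = 1)
  tr <- calcium_trace(times, 1 + rnorm(length(times), 0, 0.05))
  st <- detect_spikes(tr)
  expect_length(st$times, 0)
  sc <- score_oocyte(tr)
  expect_identical(sc$axf, 0)
  expect_identical(sc$category, "0")
})

test_that("injected impulses are recovered exactly in a noiseless trace", {
  spike_t <- c(600, 1800, 3000, 4200, 5400, 6600)
  tr <- impulse_trace(spike_t, amplitude = 2)
  st <- detect_spikes(tr)
  expect_identical(st$times, spike_t)
  expect_identical(st$amplitudes, rep(2, 6))
})

test_that("the refractory rule merges nearby peaks, keeping the larger", {
  times <- seq(0, 7199, by = 1)
  v <- rep(1, length(times))
  v[times == 1000] <- 3.0
  v[times == 1010] <- 2.5
  st <- detect_spikes(calcium_trace(times, v),
                      detector_params(refractory = 30))
  expect_length(st$times, 1)
  expect_identical(st$times, 1000)
  # wider spacing keeps both
  v[times == 1010] <- 1
  v[times == 1040] <- 2.5
  st2 <- detect_spikes(calcium_trace(times, v), detector_params(refractory = 30))
  expect_length(st2$times, 2)
})

test_that("trace validation rejects non-monotone times", {
  expect_error(calcium_trace(c(0, 1, 1), c(1, 1, 1)), "strictly increasing")
  expect_error(calcium_trace(c(0, 1), c(1, NA)), "finite")
  expect_error(calcium_trace(1, 1), ">= 2")
})

test_that("AxF is mean amplitude times spikes per hour", {
  tr <- impulse_trace(c(600, 1800, 3000, 4200, 5400, 6600), amplitude = 2)
  sc <- score_oocyte(tr)
  expect_identical(sc$n_spikes, 6L)
  expect_identical(sc$A, 2)
  expect_identical(sc$F, 3)
  expect_identical(sc$axf, 6)
  expect_identical(sc$category, "++")

  many <- impulse_trace(seq(100, 7000, by = 300), amplitude = 1)  # 24 spikes
  sc24 <- score_oocyte(many)
  expect_identical(sc24$n_spikes, 24L)
  expect_identical(sc24$F, 12)
  expect_identical(sc24$category, "++++")
})

test_that("frequency categories bin spike counts with closed boundaries", {
  expect_identical(categorize_count(c(0, 1, 2, 3, 9, 10, 20, 21)),
                   c("0", "+", "+", "++", "++", "+++", "+++", "++++"))
  expect_error(categorize_count(-1), "non-negative")
  # total monotone step function on 0..40
  lev <- c("0", "+", "++", "+++", "++++")
  idx <- match(categorize_count(0:40), lev)
  expect_false(anyNA(idx))
  expect_true(all(diff(idx) >= 0))
})

test_that("scoring is invariant to a constant offset", {
  spike_t <- c(900, 2500, 5000)
  tr <- impulse_trace(spike_t, amplitude = 1.5)
  shifted <- calcium_trace(tr$times, tr$values + 10, assay = "MOCA")
  expect_identical(score_oocyte(tr)$axf, score_oocyte(shifted)$axf)
})

test_that("patient summaries average AxF and tabulate categories", {
  expect_identical(patient_summary(list(0, 0, 0))$mean_axf, 0)
  expect_identical(patient_summary(list(6, 12))$mean_axf, 9)
  scores <- lapply(c(0, 600), function(s)
    score_oocyte(impulse_trace(c(600 + s, 3000 + s), amplitude = 2)))
  ps <- patient_summary(scores)
  expect_identical(ps$n, 2L)
  expect_identical(as.integer(ps$category_counts[["+"]]), 2L)
  expect_error(patient_summary(list()), ">= 1")
})

test_that("competence thresholds are strict and assay-specific", {
  expect_identical(competence_flag(85.71, "MOCA"), "normal_range")
  expect_identical(competence_flag(9, "MOCA"), "deficient")
  expect_identical(competence_flag(0.60, "HOCA"), "deficient")
  expect_identical(competence_flag(0.61, "HOCA"), "normal_range")
  expect_identical(competence_flag(0, "HOCA"), "deficient")
  expect_error(competence_flag(1, "MOAT"), "unknown assay")
  # monotone: raising AxF never flips normal -> deficient
  flags <- vapply(seq(0, 20, by = 0.5), competence_flag, character(1),
                  assay = "MOCA")
  expect_true(all(diff(flags == "normal_range") >= 0))
})

test_that("control comparison gates the t-test on Shapiro-Wilk normality", {
  # constant-like patient sample vs spread control: rank test, significant
  res <- suppressWarnings(
    compare_with_control(rep(0, 8), c(3.1, 4.2, 3.8, 4.5, 3.2, 4.8, 3.6, 4.1))
  )
  expect_identical(res$test_used, "mann_whitney")
  expect_true(res$significant)
  expect_warning(
    compare_with_control(rep(0, 8), c(3.1, 4.2, 3.8, 4.5, 3.2, 4.8, 3.6, 4.1)),
    "rank test"
  )
  # normal samples use the t-test
  set.seed(7)
  res_t <- compare_with_control(rnorm(20, 5), rnorm(20, 5))
  expect_identical(res_t$test_used, "t_test")
  # alpha = 1 flags any untied comparison
  expect_true(compare_with_control(c(1, 2, 3), c(4, 5, 6), alpha = 1)$significant)
  expect_error(compare_with_control(c(1, 2), c(1, 2, 3)), ">= 3")
})

test_that("identical distributions are rarely called different under the null", {
  rejections <- vapply(1:100, function(s) {
    set.seed(s)
    compare_with_control(rnorm(20, 10, 2), rnorm(20, 10, 2))$significant
  }, logical(1))
  expect_gte(mean(!rejections), 0.90)
})

test_that("long-format trace files score one row per oocyte", {
  tr1 <- impulse_trace(c(600, 3000), amplitude = 2)
  tr2 <- impulse_trace(c(1200, 2400, 3600, 4800), amplitude = 1)
  tab <- rbind(
    data.frame(time_s = tr1$times, ratio = tr1$values, oocyte_id = "o1",
               assay = "MOCA"),
    data.frame(time_s = tr2$times, ratio = tr2$values, oocyte_id = "o2",
               assay = "MOCA")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  out <- score_trace_file(path)
  expect_identical(out$n_spikes[order(out$oocyte_id)], c(2L, 4L))
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab[, -1], bad, row.names = FALSE)
  expect_error(score_trace_file(bad), "missing column")
})
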