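# Calcium oscillation scoring of sperm-injected oocytes.
#
# A Fura-2 ratio trace is reduced to a spike train (local maxima whose height
# above a rolling-median baseline clears a robust noise threshold, thinned by a
# refractory time), then to the oocyte's A (mean spike amplitude, AU),
# F (spikes per hour) and their product AxF, the total-calcium-released
# statistic. Spike counts over the recording map to the frequency categories
# "0", "+", "++", "+++", "++++"; mean AxF per patient is compared to the
# assay-specific competence thresholds (MOCA > 9, HOCA > 0.6).

#' A per-oocyte calcium ratio trace
#'
#' @param times Sampling times in seconds, strictly increasing, >= 2 samples.
#' @param values Fura-2 ratio values (arbitrary units), finite.
#' @param oocyte_id Oocyte identifier.
#' @param assay `"MOCA"` (mouse, 2 h recording) or `"HOCA"` (human, 10 h).
#' @return An object of class `"calcium_trace"`.
#' @export
calcium_trace <- function(times, values, oocyte_id = "oocyte", assay = c("MOCA", "HOCA")) {
  assay <- match.arg(assay)
  if (length(times) != length(values) || length(times) < 2L) {
    stop_fertscreen("trace needs >= 2 paired samples")
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop_fertscreen("times must be finite and strictly increasing")
  }
  if (any(!is.finite(values))) stop_fertscreen("values must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 oocyte_id = oocyte_id, assay = assay),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat("Calcium trace ", x$oocyte_id, " (", x$assay, "): ",
      length(x$times), " samples over ",
      sprintf("%.2f h\n", trace_duration_hours(x)), sep = "")
  invisible(x)
}

# nominal recording span: n * dt for a regular grid, so a 2 h recording
# sampled on [0, 7200) scores F against exactly 2 h
trace_duration_hours <- function(trace) {
  dt <- stats::median(diff(trace$times))
  (trace$times[length(trace$times)] - trace$times[1] + dt) / 3600
}

#' Spike-detector settings
#'
#' @param baseline_window Rolling-median span in seconds used as the local
#'   baseline; default 300 s (long against a spike, short against drift).
#' @param noise_k Prominence multiplier on the robust noise SD (MAD-based);
#'   default 4.
#' @param min_amplitude Absolute amplitude floor in AU; default 0.
#' @param refractory Minimum separation between accepted spikes in seconds;
#'   default 30.
#' @return An object of class `"detector_params"`.
#' @export
detector_params <- function(baseline_window = 300, noise_k = 4,
                            min_amplitude = 0, refractory = 30) {
  if (baseline_window <= 0 || noise_k <= 0 || refractory <= 0 || min_amplitude < 0) {
    stop_fertscreen("detector parameters must be positive (min_amplitude >= 0)")
  }
  structure(list(baseline_window = baseline_window, noise_k = noise_k,
                 min_amplitude = min_amplitude, refractory = refractory),
            class = "detector_params")
}

rolling_median_baseline <- function(values, times, window) {
  dt <- stats::median(diff(times))
  k <- max(3L, as.integer(round(window / dt)))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(values) %% 2L == 1L) length(values) else length(values) - 1L)
  as.numeric(stats::runmed(values, k, endrule = "median"))
}

#' Detect calcium spikes in a trace
#'
#' Spikes are strict local maxima of the baseline-subtracted trace whose height
#' exceeds `max(noise_k * robust_noise_sd, min_amplitude)`, where the baseline
#' is a rolling median and the noise SD is the MAD of the residual. Candidate
#' peaks are accepted in order of decreasing amplitude subject to the
#' refractory separation, so the procedure is deterministic for a fixed input.
#' Amplitude is peak minus local baseline; results are invariant to adding a
#' constant offset to the whole trace.
#'
#' @param trace A [calcium_trace()].
#' @param params A [detector_params()].
#' @return An object of class `"spike_train"`: `times`, `amplitudes` (sorted by
#'   time), `threshold`, `noise_sd`, plus the inputs' metadata.
#' @export
detect_spikes <- function(trace, params = detector_params()) {
  if (!inherits(trace, "calcium_trace")) {
    trace <- do.call(calcium_trace, trace)  # allow plain lists
  }
  v <- trace$values
  t <- trace$times
  baseline <- rolling_median_baseline(v, t, params$baseline_window)
  resid <- v - baseline
  noise_sd <- stats::mad(resid)  # MAD scaled to SD under normality
  threshold <- max(params$noise_k * noise_sd, params$min_amplitude)
  n <- length(v)
  is_peak <- c(FALSE, resid[2:(n - 1)] > resid[1:(n - 2)] &
                 resid[2:(n - 1)] > resid[3:n], FALSE)
  cand <- which(is_peak & resid > threshold)
  # refractory thinning, largest amplitude first
  keep <- integer(0)
  for (i in cand[order(-resid[cand], t[cand])]) {
    if (all(abs(t[i] - t[keep]) >= params$refractory)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  structure(list(times = t[keep], amplitudes = resid[keep],
                 threshold = threshold, noise_sd = noise_sd,
                 oocyte_id = trace$oocyte_id, assay = trace$assay,
                 duration_hours = trace_duration_hours(trace)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("Spike train ", x$oocyte_id, " (", x$assay, "): ", length(x$times),
      " spikes over ", sprintf("%.2f h", x$duration_hours),
      sprintf("  [threshold %.3g AU]\n", x$threshold), sep = "")
  invisible(x)
}

#' Frequency category from a spike count
#'
#' Categories over the full recording window: `0` spikes "0", `1-2` "+",
#' `3-9` "++", `10-20` "+++", `>20` "++++".
#'
#' @param n_spikes Non-negative integer(s).
#' @return Character vector of categories.
#' @examples
#' categorize_count(c(0, 2, 9, 20, 21))
#' @export
categorize_count <- function(n_spikes) {
  if (any(!vapply(n_spikes, is_count, logical(1)))) {
    stop_fertscreen("n_spikes must be non-negative integers")
  }
  cut(n_spikes, breaks = c(-0.5, 0.5, 2.5, 9.5, 20.5, Inf),
      labels = c("0", "+", "++", "+++", "++++")) |> as.character()
}

#' Score one oocyte: A, F and AxF
#'
#' `A` is the mean detected spike amplitude (AU), `F` the spike count divided
#' by the recording duration in hours, and `axf = A * F` the total-calcium-
#' released statistic. An oocyte with no spikes scores A = F = AxF = 0,
#' category "0".
#'
#' @param trace A [calcium_trace()].
#' @param params A [detector_params()].
#' @return An object of class `"oocyte_score"`: `n_spikes`, `A`, `F`, `axf`,
#'   `category`, `oocyte_id`, `assay`.
#' @export
score_oocyte <- function(trace, params = detector_params()) {
  st <- detect_spikes(trace, params)
  n <- length(st$times)
  A <- if (n == 0L) 0 else mean(st$amplitudes)
  F <- n / st$duration_hours
  structure(list(n_spikes = n, A = A, F = F, axf = A * F,
                 category = categorize_count(n),
                 oocyte_id = st$oocyte_id, assay = st$assay),
            class = "oocyte_score")
}

#' @export
print.oocyte_score <- function(x, ...) {
  cat(sprintf("Oocyte %s (%s): %d spikes, A = %.3g AU, F = %.3g /h, AxF = %.3g  [%s]\n",
              x$oocyte_id, x$assay, x$n_spikes, x$A, x$F, x$axf, x$category))
  invisible(x)
}

#' Summarize a patient's oocyte scores
#'
#' @param scores List of `"oocyte_score"` objects (or bare AxF numbers).
#' @return List with `n`, `mean_axf` (arithmetic mean over oocytes) and
#'   `category_counts` (histogram over the five frequency categories).
#' @export
patient_summary <- function(scores) {
  if (length(scores) == 0L) stop_fertscreen("patient_summary needs >= 1 score")
  axf <- vapply(scores, function(s)
    if (inherits(s, "oocyte_score")) s$axf else as.numeric(s), numeric(1))
  cats <- vapply(scores, function(s)
    if (inherits(s, "oocyte_score")) s$category else NA_character_, character(1))
  counts <- table(factor(cats, levels = c("0", "+", "++", "+++", "++++")))
  list(n = length(axf), mean_axf = mean(axf), category_counts = counts)
}

#' Fertilization-competence flag from mean AxF
#'
#' Thresholds for the normal-fertilization range are strict: mean AxF must
#' exceed 9 AU for the mouse assay (MOCA) and 0.6 AU for the human assay
#' (HOCA); a value at or below the threshold is scored deficient.
#'
#' @param mean_axf Non-negative mean AxF.
#' @param assay `"MOCA"` or `"HOCA"`.
#' @param thresholds List with `moca_normal` (default 9) and `hoca_normal`
#'   (default 0.6).
#' @return `"normal_range"` or `"deficient"`.
#' @examples
#' competence_flag(85.71, "MOCA")  # normal_range
#' competence_flag(0.60, "HOCA")   # deficient (strict >)
#' @export
competence_flag <- function(mean_axf, assay,
                            thresholds = list(moca_normal = 9, hoca_normal = 0.6)) {
  if (!is.numeric(mean_axf) || mean_axf < 0) stop_fertscreen("mean_axf must be >= 0")
  thr <- switch(assay,
                MOCA = thresholds$moca_normal,
                HOCA = thresholds$hoca_normal,
                stop_fertscreen("unknown assay '", assay, "'"))
  if (mean_axf > thr) "normal_range" else "deficient"
}

#' Compare patient and control AxF distributions
#'
#' Normality of both samples is assessed with the Shapiro-Wilk test at `alpha`;
#' if neither rejects, a two-sided two-sample t-test is used, otherwise the
#' two-sided Mann-Whitney U (Wilcoxon rank-sum) test. Degenerate (constant)
#' samples, on which Shapiro-Wilk is undefined, fall back to the rank test
#' with a warning.
#'
#' @param patient_axf,control_axf Numeric vectors, >= 3 values each.
#' @param alpha Significance level, default 0.05.
#' @return List with `test_used` (`"t_test"` or `"mann_whitney"`), `p_value`
#'   and `significant` (`p < alpha`).
#' @export
compare_with_control <- function(patient_axf, control_axf, alpha = 0.05) {
  if (length(patient_axf) < 3L || length(control_axf) < 3L) {
    stop_fertscreen("both samples need >= 3 values")
  }
  normal_p <- function(x) {
    if (length(unique(x)) < 3L) return(NA_real_)  # shapiro.test undefined
    stats::shapiro.test(x)$p.value
  }
  sw <- c(normal_p(patient_axf), normal_p(control_axf))
  if (anyNA(sw)) {
    warning("near-constant sample: falling back to the rank test")
    use_t <- FALSE
  } else {
    use_t <- all(sw >= alpha)
  }
  if (use_t) {
    ht <- stats::t.test(patient_axf, control_axf)
    test_used <- "t_test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(patient_axf, control_axf, exact = FALSE))
    test_used <- "mann_whitney"
  }
  list(test_used = test_used, p_value = ht$p.value,
       significant = ht$p.value < alpha)
}

#' Read long-format trace CSV and score every oocyte
#'
#' Expects columns `time_s, ratio, oocyte_id, assay` (long format, one file per
#' patient).
#'
#' @param path Path to the CSV file.
#' @param params A [detector_params()].
#' @return A data.frame with columns `oocyte_id, assay, n_spikes, A, F, axf,
#'   category`.
#' @export
score_trace_file <- function(path, params = detector_params()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "ratio", "oocyte_id", "assay")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop_fertscreen("trace CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  rows <- lapply(split(tab, tab$oocyte_id), function(g) {
    g <- g[order(g$time_s), ]
    sc <- score_oocyte(calcium_trace(g$time_s, g$ratio, g$oocyte_id[1],
                                     g$assay[1]), params)
    data.frame(oocyte_id = sc$oocyte_id, assay = sc$assay, n_spikes = sc$n_spikes,
               A = sc$A, F = sc$F, axf = sc$axf, category = sc$category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
plot.calcium_trace <- function(x, params = detector_params(), spikes = TRUE, ...) {
  plot(x$times / 3600, x$values, type = "l", xlab = "time (h)",
       ylab = "Fura-2 ratio (AU)",
       main = paste0(x$oocyte_id, " (", x$assay, ")"), ...)
  if (spikes) {
    st <- detect_spikes(x, params)
    if (length(st$times)) {
      points(st$times / 3600, x$values[match(st$times, x$times)],
             pch = 25, bg = "red")
    }
  }
  invisible(x)
}
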