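# Clinical cycle accounting and sperm-phenotype rates.
#
# Treatment cycles (conventional ICSI vs ICSI with assisted oocyte activation)
# are pooled into numerator/denominator rates -- fertilization (2PN/MII),
# blastocyst (blastocysts/2PN over cycles with blastocyst culture), positive
# hCG per cycle and live birth per cycle -- and compared between arms with an
# exact two-sided Fisher test. Sperm-phenotype calls (acrosome detachment by
# TEM, ACTL7A immunofluorescence expression classes) feed the same rate/test
# machinery.

.outcome_tokens <- c("LB", "M", "BP", "Ong", "ND", "none")
.cycle_columns <- c("patient_id", "arm", "n_cycles", "mii", "two_pn", "blastocysts",
                    "embryos_transferred", "transfer_day", "hcg_positive", "outcomes")

#' Read and validate a cycle table
#'
#' CSV columns: `patient_id, arm (ICSI/ICSI_AOA), n_cycles, mii, two_pn,
#' blastocysts` (empty = no blastocyst culture), `embryos_transferred,
#' transfer_day, hcg_positive, outcomes` (semicolon-joined tokens over
#' LB, M, BP, Ong, ND, none). A row may pool several cycles of one patient and
#' arm (`n_cycles`); counts are additive so pooled rows aggregate identically.
#'
#' @param path Path to the CSV file.
#' @return Validated data.frame of cycle records.
#' @export
read_cycle_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"n_cycles" %in% names(tab)) tab$n_cycles <- 1L
  missing <- setdiff(.cycle_columns, names(tab))
  if (length(missing)) {
    stop_fertscreen("cycle table missing column(s): ", paste(missing, collapse = ", "))
  }
  diag <- validate_cycles(tab)
  if (length(diag)) {
    stop_fertscreen("invalid cycle table:\n  ", paste(diag, collapse = "\n  "),
                    class = "fertscreen_validation_error")
  }
  tab
}

# row-level diagnostics shared by read_cycle_table() and validate_inputs()
validate_cycles <- function(tab) {
  problems <- character(0)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    line <- i + 1L
    if (!row$arm %in% c("ICSI", "ICSI_AOA")) {
      problems <- c(problems, paste0("line ", line, ": arm '", row$arm, "'"))
    }
    if (!is.na(row$two_pn) && !is.na(row$mii) && row$two_pn > row$mii) {
      problems <- c(problems, paste0("line ", line, ": two_pn > mii (",
                                     row$two_pn, " > ", row$mii, ")"))
    }
    if (!is.na(row$blastocysts) && row$blastocysts > row$two_pn) {
      problems <- c(problems, paste0("line ", line, ": blastocysts > two_pn"))
    }
    toks <- parse_outcomes(row$outcomes)
    bad <- setdiff(toks, .outcome_tokens)
    if (length(bad)) {
      problems <- c(problems, paste0("line ", line, ": unknown outcome token '",
                                     paste(bad, collapse = "','"), "'"))
    }
    clinical <- sum(toks != "none")
    if (!is.na(row$hcg_positive) && row$hcg_positive < clinical) {
      problems <- c(problems, paste0("line ", line,
                                     ": more clinical outcomes than positive hCG"))
    }
  }
  problems
}

parse_outcomes <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Study-inclusion rule for one patient
#'
#' A patient is eligible when at least one conventional ICSI cycle (or pooled
#' cycle row) had at least four MII oocytes injected and a fertilization rate
#' of at most 33.33% (evaluated exactly as `3 * two_pn <= mii`, avoiding
#' decimal-rounding artifacts).
#'
#' @param cycles Cycle data.frame rows for one patient.
#' @return `TRUE`/`FALSE`.
#' @export
eligibility <- function(cycles) {
  icsi <- cycles[cycles$arm == "ICSI", , drop = FALSE]
  if (nrow(icsi) == 0L) return(FALSE)
  any(icsi$mii >= 4L & 3L * icsi$two_pn <= icsi$mii)
}

#' Mouse oocyte activation test (MOAT) group
#'
#' Activation rate = 2-cell embryos / MII oocytes injected. Group 1: rate
#' <= 20%; group 3: rate >= 85%; group 2 otherwise (the published band is
#' 21-84%, with >85% for group 3; rates falling in the printed gap are
#' assigned group 2).
#'
#' @param two_cell,mii Counts; `mii >= 1`, `two_cell <= mii`.
#' @return List of class `"moat_result"`: `two_cell`, `mii`,
#'   `activation_rate`, `group`.
#' @examples
#' moat_group(5, 26)    # group 1 (19.23%)
#' moat_group(17, 19)   # group 3 (89.47%)
#' @export
moat_group <- function(two_cell, mii) {
  if (!is_count(two_cell) || !is_count(mii) || mii < 1) {
    stop_fertscreen("moat_group needs counts with mii >= 1")
  }
  if (two_cell > mii) stop_fertscreen("two_cell exceeds mii")
  rate <- two_cell / mii
  group <- if (rate <= 0.20) 1L else if (rate >= 0.85) 3L else 2L
  structure(list(two_cell = as.integer(two_cell), mii = as.integer(mii),
                 activation_rate = rate, group = group),
            class = "moat_result")
}

#' @export
print.moat_result <- function(x, ...) {
  cat("MOAT group ", x$group, "  [activation ",
      fmt_pct(x$two_cell, x$mii), "]\n", sep = "")
  invisible(x)
}

#' Pooled clinical rate over a set of cycles
#'
#' @param cycles Cycle data.frame (typically one arm).
#' @param kind One of `"fertilization"` (sum 2PN / sum MII), `"blastocyst"`
#'   (sum blastocysts / sum 2PN, restricted to rows with blastocyst culture),
#'   `"hcg_per_cycle"` (sum positive hCG / number of cycles), `"lb_per_cycle"`
#'   (live births / number of cycles).
#' @return A [rate_summary()].
#' @export
aggregate_rate <- function(cycles, kind = c("fertilization", "blastocyst",
                                            "hcg_per_cycle", "lb_per_cycle")) {
  kind <- match.arg(kind)
  if (nrow(cycles) == 0L) stop_fertscreen("no cycles selected")
  n_cycles <- sum(cycles$n_cycles)
  switch(kind,
    fertilization = rate_summary(sum(cycles$two_pn), sum(cycles$mii),
                                 "fertilization rate (2PN/MII)"),
    blastocyst = {
      cult <- cycles[!is.na(cycles$blastocysts), , drop = FALSE]
      if (nrow(cult) == 0L) stop_fertscreen("no cycles with blastocyst culture")
      rate_summary(sum(cult$blastocysts), sum(cult$two_pn),
                   "blastocyst rate (blastocyst/2PN)")
    },
    hcg_per_cycle = rate_summary(sum(cycles$hcg_positive), n_cycles,
                                 "positive hCG rate per cycle"),
    lb_per_cycle = {
      lb <- sum(vapply(cycles$outcomes, function(o)
        sum(parse_outcomes(o) == "LB"), integer(1)))
      rate_summary(lb, n_cycles, "live birth rate per cycle")
    })
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of every
#' table whose probability does not exceed that of the observed table (with a
#' relative tolerance of 1e-7 on the comparison) -- the probability-mass
#' definition of the two-sided exact test.
#'
#' @param a,b,c,d Cell counts of the table `rbind(c(a, b), c(c, d))`;
#'   non-negative integers with both row margins positive.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(1, 1, 1, 1)  # 1
#' fisher_exact_2x2(5, 42, 21, 14)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (!all(vapply(cells, is_count, logical(1)))) {
    stop_fertscreen("cells must be non-negative integers")
  }
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0) stop_fertscreen("both group margins must be positive")
  # a degenerate column margin (all successes or all failures) gives p = 1
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(a, m, n, k)
  min(sum(dens[dens <= d_obs * (1 + 1e-7)]), 1)
}

#' Compare the ICSI and ICSI-AOA arms
#'
#' For fertilization, blastocyst, positive hCG and live-birth rates: pooled
#' [rate_summary()]s for both arms, the exact Fisher p-value on the underlying
#' 2x2 counts, and significance at `alpha`.
#'
#' @param cycles Cycle data.frame containing both arms.
#' @param alpha Significance level, default 0.05.
#' @return An object of class `"arm_comparison"`: a named list over the four
#'   endpoints, each holding `icsi`, `icsi_aoa`, `p_value`, `significant`.
#' @export
compare_arms <- function(cycles, alpha = 0.05) {
  arms <- split(cycles, cycles$arm)
  if (!all(c("ICSI", "ICSI_AOA") %in% names(arms))) {
    stop_fertscreen("both arms must be present")
  }
  endpoint <- function(kind) {
    r1 <- aggregate_rate(arms$ICSI, kind)
    r2 <- aggregate_rate(arms$ICSI_AOA, kind)
    p <- fisher_exact_2x2(r2$numerator, r2$denominator - r2$numerator,
                          r1$numerator, r1$denominator - r1$numerator)
    list(icsi = r1, icsi_aoa = r2, p_value = p, significant = p < alpha)
  }
  structure(
    list(fertilization = endpoint("fertilization"),
         blastocyst = tryCatch(endpoint("blastocyst"), fertscreen_error = function(e) NULL),
         hcg = endpoint("hcg_per_cycle"),
         live_birth = endpoint("lb_per_cycle"),
         alpha = alpha),
    class = "arm_comparison"
  )
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat("ICSI vs ICSI-AOA outcome comparison (Fisher exact, alpha =", x$alpha, ")\n")
  for (nm in c("fertilization", "blastocyst", "hcg", "live_birth")) {
    e <- x[[nm]]
    if (is.null(e)) next
    cat(sprintf("  %-13s ICSI %s  vs  AOA %s   p = %.3g%s\n", nm,
                fmt_pct(e$icsi$numerator, e$icsi$denominator),
                fmt_pct(e$icsi_aoa$numerator, e$icsi_aoa$denominator),
                e$p_value, if (e$significant) " *" else ""))
  }
  invisible(x)
}

#' Acrosome detachment call for one sperm cell
#'
#' A cell (with an intact acrosome) is scored detached when the detachment
#' spans at least 50% of the acrosome, or when the acrosome shows clear
#' folding/curving with more than 50% detached.
#'
#' @param detachment_fraction Fraction of the acrosome length detached, `[0, 1]`.
#' @param folded_curved Logical.
#' @return `TRUE` (detached) or `FALSE`.
#' @examples
#' detachment_call(0.50)        # TRUE
#' detachment_call(0.49)        # FALSE
#' @export
detachment_call <- function(detachment_fraction, folded_curved = FALSE) {
  if (!is_prob(detachment_fraction)) {
    stop_fertscreen("detachment_fraction must lie in [0, 1]")
  }
  detachment_fraction >= 0.5 || (isTRUE(folded_curved) && detachment_fraction > 0.5)
}

#' Acrosome detachment rate with control comparison
#'
#' @param cells Data.frame of sperm-cell annotations for one sample with
#'   columns `acrosome_intact`, `detachment_fraction`, `folded_curved`; only
#'   intact-acrosome cells enter the rate.
#' @param control_cells Same, for the control sample; optional.
#' @param min_cells Analysis floor on intact cells (default 20); fewer cells
#'   triggers a warning but the rate is still computed (flagged).
#' @return List with `rate` (a [rate_summary()]), `fisher_p` (vs control, `NA`
#'   when no control is given) and `low_n` flag.
#' @export
detachment_rate <- function(cells, control_cells = NULL, min_cells = 20L) {
  intact <- cells[cells$acrosome_intact, , drop = FALSE]
  if (nrow(intact) == 0L) stop_fertscreen("no intact-acrosome cells")
  low_n <- nrow(intact) < min_cells
  if (low_n) warning("fewer than ", min_cells, " intact cells; rate flagged low_n")
  det <- mapply(detachment_call, intact$detachment_fraction, intact$folded_curved)
  rs <- rate_summary(sum(det), length(det), "acrosome detachment rate")
  fisher_p <- NA_real_
  if (!is.null(control_cells)) {
    ci <- control_cells[control_cells$acrosome_intact, , drop = FALSE]
    cdet <- mapply(detachment_call, ci$detachment_fraction, ci$folded_curved)
    fisher_p <- fisher_exact_2x2(sum(det), length(det) - sum(det),
                                 sum(cdet), length(cdet) - sum(cdet))
  }
  list(rate = rs, fisher_p = fisher_p, low_n = low_n)
}

#' Immunofluorescence expression class of one sperm cell
#'
#' Intensity is background-corrected (`intensity - background`, floored at 0)
#' and binned: `corrected <= invisible_max` invisible, `corrected >=
#' obvious_min` obvious, weak in between.
#'
#' @param if_intensity,if_background Mean grey values (AU).
#' @param thresholds List with `invisible_max` and `obvious_min`
#'   (`obvious_min > invisible_max`).
#' @return `"invisible"`, `"weak"` or `"obvious"`.
#' @export
if_expression_class <- function(if_intensity, if_background,
                                thresholds = list(invisible_max = 5, obvious_min = 30)) {
  if (thresholds$obvious_min <= thresholds$invisible_max) {
    stop_fertscreen("obvious_min must exceed invisible_max")
  }
  if (is.na(if_intensity) || is.na(if_background)) {
    stop_fertscreen("intensity and background must both be present")
  }
  corrected <- max(if_intensity - if_background, 0)
  if (corrected <= thresholds$invisible_max) "invisible"
  else if (corrected >= thresholds$obvious_min) "obvious"
  else "weak"
}

#' Proportion of sperm cells expressing the stained protein
#'
#' Expression = weak or obvious class, over intact-acrosome cells.
#'
#' @param cells Data.frame with columns `acrosome_intact`, `if_intensity`,
#'   `if_background`.
#' @param thresholds As in [if_expression_class()].
#' @param min_cells Analysis floor (default 50); fewer cells flags `low_n`.
#' @return List with `rate` (a [rate_summary()]), `class_counts` and `low_n`.
#' @export
expression_proportion <- function(cells, thresholds = list(invisible_max = 5,
                                                           obvious_min = 30),
                                  min_cells = 50L) {
  intact <- cells[cells$acrosome_intact, , drop = FALSE]
  if (nrow(intact) == 0L) stop_fertscreen("no intact-acrosome cells")
  cls <- mapply(if_expression_class, intact$if_intensity, intact$if_background,
                MoreArgs = list(thresholds = thresholds))
  counts <- table(factor(cls, levels = c("invisible", "weak", "obvious")))
  list(rate = rate_summary(sum(cls != "invisible"), length(cls),
                           "cells with expression"),
       class_counts = counts,
       low_n = nrow(intact) < min_cells)
}
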