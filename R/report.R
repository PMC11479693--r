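# End-to-end report over the packaged study tables, and schema diagnostics
# for user-supplied input files.

#' Regenerate the study's summary numbers from the packaged tables
#'
#' Runs the full pipeline over the packaged fixtures: rarity-filters the
#' variant table, classifies every variant from its (derived) point totals
#' pre and post functional evidence, computes carrier and recurrence
#' frequencies, MOAT groups, pooled clinical rates per arm and the exact
#' Fisher comparisons. Golden marginal totals are re-checked; any deviation
#' raises an error.
#'
#' @param alpha Significance level for the arm comparisons, default 0.05.
#' @param path Optional path; when given, the report is also written as JSON.
#' @return An object of class `"paper_report"`: nested list with elements
#'   `carrier_rates`, `recurrence`, `classifications`, `moat`,
#'   `arm_comparison`.
#' @export
run_paper_report <- function(alpha = 0.05, path = NULL) {
  fx <- fertscreen_fixtures()
  surviving <- filter_by_af(fx$variants, 0.05)

  carrier_rates <- lapply(c("PLCZ1", "ACTL7A", "ACTL9"), function(g)
    carrier_frequency(surviving, fx$roster, g))
  names(carrier_rates) <- c("PLCZ1", "ACTL7A", "ACTL9")
  recurrence <- lapply(c("p.Ser500Leu", "p.His233Leu"), function(pc)
    variant_recurrence(surviving, fx$roster, pc))
  names(recurrence) <- c("p.Ser500Leu", "p.His233Leu")

  classify_points <- function(n) {
    cl <- classify(evidence_for_points(n))
    lab <- cl$category
    if (lab == "VUS") lab <- paste0("VUS (", sub("_", " ", cl$vus_tier), ")")
    list(points = cl$net_points, posterior = round_half_up(cl$posterior, 3),
         label = lab)
  }
  classifications <- lapply(seq_len(nrow(surviving)), function(i) {
    row <- surviving[i, ]
    list(patient = row$patient_id, gene = row$gene,
         protein_change = row$protein_change,
         pre = classify_points(row$points_pre),
         post = classify_points(row$points_post))
  })

  moat <- lapply(seq_len(nrow(fx$functional)), function(i) {
    row <- fx$functional[i, ]
    if (row$patient_id == "C") return(NULL)
    mg <- moat_group(row$moat_two_cell, row$moat_mii)
    list(patient = row$patient_id, group = mg$group,
         activation_rate = mg$activation_rate)
  })
  moat <- Filter(Negate(is.null), moat)

  arms <- compare_arms(fx$cycles, alpha)

  # golden marginals: a corrupted fixture or a regression in the pipeline
  # must not produce a silently wrong report
  stopifnot(
    carrier_rates$PLCZ1$numerator == 16L, carrier_rates$PLCZ1$denominator == 55L,
    arms$fertilization$icsi_aoa$numerator == 199L,
    arms$fertilization$icsi_aoa$denominator == 322L
  )

  report <- structure(
    list(carrier_rates = carrier_rates, recurrence = recurrence,
         classifications = classifications, moat = moat,
         arm_comparison = arms),
    class = "paper_report"
  )
  if (!is.null(path)) {
    jsonable <- list(
      carrier_rates = lapply(carrier_rates, function(r)
        list(numerator = r$numerator, denominator = r$denominator,
             percent = round_half_up(100 * r$rate, 2))),
      recurrence = lapply(recurrence, function(r)
        list(numerator = r$numerator, denominator = r$denominator,
             percent = round_half_up(100 * r$rate, 2))),
      arm_comparison = lapply(
        arms[c("fertilization", "blastocyst", "hcg", "live_birth")],
        function(e) if (is.null(e)) NULL else list(
          icsi = list(numerator = e$icsi$numerator,
                      denominator = e$icsi$denominator,
                      percent = round_half_up(100 * e$icsi$rate, 2)),
          icsi_aoa = list(numerator = e$icsi_aoa$numerator,
                          denominator = e$icsi_aoa$denominator,
                          percent = round_half_up(100 * e$icsi_aoa$rate, 2)),
          p_value = e$p_value))
    )
    jsonlite::write_json(jsonable, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}

#' @export
print.paper_report <- function(x, ...) {
  cat("Fertilization-failure workup report\n\nCarrier frequencies:\n")
  for (g in names(x$carrier_rates)) {
    cat("  ", g, ": ", format(x$carrier_rates[[g]]), "\n", sep = "")
  }
  cat("Recurrent variants:\n")
  for (pc in names(x$recurrence)) {
    cat("  ", pc, ": ", format(x$recurrence[[pc]]), "\n", sep = "")
  }
  cat("\n")
  print(x$arm_comparison)
  invisible(x)
}

#' Schema diagnostics for input files
#'
#' Checks each supplied file against its expected schema and row-level
#' invariants without mutating anything; problems are returned as messages,
#' not thrown.
#'
#' @param cycles,variants,traces Optional file paths (cycle CSV, variant TSV,
#'   trace CSV).
#' @return Character vector of diagnostics; empty when all files are
#'   well-formed.
#' @export
validate_inputs <- function(cycles = NULL, variants = NULL, traces = NULL) {
  diags <- character(0)
  note <- function(file, msgs) {
    if (length(msgs)) paste0(basename(file), ": ", msgs) else character(0)
  }
  if (!is.null(cycles)) {
    diags <- c(diags, tryCatch({
      tab <- utils::read.csv(cycles, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
      if (!"n_cycles" %in% names(tab)) tab$n_cycles <- 1L
      missing <- setdiff(.cycle_columns, names(tab))
      if (length(missing)) {
        note(cycles, paste("missing column(s):", paste(missing, collapse = ", ")))
      } else {
        note(cycles, validate_cycles(tab))
      }
    }, error = function(e) note(cycles, conditionMessage(e))))
  }
  if (!is.null(variants)) {
    diags <- c(diags, tryCatch({
      read_variant_table(variants)
      character(0)
    }, error = function(e) note(variants, conditionMessage(e))))
  }
  if (!is.null(traces)) {
    diags <- c(diags, tryCatch({
      tab <- utils::read.csv(traces, stringsAsFactors = FALSE)
      missing <- setdiff(c("time_s", "ratio", "oocyte_id", "assay"), names(tab))
      msgs <- character(0)
      if (length(missing)) {
        msgs <- paste("missing column(s):", paste(missing, collapse = ", "))
      } else {
        for (oid in unique(tab$oocyte_id)) {
          tt <- tab$time_s[tab$oocyte_id == oid]
          if (any(diff(sort(tt)) <= 0)) {
            msgs <- c(msgs, paste0("oocyte ", oid, ": duplicated time points"))
          }
        }
      }
      note(traces, msgs)
    }, error = function(e) note(traces, conditionMessage(e))))
  }
  diags
}
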