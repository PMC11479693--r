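# Packaged transcriptions of the study's three summary tables, plus the
# cohort roster. The variant table carries net ACMG point totals recovered
# from the printed posterior probabilities with invert_posterior() (the
# per-criterion evidence sets are not published); these columns are derived,
# not printed, and are labelled as such. The cycle table pools each patient's
# cycles per arm exactly as printed, with the printed TOTAL row used as an
# integrity checksum.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "fertscreen")
  if (!nzchar(p)) stop_fertscreen("fixture '", file, "' not found")
  p
}

#' Packaged study tables
#'
#' Loads the transcribed variant, functional-assay and clinical-cycle tables
#' together with the screening roster (cohort 1: 28 patients, PLCZ1 only;
#' cohort 2: 27 patients, PLCZ1 + ACTL7A + ACTL9). Each table is
#' integrity-checked against its printed marginal totals at load time.
#'
#' @return List with elements `variants` (data.frame, one row per
#'   patient-variant, including derived `points_pre`/`points_post` columns),
#'   `functional` (MOAT counts and mean AxF summaries per patient, control row
#'   `C`), `cycles` (pooled per patient and arm, [read_cycle_table()] schema)
#'   and `roster` (a [cohort_roster()]).
#' @examples
#' fx <- fertscreen_fixtures()
#' nrow(fx$variants)
#' @export
fertscreen_fixtures <- function() {
  variants <- read_variant_table(fixture_path("table1_variants.tsv"))
  functional <- utils::read.delim(fixture_path("table2_functional.tsv"),
                                  stringsAsFactors = FALSE,
                                  na.strings = c("NA", ""))
  cycles <- read_cycle_table(fixture_path("table3_cycles.csv"))

  check <- function(ok, what) {
    if (!ok) stop_fertscreen("fixture integrity check failed: ", what,
                             class = "fertscreen_integrity_error")
  }
  check(nrow(variants) == 25L, "variant table row count")
  check(nrow(functional) == 20L, "functional table row count")
  icsi <- cycles[cycles$arm == "ICSI", ]
  aoa <- cycles[cycles$arm == "ICSI_AOA", ]
  # printed TOTAL row of the cycle table
  check(sum(icsi$n_cycles) == 47L && sum(aoa$n_cycles) == 35L, "cycle counts")
  check(sum(icsi$two_pn) == 56L && sum(icsi$mii) == 498L, "ICSI 2PN/MII totals")
  check(sum(aoa$two_pn) == 199L && sum(aoa$mii) == 322L, "AOA 2PN/MII totals")
  check(sum(icsi$hcg_positive) == 5L && sum(aoa$hcg_positive) == 21L,
        "positive hCG totals")
  cult <- aoa[!is.na(aoa$blastocysts), ]
  check(sum(cult$blastocysts) == 94L && sum(cult$two_pn) == 143L,
        "blastocyst totals")

  roster <- cohort_roster(list(
    `1` = list(patients = paste0("P", 1:28), genes = "PLCZ1"),
    `2` = list(patients = paste0("P", 29:55),
               genes = c("PLCZ1", "ACTL7A", "ACTL9"))
  ))
  list(variants = variants, functional = functional, cycles = cycles,
       roster = roster)
}
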