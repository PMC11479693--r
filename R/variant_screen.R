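# Candidate-variant table handling: parsing/validation, the rarity filter
# (gnomAD allele frequency < 5%), in-silico annotation rules (REVEL,
# AlphaMissense) and cohort carrier/recurrence frequencies.

.variant_columns <- c("patient_id", "cohort", "gene", "transcript", "cdna_change",
                      "protein_change", "zygosity", "rsid", "gnomad_af", "revel",
                      "alphamissense", "consequence")
.consequences <- c("missense", "nonsense", "frameshift", "synonymous", "other")

#' Read and validate a variant table
#'
#' Reads a TSV with one row per patient-variant observation. Required columns:
#' `patient_id, cohort, gene, transcript, cdna_change, protein_change, zygosity
#' (het/hom), rsid, gnomad_af, revel, alphamissense, consequence`. Scores must
#' lie in `[0, 1]` when present; REVEL/AlphaMissense must be absent for
#' non-missense consequences. Extra columns are kept.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of validated variant records.
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  missing <- setdiff(.variant_columns, names(tab))
  if (length(missing)) {
    stop_fertscreen("variant table missing column(s): ",
                    paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0L) return(tab)
  problems <- character(0)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    line <- i + 1L  # header is line 1
    if (!row$zygosity %in% c("het", "hom")) {
      problems <- c(problems, paste0("line ", line, ": zygosity '", row$zygosity, "'"))
    }
    if (!row$consequence %in% .consequences) {
      problems <- c(problems, paste0("line ", line, ": consequence '",
                                     row$consequence, "'"))
    }
    for (col in c("gnomad_af", "revel", "alphamissense")) {
      v <- row[[col]]
      if (!is.na(v) && (v < 0 || v > 1)) {
        problems <- c(problems, paste0("line ", line, ": ", col, " = ", v,
                                       " outside [0,1]"))
      }
    }
    if (!is.na(row$consequence) && row$consequence != "missense" &&
        (!is.na(row$revel) || !is.na(row$alphamissense))) {
      problems <- c(problems, paste0("line ", line,
                                     ": missense scores on non-missense variant"))
    }
  }
  if (length(problems)) {
    stop_fertscreen("invalid variant table:\n  ",
                    paste(problems, collapse = "\n  "),
                    class = "fertscreen_validation_error")
  }
  tab
}

#' Rarity filter on population allele frequency
#'
#' Keeps records whose gnomAD allele frequency is below the threshold
#' (strict `<`) or absent; a novel variant with no population record cannot
#' argue commonness and therefore passes. Order is preserved.
#'
#' @param records Variant data.frame (as from [read_variant_table()]).
#' @param threshold Allele-frequency cut-off in (0, 1]; default 0.05.
#' @return The filtered data.frame.
#' @examples
#' \dontrun{filter_by_af(variants, threshold = 0.05)}
#' @export
filter_by_af <- function(records, threshold = 0.05) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop_fertscreen("threshold must lie in (0, 1]")
  }
  keep <- is.na(records$gnomad_af) | records$gnomad_af < threshold
  records[keep, , drop = FALSE]
}

#' REVEL pathogenicity flag
#'
#' A REVEL ensemble score above 0.5 is read as supporting pathogenicity.
#'
#' @param score REVEL score(s) in `[0, 1]`; `NA` (non-missense) stays `NA`.
#' @return Logical vector; `TRUE` iff `score > 0.5`.
#' @examples
#' revel_flag(c(0.910, 0.099, 0.5, NA))
#' @export
revel_flag <- function(score) {
  bad <- !is.na(score) & (score < 0 | score > 1)
  if (any(bad)) stop_fertscreen("REVEL score outside [0,1]")
  ifelse(is.na(score), NA, score > 0.5)
}

#' AlphaMissense pathogenicity bin
#'
#' Bins an AlphaMissense score into the published classes: `[0, 0.34)` likely
#' benign, `[0.34, 0.564)` uncertain, `[0.564, 1]` likely pathogenic.
#'
#' @param score AlphaMissense score(s) in `[0, 1]`; `NA` stays `NA`.
#' @return Character vector over `likely_benign`, `uncertain`,
#'   `likely_pathogenic`.
#' @examples
#' alphamissense_bin(c(0.880, 0.171, 0.533))
#' @export
alphamissense_bin <- function(score) {
  bad <- !is.na(score) & (score < 0 | score > 1)
  if (any(bad)) stop_fertscreen("AlphaMissense score outside [0,1]")
  out <- rep(NA_character_, length(score))
  out[!is.na(score) & score < 0.34] <- "likely_benign"
  out[!is.na(score) & score >= 0.34 & score < 0.564] <- "uncertain"
  out[!is.na(score) & score >= 0.564] <- "likely_pathogenic"
  out
}

#' Cohort roster: who was screened for which genes
#'
#' A gene's carrier denominator is the number of patients whose cohort was
#' screened for that gene (e.g. a first cohort screened for `PLCZ1` only and a
#' second for `PLCZ1`, `ACTL7A` and `ACTL9`).
#'
#' @param cohorts Named list: cohort id -> list(patients = character vector,
#'   genes = character vector).
#' @return An object of class `"cohort_roster"`.
#' @examples
#' cohort_roster(list(
#'   `1` = list(patients = paste0("P", 1:28), genes = "PLCZ1"),
#'   `2` = list(patients = paste0("P", 29:55),
#'              genes = c("PLCZ1", "ACTL7A", "ACTL9"))))
#' @export
cohort_roster <- function(cohorts) {
  for (cid in names(cohorts)) {
    co <- cohorts[[cid]]
    if (is.null(co$patients) || is.null(co$genes)) {
      stop_fertscreen("each cohort needs $patients and $genes")
    }
    if (anyDuplicated(co$patients)) {
      stop_fertscreen("duplicate patient ids in cohort ", cid)
    }
  }
  all_p <- unlist(lapply(cohorts, `[[`, "patients"), use.names = FALSE)
  if (anyDuplicated(all_p)) stop_fertscreen("a patient appears in two cohorts")
  structure(list(cohorts = cohorts), class = "cohort_roster")
}

patients_screened_for <- function(roster, gene) {
  hit <- lapply(roster$cohorts, function(co)
    if (gene %in% co$genes) co$patients else character(0))
  unlist(hit, use.names = FALSE)
}

#' Carrier frequency of a gene in the screened population
#'
#' Numerator: distinct patients with at least one surviving record in the gene.
#' Denominator: patients screened for that gene per the roster.
#'
#' @param records Variant data.frame (post-filtering).
#' @param roster A [cohort_roster()].
#' @param gene Gene symbol.
#' @return A [rate_summary()].
#' @export
carrier_frequency <- function(records, roster, gene) {
  screened <- patients_screened_for(roster, gene)
  if (length(screened) == 0L) {
    stop_fertscreen("gene '", gene, "' was screened in no cohort")
  }
  carriers <- unique(records$patient_id[records$gene == gene])
  carriers <- intersect(carriers, screened)
  rate_summary(length(carriers), length(screened),
               paste0(gene, " carrier frequency"))
}

#' Recurrence of one protein change in the screened population
#'
#' Distinct carriers of the protein change over patients screened for its gene.
#' A change never observed yields a zero-numerator rate over the denominator of
#' the gene given in `gene` (inferred from records when omitted).
#'
#' @param records Variant data.frame.
#' @param roster A [cohort_roster()].
#' @param protein_change HGVS p. string.
#' @param gene Gene symbol; required if the change is absent from `records`.
#' @return A [rate_summary()].
#' @export
variant_recurrence <- function(records, roster, protein_change, gene = NULL) {
  if (!nzchar(protein_change)) stop_fertscreen("protein_change must be non-empty")
  hits <- records[!is.na(records$protein_change) &
                    records$protein_change == protein_change, , drop = FALSE]
  if (is.null(gene)) {
    if (nrow(hits) == 0L) {
      stop_fertscreen("unseen protein change; supply gene= for the denominator")
    }
    gene <- hits$gene[1]
  }
  screened <- patients_screened_for(roster, gene)
  carriers <- intersect(unique(hits$patient_id), screened)
  rate_summary(length(carriers), length(screened),
               paste0(protein_change, " recurrence"))
}

#' Per-gene zygosity profile of one patient
#'
#' @param records Variant data.frame.
#' @param patient Patient id.
#' @return A data.frame with one row per gene carrying `hom`, `het` counts and
#'   a `compound_het` flag (two or more distinct heterozygous variants in the
#'   same gene). Zero rows for a patient with no records.
#' @export
zygosity_profile <- function(records, patient) {
  mine <- records[records$patient_id == patient, , drop = FALSE]
  if (nrow(mine) == 0L) {
    return(data.frame(gene = character(0), hom = integer(0), het = integer(0),
                      compound_het = logical(0)))
  }
  out <- lapply(split(mine, mine$gene), function(g) {
    het_changes <- unique(g$protein_change[g$zygosity == "het"])
    data.frame(gene = g$gene[1],
               hom = sum(g$zygosity == "hom"),
               het = sum(g$zygosity == "het"),
               compound_het = length(het_changes) >= 2L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
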