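# Points-based Bayesian ACMG/AMP variant classification.
#
# Evidence criteria (PVS1, PS1-4, PM1-6, PP1-5, BA1, BS1-4, BP1-7) are combined
# on the naturally scaled point scale: supporting = 1 point, moderate = 2,
# strong = 4, very strong = 8, benign criteria negative.  The net point total N
# maps to a posterior probability of pathogenicity through
#
#   O    = odds_very_strong ^ (N / 8)
#   post = O * prior / ((O - 1) * prior + 1)
#
# with prior 0.10 and odds_very_strong 350 by default, and to the five ACMG
# categories by point bounds (>= 10 P, 6..9 LP, 0..5 VUS, -6..-1 LB, <= -7 B).
# VUS are sub-graded by a temperature tier (hot .. ice cold) from the same
# point total.

.strength_levels  <- c("stand_alone", "very_strong", "strong", "moderate", "supporting")
.strength_points  <- c(very_strong = 8L, strong = 4L, moderate = 2L, supporting = 1L)
.acmg_categories  <- c("P", "LP", "VUS", "LB", "B")
.vus_tiers        <- c("hot", "warm", "tepid", "cool", "cold", "ice_cold")

#' One ACMG/AMP evidence criterion at an applied strength
#'
#' An evidence item records a criterion code (e.g. `PS3`, `PM2`, `BP4`), its
#' direction and the strength at which it is applied. Modified-strength use
#' (e.g. `PS3` applied at supporting level after limited functional data) is
#' expressed through `strength`, which is deliberately decoupled from the code.
#'
#' @param criterion_code Criterion token. Must start with `P` for pathogenic
#'   or `B` for benign evidence, in agreement with `direction`.
#' @param direction `"pathogenic"` or `"benign"`.
#' @param strength One of `"stand_alone"` (BA1 only), `"very_strong"`,
#'   `"strong"`, `"moderate"`, `"supporting"`.
#' @return An object of class `"evidence_item"`.
#' @examples
#' evidence_item("PS3", "pathogenic", "strong")
#' evidence_item("BA1", "benign", "stand_alone")
#' @export
evidence_item <- function(criterion_code, direction, strength) {
  direction <- match.arg(direction, c("pathogenic", "benign"))
  strength  <- match.arg(strength, .strength_levels)
  if (!is.character(criterion_code) || length(criterion_code) != 1L ||
      !nzchar(criterion_code)) {
    stop_fertscreen("criterion_code must be a non-empty string")
  }
  prefix <- toupper(substr(criterion_code, 1L, 1L))
  if ((direction == "pathogenic" && prefix != "P") ||
      (direction == "benign" && prefix != "B")) {
    stop_fertscreen("criterion code '", criterion_code,
                    "' disagrees with direction '", direction, "'")
  }
  if (strength == "stand_alone" && direction != "benign") {
    stop_fertscreen("stand_alone strength is reserved for benign evidence (BA1)")
  }
  structure(
    list(criterion_code = toupper(criterion_code), direction = direction,
         strength = strength),
    class = "evidence_item"
  )
}

#' @export
print.evidence_item <- function(x, ...) {
  cat(x$criterion_code, " (", x$direction, ", ", x$strength, ")\n", sep = "")
  invisible(x)
}

#' Parameters of the Bayesian point framework
#'
#' @param prior Prior probability of pathogenicity, in (0, 1). Default 0.10,
#'   i.e. the posterior reported for a variant with no net evidence.
#' @param odds_very_strong Odds of pathogenicity carried by one very strong
#'   pathogenic criterion; must exceed 1. Default 350.
#' @param point_of_strength Named integer vector mapping strength to points.
#' @param category_bounds Named list of inclusive point bounds per category.
#' @return An object of class `"bayes_params"`.
#' @examples
#' bayes_params()
#' @export
bayes_params <- function(prior = 0.10, odds_very_strong = 350,
                         point_of_strength = .strength_points,
                         category_bounds = list(P = c(10L, Inf), LP = c(6L, 9L),
                                                VUS = c(0L, 5L), LB = c(-6L, -1L),
                                                B = c(-Inf, -7L))) {
  if (!is_prob(prior) || prior <= 0 || prior >= 1) {
    stop_fertscreen("prior must lie strictly in (0, 1)")
  }
  if (!is.numeric(odds_very_strong) || odds_very_strong <= 1) {
    stop_fertscreen("odds_very_strong must exceed 1")
  }
  if (!all(c("very_strong", "strong", "moderate", "supporting") %in%
           names(point_of_strength))) {
    stop_fertscreen("point_of_strength must name very_strong, strong, moderate, supporting")
  }
  structure(
    list(prior = prior, odds_very_strong = odds_very_strong,
         point_of_strength = point_of_strength, category_bounds = category_bounds),
    class = "bayes_params"
  )
}

#' @export
print.bayes_params <- function(x, ...) {
  cat("Bayesian ACMG point framework\n")
  cat("  prior:", x$prior, "  odds(very strong):", x$odds_very_strong, "\n")
  cat("  points:", paste(names(x$point_of_strength), x$point_of_strength,
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Signed point value of one evidence item
#'
#' Pathogenic items contribute `+point_of_strength[strength]`, benign items the
#' negative. The stand-alone benign criterion (BA1) has no finite point value;
#' it returns `NA` and forces category B in [categorize()].
#'
#' @param item An [evidence_item()].
#' @param params A [bayes_params()].
#' @return Integer points, or `NA_integer_` for stand-alone evidence.
#' @examples
#' points_of(evidence_item("PS3", "pathogenic", "strong"))    # +4
#' points_of(evidence_item("BS3", "benign", "strong"))        # -4
#' @export
points_of <- function(item, params = bayes_params()) {
  if (!inherits(item, "evidence_item")) {
    stop_fertscreen("points_of expects an evidence_item")
  }
  if (item$strength == "stand_alone") return(NA_integer_)
  pts <- params$point_of_strength[[item$strength]]
  if (is.null(pts)) stop_fertscreen("unknown strength '", item$strength, "'")
  as.integer(if (item$direction == "pathogenic") pts else -pts)
}

has_stand_alone_benign <- function(evidence) {
  any(vapply(evidence, function(e) e$strength == "stand_alone", logical(1)))
}

#' Net point total of an evidence set
#'
#' @param evidence List of [evidence_item()]s; may be empty.
#' @param params A [bayes_params()].
#' @return Signed integer sum of the items' points. Stand-alone (BA1) items
#'   carry no points and are skipped here; [classify()] handles their category
#'   override.
#' @examples
#' net_points(list(evidence_item("PS3", "pathogenic", "strong"),
#'                 evidence_item("PP3", "pathogenic", "supporting")))  # 5
#' @export
net_points <- function(evidence, params = bayes_params()) {
  if (length(evidence) == 0L) return(0L)
  pts <- vapply(evidence, points_of, integer(1), params = params)
  sum(pts, na.rm = TRUE)
}

#' Posterior probability of pathogenicity at a net point total
#'
#' Evaluates `O = odds_very_strong^(net_points/8)` and
#' `posterior = O * prior / ((O - 1) * prior + 1)`. At zero net points the
#' prior is returned exactly.
#'
#' @param net_points Signed integer (vectorised).
#' @param params A [bayes_params()].
#' @return Posterior probability in (0, 1), full precision (round for display).
#' @examples
#' posterior_probability(0)   # 0.1 (the prior)
#' round(posterior_probability(5), 3)  # 0.812
#' @export
posterior_probability <- function(net_points, params = bayes_params()) {
  odds <- params$odds_very_strong ^ (net_points / 8)
  post <- odds * params$prior / ((odds - 1) * params$prior + 1)
  post[net_points == 0] <- params$prior
  post
}

#' ACMG category from a net point total
#'
#' Point bounds (defaults): `>= 10` pathogenic (P), `6..9` likely pathogenic
#' (LP), `0..5` uncertain significance (VUS), `-6..-1` likely benign (LB),
#' `<= -7` benign (B). Any stand-alone benign criterion (BA1) in `evidence`
#' forces B regardless of points.
#'
#' @param net_points Signed integer.
#' @param evidence Optional evidence list, checked for stand-alone items.
#' @param params A [bayes_params()].
#' @return One of `"P"`, `"LP"`, `"VUS"`, `"LB"`, `"B"`.
#' @examples
#' categorize(9)    # "LP"
#' categorize(10)   # "P"
#' categorize(-7)   # "B"
#' @export
categorize <- function(net_points, evidence = list(), params = bayes_params()) {
  if (has_stand_alone_benign(evidence)) return("B")
  b <- params$category_bounds
  for (cat in names(b)) {
    if (net_points >= b[[cat]][1] && net_points <= b[[cat]][2]) return(cat)
  }
  stop_fertscreen("category bounds do not cover ", net_points, " points")
}

#' VUS temperature tier from a net point total
#'
#' Sub-grades variants of uncertain significance by how close their evidence
#' sits to the likely-pathogenic boundary: 5 points hot, 4 warm, 3 tepid,
#' 2 cool, 1 cold, 0 ice cold.
#'
#' @param net_points Integer in 0..5 (the VUS band).
#' @return One of `"hot"`, `"warm"`, `"tepid"`, `"cool"`, `"cold"`, `"ice_cold"`.
#' @examples
#' vus_tier(5)  # "hot"
#' vus_tier(0)  # "ice_cold"
#' @export
vus_tier <- function(net_points) {
  if (!is_count(net_points) || net_points > 5) {
    stop_fertscreen("vus_tier is defined on the VUS band 0..5 points only")
  }
  .vus_tiers[6L - net_points]
}

#' Classify a variant from its evidence set
#'
#' Composes [net_points()], [posterior_probability()], [categorize()] and
#' [vus_tier()] into one classification result.
#'
#' @param evidence List of [evidence_item()]s (possibly empty: a variant with
#'   no applicable criteria is an ice-cold VUS at the prior).
#' @param params A [bayes_params()].
#' @return An object of class `"acmg_classification"` with fields `net_points`,
#'   `posterior` (full precision), `category`, `vus_tier` (`NA` unless VUS) and
#'   `evidence_used`.
#' @examples
#' classify(list(evidence_item("PS3", "pathogenic", "strong"),
#'               evidence_item("PM2", "pathogenic", "moderate")))
#' @export
classify <- function(evidence = list(), params = bayes_params()) {
  if (inherits(evidence, "evidence_item")) evidence <- list(evidence)
  ok <- vapply(evidence, inherits, logical(1), what = "evidence_item")
  if (!all(ok)) stop_fertscreen("evidence must be a list of evidence_item objects")
  n <- net_points(evidence, params)
  category <- categorize(n, evidence, params)
  structure(
    list(net_points = n,
         posterior = posterior_probability(n, params),
         category = category,
         vus_tier = if (category == "VUS") vus_tier(n) else NA_character_,
         evidence_used = evidence,
         params = params),
    class = "acmg_classification"
  )
}

#' Re-classify after functional (or any additional) evidence
#'
#' Functional assays performed on a patient's sperm (calcium-release testing,
#' immunofluorescence, acrosome ultrastructure) enter the classification as
#' additional criteria, typically PS3/BS3 at full or modified strength. The
#' category may move in either direction.
#'
#' @param base An `"acmg_classification"` from [classify()].
#' @param extra List of additional [evidence_item()]s.
#' @param params A [bayes_params()]; defaults to the one stored in `base`.
#' @return A new `"acmg_classification"` over the combined evidence.
#' @examples
#' pre <- classify(rep(list(evidence_item("PP3", "pathogenic", "supporting")), 5))
#' update_with_functional(pre, list(evidence_item("PS3", "pathogenic", "supporting")))
#' @export
update_with_functional <- function(base, extra, params = base$params) {
  if (!inherits(base, "acmg_classification")) {
    stop_fertscreen("base must come from classify()")
  }
  if (inherits(extra, "evidence_item")) extra <- list(extra)
  classify(c(base$evidence_used, extra), params)
}

#' Recover a net point total from a printed posterior
#'
#' Scans integer point totals and returns the one whose posterior is nearest
#' the given value (ties broken toward 0). Used to reconstruct point totals
#' from published posterior probabilities when the underlying criteria sets
#' are not available.
#'
#' @param posterior Probability strictly in (0, 1).
#' @param params A [bayes_params()].
#' @param range Integer scan bounds.
#' @return The minimizing integer point total.
#' @examples
#' invert_posterior(0.949)  # 7
#' invert_posterior(0.1)    # 0
#' @export
invert_posterior <- function(posterior, params = bayes_params(),
                             range = c(-25L, 25L)) {
  if (!is_prob(posterior) || posterior <= 0 || posterior >= 1) {
    stop_fertscreen("posterior must lie strictly in (0, 1)")
  }
  n <- seq.int(range[1], range[2])
  err <- abs(posterior_probability(n, params) - posterior)
  # ties toward 0: order candidates by |n| within equal error
  ord <- order(err, abs(n))
  as.integer(n[ord[1]])
}

#' @export
print.acmg_classification <- function(x, digits = 3, ...) {
  lab <- x$category
  if (lab == "VUS") lab <- paste0("VUS (", sub("_", " ", x$vus_tier), ")")
  cat("ACMG Bayesian classification: ", lab,
      sprintf("  [%+d points, posterior P = %.3f]\n",
              x$net_points, round_half_up(x$posterior, digits)), sep = "")
  if (length(x$evidence_used)) {
    codes <- vapply(x$evidence_used, function(e)
      paste0(e$criterion_code, "(", substr(e$strength, 1, 3), ")"), character(1))
    cat("  evidence:", paste(codes, collapse = " "), "\n")
  } else {
    cat("  evidence: none (prior returned)\n")
  }
  invisible(x)
}

#' Read per-variant evidence sets from JSON
#'
#' Expects a JSON object mapping variant ids to arrays of
#' `{criterion, direction, strength}` records.
#'
#' @param path Path to the JSON file.
#' @return Named list of evidence lists.
#' @export
read_evidence_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(items) {
    lapply(items, function(it) {
      for (f in c("criterion", "direction", "strength")) {
        if (is.null(it[[f]])) stop_fertscreen("evidence record missing field '", f, "'")
      }
      evidence_item(it$criterion, it$direction, it$strength)
    })
  })
}

#' Tabulate classifications for a set of variants
#'
#' @param evidence_sets Named list of evidence lists (e.g. from
#'   [read_evidence_json()]).
#' @param params A [bayes_params()].
#' @param path Optional path; when given the table is also written as TSV.
#' @return A data.frame with columns `variant_id`, `net_points`, `posterior`
#'   (3 decimals, half-up), `category`, `vus_tier`, `evidence_list`.
#' @export
classification_report <- function(evidence_sets, params = bayes_params(),
                                  path = NULL) {
  rows <- lapply(names(evidence_sets), function(id) {
    cl <- classify(evidence_sets[[id]], params)
    data.frame(
      variant_id = id,
      net_points = cl$net_points,
      posterior = round_half_up(cl$posterior, 3),
      category = cl$category,
      vus_tier = cl$vus_tier,
      evidence_list = paste(vapply(cl$evidence_used, function(e)
        paste(e$criterion_code, e$strength, sep = ":"), character(1)),
        collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
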