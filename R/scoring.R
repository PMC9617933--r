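# Symptom weighting, selection and the total weighted score that drives
# the optimization loop.

#' A baseline symptom assessment
#'
#' Scores use the clinical 0-4 scale with 0.1 resolution; `baseline_off`
#' is the severity without therapy, `baseline_on` the severity under the
#' pre-existing (standard-of-care) stimulation. The improvement assumption
#' requires on <= off: violating assessments are kept but flagged and
#' receive weight zero.
#'
#' @param symptom symptom name (e.g. `"rigidity"`), combined with
#'   `laterality` into the symptom id.
#' @param laterality `"left"` or `"right"`.
#' @param source `"clinician"` or `"sensor"`.
#' @param baseline_off,baseline_on scores in [0, 4].
#' @return an object of class `symptom_assessment`.
#' @export
symptom_assessment <- function(symptom, laterality = c("left", "right"),
                               source = c("clinician", "sensor"),
                               baseline_off, baseline_on) {
  laterality <- match.arg(laterality)
  source <- match.arg(source)
  for (s in c(baseline_off, baseline_on)) {
    if (!is.numeric(s) || s < 0 || s > 4) stop("baseline scores must lie in [0, 4]")
  }
  structure(list(symptom_id = paste(symptom, laterality, sep = "_"),
                 symptom = symptom, laterality = laterality, source = source,
                 baseline_off = round(baseline_off, 1),
                 baseline_on = round(baseline_on, 1),
                 flagged = baseline_on > baseline_off),
            class = "symptom_assessment")
}

#' Raw symptom weight from baseline severity and improvement
#'
#' The weight multiplies the symptom's untreated severity, Delta/4 with
#' Delta = off - on, by its relative improvement Delta/off, i.e.
#' w = Delta^2 / (4 * off), quantized to 0.001. A symptom with no
#' improvement (or no baseline severity) gets weight zero. This product
#' form is the unique simple rule reproducing the three published worked
#' examples (4->0: 1.0, 2->0: 0.50, 2->1: 0.125); the clinically deployed
#' rule is proprietary, so this is a documented assumption.
#'
#' @param baseline_off,baseline_on scores in [0, 4].
#' @return raw weight in [0, 1], resolution 0.001.
#' @export
compute_weight <- function(baseline_off, baseline_on) {
  if (baseline_off < 0 || baseline_off > 4 || baseline_on < 0 || baseline_on > 4) {
    stop("baseline scores must lie in [0, 4]")
  }
  delta <- baseline_off - baseline_on
  if (baseline_off == 0 || delta <= 0) return(0)
  round((delta / 4) * (delta / baseline_off), 3)
}

#' Rank symptoms by weight and build the weighted-score specification
#'
#' Keeps at most `max_n` symptoms (four per hemisphere in the published
#' workflow), ranked by raw weight; ties are broken clinician-before-
#' sensor, then lexically by symptom id. Kept weights are renormalized to
#' sum to one.
#'
#' @param assessments list of [symptom_assessment()] objects.
#' @param max_n maximum number of symptoms kept.
#' @return an object of class `weighted_score_spec` with fields
#'   `symptom_id`, `source`, `raw_weight`, `weight` (normalized).
#' @export
select_symptoms <- function(assessments, max_n = 4L) {
  stopifnot(length(assessments) >= 1L)
  raw <- vapply(assessments, function(a) {
    if (isTRUE(a$flagged)) 0 else compute_weight(a$baseline_off, a$baseline_on)
  }, numeric(1))
  if (all(raw == 0)) stop("no responsive symptoms")
  ids <- vapply(assessments, `[[`, character(1), "symptom_id")
  src <- vapply(assessments, `[[`, character(1), "source")
  ord <- order(-raw, src != "clinician", ids)
  keep <- ord[raw[ord] > 0][seq_len(min(max_n, sum(raw > 0)))]
  w <- raw[keep] / sum(raw[keep])
  structure(list(symptom_id = ids[keep], source = src[keep],
                 raw_weight = raw[keep], weight = w,
                 baseline_off = vapply(assessments[keep], `[[`,
                                       numeric(1), "baseline_off")),
            class = "weighted_score_spec")
}

#' @export
print.weighted_score_spec <- function(x, ...) {
  cat("<weighted_score_spec>\n")
  for (i in seq_along(x$symptom_id)) {
    cat(sprintf("  %-28s %-9s raw %.3f  normalized %.3f\n",
                x$symptom_id[i], x$source[i], x$raw_weight[i], x$weight[i]))
  }
  invisible(x)
}

#' Total weighted symptom score
#'
#' The scalar optimizer feedback: the normalized-weight average of the
#' selected symptoms' current 0-4 scores. Lower is better. The
#' side-effect flag is carried through untouched so that score-map
#' boundary handling sees it.
#'
#' @param spec a [select_symptoms()] result.
#' @param scores named numeric (by symptom id) or positional vector of 0-4
#'   scores, one per selected symptom, at 0.1 resolution.
#' @param side_effect logical flag observed with these scores.
#' @return scalar in [0, 4] with attribute `side_effect`.
#' @export
total_weighted_score <- function(spec, scores, side_effect = FALSE) {
  stopifnot(inherits(spec, "weighted_score_spec"))
  if (!is.null(names(scores))) {
    missing <- setdiff(spec$symptom_id, names(scores))
    if (length(missing)) stop("missing symptom score(s): ",
                              paste(missing, collapse = ", "))
    scores <- scores[spec$symptom_id]
  } else if (length(scores) != length(spec$symptom_id)) {
    stop("need one score per selected symptom")
  }
  if (any(scores < 0 | scores > 4)) stop("scores must lie in [0, 4]")
  s <- sum(spec$weight * scores)
  attr(s, "side_effect") <- isTRUE(side_effect)
  s
}
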