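# Bundled fixture scores. Numeric targets, stiffnesses and durations are
# repository constants calibrated to the surrogate plant (chosen so the
# default geometry and formant map reach their calibration ranges); they
# are not transcriptions of any measured utterance.

#' Fixture gestural scores
#'
#' Ready-made scores used by the simulation experiments and examples:
#' a vowel sequence (schwa - low back vowel - high front vowel,
#' tongue-body gestures only), a sustained schwa, vowel-consonant-vowel
#' utterances with a bilabial (`score_aba()`) or tongue-tip
#' (`score_ada()`) closure, and the word "mod" (bilabial closure + velum
#' opening + pharyngeal vowel, then a tongue-tip closure).
#'
#' All gestures use critically damped dynamics with stiffness 400 1/s^2
#' (unit mass), which settles to within 2% of the target in about 0.3 s.
#'
#' @param duration For `score_sustained_schwa()`, total duration (s).
#' @return An `sfc_score`.
#' @name fixture_scores
NULL

gest <- function(task, target, onset, offset, stiffness = 400) {
  data.frame(task = task, target = target, mass = 1, stiffness = stiffness,
             damping = "critical", onset = onset, offset = offset)
}

#' @rdname fixture_scores
#' @export
score_vowel_sequence <- function() {
  gestural_score(rbind(
    gest("TBCD", 1.00, 0.00, 0.35), gest("TBCL", 1.50, 0.00, 0.35),
    gest("TBCD", 0.70, 0.35, 0.75), gest("TBCL", 0.90, 0.35, 0.75),
    gest("TBCD", 0.15, 0.75, 1.10), gest("TBCL", 2.00, 0.75, 1.10)
  ), duration = 1.125)
}

#' @rdname fixture_scores
#' @export
score_sustained_schwa <- function(duration = 1.2) {
  gestural_score(rbind(
    gest("TBCD", 1.00, 0.00, duration), gest("TBCL", 1.50, 0.00, duration)
  ), duration = duration)
}

#' @rdname fixture_scores
#' @export
score_aba <- function() {
  gestural_score(rbind(
    gest("TBCD", 0.70, 0.00, 1.00), gest("TBCL", 0.90, 0.00, 1.00),
    gest("LA", 0.00, 0.35, 0.60)
  ), duration = 1.0)
}

#' @rdname fixture_scores
#' @export
score_ada <- function() {
  gestural_score(rbind(
    gest("TBCD", 0.70, 0.00, 1.00), gest("TBCL", 0.90, 0.00, 1.00),
    gest("TTCD", 0.00, 0.35, 0.60), gest("TTCL", 1.20, 0.35, 0.60)
  ), duration = 1.0)
}

#' @rdname fixture_scores
#' @export
score_mod <- function() {
  gestural_score(rbind(
    gest("LA", 0.00, 0.00, 0.25),
    gest("VEL", 0.50, 0.00, 0.25),
    gest("TBCD", 0.80, 0.00, 0.50),
    gest("TTCD", 0.00, 0.55, 0.80)
  ), duration = 0.85)
}
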