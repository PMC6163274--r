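#' Extract systolic blood pressure from the raw ABP waveform
#'
#' Per-beat SBP is the maximum ABP within the beat, with a parabolic
#' (3-point) vertex refinement so the value does not depend on where the
#' pressure peak falls between samples; the subject-level SBP is the median
#' of the per-beat values. The ABP is used raw: it is the reference
#' measurement and is never filtered.
#'
#' @param abp raw ABP samples, mmHg.
#' @param beats beat list from [segment_beats()].
#' @return Subject SBP, mmHg.
#' @export
extract_sbp <- function(abp, beats) {
  if (length(beats) < 1L) stop("extract_sbp() needs at least one beat")
  per_beat <- vapply(beats, function(b) {
    w <- b$i_start:b$i_end
    i <- w[which.max(abp[w])]
    if (i <= 1L || i >= length(abp)) return(abp[i])
    den <- abp[i - 1L] - 2 * abp[i] + abp[i + 1L]
    if (!is.finite(den) || abs(den) < .Machine$double.eps) return(abp[i])
    abp[i] - (abp[i - 1L] - abp[i + 1L])^2 / (8 * den)
  }, numeric(1))
  stats::median(per_beat)
}

#' Assign a blood-pressure category from SBP
#'
#' Category bands follow the JNC7 systolic thresholds: below
#' `thresh_prehyp` (default 120 mmHg) is normotension, up to but excluding
#' `thresh_hyp` (default 140 mmHg) is prehypertension, and at or above it
#' hypertension. Each lower bound belongs to the higher category.
#'
#' @param sbp systolic pressure(s), mmHg, in (50, 300).
#' @param config a [pipeline_config()] (`thresh_prehyp`, `thresh_hyp`).
#' @return Character vector of categories: `"normotension"`,
#'   `"prehypertension"` or `"hypertension"`.
#' @export
#' @examples
#' label_bp_category(c(119.9, 120, 140))
label_bp_category <- function(sbp, config = pipeline_config()) {
  if (any(!is.finite(sbp)) || any(sbp <= 50) || any(sbp >= 300)) {
    stop("sbp out of the plausible range (50, 300) mmHg")
  }
  ifelse(sbp >= config$thresh_hyp, "hypertension",
         ifelse(sbp >= config$thresh_prehyp, "prehypertension",
                "normotension"))
}
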