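# Shared fixtures and independent oracles used across the suite.

# A clean ordered course: phases 0..7 as constant runs with single-step
# boundaries.
clean_course <- function(frames_per_phase = rep(60L, 8L), fps = 2) {
  annotation_sequence(rep(0:7, times = frames_per_phase), fps = fps,
                      source = "SYNTH")
}

# Literal restatement of the three buffer-state rules, independent of the
# diff-based implementation: one distinct label -> UNIFORM; exactly two
# distinct labels with the window equal to its own sort (every copy of the
# smaller before every copy of the larger) -> TRANSITION; anything else ->
# FLICKER.
oracle_classify <- function(window) {
  distinct <- unique(window)
  if (length(distinct) == 1L) return("UNIFORM")
  if (length(distinct) == 2L && identical(window, sort(window))) {
    return("TRANSITION")
  }
  "FLICKER"
}

# Mann-Whitney pairwise AUC: probability that a random aberrant score
# exceeds a random regular score, ties counted half.
oracle_auc <- function(scores, aberrant) {
  cases <- scores[aberrant]
  controls <- scores[!aberrant]
  cmp <- outer(cases, controls, ">") + 0.5 * outer(cases, controls, "==")
  mean(cmp)
}

# Youden's J at an explicit threshold (higher score => predicted aberrant,
# strict >).
oracle_j <- function(t, scores, aberrant) {
  sens <- mean(scores[aberrant] > t)
  spec <- mean(scores[!aberrant] <= t)
  sens + spec - 1
}

# Maximum attainable J over every candidate threshold (all midpoints plus
# sentinels beyond the observed range).
oracle_max_j <- function(scores, aberrant) {
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  max(vapply(cand, oracle_j, numeric(1), scores = scores,
             aberrant = aberrant))
}
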