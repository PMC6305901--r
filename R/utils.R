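# Internal helpers: seed streams, argument checking, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a root seed
#'
#' All randomness in the package flows from one root seed. Sub-streams
#' (per subject, per trial, per stage) are derived with a fixed integer
#' hash so that changing one stream never perturbs another. The rule is
#' a single step of the MINSTD linear congruential generator applied to
#' `root + key`, which keeps every derived seed in `[1, 2^31 - 2]`.
#'
#' @param root integer root seed.
#' @param key integer stream key (>= 0); distinct keys give distinct,
#'   effectively independent streams.
#' @return an integer seed usable with [set.seed()].
#' @export
child_seed <- function(root, key) {
  stopifnot(is.numeric(root), length(root) == 1, is.finite(root),
            is.numeric(key), length(key) == 1, key >= 0)
  m <- 2147483647  # 2^31 - 1, prime
  x <- (as.numeric(root) %% m + 1) * 48271 %% m
  x <- (x + as.numeric(key) * 69621) %% m
  x <- (x * 48271) %% m
  as.integer(x %% (m - 1) + 1)
}

abort_ps <- function(msg, class, ...) {
  stop(structure(class = c(class, "ps_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

check_scalar_num <- function(x, name, positive = FALSE, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_ps(sprintf("`%s` must be a finite numeric scalar", name),
             "ps_invalid_parameter")
  if (positive && x <= 0)
    abort_ps(sprintf("`%s` must be > 0 (got %g)", name, x),
             "ps_invalid_parameter")
  if (x < min || x > max)
    abort_ps(sprintf("`%s` must be in [%g, %g] (got %g)", name, min, max, x),
             "ps_invalid_parameter")
  invisible(x)
}

match_condition <- function(condition) {
  match.arg(condition, c("predicted", "unpredicted", "cheated"))
}

match_direction <- function(direction) {
  match.arg(direction, c("posterior", "anterior"))
}

match_stim_phase <- function(stim_phase) {
  match.arg(stim_phase, c("none", "SLR", "MLR", "LLR"))
}

#' @keywords internal
ps_muscles <- function() c("SOL", "MG", "TA", "RF", "BF", "GMAX")

#' @keywords internal
ps_phases <- function() c("PRE", "SLR", "MLR", "LLR", "BMR")

# Nearest sample index (1-based) for time t_ms on a grid where index
# `onset_index` corresponds to t = 0 and spacing is 1000/sr ms.
nearest_sample <- function(t_ms, onset_index, sr) {
  as.integer(round(onset_index + t_ms * sr / 1000))
}

# Half-open window [a, b) in ms -> 1-based sample indices on a grid with
# onset at `onset_index` and rate `sr` Hz. Empty windows return integer(0).
window_indices <- function(a_ms, b_ms, onset_index, sr) {
  i0 <- as.integer(ceiling(onset_index + a_ms * sr / 1000 - 1e-9))
  i1 <- as.integer(ceiling(onset_index + b_ms * sr / 1000 - 1e-9)) - 1L
  if (i1 < i0) return(integer(0))
  seq.int(i0, i1)
}
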