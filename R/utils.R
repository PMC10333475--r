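# Internal helpers: units, angles, seeded evaluation.

MMHG_PA <- 133.322  # 1 mmHg in Pa

mmhg_to_pa <- function(x) x * MMHG_PA
pa_to_mmhg <- function(x) x / MMHG_PA

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Angle between two direction vectors, in degrees in [0, 180].
vec_angle <- function(u, v) {
  cu <- u / sqrt(sum(u^2))
  cv <- v / sqrt(sum(v^2))
  rad2deg(acos(pmin(1, pmax(-1, sum(cu * cv)))))
}

# Acute angle between two *lines* (direction sign ignored), degrees in [0, 90].
line_angle <- function(u, v) {
  a <- vec_angle(u, v)
  if (a > 90) 180 - a else a
}

# Evaluate `expr` with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a child seed < 2^31 from a root seed and a stage label.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) + 7919L * (h %% 104729L)) %% 2147483647L
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}
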