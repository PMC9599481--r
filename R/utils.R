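`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' A single master seed fans out to per-stage sub-seeds by a stable arithmetic
#' derivation, so any stage can be re-run in isolation and reproduce its
#' stream. The result is always a valid 32-bit seed.
#'
#' @param seed integer master seed.
#' @param label character stage label, e.g. `"cohort"` or `"split"`.
#' @return An integer in `[0, 2^31)`.
#' @export
sub_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  code <- utf8ToInt(label)
  h <- sum(code * seq_along(code))
  as.integer((abs(seed) * 48271 + h * 9973) %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# Timestamped, stage-scoped, machine-parseable log line.
lpn_log <- function(stage, ...) {
  message(sprintf("[%s] stage=%s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                  paste0(..., collapse = " ")))
}

is_fraction <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
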