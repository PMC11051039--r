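#' @keywords internal
"_PACKAGE"

# Stage offsets for the documented seeding scheme: every source of randomness
# in the pipeline draws from derive_seed(seed, stage[, index]), so a single
# PipelineConfig$seed reproduces the whole run.
.stage_offsets <- c(
  simulate = 11L, rank = 23L, ifs = 37L, smote = 41L,
  fold = 53L, rules = 67L, lasso = 71L, mcfs = 83L
)

#' Derive a per-stage random seed from the pipeline seed
#'
#' Deterministic mixing of the top-level seed with a stage name and an
#' optional index (e.g. fold number or subset number), kept within the
#' 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed integer top-level seed.
#' @param stage stage name: "simulate", "rank", "ifs", "smote", "fold",
#'   "rules", "lasso" or "mcfs".
#' @param index nonnegative integer sub-index (default 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (!stage %in% names(.stage_offsets)) {
    stop("unknown seeding stage: ", stage)
  }
  off <- .stage_offsets[[stage]]
  # mix in 64-bit double space, then fold into [0, 2^31 - 2]
  v <- (abs(seed) %% 2147483647) * 2654435761
  v <- (v + off * 97003 + index * 1013) %% 2147483629
  as.integer(v)
}

# One structured log line per pipeline stage: stage name, elapsed wall time,
# and input/output shapes supplied by the caller.
log_stage <- function(stage, t0, ...) {
  info <- c(...)
  shapes <- if (length(info)) {
    paste(names(info), unname(info), sep = "=", collapse = " ")
  } else ""
  message(sprintf("[ifsmarker] stage=%s elapsed=%.2fs %s",
                  stage, as.numeric(Sys.time()) - as.numeric(t0), shapes))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
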