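# internal helpers: validation, seeding, small numerics

abort_validation <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-stage seed derivation: one user seed fans out to named stage streams so
# stages can be re-run independently; kept below 2^31
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(simulate = 11L, counts = 23L, annotate = 37L, width = 53L,
               entropy = 71L, de = 89L, enrich = 107L, palette = 131L,
               correlate = 151L, bootstrap = 173L)
  if (!stage %in% names(offsets)) {
    abort_validation("unknown seeding stage: ", stage)
  }
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483629)
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

log_msg <- function(...) message("[retcomp] ", ...)
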