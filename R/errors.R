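# Condition helpers. Every user-facing failure mode has a stable condition
# class (seqspace_<kind>) so callers and tests can catch them precisely.

stop_seqspace <- function(kind, msg, ...) {
  abort(msg, class = c(paste0("seqspace_", kind), "seqspace_error"), ...)
}

stop_duplicate_id <- function(msg, ...) stop_seqspace("duplicate_id", msg, ...)
stop_empty_input  <- function(msg, ...) stop_seqspace("empty_input", msg, ...)
stop_format       <- function(msg, ...) stop_seqspace("format", msg, ...)
stop_refinement   <- function(msg, ...) stop_seqspace("refinement", msg, ...)
stop_universe     <- function(msg, ...) stop_seqspace("universe", msg, ...)
stop_dimension    <- function(msg, ...) stop_seqspace("dimension", msg, ...)
stop_coverage     <- function(msg, ...) stop_seqspace("coverage", msg, ...)
stop_tool_not_found <- function(msg, ...) stop_seqspace("tool_not_found", msg, ...)
stop_memory_budget  <- function(msg, ...) stop_seqspace("memory_budget", msg, ...)
stop_parameter      <- function(msg, ...) stop_seqspace("parameter", msg, ...)
stop_external_tool  <- function(msg, ...) stop_seqspace("external_tool", msg, ...)

# Deterministic string hash (31-polynomial mod a Mersenne prime); used to
# derive per-object seeds and stable category colors without any non-base
# dependency. Kept within 2^31 so results are exact in doubles.
str_hash32 <- function(x) {
  vapply(x, function(s) {
    h <- 17
    for (b in utf8ToInt(enc2utf8(s))) {
      h <- (h * 31 + b) %% 2147483647
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# Sub-seed derivation: keep everything inside .Machine$integer.max.
derive_seed <- function(seed, key) {
  as.integer((seed + str_hash32(as.character(key))) %% 2147483647L)
}
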