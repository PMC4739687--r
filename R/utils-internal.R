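# Internal helpers shared across modules. Not exported.

# Require a single finite numeric value, optionally bounded.
check_scalar <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  if (integer && x != as.integer(x)) {
    stop("`", name, "` must be a whole number", call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop("`", name, "` must be in [", lower, ", ", upper, "]", call. = FALSE)
  }
  invisible(x)
}

check_seed <- function(seed) {
  check_scalar(seed, "seed", lower = -2^31 + 1, upper = 2^31 - 1, integer = TRUE)
  as.integer(seed)
}

# All randomness in the package flows through this wrapper so that callers'
# RNG state is never touched and a fixed seed gives byte-identical output.
with_sim_seed <- function(seed, code) {
  withr::with_seed(check_seed(seed), code)
}

# Vectorised base validation for nucleotide arguments.
check_bases <- function(x, name) {
  if (!is.character(x) || any(is.na(x)) || any(!x %in% c("A", "C", "G", "T"))) {
    stop("`", name, "` must contain only A, C, G or T", call. = FALSE)
  }
  invisible(x)
}

# data.frame constructor that never mangles strings or row names.
df <- function(...) data.frame(..., stringsAsFactors = FALSE, row.names = NULL)

# GRanges from a data.frame with scaffold/start/end columns (1-based inclusive).
as_granges <- function(d, seqnames = "scaffold", start = "start", end = "end") {
  GenomicRanges::GRanges(
    seqnames = d[[seqnames]],
    ranges = IRanges::IRanges(start = d[[start]], end = d[[end]])
  )
}
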