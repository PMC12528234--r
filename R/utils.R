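# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483629
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_alignments <- function() {
  data.frame(
    read_id = character(), genome_id = character(), contig = character(),
    start0 = integer(), strand = character(), aligned_length = integer(),
    mismatches = integer(), identity = numeric(),
    stringsAsFactors = FALSE
  )
}

# Validate an alignment table against the ReadAlignment contract.
check_alignments <- function(alignments) {
  required <- c("read_id", "genome_id", "contig", "start0", "strand",
                "aligned_length", "mismatches", "identity")
  if (!is.data.frame(alignments) || !all(required %in% names(alignments))) {
    stop("`alignments` must be a data frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  invisible(alignments)
}
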