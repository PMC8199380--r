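# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_fwctex <- function(msg, class) {
  rlang::abort(msg, class = c(class, "fwctex_error"))
}

# Deterministic sub-stream seed: one base seed fans out to per-patient /
# per-stage streams without correlated draws. Kept below 2^31 - 1.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed) %% 2147483647
  for (id in ids) {
    s <- (s * 48271 + as.double(id) * 16807 + 12345) %% 2147483647
  }
  as.integer(s)
}

# Mirror (reflect-without-repeat) padding of a matrix by r pixels per side.
pad_mirror <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  if (r >= nr || r >= nc) {
    abort_fwctex(
      sprintf("padding radius %d too large for a %d x %d field", r, nr, nc),
      "fwctex_kernel_too_large"
    )
  }
  if (r == 0L) return(x)
  ri <- c(seq(r + 1L, 2L, by = -1L), seq_len(nr), seq(nr - 1L, nr - r, by = -1L))
  ci <- c(seq(r + 1L, 2L, by = -1L), seq_len(nc), seq(nc - 1L, nc - r, by = -1L))
  x[ri, ci, drop = FALSE]
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}
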