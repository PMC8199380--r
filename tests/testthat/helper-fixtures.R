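# shared fixtures and independent oracles

# small, fast cohort configuration for unit tests
tiny_config <- function(...) {
  defaults <- list(n_patients = 10L, image_shape = c(48L, 48L),
                   mutation_available = 6L, seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# independent mirror-padded direct convolution: nested loops, no FFT
direct_convolve_mirror <- function(field, weights) {
  nr <- nrow(field); nc <- ncol(field)
  kr <- (nrow(weights) - 1) / 2
  kc <- (ncol(weights) - 1) / 2
  reflect <- function(i, n) {
    # reflect-without-repeat: ..., 3, 2, |1, 2, ..., n|, n-1, n-2, ...
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      acc <- 0
      for (dr in -kr:kr) {
        for (dc in -kc:kc) {
          acc <- acc + weights[dr + kr + 1, dc + kc + 1] *
            field[reflect(r + dr, nr), reflect(cl + dc, nc)]
        }
      }
      out[r, cl] <- acc
    }
  }
  out
}

dice_coefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# independent permutation oracle: two-sided Mann-Whitney p by complete
# enumeration of all group assignments
enumerate_mw_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x); N <- length(pooled)
  u_of <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(seq_len(m))
  dev <- abs(u_obs - m * (N - m) / 2)
  combos <- utils::combn(N, m)
  us <- apply(combos, 2, u_of)
  mean(abs(us - m * (N - m) / 2) >= dev - 1e-9)
}
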