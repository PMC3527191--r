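# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators route their randomness through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

stop_if_not_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

# Count of 8-connected TRUE neighbours for every cell of a logical matrix.
# Cells beyond the border count as FALSE.
neighbor_count <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  core <- function(dr, dc) {
    m[(2L + dr):(nrow(mask) + 1L + dr), (2L + dc):(ncol(mask) + 1L + dc)]
  }
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  out <- core(-1L, -1L) + core(-1L, 0L) + core(-1L, 1L) +
    core(0L, -1L) + core(0L, 1L) +
    core(1L, -1L) + core(1L, 0L) + core(1L, 1L)
  dimnames(out) <- NULL
  out
}

# Shift a matrix by (dr, dc), padding with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  out <- matrix(fill, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dr
  src_c <- seq_len(ncol(m)) - dc
  ok_r <- src_r >= 1L & src_r <= nrow(m)
  ok_c <- src_c >= 1L & src_c <= ncol(m)
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  out
}
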