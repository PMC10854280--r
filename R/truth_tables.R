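# Internal truth-table conventions.
#
# A function of arity m is stored as a table of 2^m bits.  Row k (1-based)
# holds the output for the assignment whose bits are the binary digits of
# k - 1 with the FIRST input as the most significant bit, i.e. rows follow
# the counting order 00..0, 00..1, ..., 11..1.  The same convention is used
# for network states: x1 is the leftmost character of a printed state string
# and the most significant bit of a state index.

# all 2^m assignments as a 2^m x m integer matrix
tt_rows <- function(m) {
  m <- as.integer(m)
  if (m == 0L) {
    return(matrix(integer(0), nrow = 1L, ncol = 0L))
  }
  cols <- lapply(seq_len(m), function(j) {
    rep(rep(0:1, each = 2L^(m - j)), times = 2L^(j - 1L))
  })
  mat <- do.call(cbind, cols)
  storage.mode(mat) <- "integer"
  mat
}

# 1-based table row index for a 0/1 assignment vector
tt_index <- function(bits) {
  m <- length(bits)
  if (m == 0L) return(1L)
  as.integer(sum(bits * 2L^(m - seq_len(m)))) + 1L
}

# vectorised: rows of a 0/1 matrix -> 1-based table row indices
tt_index_mat <- function(mat) {
  m <- ncol(mat)
  if (m == 0L) return(rep(1L, nrow(mat)))
  as.integer(mat %*% 2L^(m - seq_len(m))) + 1L
}

int_to_bits <- function(i, m) {
  if (m == 0L) return(integer(0))
  bits <- as.integer(intToBits(i))[seq_len(m)]
  rev(bits)
}

check_binary <- function(x, what) {
  if (any(is.na(x)) || !all(x %in% c(0L, 1L))) {
    stop(sprintf("%s must contain only 0/1 values", what), call. = FALSE)
  }
  as.integer(x)
}
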