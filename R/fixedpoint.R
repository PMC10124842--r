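#' Two's-complement fixed-point format
#'
#' All in-circuit arithmetic uses `m`-qubit two's-complement registers with `p`
#' fractional bits, i.e. a register holds an integer `v` in
#' `[-2^(m-1), 2^(m-1) - 1]` representing the value `v * 2^-p`.
#'
#' @param m Total number of bits (integer >= 1).
#' @param p Number of fraction bits (integer >= 0, at most `m - 1`).
#' @return An object of class `fixed_point_format` with fields `m` and `p`.
#' @examples
#' fmt <- fixed_point_format(9, 5)
#' fp_encode(-3.8125, fmt)
#' @export
fixed_point_format <- function(m, p = 0L) {
  m <- as.integer(m)
  p <- as.integer(p)
  if (is.na(m) || m < 1L) stop("'m' must be an integer >= 1")
  if (is.na(p) || p < 0L) stop("'p' must be an integer >= 0")
  if (m < p + 1L) stop("total width m must be at least p + 1")
  if (m > 30L) stop("register widths above 30 bits are not supported")
  structure(list(m = m, p = p), class = "fixed_point_format")
}

#' @export
print.fixed_point_format <- function(x, ...) {
  cat(sprintf("<fixed point: m = %d bits, p = %d fraction bits, range [%s, %s], ulp %g>\n",
              x$m, x$p, format(fp_min(x)), format(fp_max(x)), 2^-x$p))
  invisible(x)
}

fp_min <- function(fmt) -(2^(fmt$m - 1)) / 2^fmt$p
fp_max <- function(fmt) (2^(fmt$m - 1) - 1) / 2^fmt$p

#' Round a value onto the fixed-point grid
#'
#' Rounds to the nearest multiple of `2^-p`, with ties rounded away from zero.
#' This is the rounding rule used throughout: the classical energy model and the
#' in-circuit multiplier quantize identically, so gate-level and reference
#' energies agree bit for bit.
#'
#' @param x Numeric vector.
#' @param p Number of fraction bits.
#' @return `x` rounded onto the `2^-p` grid.
#' @examples
#' quantize(0.01, 5)   # 0: nearest multiple of 1/32
#' quantize(-3.8, 5)
#' @export
quantize <- function(x, p) {
  scale <- 2^p
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Quantize toward -Inf on the 2^-p grid (used only for MR thresholds, which are
# deliberately floored so the grid boundary never admits extra answer states).
quantize_floor <- function(x, p) floor(x * 2^p) / 2^p

# Exact scaled-integer representation; errors if off-grid or out of range.
fp_to_int <- function(value, fmt) {
  iv <- value * 2^fmt$p
  if (any(abs(iv - round(iv)) > 1e-9))
    stop(sprintf("value %s is not representable with %d fraction bits",
                 format(value[which.max(abs(iv - round(iv)))]), fmt$p))
  iv <- round(iv)
  lo <- -(2^(fmt$m - 1)); hi <- 2^(fmt$m - 1) - 1
  if (any(iv < lo | iv > hi))
    stop(sprintf("value %s out of range for a %d-bit two's-complement register",
                 format(value[which(iv < lo | iv > hi)[1]]), fmt$m))
  iv
}

int_to_bitstring <- function(v, m) {
  bits <- integer(m)
  for (j in m:1) {
    bits[j] <- v %% 2
    v <- v %/% 2
  }
  paste(bits, collapse = "")
}

bitstring_to_bits <- function(s) as.integer(strsplit(s, "", fixed = TRUE)[[1]])
bits_to_bitstring <- function(bits) paste(bits, collapse = "")

#' Encode a fixed-point value as a two's-complement bitstring
#'
#' @param value Value on the `2^-p` grid, within the format's range.
#' @param fmt A [fixed_point_format()].
#' @return A bitstring of length `m`, most-significant bit first.
#' @examples
#' fp_encode(-4, fixed_point_format(4))   # "1100"
#' @export
fp_encode <- function(value, fmt) {
  iv <- fp_to_int(value, fmt)
  if (iv < 0) iv <- iv + 2^fmt$m
  int_to_bitstring(iv, fmt$m)
}

#' Decode a two's-complement bitstring to its fixed-point value
#'
#' @param bits Bitstring of length `m` (or an integer 0/1 vector).
#' @param fmt A [fixed_point_format()].
#' @return The represented value, exact on the `2^-p` grid.
#' @export
fp_decode <- function(bits, fmt) {
  if (is.character(bits)) bits <- bitstring_to_bits(bits)
  if (length(bits) != fmt$m) stop("bit width does not match the format")
  iv <- sum(bits * 2^((fmt$m - 1):0))
  if (iv >= 2^(fmt$m - 1)) iv <- iv - 2^fmt$m
  iv / 2^fmt$p
}
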