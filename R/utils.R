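#' @keywords internal
"_PACKAGE"

# numeric guard used for singular denominators (Pa scale)
.EPS_PA <- 1e-12

#' Round half-up to a fixed number of decimals
#'
#' Base R `round()` rounds half to even; clinical tables conventionally round
#' half up (0.05 -> 0.1). Used for cohort percentage reporting.
#'
#' @param x numeric vector
#' @param digits decimal places (default 1)
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

vec_norm <- function(m) {
  if (is.matrix(m)) sqrt(rowSums(m * m)) else sqrt(sum(m * m))
}

normalize <- function(v) {
  n <- sqrt(sum(v * v))
  stop_if_not(n > 0, "cannot normalize a zero vector")
  v / n
}

# cross products of rows of two n x 3 matrices
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Derive a stream of distinct 31-bit sub-seeds from one master seed.
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
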