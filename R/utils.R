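# Shared numeric helpers.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all reported rates and
#' percentages. `round()` in R rounds half to even, which would print
#' 0.0667 as 0.07 but 0.125 as 0.12; reported tables use half-up.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vuscope <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "vuscope_error", "error", "condition")))
}

# Parameter validation used across generators and analyzers.
check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_vuscope("`%s` must be a probability in [0, 1]", name,
                 class = "vuscope_parameter_error")
  x
}

# Euclidean distance matrix between two coordinate matrices (n x 3, m x 3).
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) v / vnorm(v)
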