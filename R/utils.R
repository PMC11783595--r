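#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim rnorm rpois runif sd median coef lm dnorm
#' @importFrom utils read.csv write.csv head tail
NULL

# Convert a Gaussian full width at half maximum to its standard deviation.
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Evaluate an expression with a temporarily seeded RNG, restoring the
# caller's RNG state afterwards so generators are pure functions of their
# seed argument.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Scaled complementary error function exp(x^2) erfc(x), finite for all
# x >= 0: direct evaluation below x = 25, asymptotic continued expansion
# 1/(x sqrt(pi)) (1 - 1/(2x^2) + 3/(4x^4) - 15/(8x^6)) beyond, where the
# direct form overflows.
erfcx_safe <- function(x) {
  out <- numeric(length(x))
  small <- x < 25
  if (any(small)) out[small] <- pracma::erfcx(x[small])
  if (any(!small)) {
    xl <- x[!small]
    ix2 <- 1 / (2 * xl^2)
    out[!small] <- (1 - ix2 + 3 * ix2^2 - 15 * ix2^3) / (xl * sqrt(pi))
  }
  out
}

# Unit-amplitude exponential decay exp(-k t) * step(t), analytically
# convolved with a unit-area Gaussian of width sigma. Stabilized with the
# scaled complementary error function where the naive form overflows
# (sigma << 1/k regime): exp(A) erfc(B) = erfcx(B) exp(-t^2 / (2 sigma^2))
# since A - B^2 = -t^2/(2 sigma^2).
exp_gauss <- function(t, k, sigma) {
  if (sigma <= 0) {
    return(ifelse(t >= 0, exp(-k * t), 0))
  }
  B <- (sigma * k - t / sigma) / sqrt(2)
  out <- numeric(length(t))
  pos <- B >= 0
  if (any(pos)) {
    out[pos] <- 0.5 * erfcx_safe(B[pos]) * exp(-t[pos]^2 / (2 * sigma^2))
  }
  if (any(!pos)) {
    tn <- t[!pos]
    out[!pos] <- 0.5 * exp(sigma^2 * k^2 / 2 - k * tn) * pracma::erfc(B[!pos])
  }
  out
}

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
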