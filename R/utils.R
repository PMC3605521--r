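# Shared numeric policy: relative tolerance for identities, absolute at zero.
.nb_tol <- list(rel = 1e-10, abs = 1e-12)

#' Geometric mean
#'
#' @param x strictly positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @export
geomean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stream seed derived from a master seed; kept < 2^31.
.nb_substream <- function(seed, k) {
  as.integer((as.double(seed) + 104729 * as.double(k)) %% 2147483629)
}
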