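#' Compositions on the simplex
#'
#' A composition is a vector of strictly positive parts carrying only relative
#' information, closed so that its parts sum to a constant kappa (the unit or
#' scale of measurement: 1 for fractions, 100 for percent, 1000 for g/kg dry
#' matter). `composition()` validates and closes a raw concentration vector;
#' [closure()] is the underlying operator.
#'
#' @param values strictly positive numeric vector of part concentrations.
#' @param labels part names; defaults to `names(values)` or `part1..partD`.
#' @param kappa closure constant (> 0).
#' @param unit unit annotation attached to kappa, e.g. `"unitless"`, `"%"`,
#'   `"g/kg"`. Bookkeeping only; never triggers implicit conversion.
#' @param close if `FALSE`, require `values` to already sum to kappa.
#' @return an object of class `composition`: a named numeric vector with
#'   attributes `kappa` and `unit`.
#' @examples
#' composition(c(N = 2.50, P = 0.15), kappa = 2.65, unit = "%")
#' @export
composition <- function(values, labels = NULL, kappa = sum(values),
                        unit = "unitless", close = TRUE) {
  labels <- labels %||% names(values) %||% paste0("part", seq_along(values))
  v <- as.numeric(values)
  if (length(v) < 2L) stop("a composition needs at least D = 2 parts")
  if (length(labels) != length(v)) stop("labels must match the number of parts")
  if (anyDuplicated(labels)) stop("part labels must be unique")
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    stop("kappa must be a single positive number")
  }
  bad <- which(!is.finite(v) | v <= 0)
  if (length(bad)) {
    stop("parts must be strictly positive; offending part(s): ",
         paste(labels[bad], collapse = ", "))
  }
  if (close) {
    v <- v * (kappa / sum(v))
  } else if (abs(sum(v) - kappa) > 1e-12 * kappa) {
    stop("parts do not sum to kappa and close = FALSE")
  }
  structure(stats::setNames(v, labels), kappa = kappa, unit = unit,
            class = "composition")
}

#' Closure operator
#'
#' Rescales a positive vector so its parts sum to `kappa`. Idempotent: closing
#' an already-closed composition returns it unchanged.
#'
#' @inheritParams composition
#' @return a [composition()].
#' @export
closure <- function(values, kappa = 1, labels = NULL, unit = "unitless") {
  if (length(values) == 0L) stop("cannot close an empty vector")
  composition(values, labels = labels, kappa = kappa, unit = unit)
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("<composition> D = %d, kappa = %g (%s)\n",
              length(x), attr(x, "kappa"), attr(x, "unit")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Kappa and unit accessors
#' @param x a composition or composition table.
#' @return the closure constant / unit annotation.
#' @export
comp_kappa <- function(x) attr(x, "kappa")

#' @rdname comp_kappa
#' @export
comp_unit <- function(x) attr(x, "unit")

#' Filling value
#'
#' The unanalysed remainder of the tissue mass: the difference between the
#' measurement scale kappa and the sum of analytical results. Appending it
#' closes the vector to kappa exactly.
#'
#' @param concentrations positive numeric vector on the kappa scale.
#' @param kappa measurement scale (e.g. 1000 g/kg dry matter, 100 %).
#' @return the scalar filling value, strictly positive.
#' @examples
#' filling_value(c(N = 25, P = 1.5, K = 10, Ca = 15, Mg = 2), kappa = 1000)
#' @export
filling_value <- function(concentrations, kappa) {
  s <- sum(concentrations)
  if (s >= kappa) {
    stop(sprintf(paste0("sum of concentrations (%g) is not below kappa (%g); ",
                        "no strictly positive filling value exists - check the ",
                        "measurement unit or kappa"), s, kappa))
  }
  kappa - s
}

#' Append a filling value part
#'
#' @inheritParams filling_value
#' @param unit unit annotation.
#' @param label name of the filling-value part.
#' @return a [composition()] over the original parts plus `label`, closed to
#'   kappa without rescaling the measured parts.
#' @export
with_filling_value <- function(concentrations, kappa, unit = "unitless",
                               label = "Fv") {
  fv <- filling_value(concentrations, kappa)
  v <- c(concentrations, stats::setNames(fv, label))
  composition(v, kappa = kappa, unit = unit, close = FALSE)
}

#' Additive log-ratio transform
#'
#' `alr` expresses each part as the natural log of its ratio to a chosen
#' denominator part: entry j is `ln(c_j / c_denom)`. Invariant to the closure
#' constant. Coordinates are oblique (not orthonormal), which is why distances
#' are never computed on alr values here.
#'
#' @param comp a [composition()], or a matrix/table via methods.
#' @param denominator label of the denominator part.
#' @param ... passed to methods.
#' @return named numeric vector of length D-1; names are `"num/denom"`.
#' @examples
#' alr(composition(c(N = 2.50, P = 0.15)), denominator = "N")  # P/N = -2.81
#' @export
alr <- function(comp, denominator, ...) UseMethod("alr")

#' @rdname alr
#' @export
alr.composition <- function(comp, denominator = names(comp)[length(comp)], ...) {
  if (!denominator %in% names(comp)) {
    stop("unknown denominator part: ", denominator)
  }
  num <- setdiff(names(comp), denominator)
  stats::setNames(log(as.numeric(comp[num]) / as.numeric(comp[denominator])),
                  paste0(num, "/", denominator))
}

#' Centered log-ratio transform
#'
#' Each part over the geometric mean of all parts, logged. The D clr values
#' sum to zero, so clr covariance matrices are singular; clr is used here as
#' the SBP-free route to Aitchison geometry.
#'
#' @inheritParams alr
#' @return named numeric vector of length D summing to 0.
#' @export
clr <- function(comp, ...) UseMethod("clr")

#' @rdname clr
#' @export
clr.composition <- function(comp, ...) {
  lv <- log(as.numeric(comp))
  stats::setNames(lv - mean(lv), names(comp))
}

#' Ratio combinatorics of a D-part ionome
#'
#' A D-part composition generates D(D-1)/2 dual ratios (x/y) and D(D-1)^2/2
#' amalgamated ratios (x over a sum of one or more other parts, excluding the
#' duals), yet carries only D-1 degrees of freedom: the motivation for working
#' with D-1 orthonormal balances instead of raw ratios.
#'
#' @param D integer number of parts, >= 2.
#' @return object of class `ratio_counts`: list with `D`, `dual`,
#'   `amalgamated`, `dof`.
#' @examples
#' count_ratios(10)  # 45 dual, 405 amalgamated, 9 dof
#' @export
count_ratios <- function(D) {
  D <- as.integer(D)
  if (length(D) != 1L || is.na(D) || D < 2L) stop("D must be an integer >= 2")
  structure(list(D = D,
                 dual = as.integer(D * (D - 1L) / 2),
                 amalgamated = as.integer(D * (D - 1L)^2 / 2),
                 dof = D - 1L),
            class = "ratio_counts")
}

#' @export
print.ratio_counts <- function(x, ...) {
  cat(sprintf("D = %d parts: %d dual ratios, %d amalgamated ratios, %d dof\n",
              x$D, x$dual, x$amalgamated, x$dof))
  invisible(x)
}

#' Multiplicative replacement of below-detection values
#'
#' Compositions must be strictly positive; zeros are rejected by the
#' constructors. This optional preprocessing hook replaces zeros (or values
#' below a stated detection limit) by `fraction * detection_limit` and rescales
#' the remaining parts multiplicatively so the total is preserved.
#'
#' @param values numeric vector, possibly containing zeros.
#' @param detection_limit user-supplied detection limit (same scale as values).
#' @param fraction multiplier applied to the detection limit (default 0.65, a
#'   common choice for rounded zeros).
#' @return strictly positive vector with the same sum.
#' @export
replace_below_detection <- function(values, detection_limit, fraction = 0.65) {
  if (detection_limit <= 0) stop("detection_limit must be positive")
  repl <- fraction * detection_limit
  low <- values < detection_limit
  if (!any(low)) return(values)
  if (any(values[!low] <= 0)) stop("values above the detection limit must be positive")
  total <- sum(values)
  mass <- repl * sum(low)
  if (mass >= total) stop("replacement mass exceeds the vector total; lower the detection limit")
  out <- values
  out[low] <- repl
  out[!low] <- values[!low] * (total - mass) / sum(values[!low])
  out
}

#' Explicit unit conversion
#'
#' Converts between percent dry mass and g/kg dry matter (factor 10).
#' Conversion is always explicit: statistics on raw concentrations depend on
#' the measurement scale, so silent rescaling is never performed.
#'
#' @param comp a [composition()].
#' @param to `"%"` or `"g/kg"`.
#' @return a composition on the new scale with kappa converted accordingly.
#' @export
convert_unit <- function(comp, to = c("%", "g/kg")) {
  to <- match.arg(to)
  from <- comp_unit(comp)
  if (!from %in% c("%", "g/kg")) {
    stop("conversion defined only between '%' and 'g/kg'; composition has unit '",
         from, "'")
  }
  if (from == to) return(comp)
  f <- if (to == "g/kg") 10 else 0.1
  composition(as.numeric(comp) * f, labels = names(comp),
              kappa = comp_kappa(comp) * f, unit = to, close = FALSE)
}
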