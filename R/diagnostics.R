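#' Anderson-Darling test for normality
#'
#' Composite-hypothesis version: mean and variance are estimated from the
#' sample, the statistic is corrected by `(1 + 0.75/n + 2.25/n^2)` (Stephens'
#' small-sample modification) and the p-value uses the standard case-3
#' piecewise-exponential approximation. Deterministic; requires n >= 8.
#'
#' @param x numeric sample, n >= 8, finite, non-constant.
#' @return list of class `nb_adtest` with `statistic` (uncorrected A^2),
#'   `statistic_mod` (corrected A*^2 used for the p-value), `p.value`, `n`.
#' @export
anderson_darling <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("sample contains non-finite values")
  n <- length(x)
  if (n < 8L) stop("Anderson-Darling test requires n >= 8, got ", n)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate sample: zero variance")
  z <- stats::pnorm((sort(x) - mean(x)) / s)
  # guard the log tails against underflow on extreme standardized values
  z <- pmin(pmax(z, .Machine$double.xmin), 1 - .Machine$double.eps)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(z) + log(1 - rev(z))))
  A2m <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (A2m >= 0.6) {
    exp(1.2937 - 5.709 * A2m + 0.0186 * A2m^2)
  } else if (A2m > 0.34) {
    exp(0.9177 - 4.279 * A2m - 1.38 * A2m^2)
  } else if (A2m > 0.2) {
    1 - exp(-8.318 + 42.796 * A2m - 59.938 * A2m^2)
  } else {
    1 - exp(-13.436 + 101.14 * A2m - 223.73 * A2m^2)
  }
  structure(list(statistic = A2, statistic_mod = A2m,
                 p.value = min(max(p, 0), 1), n = n),
            class = "nb_adtest")
}

#' @export
print.nb_adtest <- function(x, ...) {
  cat(sprintf("Anderson-Darling: A^2 = %.4f (modified %.4f), n = %d, p = %.4g\n",
              x$statistic, x$statistic_mod, x$n, x$p.value))
  invisible(x)
}

#' Data representations of a composition table
#'
#' Returns the samples x variables matrix used by the diagnostic and
#' discriminant stages: `raw` (concentrations as stored), `log` (their
#' natural logs), `alr`, `clr`, or `ilr` balances. A filling-value part
#' (named `"Fv"` by default) is excluded from the raw, log, alr and clr
#' variables: it is the unanalysed remainder, not a nutrient, and keeping it
#' would make raw variables of a closed table exactly collinear. The ilr
#' representation is driven entirely by the SBP's part labels (which may
#' themselves include the filling value).
#'
#' @param table a [composition_table()].
#' @param sbp SBP (required for `ilr`).
#' @param representation one of `"raw"`, `"log"`, `"alr"`, `"clr"`, `"ilr"`.
#' @param alr_denominator denominator part for `alr` (default: last retained
#'   part).
#' @param filling_label part name treated as the filling value (default
#'   `"Fv"`); set to `NULL` to keep every part.
#' @return numeric matrix with sample ids as rownames.
#' @export
representation_matrix <- function(table, sbp = NULL,
                                  representation = c("ilr", "raw", "log",
                                                     "alr", "clr"),
                                  alr_denominator = NULL,
                                  filling_label = "Fv") {
  representation <- match.arg(representation)
  m <- part_matrix(table)
  if (representation == "ilr") {
    if (is.null(sbp)) stop("an SBP is required for the ilr representation")
    return(ilr(table, sbp))
  }
  keep <- colnames(m)
  if (!is.null(filling_label) && filling_label %in% keep &&
      length(keep) > 2L) {
    keep <- setdiff(keep, filling_label)
  }
  m <- m[, keep, drop = FALSE]
  switch(representation,
         raw = m,
         log = log(m),
         alr = {
           denom <- alr_denominator %||% keep[length(keep)]
           if (!denom %in% keep) stop("unknown denominator part: ", denom)
           num <- setdiff(keep, denom)
           out <- log(m[, num, drop = FALSE] / m[, denom])
           colnames(out) <- paste0(num, "/", denom)
           out
         },
         clr = log(m) - rowMeans(log(m)))
}

#' Normality across data representations
#'
#' Runs the Anderson-Darling test on every (variable, group) cell of each
#' requested representation and reports the fraction of cells not rejected at
#' `alpha` ("flagged normal"). With ionomes that are Gaussian in balance
#' coordinates, the ilr fraction is expected near 1 - alpha while raw and
#' ordinary-log fractions fall as skew grows.
#'
#' @param table a [composition_table()] (a missing group column is treated as
#'   one pooled group).
#' @param sbp SBP for the ilr representation.
#' @param alpha significance level (default 0.01).
#' @param representations subset of `c("raw","log","alr","ilr")`.
#' @param alr_denominator passed to [representation_matrix()].
#' @return list of class `normality_report`: `tests` (tidy data.frame:
#'   representation, group, variable, A2, p, normal), `aggregate`
#'   (representation, n_tests, fraction_normal), `alpha`. Groups smaller than
#'   8 are skipped with a warning.
#' @export
normality_by_representation <- function(table, sbp = NULL, alpha = 0.01,
                                        representations = c("raw", "log",
                                                            "alr", "ilr"),
                                        alr_denominator = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  groups <- table_groups(table) %||% rep("all", nrow(table))
  rows <- list()
  for (rep_ in representations) {
    m <- representation_matrix(table, sbp, rep_, alr_denominator)
    for (g in unique(groups)) {
      sub <- m[groups == g, , drop = FALSE]
      if (nrow(sub) < 8L) {
        warning(sprintf("group '%s' has n = %d < 8; skipped in normality tests",
                        g, nrow(sub)))
        next
      }
      for (v in colnames(sub)) {
        res <- tryCatch(anderson_darling(sub[, v]), error = function(e) {
          warning(sprintf("representation %s, group %s, variable %s: %s",
                          rep_, g, v, conditionMessage(e)))
          NULL
        })
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          representation = rep_, group = g, variable = v,
          A2 = res$statistic, p = res$p.value, normal = res$p.value > alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  tests <- do.call(rbind, rows) %||%
    data.frame(representation = character(0), group = character(0),
               variable = character(0), A2 = numeric(0), p = numeric(0),
               normal = logical(0), stringsAsFactors = FALSE)
  aggregate <- do.call(rbind, lapply(representations, function(rep_) {
    sub <- tests[tests$representation == rep_, , drop = FALSE]
    data.frame(representation = rep_, n_tests = nrow(sub),
               fraction_normal = if (nrow(sub)) mean(sub$normal) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(tests = tests, aggregate = aggregate, alpha = alpha),
            class = "normality_report")
}

#' Scale dependency of raw-data correlations
#'
#' Recomputes the Pearson correlation matrix of a table under two or more
#' closure scales (optionally embedding the measured parts into a larger total
#' via a filling value) and summarises how coefficients change. Raw-part
#' correlations are artefacts of the chosen scale - coefficients change in
#' magnitude, significance and even sign - whereas any log-ratio
#' representation gives identical matrices under every scale.
#'
#' @param table a [composition_table()]; for a Table-2-style dry-matter vs
#'   nutrient-sum contrast, supply the full dry-matter composition including
#'   the filling value and select the nutrient subcomposition in one scale.
#' @param scales list of scale specs, each a list with `kappa` (closure
#'   constant), optional `parts` (subcomposition to keep before re-closing;
#'   default all parts) and optional `label`.
#' @param representation `"raw"`, `"log"`, `"clr"` or `"ilr"` (log-ratio
#'   choices demonstrate scale invariance).
#' @param sbp SBP when `representation = "ilr"` (applied to its own parts).
#' @return list of class `scale_report`: `matrices` (named list of correlation
#'   matrices), `p_values` (same shape), `delta` (max |difference| per pair
#'   across scales, over the parts common to all scales), `sign_flip`
#'   (logical matrix), `scales`.
#' @export
scale_dependency <- function(table, scales, representation = "raw",
                             sbp = NULL) {
  if (length(scales) < 2L) stop("at least two closure scales are required")
  if (nrow(table) < 3L) stop("insufficient data: need at least 3 samples")
  mats <- list()
  ps <- list()
  for (k in seq_along(scales)) {
    sc <- scales[[k]]
    label <- sc$label %||% paste0("kappa", sc$kappa)
    if (label %in% names(mats)) label <- paste0(label, "_", k)
    m <- part_matrix(table)
    if (!is.null(sc$parts)) {
      missing <- setdiff(sc$parts, colnames(m))
      if (length(missing)) stop("unknown part(s) in scale spec: ",
                                paste(missing, collapse = ", "))
      m <- m[, sc$parts, drop = FALSE]
    }
    tab_k <- composition_table(m, kappa = sc$kappa, unit = comp_unit(table),
                               group = table_groups(table),
                               sample_id = table$sample_id)
    x <- switch(representation,
                raw = part_matrix(tab_k),
                log = log(part_matrix(tab_k)),
                clr = clr(tab_k),
                ilr = {
                  if (is.null(sbp)) stop("an SBP is required for ilr")
                  keep <- intersect(attr(tab_k, "parts"), sbp$part_labels)
                  ilr(composition_table(part_matrix(tab_k)[, keep, drop = FALSE],
                                        kappa = 1, group = table_groups(tab_k),
                                        sample_id = tab_k$sample_id), sbp)
                },
                stop("unknown representation: ", representation))
    mats[[label]] <- stats::cor(x)
    n <- nrow(x)
    r <- mats[[label]]
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
    diag(pv) <- 0
    ps[[label]] <- pv
  }
  common <- Reduce(intersect, lapply(mats, colnames))
  ref <- mats[[1]][common, common, drop = FALSE]
  delta <- Reduce(pmax, lapply(mats, function(m) {
    abs(m[common, common, drop = FALSE] - ref)
  }))
  sign_flip <- Reduce(`|`, lapply(mats, function(m) {
    sign(m[common, common, drop = FALSE]) * sign(ref) < 0
  }))
  structure(list(matrices = mats, p_values = ps, delta = delta,
                 sign_flip = sign_flip, scales = scales,
                 representation = representation),
            class = "scale_report")
}

#' Robust multivariate outlier screening
#'
#' Squared Mahalanobis distances from a minimum covariance determinant (MCD)
#' location/scatter fit, compared against the chi-square quantile at
#' `1 - alpha` with as many degrees of freedom as coordinates. Screening is
#' meant to run on ilr balances (raw-space Mahalanobis inherits the closure
#' biases); the returned mask is never applied silently.
#'
#' @param coords numeric matrix of coordinates (samples x variables), e.g.
#'   from [representation_matrix()].
#' @param alpha significance level of the cutoff (default 0.01).
#' @param seed optional integer fixing the MCD subsampling.
#' @return list of class `outlier_mask`: `distance` (squared robust
#'   Mahalanobis), `cutoff`, `flagged` (logical), `alpha`, `df`, `center`,
#'   `cov`.
#' @export
robust_outliers <- function(coords, alpha = 0.01, seed = NULL) {
  x <- as.matrix(coords)
  n <- nrow(x); d <- ncol(x)
  if (n <= d + 1L) stop("need n > dimension + 1 (got n = ", n, ", d = ", d, ")")
  fit <- tryCatch({
    if (!is.null(seed)) {
      withr_seed <- function(expr) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        set.seed(seed)
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        expr
      }
      withr_seed(MASS::cov.rob(x, method = "mcd"))
    } else {
      MASS::cov.rob(x, method = "mcd")
    }
  }, error = function(e) {
    stop("robust covariance estimation failed (", conditionMessage(e),
         "); check for collinear or constant coordinates, or reduce dimension")
  })
  if (rcond(fit$cov) < 1e-12) {
    stop("degenerate robust covariance (near-singular); remove collinear ",
         "coordinates or use fewer balances")
  }
  d2 <- stats::mahalanobis(x, fit$center, fit$cov)
  cutoff <- stats::qchisq(1 - alpha, df = d)
  structure(list(distance = stats::setNames(d2, rownames(x)), cutoff = cutoff,
                 flagged = d2 > cutoff, alpha = alpha, df = d,
                 center = fit$center, cov = fit$cov),
            class = "outlier_mask")
}

#' Per-group robust outlier screening on a composition table
#'
#' Discriminant analysis assumes within-group ellipsoids, so screening is
#' per-group by default; set `pool = TRUE` to screen the pooled table.
#'
#' @param table a [composition_table()].
#' @param sbp SBP for the default ilr representation.
#' @param representation coordinates to screen on (default `"ilr"`).
#' @param alpha cutoff level.
#' @param pool screen all samples together instead of per group.
#' @param seed passed to [robust_outliers()].
#' @return data.frame (sample_id, group, distance, cutoff, flagged).
#' @export
screen_outliers <- function(table, sbp = NULL, representation = "ilr",
                            alpha = 0.01, pool = FALSE, seed = NULL) {
  m <- representation_matrix(table, sbp, representation)
  groups <- table_groups(table) %||% rep("all", nrow(table))
  if (pool) groups <- rep("all", nrow(table))
  res <- lapply(unique(groups), function(g) {
    idx <- groups == g
    om <- robust_outliers(m[idx, , drop = FALSE], alpha = alpha, seed = seed)
    data.frame(sample_id = table$sample_id[idx], group = g,
               distance = as.numeric(om$distance), cutoff = om$cutoff,
               flagged = om$flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[match(table$sample_id, out$sample_id), , drop = FALSE]
}
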