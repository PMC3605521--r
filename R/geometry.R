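#' Aitchison distance between two compositions
#'
#' The Euclidean distance between ilr coordinate vectors. Because every valid
#' SBP yields an orthonormal basis of the same space, the distance does not
#' depend on the SBP choice, nor on the closure constants of the inputs.
#'
#' @param a,b [composition()]s over the same parts.
#' @param sbp optional SBP; when omitted the distance is computed as the
#'   Euclidean distance between clr vectors, which is identical.
#' @return nonnegative scalar.
#' @export
aitchison_distance <- function(a, b, sbp = NULL) {
  if (!identical(names(a), names(b))) {
    stop("compositions must share part labels in the same order")
  }
  if (is.null(sbp)) return(sqrt(sum((clr(a) - clr(b))^2)))
  sqrt(sum((ilr(a, sbp) - ilr(b, sbp))^2))
}

#' Aitchison norm
#'
#' The Euclidean norm of the ilr coordinate vector; equals the Aitchison
#' distance to the barycenter (equal-part composition), whose ilr vector is
#' null.
#'
#' @inheritParams aitchison_distance
#' @return nonnegative scalar.
#' @export
aitchison_norm <- function(a, sbp = NULL) {
  if (is.null(sbp)) return(sqrt(sum(clr(a)^2)))
  sqrt(sum(ilr(a, sbp)^2))
}

#' Bias of the ordinary log-Euclidean distance
#'
#' The squared Euclidean distance between ln-transformed compositions always
#' exceeds the squared Aitchison distance by `D * (ln(g(x)/g(y)))^2`, where
#' g() is the geometric mean of the closed parts: treating ordinary log
#' concentrations as Euclidean inflates distances unless the two samples share
#' a geometric mean. Both compositions must be on a single declared closure
#' scale, since the bias term (unlike the Aitchison distance) depends on it.
#'
#' @param a,b [composition()]s over the same parts.
#' @param kappa optional closure constant: both compositions are re-closed to
#'   it. If omitted, the compositions must already share a kappa; mixing
#'   scales silently is refused.
#' @param ids length-2 identifier for the pair (defaults to "a","b").
#' @return a one-row data.frame of class `distance_report` with columns
#'   `id_a`, `id_b`, `aitchison`, `log_euclidean`, `bias_term`
#'   (`log_euclidean^2 == aitchison^2 + bias_term`).
#' @export
log_euclidean_bias <- function(a, b, kappa = NULL, ids = c("a", "b")) {
  if (!identical(names(a), names(b))) {
    stop("compositions must share part labels in the same order")
  }
  if (is.null(kappa)) {
    if (abs(comp_kappa(a) - comp_kappa(b)) > 1e-12 * comp_kappa(a)) {
      stop("compositions are closed to different kappas (", comp_kappa(a),
           " vs ", comp_kappa(b), "); pass an explicit kappa to re-close")
    }
    kappa <- comp_kappa(a)
  }
  x <- as.numeric(a) * (kappa / sum(as.numeric(a)))
  y <- as.numeric(b) * (kappa / sum(as.numeric(b)))
  D <- length(x)
  eps <- sqrt(sum((log(x) - log(y))^2))
  ait <- sqrt(sum((clr(a) - clr(b))^2))
  bias <- D * (log(geomean(x) / geomean(y)))^2
  structure(data.frame(id_a = ids[1], id_b = ids[2], aitchison = ait,
                       log_euclidean = eps, bias_term = bias,
                       stringsAsFactors = FALSE),
            class = c("distance_report", "data.frame"))
}

#' Pairwise distance matrices over a composition table
#'
#' @param table a [composition_table()].
#' @param sbp optional SBP. When supplied, both metrics are computed on the
#'   SBP's subcomposition (its parts re-closed to the table's kappa), so the
#'   Aitchison and log-Euclidean entries of a report refer to the same
#'   sample space; otherwise all parts are used as stored.
#' @param metric `"aitchison"`, `"log_euclidean"`, or `"both"`.
#' @return list with symmetric zero-diagonal matrices (one per requested
#'   metric, sample ids as dimnames) and, for `"both"`, `reports`: a long-form
#'   data.frame (id_a, id_b, aitchison, log_euclidean, bias_term) over all
#'   unordered pairs.
#' @export
pairwise_distances <- function(table, sbp = NULL,
                               metric = c("both", "aitchison", "log_euclidean")) {
  metric <- match.arg(metric)
  ids <- table$sample_id
  m <- part_matrix(table)
  if (!is.null(sbp)) {
    if (!inherits(sbp, "sbp")) sbp <- sbp_validate(sbp)
    m <- m[, sbp$part_labels, drop = FALSE]
    m <- m * (attr(table, "kappa") / rowSums(m))
    psi <- sbp_to_basis(sbp)$psi
    A <- as.matrix(stats::dist(log(m) %*% t(psi)))
  } else {
    lm <- log(m)
    A <- as.matrix(stats::dist(lm - rowMeans(lm)))
  }
  dimnames(A) <- list(ids, ids)
  out <- list()
  if (metric != "log_euclidean") out$aitchison <- A
  if (metric != "aitchison") {
    E <- as.matrix(stats::dist(log(m)))
    dimnames(E) <- list(ids, ids)
    out$log_euclidean <- E
  }
  if (metric == "both") {
    pr <- which(upper.tri(A), arr.ind = TRUE)
    D <- length(attr(table, "parts"))
    out$reports <- data.frame(
      id_a = ids[pr[, 1]], id_b = ids[pr[, 2]],
      aitchison = A[pr], log_euclidean = out$log_euclidean[pr],
      bias_term = out$log_euclidean[pr]^2 - A[pr]^2,
      stringsAsFactors = FALSE)
  }
  out
}

#' Within-group distance summary
#'
#' Per-group distributional summary (median, quartiles) of all within-group
#' pairwise Aitchison and log-Euclidean distances: the tabular counterpart of
#' a per-species boxplot contrasting the two metrics.
#'
#' @param table a grouped [composition_table()].
#' @param sbp optional SBP.
#' @return data.frame with one row per (group, metric).
#' @export
distance_summary <- function(table, sbp = NULL) {
  groups <- table_groups(table)
  if (is.null(groups)) stop("table has no group column")
  res <- lapply(unique(groups), function(g) {
    sub <- table_subset(table, groups == g)
    if (nrow(sub) < 2L) return(NULL)
    pd <- pairwise_distances(sub, sbp, metric = "both")
    do.call(rbind, lapply(c("aitchison", "log_euclidean"), function(mt) {
      v <- pd$reports[[mt]]
      data.frame(group = g, metric = mt, n_pairs = length(v),
                 q25 = as.numeric(stats::quantile(v, 0.25)),
                 median = stats::median(v),
                 q75 = as.numeric(stats::quantile(v, 0.75)),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, res)
}

#' Write pairwise distances to CSV
#'
#' `write_distance_long()` writes the per-pair report
#' (id_a, id_b, aitchison, log_euclidean, bias_term);
#' `write_distance_matrix()` writes one square matrix.
#'
#' @param pd result of [pairwise_distances()] with `metric = "both"`.
#' @param path output CSV.
#' @export
write_distance_long <- function(pd, path) {
  utils::write.csv(pd$reports, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_long
#' @param which matrix to write (`"aitchison"` or `"log_euclidean"`).
#' @export
write_distance_matrix <- function(pd, path, which = "aitchison") {
  m <- pd[[which]]
  utils::write.csv(data.frame(sample_id = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
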