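#' Canonical discriminant analysis
#'
#' Classical CDA: eigen-decomposition of the pooled within-group scatter
#' against the between-group scatter. With W the within-group covariance
#' (unbiased, divisor n - g) and B the between-group covariance (divisor
#' g - 1), the canonical axes a solve `W^{-1} B a = lambda a`, normalized to
#' unit within-group variance (`a' W a = 1`) and ordered by decreasing
#' eigenvalue. Each axis is oriented so its largest-magnitude loading is
#' positive. Scores are the centered inputs projected on the retained axes
#' (at most `min(g - 1, p)`).
#'
#' @param x numeric matrix or data.frame of input variables (samples x p).
#' @param groups group labels (length = rows of x), at least 2 groups, each
#'   with more samples than variables.
#' @return object of class `cda_model`: list with `loadings` (p x k),
#'   `eigenvalues` (length k), `scores` (n x k), `group_means` (canonical
#'   space), `grand_mean`, `W`, `B`, `groups`, `group_levels`, `n_per_group`,
#'   `variables`.
#' @export
fit_cda <- function(x, groups) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  groups <- as.character(groups)
  if (length(groups) != nrow(x)) stop("groups must have one label per row")
  lev <- unique(groups)
  g <- length(lev)
  n <- nrow(x); p <- ncol(x)
  if (g < 2L) stop("need at least 2 groups")
  nk <- table(factor(groups, levels = lev))
  small <- names(nk)[nk <= p]
  if (length(small)) {
    stop("group(s) smaller than dimension + 1: ", paste(small, collapse = ", "))
  }
  grand <- colMeans(x)
  means <- do.call(rbind, lapply(lev, function(l) colMeans(x[groups == l, , drop = FALSE])))
  rownames(means) <- lev
  W <- matrix(0, p, p)
  for (l in lev) {
    xc <- sweep(x[groups == l, , drop = FALSE], 2, means[l, ])
    W <- W + crossprod(xc)
  }
  W <- W / (n - g)
  B <- matrix(0, p, p)
  for (l in lev) {
    d <- means[l, ] - grand
    B <- B + nk[[l]] * tcrossprod(d)
  }
  B <- B / (g - 1)

  singular_msg <- function() {
    vr <- apply(x, 2, stats::var)
    hint <- colnames(x)[vr < 1e-12]
    paste0("pooled within-group scatter is singular",
           if (length(hint)) paste0(" (constant variable(s): ",
                                    paste(hint, collapse = ", "), ")")
           else " (collinear variables)")
  }
  if (rcond(W) < 1e-12) stop(singular_msg())
  R <- tryCatch(chol(W), error = function(e) stop(singular_msg()))
  Ri <- backsolve(R, diag(p))
  M <- crossprod(Ri, B %*% Ri)
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  k <- min(g - 1L, p)
  lambda <- pmax(eig$values[seq_len(k)], 0)
  A <- Ri %*% eig$vectors[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive on every axis
  for (j in seq_len(k)) {
    if (A[which.max(abs(A[, j])), j] < 0) A[, j] <- -A[, j]
  }
  dimnames(A) <- list(colnames(x), paste0("can", seq_len(k)))
  scores <- sweep(x, 2, grand) %*% A
  gm <- do.call(rbind, lapply(lev, function(l) {
    colMeans(scores[groups == l, , drop = FALSE])
  }))
  rownames(gm) <- lev
  structure(list(loadings = A, eigenvalues = lambda, scores = scores,
                 group_means = gm, grand_mean = grand, W = W, B = B,
                 groups = groups, group_levels = lev,
                 n_per_group = as.integer(nk), variables = colnames(x)),
            class = "cda_model")
}

#' @export
print.cda_model <- function(x, ...) {
  cat(sprintf("<cda_model> %d groups, %d variables, %d canonical axes\n",
              length(x$group_levels), length(x$variables),
              ncol(x$loadings)))
  cat("eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}

#' Project new samples onto canonical axes and classify
#'
#' @param object a [fit_cda()] model.
#' @param newdata matrix with the model's variables.
#' @param ... unused.
#' @return list with `scores` and `class` (nearest group mean in canonical
#'   space; Euclidean distance there equals within-group Mahalanobis distance
#'   restricted to the discriminant subspace).
#' @export
predict.cda_model <- function(object, newdata, ...) {
  m <- as.matrix(newdata)[, object$variables, drop = FALSE]
  sc <- sweep(m, 2, object$grand_mean) %*% object$loadings
  d2 <- sapply(object$group_levels, function(l) {
    rowSums(sweep(sc, 2, object$group_means[l, ])^2)
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1,
                                     dimnames = list(NULL, object$group_levels))
  list(scores = sc, class = object$group_levels[max.col(-d2)])
}

#' Discriminant analysis across data representations
#'
#' Fits one CDA per requested representation of the same samples. The alr and
#' ilr representations differ by an invertible linear map, to which CDA is
#' invariant: their eigenvalues and cross-validated misclassification
#' coincide. Raw and ordinary-log representations have no such guarantee.
#'
#' @param table a grouped [composition_table()].
#' @param sbp SBP for the ilr representation.
#' @param representations subset of `c("raw","log","alr","ilr")`.
#' @param groups group labels; defaults to the table's group column.
#' @param alr_denominator passed to [representation_matrix()].
#' @return named list of `cda_model`s, one per representation.
#' @export
compare_representations <- function(table, sbp = NULL,
                                    representations = c("raw", "log",
                                                        "alr", "ilr"),
                                    groups = NULL, alr_denominator = NULL) {
  groups <- groups %||% table_groups(table)
  if (is.null(groups)) stop("no group labels available")
  out <- lapply(representations, function(rep_) {
    fit_cda(representation_matrix(table, sbp, rep_, alr_denominator), groups)
  })
  stats::setNames(out, representations)
}

#' Confidence ellipses in the canonical plane
#'
#' For each group, in the plane of two canonical axes: a `data_95` ellipse
#' from the group score covariance scaled by the chi-square quantile
#' (2 df, level) - asymptotically enclosing `level` of that group's score
#' distribution - and a `mean_confidence_95` ellipse with the covariance
#' further divided by n, so its radii shrink with sqrt(n). Two mean ellipses
#' are reported as overlapping when the distance between centers is below the
#' sum of their radii along the center-to-center direction (a conservative
#' directional test, not an exact one).
#'
#' @param model a [fit_cda()] model with >= 2 axes.
#' @param level coverage level (default 0.95).
#' @param axes which two canonical axes (default 1:2).
#' @return list of class `ellipse_set`: `ellipses` (data.frame: group, kind,
#'   center_x, center_y, semi_major, semi_minor, angle (radians), n) and
#'   `mean_overlap` (logical symmetric matrix across groups).
#' @export
confidence_ellipses <- function(model, level = 0.95, axes = c(1L, 2L)) {
  if (ncol(model$scores) < 2L) stop("need at least 2 canonical axes for ellipses")
  q <- stats::qchisq(level, df = 2)
  rows <- list()
  covs <- list(); centers <- list(); ns <- list()
  for (l in model$group_levels) {
    sc <- model$scores[model$groups == l, axes, drop = FALSE]
    n <- nrow(sc)
    if (n < 3L) {
      warning("group '", l, "' has n < 3; no ellipse computed")
      next
    }
    S <- stats::cov(sc)
    e <- eigen(S, symmetric = TRUE)
    ang <- atan2(e$vectors[2, 1], e$vectors[1, 1])
    ctr <- colMeans(sc)
    for (kind in c("data_95", "mean_confidence_95")) {
      f <- if (kind == "data_95") q else q / n
      rows[[length(rows) + 1L]] <- data.frame(
        group = l, kind = kind, center_x = ctr[1], center_y = ctr[2],
        semi_major = sqrt(pmax(e$values[1], 0) * f),
        semi_minor = sqrt(pmax(e$values[2], 0) * f),
        angle = ang, n = n, stringsAsFactors = FALSE)
    }
    covs[[l]] <- S; centers[[l]] <- ctr; ns[[l]] <- n
  }
  lv <- names(centers)
  ov <- matrix(NA, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i == j) { ov[i, j] <- TRUE; next }
    d <- centers[[j]] - centers[[i]]
    len <- sqrt(sum(d^2))
    if (len == 0) { ov[i, j] <- TRUE; next }
    u <- d / len
    ri <- sqrt(q / ns[[i]] * drop(t(u) %*% covs[[i]] %*% u))
    rj <- sqrt(q / ns[[j]] * drop(t(u) %*% covs[[j]] %*% u))
    ov[i, j] <- len < ri + rj
  }
  structure(list(ellipses = do.call(rbind, rows), mean_overlap = ov,
                 level = level, axes = axes),
            class = "ellipse_set")
}

#' Cross-validated misclassification rate
#'
#' Leave-one-out (default) or k-fold cross-validation of the CDA
#' nearest-group-mean classifier. Deterministic given `seed` and the fold
#' specification.
#'
#' @param x input matrix (samples x variables).
#' @param groups group labels.
#' @param folds number of folds, or `NULL` for leave-one-out.
#' @param seed integer seed used to shuffle samples into folds (ignored for
#'   leave-one-out).
#' @return misclassification rate in \[0, 1\].
#' @export
cv_misclassification <- function(x, groups, folds = NULL, seed = 1L) {
  x <- as.matrix(x)
  groups <- as.character(groups)
  n <- nrow(x)
  if (is.null(folds)) {
    assign_fold <- seq_len(n)
    nf <- n
  } else {
    nf <- as.integer(folds)
    set.seed(seed)
    assign_fold <- sample(rep_len(seq_len(nf), n))
  }
  wrong <- 0L
  for (f in seq_len(nf)) {
    test <- assign_fold == f
    fit <- fit_cda(x[!test, , drop = FALSE], groups[!test])
    pred <- predict(fit, x[test, , drop = FALSE])$class
    wrong <- wrong + sum(pred != groups[test])
  }
  wrong / n
}

#' Write discriminant outputs
#'
#' Writes scores, loadings, eigenvalues and ellipse parameters as CSV and a
#' figure-ready JSON bundle for a canonical-plane panel.
#'
#' @param model a [fit_cda()] model.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix (e.g. the representation tag).
#' @param level ellipse coverage level.
#' @return invisibly, the paths written.
#' @export
write_cda <- function(model, dir, prefix = "cda", level = 0.95) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    scores = file.path(dir, paste0(prefix, "_scores.csv")),
    loadings = file.path(dir, paste0(prefix, "_loadings.csv")),
    eigenvalues = file.path(dir, paste0(prefix, "_eigenvalues.csv")),
    ellipses = file.path(dir, paste0(prefix, "_ellipses.csv")),
    json = file.path(dir, paste0(prefix, "_panel.json")))
  utils::write.csv(data.frame(sample_id = rownames(model$scores) %||%
                                seq_len(nrow(model$scores)),
                              group = model$groups, model$scores,
                              check.names = FALSE),
                   paths["scores"], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(variable = rownames(model$loadings),
                              model$loadings, check.names = FALSE),
                   paths["loadings"], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(axis = seq_along(model$eigenvalues),
                              eigenvalue = model$eigenvalues),
                   paths["eigenvalues"], row.names = FALSE, quote = FALSE)
  ell <- if (ncol(model$scores) >= 2 && min(table(model$groups)) >= 3) {
    confidence_ellipses(model, level = level)
  } else NULL
  if (!is.null(ell)) {
    utils::write.csv(ell$ellipses, paths["ellipses"], row.names = FALSE,
                     quote = FALSE)
  }
  jsonlite::write_json(
    list(eigenvalues = model$eigenvalues,
         groups = model$group_levels,
         scores = data.frame(group = model$groups, model$scores),
         ellipses = if (!is.null(ell)) ell$ellipses else NULL),
    paths["json"], dataframe = "columns", digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
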