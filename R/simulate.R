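#' Group specification for ionome simulation
#'
#' One group (species, cultivar) is a Gaussian cloud in ilr balance space:
#' the logistic-normal model under which log-ratio coordinates - not raw
#' concentrations - are the natural Gaussian scale.
#'
#' @param label group label.
#' @param mean_ilr mean balance vector (length D-1, SBP row order).
#' @param cov_ilr (D-1) x (D-1) symmetric positive-definite covariance.
#' @param n number of samples (>= 2).
#' @return list of class `group_spec`.
#' @export
group_spec <- function(label, mean_ilr, cov_ilr, n) {
  mean_ilr <- as.numeric(mean_ilr)
  cov_ilr <- as.matrix(cov_ilr)
  if (n < 2L) stop("group '", label, "': n must be >= 2")
  ev <- tryCatch(eigen(cov_ilr, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) -1)
  if (!isTRUE(all.equal(cov_ilr, t(cov_ilr), check.attributes = FALSE)) ||
      any(ev < -1e-12 * max(abs(ev), 1))) {
    stop("group '", label, "': cov_ilr must be symmetric positive semi-definite")
  }
  if (length(mean_ilr) != nrow(cov_ilr)) {
    stop("group '", label, "': mean and covariance dimensions differ")
  }
  structure(list(label = label, mean_ilr = mean_ilr, cov_ilr = cov_ilr,
                 n = as.integer(n)),
            class = "group_spec")
}

#' Simulation specification
#'
#' @param sbp SBP over the nutrient parts (defines the balance order of the
#'   group means).
#' @param groups list of [group_spec()]s sharing the SBP's dimension.
#' @param kappa,unit closure scale of the emitted table.
#' @param fv_fraction optional mean filling-value mass fraction in (0, 1):
#'   when set, the nutrient subcomposition is embedded into dry matter by
#'   drawing the \[nutrients | Fv\] balance as a Gaussian around the value
#'   implied by this fraction. Either a single number shared by all groups or
#'   a named vector with one entry per group label.
#' @param fv_sd standard deviation of the filling-value balance (default 0.1).
#' @param seed master seed; each group draws from its own derived stream, so
#'   adding a group never perturbs existing groups.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(sbp, groups, kappa = 100, unit = "%",
                            fv_fraction = NULL, fv_sd = 0.1, seed = 1L) {
  if (!inherits(sbp, "sbp")) sbp <- sbp_validate(sbp)
  d <- length(sbp$part_labels) - 1L
  ok <- vapply(groups, function(g) length(g$mean_ilr) == d, logical(1))
  if (!all(ok)) stop("all group specs must have mean vectors of length ", d)
  labs <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("group labels must be unique")
  if (!is.null(fv_fraction)) {
    if (any(fv_fraction <= 0 | fv_fraction >= 1)) {
      stop("fv_fraction must be in (0, 1)")
    }
    if (length(fv_fraction) > 1L && !all(labs %in% names(fv_fraction))) {
      stop("per-group fv_fraction must be named with every group label")
    }
  }
  structure(list(sbp = sbp, groups = groups, kappa = kappa, unit = unit,
                 fv_fraction = fv_fraction, fv_sd = fv_sd,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# SBP over parts + Fv whose first row balances all nutrients against Fv,
# followed by the original rows padded with a 0 for Fv (the Table-1 style
# "Optional" embedding). Balances among the nutrients are unchanged by it.
.sbp_with_fv <- function(sbp) {
  D <- length(sbp$part_labels)
  sbp_validate(rbind(c(rep(1, D), -1), cbind(sbp$matrix, 0)),
               part_labels = c(sbp$part_labels, "Fv"))
}

#' Simulate multi-group ionomes
#'
#' Draws each group's balance vectors from its Gaussian, back-transforms via
#' the inverse ilr map and closes to kappa, so simulated concentrations are
#' strictly positive and exactly closed by construction. With
#' `fv_fraction` set, a sixth part `Fv` is added through the
#' \[nutrients | Fv\] balance and the table is emitted over parts + Fv.
#'
#' @param spec a [simulation_spec()].
#' @return list of class `ionome_sim`: `table` (a [composition_table()] with
#'   group labels) and `truth` (per-group means/covariances in ilr space, the
#'   mean compositions, seeds, and the SBP actually used).
#' @export
simulate_ionomes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  use_fv <- !is.null(spec$fv_fraction)
  sbp_out <- if (use_fv) .sbp_with_fv(spec$sbp) else spec$sbp
  blocks <- list()
  truth_groups <- list()
  for (k in seq_along(spec$groups)) {
    gs <- spec$groups[[k]]
    sk <- .nb_substream(spec$seed, k)
    set.seed(sk)
    z <- MASS::mvrnorm(gs$n, mu = gs$mean_ilr, Sigma = gs$cov_ilr)
    z <- matrix(z, nrow = gs$n)
    if (use_fv) {
      f <- if (length(spec$fv_fraction) > 1L) {
        spec$fv_fraction[[gs$label]]
      } else {
        spec$fv_fraction
      }
      # mean [nutrients | Fv] balance implied by the mean composition and f
      zmean <- ilr_inverse(gs$mean_ilr, spec$sbp, kappa = 1)
      D <- length(zmean)
      mu0 <- sqrt(D / (D + 1)) * log((1 - f) * geomean(as.numeric(zmean)) / f)
      b0 <- stats::rnorm(gs$n, mu0, spec$fv_sd)
      z <- cbind(b0, z)
    }
    comp <- ilr_inverse(z, sbp_out, kappa = spec$kappa, unit = spec$unit)
    m <- part_matrix(comp)
    blocks[[k]] <- m
    truth_groups[[gs$label]] <- list(
      mean_ilr = gs$mean_ilr, cov_ilr = gs$cov_ilr, n = gs$n, seed = sk,
      mean_composition = as.numeric(ilr_inverse(gs$mean_ilr, spec$sbp,
                                                kappa = spec$kappa)))
  }
  m <- do.call(rbind, blocks)
  group <- rep(vapply(spec$groups, `[[`, character(1), "label"),
               vapply(spec$groups, `[[`, integer(1), "n"))
  tab <- composition_table(m, kappa = spec$kappa, unit = spec$unit,
                           group = group, close = FALSE)
  structure(list(table = tab,
                 truth = list(groups = truth_groups, seed = spec$seed,
                              sbp = sbp_out, kappa = spec$kappa,
                              fv_fraction = spec$fv_fraction)),
            class = "ionome_sim")
}

#' Simulation spec JSON round trip
#'
#' @param spec a [simulation_spec()].
#' @param path JSON file.
#' @export
simulation_spec_to_json <- function(spec, path) {
  jsonlite::write_json(
    list(part_labels = spec$sbp$part_labels,
         sbp = apply(spec$sbp$matrix, 1, as.list),
         groups = lapply(spec$groups, function(g) {
           list(label = g$label, mean_ilr = g$mean_ilr,
                cov_ilr = apply(g$cov_ilr, 1, as.list), n = g$n)
         }),
         kappa = spec$kappa, unit = spec$unit,
         fv_fraction = if (!is.null(spec$fv_fraction)) as.list(spec$fv_fraction),
         fv_sd = spec$fv_sd,
         seed = spec$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname simulation_spec_to_json
#' @export
simulation_spec_from_json <- function(path) {
  o <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  sbp <- sbp_validate(as.matrix(o$sbp), part_labels = o$part_labels)
  groups <- lapply(seq_len(nrow(o$groups)), function(i) {
    g <- o$groups[i, ]
    group_spec(g$label, unlist(g$mean_ilr),
               as.matrix(g$cov_ilr[[1]]), g$n)
  })
  fv <- o$fv_fraction
  if (!is.null(fv)) fv <- unlist(fv)
  simulation_spec(sbp, groups, kappa = o$kappa, unit = o$unit,
                  fv_fraction = fv, fv_sd = o$fv_sd %||% 0.1,
                  seed = o$seed)
}

# Mean leaf nutrient profiles (percent dry mass) used by the preset panel.
# Chosen once from typical published foliar survey ranges for each crop;
# the two wild species carry low-Ca, ericaceous-type signatures.
.panel_profiles <- function() {
  rbind(
    kiwifruit  = c(N = 2.50, P = 0.20, K = 2.50, Ca = 3.00, Mg = 0.35),
    guava      = c(N = 2.00, P = 0.14, K = 1.60, Ca = 1.00, Mg = 0.25),
    orange     = c(N = 2.70, P = 0.14, K = 1.20, Ca = 4.00, Mg = 0.30),
    mango      = c(N = 1.20, P = 0.10, K = 0.60, Ca = 2.50, Mg = 0.20),
    apple      = c(N = 2.20, P = 0.20, K = 1.40, Ca = 1.20, Mg = 0.25),
    cranberry  = c(N = 1.00, P = 0.10, K = 0.45, Ca = 0.70, Mg = 0.20),
    blueberry  = c(N = 1.70, P = 0.12, K = 0.45, Ca = 0.45, Mg = 0.17),
    cloudberry = c(N = 2.30, P = 0.25, K = 1.40, Ca = 0.35, Mg = 0.27))
}

#' Preset eight-species ionome panel
#'
#' A documented default simulation over (N, P, K, Ca, Mg) with the
#' knowledge-driven SBP of [default_ionome_sbp()]: six domesticated fruit
#' crops and two wild species whose balance signatures form a separate
#' super-cluster (low Ca relative to the mobile macronutrients). Group means
#' are the ilr images of fixed leaf-tissue concentration profiles; the
#' within-group covariance is diagonal with sd 0.15 per balance, a typical
#' field-survey spread on the log-ratio scale; n = 150 per group. Each
#' species' nutrients are embedded in leaf dry matter through a filling
#' value whose mean fraction is one minus that species' total nutrient
#' content, so emitted tables carry six parts (N, P, K, Ca, Mg, Fv) in
#' percent dry mass and the raw nutrient columns are not sum-constrained.
#'
#' @param seed master seed.
#' @param n_per_group samples per group (default 150).
#' @return a [simulation_spec()] with attributes `wild` (the wild group
#'   labels) and `min_wild_mahalanobis` (the smallest Mahalanobis distance,
#'   under the declared within-group covariance, between any wild and any
#'   domesticated group mean - the declared effect size separating the
#'   super-clusters).
#' @export
preset_species_panel <- function(seed = 42L, n_per_group = 150L) {
  sbp <- default_ionome_sbp()
  prof <- .panel_profiles()
  sd_b <- 0.15
  cov_ilr <- diag(sd_b^2, 4)
  groups <- lapply(rownames(prof), function(sp) {
    comp <- composition(prof[sp, ], kappa = 100, unit = "%")
    group_spec(sp, ilr(comp, sbp), cov_ilr, n_per_group)
  })
  fv <- 1 - rowSums(prof) / 100
  spec <- simulation_spec(sbp, groups, kappa = 100, unit = "%",
                          fv_fraction = fv, fv_sd = 0.05, seed = seed)
  wild <- c("blueberry", "cloudberry")
  means <- do.call(rbind, lapply(groups, `[[`, "mean_ilr"))
  rownames(means) <- rownames(prof)
  dom <- setdiff(rownames(prof), wild)
  dmin <- min(outer(wild, dom, Vectorize(function(w, d) {
    sqrt(stats::mahalanobis(means[w, ], means[d, ], cov_ilr))
  })))
  attr(spec, "wild") <- wild
  attr(spec, "min_wild_mahalanobis") <- dmin
  spec
}
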