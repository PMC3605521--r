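#' Pipeline run configuration
#'
#' @param input path to a composition CSV, or a [composition_table()].
#' @param sbp path to an SBP CSV/JSON, an `sbp` object, or `NULL` for
#'   [default_ionome_sbp()].
#' @param outdir output directory.
#' @param kappa,unit closure scale applied when reading CSV input.
#' @param representations representations carried through diagnostics and
#'   discriminant analysis.
#' @param alpha_outlier,alpha_normality significance levels.
#' @param outlier_representation coordinates used for outlier screening
#'   (default `"ilr"`).
#' @param pool_outliers screen pooled instead of per group.
#' @param seed integer seed for all stochastic stages.
#' @param decimal decimal separator for CSV input.
#' @param log_level `"quiet"`, `"info"` or `"json"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(input, outdir, sbp = NULL, kappa = 100, unit = "%",
                       representations = c("raw", "log", "alr", "ilr"),
                       alpha_outlier = 0.01, alpha_normality = 0.01,
                       outlier_representation = "ilr", pool_outliers = FALSE,
                       seed = 1L, decimal = ".", log_level = "info") {
  for (a in c(alpha_outlier, alpha_normality)) {
    if (!(a > 0 && a < 1)) stop("alpha levels must lie in (0, 1)")
  }
  bad <- setdiff(representations, c("raw", "log", "alr", "clr", "ilr"))
  if (length(bad)) stop("unknown representation(s): ", paste(bad, collapse = ", "))
  if (is.character(input) && !file.exists(input)) {
    stop("input path does not exist: ", input)
  }
  structure(list(input = input, outdir = outdir, sbp = sbp, kappa = kappa,
                 unit = unit, representations = representations,
                 alpha_outlier = alpha_outlier,
                 alpha_normality = alpha_normality,
                 outlier_representation = outlier_representation,
                 pool_outliers = pool_outliers, seed = as.integer(seed),
                 decimal = decimal, log_level = log_level),
            class = "run_config")
}

.nb_log <- function(cfg, stage, msg) {
  if (cfg$log_level == "quiet") return(invisible())
  if (cfg$log_level == "json") {
    message(jsonlite::toJSON(list(stage = stage, message = msg),
                             auto_unbox = TRUE))
  } else {
    message(sprintf("[%s] %s", stage, msg))
  }
}

.resolve_sbp <- function(sbp) {
  if (is.null(sbp)) return(default_ionome_sbp())
  if (inherits(sbp, "sbp")) return(sbp)
  if (is.character(sbp)) {
    if (grepl("\\.json$", sbp)) return(sbp_from_json(sbp))
    return(sbp_from_csv(sbp))
  }
  sbp_validate(sbp)
}

#' Run the full diagnostic pipeline
#'
#' Stages, in order: read and close the table, robust outlier screening on
#' balance coordinates, normality diagnostics per representation, pairwise
#' distance summary (Aitchison vs log-Euclidean), discriminant analysis per
#' representation with confidence ellipses. Every artifact is written under
#' `outdir` together with a manifest (input hash, seed, package version,
#' parameters, outputs) so a run is a pure function of (input bytes, config,
#' seed). A stage failure leaves earlier artifacts intact.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  sbp <- .resolve_sbp(config$sbp)
  manifest <- list(package = "nutribalance",
                   version = as.character(utils::packageVersion("nutribalance")),
                   seed = config$seed,
                   parameters = config[c("kappa", "unit", "representations",
                                         "alpha_outlier", "alpha_normality",
                                         "outlier_representation",
                                         "pool_outliers")],
                   outputs = character(0))
  # manifest records outdir-relative paths so identical runs into different
  # directories produce identical manifests
  rel <- function(p) sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1",
                                          config$outdir), "/?"), "", p)
  add_output <- function(p) manifest$outputs <<- c(manifest$outputs, rel(p))

  .nb_log(config, "read", "loading composition table")
  if (inherits(config$input, "composition_table")) {
    tab <- config$input
    manifest$input <- list(kind = "in-memory", n = nrow(tab))
  } else {
    tab <- read_composition_table(config$input, kappa = config$kappa,
                                  unit = config$unit, decimal = config$decimal)
    manifest$input <- list(kind = "csv", path = config$input,
                           md5 = unname(tools::md5sum(config$input)),
                           n = nrow(tab))
  }
  sbp_path <- file.path(config$outdir, "sbp.csv")
  sbp_to_csv(sbp, sbp_path); add_output(sbp_path)

  .nb_log(config, "outliers", sprintf("robust screening (%s, alpha = %g)",
                                      config$outlier_representation,
                                      config$alpha_outlier))
  mask <- screen_outliers(tab, sbp,
                          representation = config$outlier_representation,
                          alpha = config$alpha_outlier,
                          pool = config$pool_outliers, seed = config$seed)
  p <- file.path(config$outdir, "outliers.csv")
  utils::write.csv(mask, p, row.names = FALSE, quote = FALSE); add_output(p)
  kept <- table_subset(tab, !mask$flagged)
  manifest$outliers <- list(flagged = sum(mask$flagged), kept = nrow(kept))

  .nb_log(config, "normality", "Anderson-Darling across representations")
  nr <- suppressWarnings(
    normality_by_representation(kept, sbp, alpha = config$alpha_normality,
                                representations = config$representations))
  p <- file.path(config$outdir, "normality_tests.csv")
  utils::write.csv(nr$tests, p, row.names = FALSE, quote = FALSE); add_output(p)
  p <- file.path(config$outdir, "normality_summary.json")
  jsonlite::write_json(list(alpha = nr$alpha, aggregate = nr$aggregate),
                       p, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  add_output(p)

  .nb_log(config, "distance", "Aitchison vs log-Euclidean summary")
  if (!is.null(table_groups(kept))) {
    ds <- distance_summary(kept, sbp)
    p <- file.path(config$outdir, "distance_summary.csv")
    utils::write.csv(ds, p, row.names = FALSE, quote = FALSE); add_output(p)
  }

  groups <- table_groups(kept)
  if (!is.null(groups) && length(unique(groups)) >= 2) {
    .nb_log(config, "da", paste("canonical discriminant analysis:",
                                paste(config$representations, collapse = ", ")))
    models <- compare_representations(kept, sbp,
                                      representations = config$representations)
    for (rep_ in names(models)) {
      paths <- write_cda(models[[rep_]], file.path(config$outdir, "da"),
                         prefix = rep_)
      for (pp in paths) add_output(pp)
    }
    manifest$da <- lapply(models, function(m) {
      list(eigenvalues = m$eigenvalues,
           cv_misclassification = NA)
    })
  } else {
    .nb_log(config, "da", "skipped: fewer than 2 groups")
  }

  p <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       null = "null")
  .nb_log(config, "done", paste("manifest:", p))
  invisible(manifest)
}

# ---- Command-line interface ------------------------------------------------

.cli_spec_opts <- function() {
  list(
    optparse::make_option("--sbp", type = "character", default = NULL,
                          help = "SBP CSV/JSON [default: built-in 5-nutrient SBP]"),
    optparse::make_option("--kappa", type = "double", default = 100,
                          help = "closure constant [default %default]"),
    optparse::make_option("--unit", type = "character", default = "%",
                          help = "unit annotation [default %default]"),
    optparse::make_option("--decimal", type = "character", default = ".",
                          help = "decimal separator [default '.']"),
    optparse::make_option(c("-o", "--out"), type = "character",
                          default = "nutribalance_out",
                          help = "output file/directory"))
}

.cli_read <- function(opts, input) {
  read_composition_table(input, kappa = opts$kappa, unit = opts$unit,
                         decimal = opts$decimal)
}

#' Command-line entry point
#'
#' Subcommands: `transform` (write a chosen representation of a composition
#' CSV), `distance` (pairwise Aitchison / log-Euclidean distances),
#' `diagnose` (outlier + normality reports), `da` (discriminant analysis),
#' `simulate` (synthetic panel from a JSON spec or the preset), `run` (full
#' pipeline). Invoke via the installed `exec/nutribalance` script or
#' `Rscript -e 'nutribalance::nutribalance_main()' args...`.
#'
#' @param argv character vector of arguments (default: command line).
#' @return integer exit status (0 on success), invisibly.
#' @export
nutribalance_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: nutribalance <transform|distance|diagnose|da|simulate|run>",
                 "[options] [input.csv]")
  if (length(argv) < 1L) { message(usage); return(invisible(2L)) }
  cmd <- argv[1]
  rest <- argv[-1]
  status <- tryCatch({
    switch(cmd,
           transform = .cli_transform(rest),
           distance = .cli_distance(rest),
           diagnose = .cli_diagnose(rest),
           da = .cli_da(rest),
           simulate = .cli_simulate(rest),
           run = .cli_run(rest),
           { message(usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status %||% 0L))
}

.cli_transform <- function(args) {
  opts_def <- c(.cli_spec_opts(), list(
    optparse::make_option("--representation", type = "character",
                          default = "ilr",
                          help = "raw|log|alr|clr|ilr [default %default]")))
  pa <- optparse::parse_args(optparse::OptionParser(option_list = opts_def),
                             args = args, positional_arguments = 1)
  tab <- .cli_read(pa$options, pa$args[1])
  sbp <- .resolve_sbp(pa$options$sbp)
  m <- representation_matrix(tab, sbp, pa$options$representation)
  colnames(m) <- gsub(" \\| ", "_vs_", gsub("[][]", "", colnames(m)))
  colnames(m) <- gsub("[^A-Za-z0-9_./]", ".", colnames(m))
  out <- data.frame(sample_id = tab$sample_id, check.names = FALSE)
  if (!is.null(table_groups(tab))) out$group <- table_groups(tab)
  utils::write.csv(cbind(out, as.data.frame(m)), pa$options$out,
                   row.names = FALSE, quote = FALSE)
  0L
}

.cli_distance <- function(args) {
  opts_def <- c(.cli_spec_opts(), list(
    optparse::make_option("--metric", type = "character", default = "both",
                          help = "aitchison|log_euclidean|both")))
  pa <- optparse::parse_args(optparse::OptionParser(option_list = opts_def),
                             args = args, positional_arguments = 1)
  tab <- .cli_read(pa$options, pa$args[1])
  sbp <- .resolve_sbp(pa$options$sbp)
  pd <- pairwise_distances(tab, sbp, metric = pa$options$metric)
  if (!is.null(pd$reports)) {
    write_distance_long(pd, pa$options$out)
  } else {
    write_distance_matrix(pd, pa$options$out,
                          which = intersect(names(pd),
                                            c("aitchison", "log_euclidean"))[1])
  }
  0L
}

.cli_diagnose <- function(args) {
  opts_def <- c(.cli_spec_opts(), list(
    optparse::make_option("--alpha", type = "double", default = 0.01),
    optparse::make_option("--representation", type = "character",
                          default = "ilr",
                          help = "outlier-screening representation"),
    optparse::make_option("--seed", type = "integer", default = 1L)))
  pa <- optparse::parse_args(optparse::OptionParser(option_list = opts_def),
                             args = args, positional_arguments = 1)
  tab <- .cli_read(pa$options, pa$args[1])
  sbp <- .resolve_sbp(pa$options$sbp)
  dir.create(pa$options$out, recursive = TRUE, showWarnings = FALSE)
  mask <- screen_outliers(tab, sbp, representation = pa$options$representation,
                          alpha = pa$options$alpha, seed = pa$options$seed)
  utils::write.csv(mask, file.path(pa$options$out, "outliers.csv"),
                   row.names = FALSE, quote = FALSE)
  nr <- suppressWarnings(normality_by_representation(tab, sbp,
                                                     alpha = pa$options$alpha))
  utils::write.csv(nr$tests, file.path(pa$options$out, "normality_tests.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(alpha = nr$alpha, aggregate = nr$aggregate),
                       file.path(pa$options$out, "normality_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  0L
}

.cli_da <- function(args) {
  opts_def <- c(.cli_spec_opts(), list(
    optparse::make_option("--representation", type = "character",
                          default = "all", help = "raw|log|alr|ilr|all"),
    optparse::make_option("--group", type = "character", default = "group")))
  pa <- optparse::parse_args(optparse::OptionParser(option_list = opts_def),
                             args = args, positional_arguments = 1)
  tab <- .cli_read(pa$options, pa$args[1])
  sbp <- .resolve_sbp(pa$options$sbp)
  reps <- if (pa$options$representation == "all") {
    c("raw", "log", "alr", "ilr")
  } else pa$options$representation
  models <- compare_representations(tab, sbp, representations = reps)
  for (rep_ in names(models)) {
    write_cda(models[[rep_]], pa$options$out, prefix = rep_)
  }
  0L
}

.cli_simulate <- function(args) {
  opts_def <- list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "simulation spec JSON [default: preset panel]"),
    optparse::make_option("--seed", type = "integer", default = 42L),
    optparse::make_option(c("-o", "--out"), type = "character",
                          default = "synth"))
  pa <- optparse::parse_args(optparse::OptionParser(option_list = opts_def),
                             args = args, positional_arguments = 0)
  spec <- if (is.null(pa$options$config)) {
    preset_species_panel(seed = pa$options$seed)
  } else {
    simulation_spec_from_json(pa$options$config)
  }
  sim <- simulate_ionomes(spec)
  dir.create(pa$options$out, recursive = TRUE, showWarnings = FALSE)
  write_composition_table(sim$table, file.path(pa$options$out, "ionomes.csv"))
  truth <- sim$truth
  truth$sbp <- list(part_labels = truth$sbp$part_labels,
                    matrix = apply(truth$sbp$matrix, 1, as.list))
  truth$groups <- lapply(truth$groups, function(g) {
    g$cov_ilr <- apply(as.matrix(g$cov_ilr), 1, as.list); g
  })
  jsonlite::write_json(truth, file.path(pa$options$out, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  0L
}

.cli_run <- function(args) {
  opts_def <- c(.cli_spec_opts(), list(
    optparse::make_option("--alpha-outlier", type = "double", default = 0.01,
                          dest = "alpha_outlier"),
    optparse::make_option("--alpha-normality", type = "double", default = 0.01,
                          dest = "alpha_normality"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--log-level", type = "character", default = "info",
                          dest = "log_level")))
  pa <- optparse::parse_args(optparse::OptionParser(option_list = opts_def),
                             args = args, positional_arguments = 1)
  cfg <- run_config(input = pa$args[1], outdir = pa$options$out,
                    sbp = pa$options$sbp, kappa = pa$options$kappa,
                    unit = pa$options$unit,
                    alpha_outlier = pa$options$alpha_outlier,
                    alpha_normality = pa$options$alpha_normality,
                    seed = pa$options$seed, decimal = pa$options$decimal,
                    log_level = pa$options$log_level)
  run_pipeline(cfg)
  0L
}
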