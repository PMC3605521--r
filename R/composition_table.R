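#' Sample-by-nutrient composition tables
#'
#' A `composition_table` is a data.frame with one row per tissue sample, a
#' `sample_id` column, an optional `group` column (species, cultivar) and one
#' strictly positive column per part, each row closed to a shared kappa.
#'
#' @param parts data.frame or matrix of strictly positive concentrations
#'   (columns = parts).
#' @param kappa shared closure constant; every row is closed to it.
#' @param unit unit annotation.
#' @param group optional per-row group labels (character or factor).
#' @param sample_id per-row sample identifiers; defaults to `s1..sn`.
#' @param close if `FALSE`, rows must already sum to kappa.
#' @return data.frame of class `composition_table` with attributes `parts`
#'   (part labels), `kappa`, `unit`.
#' @export
composition_table <- function(parts, kappa = 100, unit = "unitless",
                              group = NULL, sample_id = NULL, close = TRUE) {
  m <- as.matrix(parts)
  if (is.null(colnames(m))) colnames(m) <- paste0("part", seq_len(ncol(m)))
  if (ncol(m) < 2L) stop("a composition table needs at least 2 parts")
  if (nrow(m) < 1L) stop("a composition table needs at least 1 sample")
  storage.mode(m) <- "double"
  bad <- which(!is.finite(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-positive or missing concentration at row %d, part '%s'",
                 bad[1, 1], colnames(m)[bad[1, 2]]))
  }
  if (close) {
    m <- m * (kappa / rowSums(m))
  } else {
    off <- which(abs(rowSums(m) - kappa) > 1e-9 * kappa)
    if (length(off)) stop("row ", off[1], " does not sum to kappa and close = FALSE")
  }
  sample_id <- as.character(sample_id %||% paste0("s", seq_len(nrow(m))))
  if (anyDuplicated(sample_id)) stop("sample_id values must be unique")
  df <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- as.character(group)
  df <- cbind(df, as.data.frame(m))
  structure(df, parts = colnames(m), kappa = kappa, unit = unit,
            class = c("composition_table", "data.frame"))
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("<composition_table> %d samples x %d parts [%s], kappa = %g (%s)\n",
              nrow(x), length(attr(x, "parts")),
              paste(attr(x, "parts"), collapse = ","),
              attr(x, "kappa"), attr(x, "unit")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Part matrix of a composition table
#' @param table a [composition_table()].
#' @return numeric matrix (samples x parts), rownames = sample ids.
#' @export
part_matrix <- function(table) {
  m <- as.matrix(as.data.frame(table)[, attr(table, "parts"), drop = FALSE])
  rownames(m) <- table$sample_id
  m
}

#' Group labels of a composition table
#' @param table a [composition_table()].
#' @return character vector or NULL.
#' @export
table_groups <- function(table) {
  if ("group" %in% names(table)) as.character(table$group) else NULL
}

#' Extract one sample as a composition
#' @param table a [composition_table()].
#' @param i row index or sample_id.
#' @return a [composition()].
#' @export
table_row <- function(table, i) {
  if (is.character(i)) i <- match(i, table$sample_id)
  m <- part_matrix(table)
  composition(m[i, ], labels = attr(table, "parts"),
              kappa = attr(table, "kappa"), unit = attr(table, "unit"),
              close = FALSE)
}

#' Subset a composition table by row
#' @param table a [composition_table()].
#' @param idx logical or integer row index.
#' @return a [composition_table()] with attributes preserved.
#' @export
table_subset <- function(table, idx) {
  df <- as.data.frame(table)[idx, , drop = FALSE]
  composition_table(df[, attr(table, "parts"), drop = FALSE],
                    kappa = attr(table, "kappa"), unit = attr(table, "unit"),
                    group = if ("group" %in% names(df)) df$group else NULL,
                    sample_id = df$sample_id, close = FALSE)
}

#' @rdname alr
#' @export
alr.composition_table <- function(comp, denominator = NULL, ...) {
  parts <- attr(comp, "parts")
  denominator <- denominator %||% parts[length(parts)]
  if (!denominator %in% parts) stop("unknown denominator part: ", denominator)
  m <- part_matrix(comp)
  num <- setdiff(parts, denominator)
  out <- log(m[, num, drop = FALSE] / m[, denominator])
  colnames(out) <- paste0(num, "/", denominator)
  out
}

#' @rdname clr
#' @export
clr.composition_table <- function(comp, ...) {
  lm <- log(part_matrix(comp))
  lm - rowMeans(lm)
}

# ---- CSV / JSON plumbing ---------------------------------------------------

#' Read a composition table from CSV
#'
#' Expected layout: header row with part labels plus reserved columns
#' `sample_id` and (optionally) `group`; decimal point `.`; UTF-8.
#'
#' @param path CSV file.
#' @param kappa,unit closure constant and unit to apply.
#' @param parts columns to treat as parts; default: all non-reserved columns.
#' @param close close rows to kappa (default TRUE).
#' @param decimal decimal separator (`.` or `,`).
#' @return a [composition_table()].
#' @export
read_composition_table <- function(path, kappa = 100, unit = "unitless",
                                   parts = NULL, close = TRUE, decimal = ".") {
  df <- utils::read.csv(path, check.names = FALSE, dec = decimal,
                        fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  reserved <- c("sample_id", "group")
  parts <- parts %||% setdiff(names(df), reserved)
  missing <- setdiff(parts, names(df))
  if (length(missing)) stop("part columns absent from ", path, ": ",
                            paste(missing, collapse = ", "))
  composition_table(df[, parts, drop = FALSE], kappa = kappa, unit = unit,
                    group = if ("group" %in% names(df)) df$group else NULL,
                    sample_id = if ("sample_id" %in% names(df)) df$sample_id else NULL,
                    close = close)
}

#' Write a composition table to CSV
#' @param table a [composition_table()].
#' @param path output file.
#' @export
write_composition_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' JSON serialization of compositions and ratio counts
#'
#' Round-trip helpers: `composition_to_json()` / `composition_from_json()` and
#' `ratio_counts_to_json()` / `ratio_counts_from_json()`.
#'
#' @param comp a [composition()].
#' @return JSON string, or the reconstructed object for the `from` direction.
#' @export
composition_to_json <- function(comp) {
  jsonlite::toJSON(list(labels = names(comp), parts = as.numeric(comp),
                        kappa = comp_kappa(comp), unit = comp_unit(comp)),
                   auto_unbox = TRUE, digits = NA)
}

#' @rdname composition_to_json
#' @param json JSON string produced by `composition_to_json()`.
#' @export
composition_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  composition(o$parts, labels = o$labels, kappa = o$kappa, unit = o$unit,
              close = FALSE)
}

#' @rdname composition_to_json
#' @param rc a `ratio_counts` object.
#' @export
ratio_counts_to_json <- function(rc) {
  jsonlite::toJSON(unclass(rc), auto_unbox = TRUE)
}

#' @rdname composition_to_json
#' @export
ratio_counts_from_json <- function(json) {
  o <- jsonlite::fromJSON(json)
  rc <- count_ratios(o$D)
  stopifnot(rc$dual == o$dual, rc$amalgamated == o$amalgamated, rc$dof == o$dof)
  rc
}
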