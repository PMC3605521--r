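#' Sequential binary partitions
#'
#' An SBP is a (D-1) x D matrix with entries in \{+1, -1, 0\} describing a
#' hierarchy of binary splits of the part set. The first row splits all D
#' parts into a +1 (numerator) and a -1 (denominator) group; every subsequent
#' row splits a group created by an earlier row; groups of one part are not
#' split further. Each row defines one balance (an orthonormal log contrast).
#'
#' `sbp_validate()` checks the sequential-binary structure by set containment
#' (each row's active set must equal a yet-unsplit sign-group of an earlier
#' row) and reports the first violating row.
#'
#' @param matrix numeric/integer matrix with entries in \{+1, -1, 0\},
#'   dimension (D-1) x D.
#' @param part_labels part names, length D; defaults to column names.
#' @return an object of class `sbp`: list with `matrix`, `part_labels`,
#'   `row_names` (balance designations such as `"[N,P | K]"`), `r`, `s`
#'   (numerator / denominator part counts per row).
#' @examples
#' sbp_validate(rbind(c(1, -1)), part_labels = c("N", "P"))
#' @export
sbp_validate <- function(matrix, part_labels = colnames(matrix)) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  D <- ncol(m)
  if (is.null(part_labels)) part_labels <- paste0("part", seq_len(D))
  if (D < 2L) stop("an SBP needs at least D = 2 parts")
  if (length(part_labels) != D || anyDuplicated(part_labels)) {
    stop("part_labels must be ", D, " unique names")
  }
  if (nrow(m) != D - 1L) {
    stop(sprintf("an SBP over %d parts must have %d rows, got %d",
                 D, D - 1L, nrow(m)))
  }
  if (!all(m %in% c(-1, 0, 1))) stop("SBP entries must be in {+1, -1, 0}")
  dimnames(m) <- NULL

  # open: groups awaiting their split, initialized with the full part set
  open <- list(seq_len(D))
  r <- s <- integer(nrow(m))
  for (j in seq_len(nrow(m))) {
    plus <- unname(which(m[j, ] == 1))
    minus <- unname(which(m[j, ] == -1))
    if (length(plus) == 0L || length(minus) == 0L) {
      stop(sprintf("SBP row %d must contain at least one +1 and one -1", j))
    }
    active <- sort(c(plus, minus))
    hit <- which(vapply(open, function(g) identical(g, active), logical(1)))
    if (length(hit) == 0L) {
      stop(sprintf(paste0("hierarchy violation at SBP row %d: active parts {%s} ",
                          "do not form a group created by an earlier row"),
                   j, paste(part_labels[active], collapse = ",")))
    }
    open <- open[-hit[1]]
    if (length(plus) >= 2L) open <- c(open, list(sort(plus)))
    if (length(minus) >= 2L) open <- c(open, list(sort(minus)))
    r[j] <- length(plus)
    s[j] <- length(minus)
  }
  # counting argument: D-1 rows each consuming one group and adding the
  # non-singleton halves guarantees open is empty here
  stopifnot(length(open) == 0L)
  structure(list(matrix = m, part_labels = part_labels,
                 row_names = balance_names(m, part_labels), r = r, s = s),
            class = "sbp")
}

#' Balance designations for SBP rows
#'
#' @param matrix SBP contrast matrix.
#' @param part_labels part names.
#' @param sep,open,close,gap formatting controls; the defaults give the
#'   `"[N,P | K]"` style. For file-system-safe column names use e.g.
#'   `balance_names(m, p, sep = ".", open = "", close = "", gap = "_vs_")`.
#' @return character vector, one designation per row.
#' @export
balance_names <- function(matrix, part_labels, sep = ",", open = "[",
                          close = "]", gap = " | ") {
  apply(matrix, 1, function(row) {
    paste0(open, paste(part_labels[row > 0], collapse = sep), gap,
           paste(part_labels[row < 0], collapse = sep), close)
  })
}

#' @export
print.sbp <- function(x, ...) {
  cat(sprintf("<sbp> %d balances over %d parts\n", nrow(x$matrix),
              length(x$part_labels)))
  m <- x$matrix
  dimnames(m) <- list(x$row_names, x$part_labels)
  print(m)
  invisible(x)
}

#' Orthonormal balance basis from an SBP
#'
#' Row j of the contrast matrix psi carries `+sqrt(r s / (r + s)) / r` on the
#' +1 parts and `-sqrt(r s / (r + s)) / s` on the -1 parts, where r and s are
#' the group sizes; `sqrt(r s / (r + s))` is the orthogonal coefficient of the
#' balance. psi has orthonormal rows (psi psi' = I) and zero row sums, so
#' `ilr = psi %*% log(parts)` is an isometry of the simplex.
#'
#' @param sbp an [sbp_validate()]-validated SBP (raw matrices are validated).
#' @return object of class `ilr_basis`: list with `psi` ((D-1) x D matrix) and
#'   the source `sbp`.
#' @export
sbp_to_basis <- function(sbp) {
  if (!inherits(sbp, "sbp")) sbp <- sbp_validate(sbp)
  m <- sbp$matrix
  psi <- matrix(0, nrow(m), ncol(m),
                dimnames = list(sbp$row_names, sbp$part_labels))
  for (j in seq_len(nrow(m))) {
    r <- sbp$r[j]; s <- sbp$s[j]
    coef <- sqrt(r * s / (r + s))
    psi[j, m[j, ] > 0] <- coef / r
    psi[j, m[j, ] < 0] <- -coef / s
  }
  structure(list(psi = psi, sbp = sbp), class = "ilr_basis")
}

#' Isometric log-ratio transform
#'
#' Balance j is `sqrt(r s/(r+s)) * ln(g(c+)/g(c-))`: the log contrast between
#' the geometric means of the numerator (+1) and denominator (-1) groups of
#' SBP row j, scaled to orthonormality. A positive balance means the numerator
#' group's geometric mean exceeds the denominator group's. Equals
#' `psi %*% log(parts)` and is invariant to the closure constant.
#'
#' @param x a [composition()] or [composition_table()].
#' @param sbp an [sbp_validate()] result (or raw contrast matrix).
#' @param ... passed to methods.
#' @return named numeric vector (composition) or samples x balances matrix
#'   (table); names are the SBP balance designations.
#' @examples
#' ilr(composition(c(N = 2.50, P = 0.15)), sbp_validate(rbind(c(1, -1)),
#'     part_labels = c("N", "P")))  # 1.99
#' @export
ilr <- function(x, sbp, ...) UseMethod("ilr")

# The SBP may cover a subcomposition of the available parts (e.g. the
# 5-nutrient SBP applied to a table that also carries the filling value):
# balances only involve the SBP's parts, so extra parts are simply unused.
.align_sbp <- function(labels, sbp) {
  if (!inherits(sbp, "sbp")) sbp <- sbp_validate(sbp)
  missing <- setdiff(sbp$part_labels, labels)
  if (length(missing)) {
    stop("part labels do not match SBP parts; unmatched: ",
         paste(missing, collapse = ", "))
  }
  sbp
}

#' @rdname ilr
#' @export
ilr.composition <- function(x, sbp, ...) {
  sbp <- .align_sbp(names(x), sbp)
  lx <- log(as.numeric(x)[match(sbp$part_labels, names(x))])
  psi <- sbp_to_basis(sbp)$psi
  stats::setNames(as.numeric(psi %*% lx), sbp$row_names)
}

#' @rdname ilr
#' @export
ilr.composition_table <- function(x, sbp, ...) {
  sbp <- .align_sbp(attr(x, "parts"), sbp)
  m <- part_matrix(x)[, sbp$part_labels, drop = FALSE]
  psi <- sbp_to_basis(sbp)$psi
  out <- log(m) %*% t(psi)
  colnames(out) <- sbp$row_names
  out
}

#' Inverse ilr transform
#'
#' Maps balance coordinates back to a composition:
#' `closure(exp(psi' coords), kappa)`. Round trip with [ilr()] reproduces the
#' closed composition to 1e-10 relative.
#'
#' @param coords numeric vector of length D-1, or matrix (samples x D-1).
#' @param sbp the SBP defining the basis.
#' @param kappa,unit closure constant and unit for the output.
#' @return a [composition()] (vector input) or [composition_table()] (matrix).
#' @export
ilr_inverse <- function(coords, sbp, kappa = 1, unit = "unitless") {
  if (!inherits(sbp, "sbp")) sbp <- sbp_validate(sbp)
  psi <- sbp_to_basis(sbp)$psi
  if (is.matrix(coords)) {
    if (ncol(coords) != nrow(psi)) {
      stop("coords must have ", nrow(psi), " columns to match the SBP")
    }
    m <- exp(coords %*% psi)
    composition_table(m * (kappa / rowSums(m)), kappa = kappa, unit = unit,
                      close = FALSE, sample_id = rownames(coords))
  } else {
    if (length(coords) != nrow(psi)) {
      stop("coords must have length ", nrow(psi), " to match the SBP")
    }
    v <- exp(as.numeric(t(psi) %*% as.numeric(coords)))
    composition(v, labels = sbp$part_labels, kappa = kappa, unit = unit)
  }
}

#' The knowledge-driven 5-nutrient ionome SBP
#'
#' The default partition over (N, P, K, Ca, Mg): the initiator balances the
#' mobile macronutrients N, P, K against Ca and Mg (which track soil
#' mineralogy), then N,P against K, then the Redfield-type N against P, and
#' finally Ca against Mg. With `include_fv = TRUE` the five nutrients are
#' first balanced against the filling value Fv (the unanalysed remainder of
#' dry matter), embedding the nutrient subcomposition into the full tissue.
#'
#' @param include_fv prepend the \[N,P,K,Ca,Mg | Fv\] balance and an Fv part.
#' @return an [sbp_validate()]-validated `sbp`.
#' @export
default_ionome_sbp <- function(include_fv = FALSE) {
  parts <- c("N", "P", "K", "Ca", "Mg")
  m <- rbind(c(1, 1, 1, -1, -1),
             c(1, 1, -1, 0, 0),
             c(1, -1, 0, 0, 0),
             c(0, 0, 0, 1, -1))
  if (include_fv) {
    m <- rbind(c(rep(1, 5), -1), cbind(m, 0))
    parts <- c(parts, "Fv")
  }
  sbp_validate(m, part_labels = parts)
}

# ---- SBP I/O ---------------------------------------------------------------

#' Read / write SBP matrices
#'
#' CSV layout: one row per balance, one column per part, cells in
#' \{-1, 0, 1\}; an optional first column `balance` is ignored on read.
#' JSON carries `part_labels` and the matrix rows.
#'
#' @param path file path.
#' @return `sbp_from_csv()` / `sbp_from_json()` return a validated `sbp`.
#' @export
sbp_from_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  df <- df[, setdiff(names(df), "balance"), drop = FALSE]
  sbp_validate(as.matrix(df), part_labels = names(df))
}

#' @rdname sbp_from_csv
#' @param sbp a validated `sbp`.
#' @export
sbp_to_csv <- function(sbp, path) {
  m <- as.data.frame(sbp$matrix)
  names(m) <- sbp$part_labels
  safe <- balance_names(sbp$matrix, sbp$part_labels, sep = ".", open = "",
                        close = "", gap = "_vs_")
  utils::write.csv(cbind(balance = safe, m), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname sbp_from_csv
#' @export
sbp_from_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  m <- o$matrix
  if (is.list(m)) m <- do.call(rbind, lapply(m, as.numeric))
  sbp_validate(as.matrix(m), part_labels = o$part_labels)
}

#' @rdname sbp_from_csv
#' @export
sbp_to_json <- function(sbp, path) {
  jsonlite::write_json(list(part_labels = sbp$part_labels,
                            row_names = sbp$row_names,
                            matrix = apply(sbp$matrix, 1, as.list)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

# ---- Balance dendrogram ----------------------------------------------------

#' Balance dendrogram of an SBP
#'
#' The SBP's nested splits form a binary tree whose leaves are the parts and
#' whose internal nodes are the balances. Optionally attaches per-balance
#' summary statistics (mean, sd, quartiles) computed from a coordinate matrix.
#'
#' @param sbp a validated `sbp`.
#' @param coords optional samples x balances matrix (from [ilr()]) summarised
#'   per balance.
#' @return object of class `balance_tree`: nested list with fields `balance`
#'   (designation), `row` (SBP row index), `plus`/`minus` (subtrees or leaf
#'   part names) and optional `summary`.
#' @export
balance_dendrogram <- function(sbp, coords = NULL) {
  if (!inherits(sbp, "sbp")) sbp <- sbp_validate(sbp)
  m <- sbp$matrix
  summarise <- function(j) {
    if (is.null(coords)) return(NULL)
    v <- coords[, j]
    list(mean = mean(v), sd = stats::sd(v),
         q25 = as.numeric(stats::quantile(v, 0.25)),
         median = as.numeric(stats::median(v)),
         q75 = as.numeric(stats::quantile(v, 0.75)))
  }
  build <- function(active) {
    if (length(active) == 1L) return(sbp$part_labels[active])
    j <- which(vapply(seq_len(nrow(m)), function(jj) {
      identical(sort(which(m[jj, ] != 0)), sort(active))
    }, logical(1)))[1]
    list(balance = sbp$row_names[j], row = j,
         plus = build(which(m[j, ] > 0)),
         minus = build(which(m[j, ] < 0)),
         summary = summarise(j))
  }
  structure(build(seq_along(sbp$part_labels)), class = "balance_tree")
}

#' Serialize a balance dendrogram
#'
#' @param tree a [balance_dendrogram()] result.
#' @return `tree_to_newick()`: a Newick string with file-system-safe internal
#'   node labels; `tree_to_json()`: a JSON string.
#' @export
tree_to_newick <- function(tree) {
  safe <- function(x) gsub("[^A-Za-z0-9_.]", "", gsub(" \\| ", "_vs_", x))
  rec <- function(node) {
    if (is.character(node)) return(safe(node))
    sprintf("(%s,%s)%s", rec(node$plus), rec(node$minus), safe(node$balance))
  }
  paste0(rec(unclass(tree)), ";")
}

#' @rdname tree_to_newick
#' @export
tree_to_json <- function(tree) {
  jsonlite::toJSON(unclass(tree), auto_unbox = TRUE, digits = NA, null = "null")
}

#' Leaf labels of a balance dendrogram
#' @param tree a [balance_dendrogram()] result.
#' @return character vector of part names at the leaves.
#' @export
tree_leaves <- function(tree) {
  rec <- function(node) {
    if (is.character(node)) return(node)
    c(rec(node$plus), rec(node$minus))
  }
  rec(unclass(tree))
}
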