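# Shared fixtures: random compositions, random valid SBPs, and small
# brute-force oracles used to cross-check the implementation paths.

random_comp <- function(D, kappa = 100, labels = paste0("p", seq_len(D))) {
  composition(exp(stats::rnorm(D)), labels = labels, kappa = kappa)
}

random_table <- function(n, D, kappa = 100, group = NULL) {
  m <- matrix(exp(stats::rnorm(n * D)), n, D,
              dimnames = list(NULL, paste0("p", seq_len(D))))
  composition_table(m, kappa = kappa, group = group)
}

# Random valid SBP by recursive random splits (parent rows precede children).
random_sbp <- function(labels) {
  D <- length(labels)
  rows <- list()
  split_group <- function(idx) {
    if (length(idx) < 2L) return(invisible())
    k <- sample(seq_len(length(idx) - 1L), 1)
    plus <- sort(sample(idx, k))
    minus <- setdiff(idx, plus)
    row <- numeric(D)
    row[plus] <- 1; row[minus] <- -1
    rows[[length(rows) + 1L]] <<- row
    split_group(plus)
    split_group(minus)
  }
  split_group(seq_len(D))
  sbp_validate(do.call(rbind, rows), part_labels = labels)
}

# Brute-force ratio enumeration: unordered dual pairs x/y plus x/(y+z) forms.
brute_force_ratio_counts <- function(D) {
  dual <- nrow(t(utils::combn(D, 2)))
  amalg3 <- 0L
  for (x in seq_len(D)) {
    others <- setdiff(seq_len(D), x)
    if (length(others) >= 2) amalg3 <- amalg3 + nrow(t(utils::combn(others, 2)))
  }
  list(dual = dual, amalgamated = dual + amalg3)
}

# Per-row balance oracle: sqrt(rs/(r+s)) * ln(g(plus)/g(minus)), evaluated
# term by term without the contrast-matrix machinery.
ilr_row_oracle <- function(parts, sbp_matrix) {
  vapply(seq_len(nrow(sbp_matrix)), function(j) {
    plus <- parts[sbp_matrix[j, ] > 0]
    minus <- parts[sbp_matrix[j, ] < 0]
    r <- length(plus); s <- length(minus)
    gp <- exp(mean(log(plus))); gm <- exp(mean(log(minus)))
    sqrt(r * s / (r + s)) * log(gp / gm)
  }, numeric(1))
}

# Brute-force check of the sequential-binary rule, written independently of
# sbp_validate: search for an ordering-respecting nesting by set containment.
brute_force_sbp_valid <- function(m) {
  D <- ncol(m)
  if (nrow(m) != D - 1L || !all(m %in% c(-1, 0, 1))) return(FALSE)
  open <- list(seq_len(D))
  for (j in seq_len(nrow(m))) {
    plus <- which(m[j, ] == 1); minus <- which(m[j, ] == -1)
    if (!length(plus) || !length(minus)) return(FALSE)
    act <- sort(c(plus, minus))
    hit <- Position(function(g) identical(g, act), open)
    if (is.null(hit)) return(FALSE)
    open <- open[-hit]
    if (length(plus) > 1) open <- c(open, list(sort(plus)))
    if (length(minus) > 1) open <- c(open, list(sort(minus)))
  }
  length(open) == 0L
}

table1_sbp <- function() default_ionome_sbp()
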