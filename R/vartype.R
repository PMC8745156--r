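# Physicochemical variation-type fingerprints and the pseudocount
# chi-square homogeneity test.
#
# Each substitution maps to an ordered pair (class of the wild-type
# residue, class of the mutant residue) over apolar / polar / aromatic /
# charged — 16 variation types, labelled a, p, r, c in matrix I/O.

#' Variation type of a substitution
#'
#' @param wt,mut One-letter residue codes (vectorized).
#' @return Data frame with columns `from` and `to` (class names).
#' @examples
#' variation_type("G", "D")  # apolar -> charged
#' @export
variation_type <- function(wt, mut) {
  data.frame(from = residue_class(wt), to = residue_class(mut),
             stringsAsFactors = FALSE)
}

new_type_matrix <- function(m) {
  dimnames(m) <- list(from = unname(class_labels),
                      to = unname(class_labels))
  structure(m, class = c("type_matrix", "matrix"))
}

#' Variation-type count matrix
#'
#' Counts deduplicated variants per (source class, target class) cell.
#' Distinct substitutions at the same position count separately.
#'
#' @param records A deduplicated `variant_table`.
#' @param domain Optional `"catalytic"` or `"regulatory"` filter.
#' @return A `type_matrix`: 4 x 4 count matrix with rows = wild-type
#'   class, columns = mutant class, labelled `a` (apolar), `p` (polar),
#'   `r` (aromatic), `c` (charged).
#' @export
type_matrix <- function(records, domain = NULL) {
  if (!is.null(domain)) {
    domain <- match.arg(domain, c("catalytic", "regulatory"))
    records <- records[records$domain == domain, , drop = FALSE]
  }
  m <- matrix(0L, 4, 4)
  if (nrow(records) > 0) {
    ty <- variation_type(records$wt, records$mut)
    i <- match(ty$from, names(class_labels))
    j <- match(ty$to, names(class_labels))
    for (k in seq_along(i)) m[i[k], j[k]] <- m[i[k], j[k]] + 1L
  }
  new_type_matrix(m)
}

#' Relative frequencies of a type matrix
#'
#' @param m A `type_matrix` of counts.
#' @return A `type_matrix` of frequencies summing to 1; aborts on an
#'   all-zero matrix (frequency undefined).
#' @export
type_frequencies <- function(m) {
  tot <- sum(m)
  if (tot == 0) stop("all-zero type matrix: frequencies undefined")
  new_type_matrix(unclass(m) / tot)
}

#' @export
print.type_matrix <- function(x, ...) {
  cat(sprintf("type_matrix (total %g):\n", sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Chi-square homogeneity test with pseudocount regularization
#'
#' Flattens the two 4 x 4 count matrices into a 2 x 16 contingency table,
#' adds a pseudocount to every cell (default 0.5) to regularize empty
#' cells, and applies Pearson's chi-square test of homogeneity
#' (no continuity correction, df = 15).
#'
#' @param counts_a,counts_b `type_matrix` objects of counts (same shape).
#' @param pseudocount Value added to every cell; default 0.5.
#' @return List with `statistic`, `df` and `p_value`.
#' @export
chi_square_pseudocount <- function(counts_a, counts_b, pseudocount = 0.5) {
  a <- as.vector(unclass(counts_a))
  b <- as.vector(unclass(counts_b))
  if (length(a) != length(b)) stop("matrices differ in shape")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  tab <- rbind(a, b) + pseudocount
  if (any(colSums(tab) <= 0) || any(rowSums(tab) <= 0))
    stop("non-positive margin after pseudocounts")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Background variation-type matrix
#'
#' Either samples a synthetic background emulating a large pathogenic
#' variant collection (multinomial over the 16 types) or loads explicit
#' frequencies from a 4 x 4 TSV written by [write_type_matrix()].
#'
#' @param n Number of sampled variations (ignored when `path` is given).
#' @param probs Optional 4 x 4 matrix of cell probabilities; default
#'   uniform (1/16 each).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @param path Optional TSV of explicit frequencies; takes precedence.
#' @return A frequency `type_matrix`.
#' @export
background_matrix <- function(n = 22763, probs = NULL, seed = 1,
                              path = NULL) {
  if (!is.null(path)) {
    m <- read_type_matrix(path)
    return(type_frequencies(new_type_matrix(unclass(m))))
  }
  if (is.null(probs)) probs <- matrix(1 / 16, 4, 4)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop("probs must be non-negative and sum to 1")
  counts <- with_seed(seed, as.vector(rmultinom(1, n, as.vector(probs))))
  type_frequencies(new_type_matrix(matrix(counts, 4, 4)))
}

#' Read / write a 4 x 4 type matrix as labelled TSV
#'
#' Row and column labels are `a p r c`.
#'
#' @param m A `type_matrix`.
#' @param path File path.
#' @return `read_type_matrix` returns a `type_matrix`;
#'   `write_type_matrix` returns `path` invisibly.
#' @export
write_type_matrix <- function(m, path) {
  df <- as.data.frame(unclass(m))
  write.table(cbind(type = rownames(unclass(m)), df), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_type_matrix
#' @export
read_type_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (!identical(df[[1]], unname(class_labels)) ||
      !identical(names(df)[-1], unname(class_labels)))
    stop("malformed type matrix TSV (labels must be a, p, r, c)")
  new_type_matrix(as.matrix(df[, -1]))
}

#' Heatmap of variation-type frequencies
#'
#' Base-graphics heatmap of one or more frequency matrices, mirroring the
#' per-domain fingerprint view: one column block per matrix, 16 type rows.
#'
#' @param ... Named `type_matrix` objects (counts or frequencies; counts
#'   are normalized).
#' @param file Optional PNG path; when given the plot is written there.
#' @return The plotted frequency matrix (16 types x groups), invisibly.
#' @export
plot_type_heatmap <- function(..., file = NULL) {
  mats <- list(...)
  if (is.null(names(mats)) || any(names(mats) == ""))
    names(mats) <- paste0("group", seq_along(mats))
  freq <- vapply(mats, function(m) {
    if (abs(sum(m) - 1) > 1e-6) m <- type_frequencies(m)
    as.vector(t(unclass(m)))  # row-major: from varies slowest
  }, numeric(16))
  lbl <- as.vector(t(outer(class_labels, class_labels, paste0)))
  rownames(freq) <- lbl
  if (!is.null(file)) {
    grDevices::png(file, width = 480, height = 640)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = c(4, 5, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(seq_len(ncol(freq)), seq_len(16), t(freq),
                  col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "variation type")
  graphics::axis(1, seq_len(ncol(freq)), colnames(freq), las = 2)
  graphics::axis(2, seq_len(16), rownames(freq), las = 1)
  graphics::box()
  invisible(freq)
}
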