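#' NODF nestedness
#'
#' Nestedness metric based on Overlap and Decreasing Fill. For every ordered
#' pair of rows (u above v in the working order) the pair contributes 0 when
#' degree(u) <= degree(v) (the decreasing-fill condition fails, including
#' ties) and otherwise 100 times the fraction of v's presences that overlap
#' u's. Column pairs are scored the same way. `nodf_rows` / `nodf_cols` are
#' means over row / column pairs and `nodf_total` the mean over all pairs
#' pooled, so scores run from 0 (compartmentalised) to 100 (perfectly
#' nested).
#'
#' In `"sorted"` mode rows and columns are internally sorted by descending
#' degree (the input object is not modified), which makes the score invariant
#' to any permutation of the input. In `"fixed"` mode the current order is
#' used as-is, e.g. a phylogenetic order applied via [order_matrix()];
#' fixed-order NODF can only be lower than (or equal to) sorted NODF.
#'
#' @param matrix A `bipartite_matrix` (or plain binary matrix) with more than
#'   one row or column.
#' @param order_mode `"sorted"` or `"fixed"`.
#' @return An object of class `nestedness_result`: list with `nodf_total`,
#'   `nodf_rows`, `nodf_cols`, `order_mode`.
#' @export
nodf <- function(matrix, order_mode = c("sorted", "fixed")) {
  order_mode <- match.arg(order_mode)
  m <- unclass_matrix(matrix)
  if (nrow(m) < 2 && ncol(m) < 2) {
    stop("NODF needs at least two rows or two columns")
  }
  if (order_mode == "sorted") {
    m <- m[order(-rowSums(m), rownames(m) %||% seq_len(nrow(m))),
           order(-colSums(m), colnames(m) %||% seq_len(ncol(m))),
           drop = FALSE]
  }
  row_terms <- nodf_pair_terms(m)
  col_terms <- nodf_pair_terms(t(m))
  structure(list(
    nodf_total = mean(c(row_terms, col_terms)),
    nodf_rows = if (length(row_terms)) mean(row_terms) else NA_real_,
    nodf_cols = if (length(col_terms)) mean(col_terms) else NA_real_,
    order_mode = order_mode
  ), class = "nestedness_result")
}

# Paired-overlap terms for all ordered pairs i < j (i above j) of rows of m.
nodf_pair_terms <- function(m) {
  n <- nrow(m)
  if (n < 2) return(numeric(0))
  d <- rowSums(m)
  ov <- tcrossprod(m)
  idx <- which(upper.tri(ov), arr.ind = TRUE)   # idx[,1] < idx[,2]: row 1 above
  du <- d[idx[, 1]]
  dv <- d[idx[, 2]]
  ifelse(du > dv, 100 * ov[idx] / dv, 0)
}

#' @export
print.nestedness_result <- function(x, ...) {
  cat(sprintf("NODF (%s order): total = %.3f, rows = %.3f, cols = %.3f\n",
              x$order_mode, x$nodf_total, x$nodf_rows, x$nodf_cols))
  invisible(x)
}
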