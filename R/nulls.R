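# Run expr under a local RNG state seeded with `seed` (NULL = use the
# current stream without disturbing callers' expectations).
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' ER (equiprobable) null matrix
#'
#' Reassigns the observed 1s uniformly at random over all cells: every cell
#' has the same occupancy probability and the total number of links is
#' conserved exactly. Draws leaving an empty row or column are rejected and
#' resampled up to `max_tries` times, since downstream statistics assume
#' positive degrees.
#'
#' @param matrix A `bipartite_matrix`.
#' @param seed Optional integer seed.
#' @param max_tries Resampling cap before giving up.
#' @return A `bipartite_matrix` with the same dimensions and link count.
#' @export
null_er <- function(matrix, seed = NULL, max_tries = 1000) {
  m <- unclass_matrix(matrix)
  L <- sum(m)
  local_seed(seed, {
    for (i in seq_len(max_tries)) {
      out <- m * 0L
      out[sample.int(length(m), L)] <- 1L
      if (all(rowSums(out) > 0) && all(colSums(out) > 0)) {
        return(new_bipartite_matrix(out, attr(matrix, "order_mode") %||% "given"))
      }
    }
    stop("ER null: no draw without empty rows/columns in ", max_tries,
         " tries; the matrix is probably too sparse")
  })
}

#' CE (cell-probability) null matrix
#'
#' Each cell (i, j) is occupied independently with probability equal to the
#' arithmetic mean of the fill probability of its row and of its column,
#' p_ij = (row_degree_i / n_cols + col_degree_j / n_rows) / 2, so occupancy
#' tracks the generalisation level of both partners and the expected link
#' count equals the observed one. Empty rows/columns are rejected and
#' resampled as in [null_er()].
#'
#' @inheritParams null_er
#' @return A `bipartite_matrix` with the same dimensions.
#' @export
null_ce <- function(matrix, seed = NULL, max_tries = 1000) {
  m <- unclass_matrix(matrix)
  p <- (outer(rowSums(m) / ncol(m), colSums(m) / nrow(m), "+")) / 2
  local_seed(seed, {
    for (i in seq_len(max_tries)) {
      out <- matrix(as.integer(stats::runif(length(m)) < p), nrow(m),
                    dimnames = dimnames(m))
      if (all(rowSums(out) > 0) && all(colSums(out) > 0)) {
        return(new_bipartite_matrix(out, attr(matrix, "order_mode") %||% "given"))
      }
    }
    stop("CE null: no draw without empty rows/columns in ", max_tries,
         " tries; the matrix is probably too sparse")
  })
}

#' FF (fixed-fixed) null matrix by curveball trades
#'
#' Samples from the ensemble of binary matrices with exactly the observed row
#' and column sums using the curveball algorithm: repeatedly pick two rows
#' and trade a random subset of the presences unique to each, which preserves
#' both margin vectors by construction.
#'
#' @inheritParams null_er
#' @param n_trades Number of curveball trades (default 5 times the link
#'   count, a standard mixing allowance).
#' @return A `bipartite_matrix` with identical row and column sums.
#' @export
null_ff <- function(matrix, seed = NULL, n_trades = NULL) {
  m <- unclass_matrix(matrix)
  if (is.null(n_trades)) n_trades <- 5 * sum(m)
  stopifnot(n_trades >= 1)
  rows <- lapply(seq_len(nrow(m)), function(i) which(m[i, ] == 1L))
  local_seed(seed, {
    n <- nrow(m)
    for (t in seq_len(n_trades)) {
      ij <- sample.int(n, 2)
      a <- rows[[ij[1]]]; b <- rows[[ij[2]]]
      only_a <- setdiff(a, b); only_b <- setdiff(b, a)
      if (length(only_a) == 0 || length(only_b) == 0) next
      # shuffle the pooled exclusive presences and deal them back, so the
      # number actually traded is hypergeometric (including zero)
      pool <- c(only_a, only_b)
      pool <- pool[sample.int(length(pool))]
      shared_a <- setdiff(a, only_a)
      shared_b <- setdiff(b, only_b)
      rows[[ij[1]]] <- sort(c(shared_a, pool[seq_along(only_a)]))
      rows[[ij[2]]] <- sort(c(shared_b, pool[-seq_along(only_a)]))
    }
    out <- m * 0L
    for (i in seq_len(n)) out[i, rows[[i]]] <- 1L
    new_bipartite_matrix(out, attr(matrix, "order_mode") %||% "given")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Null-ensemble test of a matrix statistic
#'
#' Evaluates `statistic` on `n_reps` independent null matrices from one of
#' the three null models and summarises the ensemble: null mean and standard
#' deviation, standardized effect size SES = (observed - null mean) / null
#' sd, and the upper-tail empirical p-value with the add-one correction
#' p = (1 + #\{null >= observed\}) / (1 + n_reps). Null matrices keep the
#' observed label order, so order-sensitive statistics (fixed-order NODF)
#' are evaluated coherently.
#'
#' @param matrix A `bipartite_matrix`.
#' @param statistic Function of a matrix returning a single number.
#' @param model `"ER"`, `"CE"` or `"FF"`.
#' @param n_reps Number of null matrices (>= 2).
#' @param seed Optional integer seed for the whole ensemble.
#' @param ... Passed to the null generator (e.g. `n_trades`).
#' @return An object of class `null_ensemble`: list with `model`, `n_reps`,
#'   `observed`, `values`, `null_mean`, `null_sd`, `ses`, `p_value`. When the
#'   null sd is zero the SES is reported as 0 with a degenerate-null warning.
#' @export
null_ensemble <- function(matrix, statistic, model = c("ER", "CE", "FF"),
                          n_reps = 1000, seed = NULL, ...) {
  model <- match.arg(model)
  stopifnot(n_reps >= 2)
  gen <- switch(model, ER = null_er, CE = null_ce, FF = null_ff)
  observed <- statistic(matrix)
  values <- local_seed(seed, vapply(seq_len(n_reps), function(i) {
    statistic(gen(matrix, seed = NULL, ...))
  }, numeric(1)))
  null_mean <- mean(values)
  null_sd <- stats::sd(values)
  if (null_sd > 0) {
    ses <- (observed - null_mean) / null_sd
  } else {
    warning("degenerate null ensemble (sd = 0); SES reported as 0")
    ses <- 0
  }
  structure(list(model = model, n_reps = n_reps, observed = observed,
                 values = values, null_mean = null_mean, null_sd = null_sd,
                 ses = ses,
                 p_value = (1 + sum(values >= observed)) / (1 + n_reps)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("%s null ensemble (n = %d): observed = %.3f, null = %.3f +/- %.3f, SES = %.3f, P = %.4g\n",
              x$model, x$n_reps, x$observed, x$null_mean, x$null_sd,
              x$ses, x$p_value))
  invisible(x)
}
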