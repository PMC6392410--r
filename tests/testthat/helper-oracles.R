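# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# Brute-force NODF: explicit double loop over all ordered row and column
# pairs of the matrix as given (no sorting).
nodf_oracle <- function(m) {
  pair_terms <- function(mm) {
    n <- nrow(mm)
    if (n < 2) return(numeric(0))
    out <- c()
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        du <- sum(mm[i, ]); dv <- sum(mm[j, ])
        out <- c(out, if (du > dv) 100 * sum(mm[i, ] & mm[j, ]) / dv else 0)
      }
    }
    out
  }
  rt <- pair_terms(m); ct <- pair_terms(t(m))
  list(total = mean(c(rt, ct)),
       rows = if (length(rt)) mean(rt) else NA_real_,
       cols = if (length(ct)) mean(ct) else NA_real_)
}

sort_desc <- function(m) {
  m[order(-rowSums(m), rownames(m) %||% seq_len(nrow(m))),
    order(-colSums(m), colnames(m) %||% seq_len(ncol(m))), drop = FALSE]
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# All set partitions of n items as membership vectors (restricted growth
# strings), for the exhaustive modularity oracle.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (m in seq_len(maxid + 1)) rec(c(prefix, m), max(maxid, m))
  }
  rec(integer(0), 0L)
  out
}

# Newman-Girvan Q computed module-by-module (independent of the package's
# vectorised implementation).
q_oracle <- function(edges, memb) {
  L <- nrow(edges)
  deg <- tabulate(c(edges[, 1], edges[, 2]), length(memb))
  acc <- 0
  for (s in unique(memb)) {
    nodes <- which(memb == s)
    within <- sum(edges[, 1] %in% nodes & edges[, 2] %in% nodes)
    acc <- acc + within / L - (sum(deg[nodes]) / (2 * L))^2
  }
  acc
}

best_partition_q <- function(edges, n) {
  max(vapply(all_partitions(n), function(p) q_oracle(edges, p), numeric(1)))
}

make_graph <- function(n, edges, guild = NULL) {
  structure(list(labels = paste0("n", seq_len(n)),
                 guild = guild %||% rep("bird_clade", n),
                 edges = edges),
            class = "interaction_graph")
}

two_triangles <- function() {
  make_graph(6, rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
}

# Random binary matrix with no empty rows/columns.
random_matrix <- function(nr, nc, fill = 0.4) {
  repeat {
    m <- matrix(as.integer(stats::runif(nr * nc) < fill), nr, nc,
                dimnames = list(paste0("f", seq_len(nr)),
                                paste0("c", seq_len(nc))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

triangular_matrix <- function(n) {
  m <- matrix(0L, n, n, dimnames = list(paste0("f", seq_len(n)),
                                        paste0("c", seq_len(n))))
  for (i in seq_len(n)) m[i, seq_len(n + 1 - i)] <- 1L
  m
}

extdata <- function(name) {
  system.file("extdata", name, package = "hummnet", mustWork = TRUE)
}

fast_schedule <- function() {
  sa_schedule(cooling = 0.95, tmin_factor = 1e-2)
}

load_fixture_maps <- function() {
  read_taxon_maps(extdata("synthetic_bird_clades.csv"),
                  extdata("synthetic_plant_families.csv"),
                  extdata("synthetic_family_syndromes.csv"))
}
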