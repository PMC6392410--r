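#' Unipartite view of a bipartite matrix
#'
#' Builds the simple graph whose nodes are the row (plant family) and column
#' (hummingbird clade) labels and whose edges are the 1-cells. Modularity is
#' maximised on this unipartite view, matching the use of a unipartite
#' annealing algorithm on mutualistic networks.
#'
#' @param matrix A `bipartite_matrix`.
#' @return An object of class `interaction_graph`: list with `labels`,
#'   `guild` (`"plant_family"` / `"bird_clade"`), and `edges` (two-column
#'   integer matrix of 1-based node indices).
#' @export
bipartite_to_graph <- function(matrix) {
  m <- unclass_matrix(matrix)
  labels <- c(rownames(m), colnames(m))
  guild <- c(rep("plant_family", nrow(m)), rep("bird_clade", ncol(m)))
  ones <- which(m == 1L, arr.ind = TRUE)
  edges <- cbind(ones[, 1], nrow(m) + ones[, 2])
  structure(list(labels = labels, guild = guild, edges = edges),
            class = "interaction_graph")
}

graph_degree <- function(graph) {
  tabulate(c(graph$edges[, 1], graph$edges[, 2]), length(graph$labels))
}

#' Newman-Girvan modularity of a partition
#'
#' M = sum over modules s of (l_s / L - (d_s / 2L)^2), where l_s is the
#' number of edges inside s, d_s the total degree of its nodes and L the
#' number of edges in the graph.
#'
#' @param graph An `interaction_graph`.
#' @param membership Integer vector of module ids, one per node (names
#'   optional).
#' @return The modularity index (a single number, at most 1).
#' @export
modularity_index <- function(graph, membership) {
  L <- nrow(graph$edges)
  if (L == 0) stop("graph has no edges")
  n <- length(graph$labels)
  if (length(membership) != n || anyNA(membership)) {
    stop("membership must assign every node")
  }
  membership <- as.integer(factor(membership))
  within <- membership[graph$edges[, 1]] == membership[graph$edges[, 2]]
  l_s <- tabulate(membership[graph$edges[, 1]][within], max(membership))
  d_s <- tapply(graph_degree(graph), membership, sum)
  sum(l_s / L) - sum((d_s / (2 * L))^2)
}

#' Annealing schedule for modularity search
#'
#' Defaults: initial temperature 1/n nodes, geometric cooling factor 0.995,
#' n^2 single-node proposals per temperature (plus one merge and one split
#' proposal each temperature step), stopping when the temperature has fallen
#' to `tmin_factor` times its initial value.
#'
#' @param t0 Initial temperature (`NULL`: 1 / number of nodes).
#' @param cooling Geometric cooling factor in (0, 1).
#' @param steps_per_temp Node-move proposals per temperature (`NULL`: n^2).
#' @param tmin_factor Stop when T < t0 * tmin_factor.
#' @return A list of schedule parameters.
#' @export
sa_schedule <- function(t0 = NULL, cooling = 0.995, steps_per_temp = NULL,
                        tmin_factor = 1e-3) {
  if (!is.numeric(cooling) || cooling <= 0 || cooling >= 1) {
    stop("cooling factor must be in (0, 1)")
  }
  stopifnot(tmin_factor > 0, tmin_factor < 1)
  list(t0 = t0, cooling = cooling, steps_per_temp = steps_per_temp,
       tmin_factor = tmin_factor)
}

#' Simulated-annealing modularity maximisation
#'
#' Searches for the node partition maximising Newman-Girvan modularity by
#' simulated annealing with single-node moves plus module merge and split
#' proposals, followed by a greedy pass so the returned membership is a
#' local maximum under single-node moves. Identical seeds and schedules give
#' identical partitions.
#'
#' @param graph An `interaction_graph` with at least one edge.
#' @param seed Optional integer seed.
#' @param schedule An [sa_schedule()].
#' @return An object of class `partition`: list with `membership` (named
#'   integer vector, module ids contiguous from 1), `n_modules`, `m_index`.
#' @export
sa_modularity <- function(graph, seed = NULL, schedule = sa_schedule()) {
  n <- length(graph$labels)
  if (nrow(graph$edges) == 0) stop("graph has no edges")
  t0 <- schedule$t0 %||% (1 / n)
  steps <- schedule$steps_per_temp %||% (n^2)
  res <- local_seed(seed,
    sa_anneal_cpp(n, graph$edges - 1L, t0, schedule$cooling,
                  as.integer(steps), t0 * schedule$tmin_factor))
  membership <- stats::setNames(res$membership, graph$labels)
  structure(list(membership = membership, n_modules = res$n_modules,
                 m_index = res$q),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d modules, M = %.4f\n", x$n_modules, x$m_index))
  invisible(x)
}

#' Consensus module membership over repeated annealing runs
#'
#' Runs the annealing search `n_runs` times and summarises the agreement.
#' Raw module ids are not comparable across runs, so consensus works through
#' co-membership frequencies: the reference partition is the highest-M run;
#' the core of a reference module is the set of its members that are never
#' separated from one another in any run (falling back to the member with the
#' highest mean co-membership when no node is that stable); and a node is
#' assigned to its reference module only when its mean co-membership with
#' that core exceeds `threshold` (the "assigned in > 90% of runs" rule),
#' otherwise it is left unassigned (NA).
#'
#' @param graph An `interaction_graph`.
#' @param n_runs Number of annealing runs (>= 2).
#' @param threshold Co-membership frequency required for assignment.
#' @param seed Optional integer seed covering all runs.
#' @param schedule An [sa_schedule()] used for every run.
#' @return An object of class `consensus_result`: list with `runs`, `mean_m`,
#'   `sd_m`, `module_count_distribution`, `co_membership` (symmetric matrix
#'   of frequencies), `reference` (best-run `partition`) and
#'   `assigned_modules` (named vector with NA for unassigned nodes).
#' @export
consensus_partition <- function(graph, n_runs = 50, threshold = 0.9,
                                seed = NULL, schedule = sa_schedule()) {
  stopifnot(n_runs >= 2)
  n <- length(graph$labels)
  runs <- local_seed(seed, lapply(seq_len(n_runs), function(i) {
    sa_modularity(graph, seed = NULL, schedule = schedule)
  }))
  consensus_from_runs(runs, graph$labels, threshold)
}

# Aggregate a list of `partition` runs into a consensus result; split out of
# consensus_partition so the rule can be exercised on constructed run sets.
consensus_from_runs <- function(runs, labels, threshold = 0.9) {
  n <- length(labels)
  n_runs <- length(runs)
  ms <- vapply(runs, function(r) r$m_index, numeric(1))
  co <- matrix(0, n, n, dimnames = list(labels, labels))
  for (r in runs) {
    co <- co + outer(r$membership, r$membership, "==")
  }
  co <- co / n_runs
  ref <- runs[[which.max(ms)]]
  assigned <- stats::setNames(rep(NA_integer_, n), labels)
  for (s in seq_len(ref$n_modules)) {
    members <- which(ref$membership == s)
    sub <- co[members, members, drop = FALSE]
    core <- members[apply(sub, 1, min) >= 1]
    if (length(core) == 0) {
      core <- members[which.max(rowMeans(sub))]
    }
    for (i in members) {
      others <- setdiff(core, i)
      freq <- if (length(others) == 0) 1 else mean(co[i, others])
      if (freq > threshold) assigned[i] <- s
    }
  }
  counts <- table(vapply(runs, function(r) r$n_modules, numeric(1)))
  structure(list(runs = runs, mean_m = mean(ms), sd_m = stats::sd(ms),
                 module_count_distribution = counts / n_runs,
                 co_membership = co, reference = ref,
                 assigned_modules = assigned),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus over %d runs: M = %.4f +/- %.4f; %d/%d nodes assigned\n",
              length(x$runs), x$mean_m, x$sd_m,
              sum(!is.na(x$assigned_modules)), length(x$assigned_modules)))
  invisible(x)
}

#' Classify a node role from its (z, c) coordinates
#'
#' Quadrants at the cutoffs z = 2.5 (within-module degree) and c = 0.62
#' (among-module connectivity): peripheral (low z, low c), connector (low z,
#' high c), module hub (high z, low c), network hub (high z, high c).
#'
#' @param z Standardized within-module degree.
#' @param c Among-module connectivity (participation coefficient).
#' @param z_cut,c_cut Role cutoffs.
#' @return Character vector of roles.
#' @export
role_from_zc <- function(z, c, z_cut = 2.5, c_cut = 0.62) {
  ifelse(z > z_cut,
         ifelse(c > c_cut, "network_hub", "module_hub"),
         ifelse(c > c_cut, "connector", "peripheral"))
}

#' Topological roles of nodes in a modular network
#'
#' For each node, z is its within-module degree standardized over the nodes
#' of its module (z = 0 when the module's within-degrees have zero spread)
#' and c = 1 - sum_t (k_it / k_i)^2 is the among-module connectivity, where
#' k_it counts the node's links into module t. Roles follow [role_from_zc()].
#'
#' @param graph An `interaction_graph`.
#' @param partition A `partition` (or a `consensus_result`, whose reference
#'   partition is then used) covering the graph.
#' @return A data frame with one row per node: `node`, `guild`, `module`,
#'   `z`, `c`, `role`.
#' @export
node_roles <- function(graph, partition) {
  if (inherits(partition, "consensus_result")) partition <- partition$reference
  membership <- partition$membership
  n <- length(graph$labels)
  stopifnot(length(membership) == n)
  k <- graph_degree(graph)
  # links from node i into module t
  mods <- sort(unique(membership))
  kit <- matrix(0L, n, length(mods))
  for (e in seq_len(nrow(graph$edges))) {
    a <- graph$edges[e, 1]; b <- graph$edges[e, 2]
    kit[a, membership[b]] <- kit[a, membership[b]] + 1L
    kit[b, membership[a]] <- kit[b, membership[a]] + 1L
  }
  k_own <- kit[cbind(seq_len(n), membership)]
  z <- numeric(n)
  for (s in mods) {
    idx <- which(membership == s)
    sdv <- stats::sd(k_own[idx])
    z[idx] <- if (length(idx) > 1 && !is.na(sdv) && sdv > 0) {
      (k_own[idx] - mean(k_own[idx])) / sdv
    } else 0
  }
  cpart <- 1 - rowSums((kit / k)^2)
  data.frame(node = graph$labels, guild = graph$guild,
             module = as.integer(membership), z = z, c = cpart,
             role = role_from_zc(z, cpart), row.names = NULL)
}

#' Null-model significance of modularity
#'
#' Compares the observed modularity (the mean M over consensus runs) with M
#' maximised on ER and FF null matrices: for each null matrix the best of
#' `sa_per_null` annealing runs is kept. SES and upper-tail empirical p per
#' [null_ensemble()] conventions. A network can score *less* modular than its
#' nulls (negative SES), which is reported as such.
#'
#' @param matrix A `bipartite_matrix`.
#' @param n_er,n_ff Number of ER / FF null matrices.
#' @param n_runs Consensus runs for the observed matrix.
#' @param sa_per_null Annealing runs per null matrix (best M kept).
#' @param seed Optional integer seed.
#' @param schedule An [sa_schedule()] used throughout.
#' @return List with elements `er` and `ff`, each a `null_ensemble`, plus
#'   `consensus`, the observed `consensus_result`.
#' @export
modularity_significance <- function(matrix, n_er = 100, n_ff = 100,
                                    n_runs = 50, sa_per_null = 1,
                                    seed = NULL, schedule = sa_schedule()) {
  local_seed(seed, {
    cons <- consensus_partition(bipartite_to_graph(matrix), n_runs = n_runs,
                                schedule = schedule)
    stat <- function(m) {
      g <- bipartite_to_graph(m)
      max(vapply(seq_len(sa_per_null), function(i) {
        sa_modularity(g, schedule = schedule)$m_index
      }, numeric(1)))
    }
    run_model <- function(model, n_reps) {
      ens <- null_ensemble(matrix, stat, model = model, n_reps = n_reps)
      ens$observed <- cons$mean_m   # observed M is the consensus mean
      ens$ses <- if (ens$null_sd > 0) (ens$observed - ens$null_mean) / ens$null_sd else 0
      ens$p_value <- (1 + sum(ens$values >= ens$observed)) / (1 + n_reps)
      ens
    }
    list(er = run_model("ER", n_er), ff = run_model("FF", n_ff),
         consensus = cons)
  })
}
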