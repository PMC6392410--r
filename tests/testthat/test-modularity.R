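test_that("bipartite graphs carry one node per label and one edge per link", {
  m <- hummnet:::new_bipartite_matrix(
    matrix(1L, 2, 2, dimnames = list(c("famA", "famB"), c("cl1", "cl2"))))
  g <- bipartite_to_graph(m)
  expect_length(g$labels, 4)
  expect_equal(nrow(g$edges), 4)
  expect_equal(g$guild, rep(c("plant_family", "bird_clade"), each = 2))

  set.seed(3)
  mm <- random_matrix(7, 5)
  expect_equal(nrow(bipartite_to_graph(mm)$edges), link_count(mm))
})

test_that("modularity index matches closed forms and igraph", {
  g <- two_triangles()
  expect_equal(modularity_index(g, rep(1, 6)), 0)
  expect_equal(modularity_index(g, c(1, 1, 1, 2, 2, 2)), 0.5)

  single <- make_graph(2, rbind(c(1, 2)))
  expect_equal(modularity_index(single, c(1, 2)), -0.5)

  expect_error(modularity_index(make_graph(2, matrix(0L, 0, 2)), c(1, 1)),
               "no edges")

  skip_if_not_installed("igraph")
  set.seed(21)
  for (i in 1:25) {
    m <- random_matrix(sample(3:8, 1), sample(3:8, 1))
    g <- bipartite_to_graph(m)
    memb <- sample.int(3, length(g$labels), replace = TRUE)
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    expect_equal(modularity_index(g, memb),
                 igraph::modularity(ig, memb), tolerance = 1e-12)
  }
})

test_that("annealing recovers exhaustive optima on small graphs", {
  g <- two_triangles()
  p <- sa_modularity(g, seed = 1)
  expect_equal(p$m_index, 0.5, tolerance = 1e-12)
  expect_equal(p$n_modules, 2)

  # complete bipartite 3x3: no partition beats the single module at M = 0
  kb <- bipartite_to_graph(hummnet:::new_bipartite_matrix(
    matrix(1L, 3, 3, dimnames = list(paste0("f", 1:3), paste0("c", 1:3)))))
  expect_equal(sa_modularity(kb, seed = 2)$m_index, 0, tolerance = 1e-12)
  expect_equal(best_partition_q(kb$edges, 6), 0, tolerance = 1e-12)

  # identical seed, identical partition
  expect_identical(sa_modularity(g, seed = 9)$membership,
                   sa_modularity(g, seed = 9)$membership)
  expect_error(sa_modularity(g, schedule = sa_schedule(cooling = 1.2)),
               "cooling")

  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    repeat {
      edges <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      edges <- edges[stats::runif(nrow(edges)) < 0.45, , drop = FALSE]
      if (nrow(edges) >= 1) break
    }
    g <- make_graph(n, unname(edges))
    got <- sa_modularity(g, seed = i)$m_index
    want <- best_partition_q(g$edges, n)
    expect_equal(got, want, tolerance = 1e-9)
    expect_gte(got, 0 - 1e-12)  # never below the single-module score
  }
})

test_that("within plus between edge fractions always total one", {
  set.seed(17)
  for (i in 1:20) {
    m <- random_matrix(5, 5)
    g <- bipartite_to_graph(m)
    memb <- sample.int(4, length(g$labels), replace = TRUE)
    within <- sum(memb[g$edges[, 1]] == memb[g$edges[, 2]]) / nrow(g$edges)
    between <- sum(memb[g$edges[, 1]] != memb[g$edges[, 2]]) / nrow(g$edges)
    expect_equal(within + between, 1)
  }
})

test_that("consensus assignment follows the >90% co-membership rule", {
  part <- function(memb, m = NULL) {
    g <- two_triangles()
    structure(list(membership = stats::setNames(memb, g$labels),
                   n_modules = max(memb),
                   m_index = m %||% q_oracle(g$edges, memb)),
              class = "partition")
  }
  labels <- two_triangles()$labels

  # unanimity: every node assigned, sd_m = 0
  runs <- replicate(10, part(c(1, 1, 1, 2, 2, 2)), simplify = FALSE)
  cons <- hummnet:::consensus_from_runs(runs, labels, 0.9)
  expect_true(all(!is.na(cons$assigned_modules)))
  expect_equal(cons$sd_m, 0)

  # node 3 switches modules in half the runs: below threshold, unassigned
  runs <- c(replicate(5, part(c(1, 1, 1, 2, 2, 2), m = 0.5), simplify = FALSE),
            replicate(5, part(c(1, 1, 2, 2, 2, 2), m = 0.4), simplify = FALSE))
  cons <- hummnet:::consensus_from_runs(runs, labels, 0.9)
  expect_true(is.na(cons$assigned_modules["n3"]))
  expect_false(anyNA(cons$assigned_modules[c("n1", "n2", "n4", "n5")]))

  # permuting module labels between runs does not change co-membership
  runs_a <- replicate(6, part(c(1, 1, 1, 2, 2, 2)), simplify = FALSE)
  runs_b <- c(runs_a[1:3],
              replicate(3, part(c(2, 2, 2, 1, 1, 1)), simplify = FALSE))
  expect_identical(hummnet:::consensus_from_runs(runs_a, labels)$co_membership,
                   hummnet:::consensus_from_runs(runs_b, labels)$co_membership)
})

test_that("node roles compute z and c from the stated formulas", {
  # star-within-module: hub has all links inside its own module -> c = 0
  g <- make_graph(5, rbind(c(1, 2), c(1, 3), c(1, 4), c(4, 5)))
  part <- structure(list(membership = stats::setNames(c(1, 1, 1, 1, 2),
                                                      g$labels),
                         n_modules = 2, m_index = 0), class = "partition")
  roles <- node_roles(g, part)
  expect_equal(roles$c[roles$node == "n1"], 0)
  # node 4 splits its 2 links across 2 modules -> c = 0.5
  expect_equal(roles$c[roles$node == "n4"], 0.5)
  # singleton module: sd undefined -> z = 0
  expect_equal(roles$z[roles$node == "n5"], 0)

  # equal within-degrees give z = 0 everywhere, peripheral at low c
  tri <- two_triangles()
  p2 <- structure(list(membership = stats::setNames(c(1, 1, 1, 2, 2, 2),
                                                    tri$labels),
                       n_modules = 2, m_index = 0.5), class = "partition")
  r2 <- node_roles(tri, p2)
  expect_true(all(r2$z == 0))
  expect_true(all(r2$role == "peripheral"))
})

test_that("role quadrants respect the 2.5 / 0.62 cutoffs", {
  zg <- c(-1, 0, 2.4, 2.6, 5)
  cg <- c(0, 0.3, 0.61, 0.63, 0.9)
  grid <- expand.grid(z = zg, c = cg)
  got <- role_from_zc(grid$z, grid$c)
  want <- ifelse(grid$z > 2.5,
                 ifelse(grid$c > 0.62, "network_hub", "module_hub"),
                 ifelse(grid$c > 0.62, "connector", "peripheral"))
  expect_identical(got, want)
})

test_that("block-structured matrices test significantly modular; ER matrices do not", {
  sched <- fast_schedule()
  gen <- generate_records(network_config(
    n_bird_species = 45, n_plant_species = 90, n_clades = 9,
    n_families = 24, target_fill = 0.08, eta = 0, n_blocks = 3,
    block_affinity = 0.95, seed = 5))
  m <- build_matrix(gen$records, gen$maps)
  sig <- modularity_significance(m, n_er = 25, n_ff = 25, n_runs = 8,
                                 seed = 3, schedule = sched)
  expect_gt(sig$er$observed, sig$er$null_mean)
  expect_lt(sig$er$p_value, 0.05)

  # ER-generated matrix: modularity indistinguishable from its own null
  set.seed(8)
  er_m <- null_er(random_matrix(10, 8, 0.35))
  sig2 <- modularity_significance(er_m, n_er = 25, n_ff = 25, n_runs = 8,
                                  seed = 4, schedule = sched)
  expect_lt(abs(sig2$er$ses), 3)
})
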