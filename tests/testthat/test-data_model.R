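records_csv <- function(lines) {
  path <- withr_tempfile()
  writeLines(c("bird_species,plant_species,source_id,plant_native", lines),
             path)
  path
}

# minimal local stand-in for withr::local_tempfile
withr_tempfile <- function() tempfile(fileext = ".csv")

toy_maps <- function() {
  taxon_maps(
    c(b1 = "Bees", b2 = "Emeralds", b3 = "Hermits"),
    c(p1 = "Fabaceae", p2 = "Fabaceae", p3 = "Rosaceae", px = "Musaceae"),
    c(Fabaceae = "ornithophilous", Rosaceae = "intermediate",
      Musaceae = "non-ornithophilous"))
}

test_that("record parsing handles flags, duplicates and bad rows", {
  p <- records_csv(c("b1,p1,s1,true", "b2,p2,s2,exotic"))
  recs <- read_interaction_records(p)
  expect_equal(nrow(recs), 2)
  expect_identical(recs$plant_native, c(TRUE, FALSE))

  # duplicates are retained at read time
  p <- records_csv(c("b1,p1,s1,1", "b1,p1,s2,1"))
  expect_equal(nrow(read_interaction_records(p)), 2)

  # empty species and unparsable flags are row-level errors with line numbers
  p <- records_csv(c("b1,p1,s1,true", "b1,,s2,true"))
  expect_error(read_interaction_records(p), "plant_species at line\\(s\\): 3")
  p <- records_csv(c("b1,p1,s1,maybe"))
  expect_error(read_interaction_records(p), "plant_native value at line\\(s\\): 2")
  p <- withr_tempfile()
  writeLines(c("bird_species,plant_species,source_id", "b1,p1,s1"), p)
  expect_error(read_interaction_records(p), "plant_native")
})

test_that("matrix construction collapses records and filters natives at the record level", {
  recs <- data.frame(
    bird_species = c("b1", "b1", "b2", "b2", "b3"),
    plant_species = c("p1", "p3", "p2", "p3", "px"),
    source_id = "s",
    plant_native = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  m <- build_matrix(recs, toy_maps())
  expect_s3_class(m, "bipartite_matrix")
  expect_setequal(rownames(m), c("Fabaceae", "Rosaceae", "Musaceae"))
  expect_equal(link_count(m), 5)
  expect_true(all(unclass(m) %in% 0:1))

  # native filter drops the exotic-only family but keeps mixed families
  mn <- build_matrix(recs, toy_maps(), native_only = TRUE)
  expect_setequal(rownames(mn), c("Fabaceae", "Rosaceae"))
  expect_lte(link_count(mn), link_count(m))
  expect_true(all(rownames(mn) %in% rownames(m)))

  # saturated case: all pairs present
  recs2 <- data.frame(bird_species = c("b1", "b1", "b2", "b2"),
                      plant_species = c("p1", "p3", "p1", "p3"),
                      source_id = "s", plant_native = TRUE)
  m2 <- build_matrix(recs2, toy_maps())
  expect_equal(unname(hummnet:::unclass_matrix(m2)), matrix(1L, 2, 2),
               ignore_attr = TRUE)

  # duplicating every record changes nothing (idempotence)
  m3 <- build_matrix(rbind(recs, recs), toy_maps())
  expect_identical(unclass(m3), unclass(m))

  expect_error(build_matrix(data.frame(bird_species = "zz",
                                       plant_species = "p1",
                                       source_id = "s", plant_native = TRUE),
                            toy_maps()),
               "unmapped species: zz")
  expect_error(build_matrix(recs[5, ], toy_maps(), native_only = TRUE),
               "no records")
})

test_that("degree ordering sorts by links with alphabetical tie-break", {
  m <- new_matrix <- build_matrix(data.frame(
    bird_species = c("b1", "b1", "b2", "b1", "b3"),
    plant_species = c("p1", "p3", "p3", "px", "px"),
    source_id = "s", plant_native = TRUE), toy_maps())
  om <- order_matrix(m, "degree")
  expect_equal(rowSums(unclass(om)), sort(rowSums(unclass(m)),
                                          decreasing = TRUE),
               ignore_attr = TRUE)
  expect_identical(attr(om, "order_mode"), "degree")
  # equal-degree rows come out alphabetically
  deg <- rowSums(unclass(om))
  for (d in unique(deg)) {
    expect_false(is.unsorted(rownames(om)[deg == d]))
  }
  # ordering never changes the degree multisets or total links
  expect_setequal(unname(rowSums(unclass(om))), unname(rowSums(unclass(m))))
  expect_equal(link_count(om), link_count(m))
})

test_that("given ordering applies permutations and validates them", {
  m <- build_matrix(data.frame(
    bird_species = c("b1", "b2", "b3"), plant_species = c("p1", "p3", "px"),
    source_id = "s", plant_native = TRUE), toy_maps())
  same <- order_matrix(m, "given", row_order = rownames(m),
                       col_order = colnames(m))
  expect_identical(hummnet:::unclass_matrix(same),
                   hummnet:::unclass_matrix(m))
  rev_rows <- order_matrix(m, "given", row_order = rev(rownames(m)))
  expect_identical(rownames(rev_rows), rev(rownames(m)))
  expect_error(order_matrix(m, "given", row_order = c("Fabaceae", "Nope")),
               "not a permutation")
})

test_that("matrix CSV round-trips labels, ordering and cells exactly", {
  set.seed(11)
  m <- new_bipartite_matrix <- hummnet:::new_bipartite_matrix(
    random_matrix(7, 4), "degree")
  path <- tempfile(fileext = ".csv")
  write_matrix_csv(m, path)
  back <- read_matrix_csv(path, order_mode = "degree")
  expect_identical(unclass(hummnet:::unclass_matrix(back)),
                   unclass(hummnet:::unclass_matrix(m)))
})

test_that("Newick tip order follows left-to-right traversal", {
  p <- tempfile(fileext = ".nwk")
  writeLines("(A,(B,C));", p)
  expect_identical(read_tip_order(p), c("A", "B", "C"))
  writeLines("((A,B),(C,D));", p)
  expect_identical(read_tip_order(p), c("A", "B", "C", "D"))
  writeLines(c("(A,B);", "(C,D);"), p)
  expect_error(read_tip_order(p), "2 trees")
  writeLines("((A,B);", p)
  expect_error(read_tip_order(p), "unbalanced parentheses")
})
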