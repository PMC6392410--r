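#' The nine hummingbird clades
#'
#' Fixed clade vocabulary used throughout the package. Hummingbird species are
#' aggregated to these clades (lineages recognised by molecular phylogenetics)
#' before any network analysis.
#'
#' @return Character vector of the nine clade names.
#' @export
hummingbird_clades <- function() {
  c("Bees", "Brilliants", "Coquettes", "Emeralds", "Hermits",
    "Mangoes", "Mountain Gems", "Patagona", "Topazes")
}

#' Floral pollination syndrome categories
#'
#' @return Character vector of the three syndrome labels.
#' @export
syndrome_levels <- function() {
  c("ornithophilous", "intermediate", "non-ornithophilous")
}

#' Read species-level visitation records
#'
#' Reads a CSV of hummingbird-flower visitation records. Each row documents
#' one reported visit of a hummingbird species to a nectar plant species.
#' Duplicate (bird, plant) pairs are retained; collapsing to binary links
#' happens in [build_matrix()].
#'
#' @param path Path to a CSV file with columns `bird_species`,
#'   `plant_species`, `source_id` and `plant_native`.
#' @return A data frame with one row per record; `plant_native` is logical
#'   (TRUE if the plant is native to the New World).
#' @export
read_interaction_records <- function(path) {
  if (!file.exists(path)) stop("record file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("bird_species", "plant_species", "source_id", "plant_native")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("record file is missing column(s): ", paste(missing, collapse = ", "))
  }
  # data rows start at line 2 (line 1 is the header)
  line_no <- seq_len(nrow(df)) + 1L
  bad_bird <- is.na(df$bird_species) | !nzchar(trimws(df$bird_species))
  if (any(bad_bird)) {
    stop("empty bird_species at line(s): ",
         paste(line_no[bad_bird], collapse = ", "))
  }
  bad_plant <- is.na(df$plant_species) | !nzchar(trimws(df$plant_species))
  if (any(bad_plant)) {
    stop("empty plant_species at line(s): ",
         paste(line_no[bad_plant], collapse = ", "))
  }
  df$plant_native <- parse_native_flag(df$plant_native, line_no)
  df[, needed]
}

# Accepts true/false, 1/0, native/exotic (any case); anything else is a
# row-level error naming the offending line.
parse_native_flag <- function(x, line_no) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(key))
  out[key %in% c("true", "1", "native")] <- TRUE
  out[key %in% c("false", "0", "exotic")] <- FALSE
  if (anyNA(out)) {
    stop("unparsable plant_native value at line(s): ",
         paste(line_no[is.na(out)], collapse = ", "))
  }
  out
}

#' Assemble taxon maps
#'
#' Bundles the species-to-group lookups needed to aggregate species-level
#' records into the clade-by-family network: hummingbird species to clade,
#' plant species to family, and plant family to floral pollination syndrome.
#'
#' @param bird_to_clade Named character vector: names are hummingbird species,
#'   values one of [hummingbird_clades()].
#' @param plant_to_family Named character vector: names are plant species,
#'   values are family names.
#' @param family_syndrome Optional named character vector: names are families,
#'   values one of [syndrome_levels()].
#' @return An object of class `taxon_maps`.
#' @export
taxon_maps <- function(bird_to_clade, plant_to_family, family_syndrome = NULL) {
  stopifnot(is.character(bird_to_clade), !is.null(names(bird_to_clade)),
            is.character(plant_to_family), !is.null(names(plant_to_family)))
  bad <- setdiff(unique(bird_to_clade), hummingbird_clades())
  if (length(bad) > 0) {
    stop("unknown clade label(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(family_syndrome)) {
    bad <- setdiff(unique(family_syndrome), syndrome_levels())
    if (length(bad) > 0) {
      stop("unknown syndrome label(s): ", paste(bad, collapse = ", "))
    }
  }
  structure(list(bird_to_clade = bird_to_clade,
                 plant_to_family = plant_to_family,
                 family_syndrome = family_syndrome),
            class = "taxon_maps")
}

#' Read taxon maps from CSV files
#'
#' @param bird_path CSV with columns `species`, `group` (clade).
#' @param plant_path CSV with columns `species`, `group` (family).
#' @param syndrome_path Optional CSV with columns `family`, `syndrome`.
#' @return An object of class `taxon_maps`.
#' @export
read_taxon_maps <- function(bird_path, plant_path, syndrome_path = NULL) {
  read_map <- function(path, key, value) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c(key, value) %in% names(df))) {
      stop("map file ", path, " must have columns ", key, ", ", value)
    }
    stats::setNames(df[[value]], df[[key]])
  }
  syn <- if (!is.null(syndrome_path)) {
    read_map(syndrome_path, "family", "syndrome")
  }
  taxon_maps(read_map(bird_path, "species", "group"),
             read_map(plant_path, "species", "group"),
             syn)
}

new_bipartite_matrix <- function(cells, order_mode = "unordered") {
  storage.mode(cells) <- "integer"
  names(dimnames(cells)) <- NULL
  structure(cells, class = c("bipartite_matrix", class(cells)),
            order_mode = order_mode)
}

#' Build the clade-by-family interaction matrix
#'
#' Collapses species-level visitation records to a binary matrix with plant
#' families in rows and hummingbird clades in columns. A cell is 1 when at
#' least one record links any species of the family to any species of the
#' clade (a single species-level record suffices; the matrix is qualitative).
#' With `native_only = TRUE` records of plants non-native to the New World are
#' discarded before aggregation, so a family remains if any native member was
#' visited. Families and clades left without links are dropped.
#'
#' @param records Data frame from [read_interaction_records()].
#' @param maps A [taxon_maps()] object covering every species in `records`.
#' @param native_only Drop records of non-native plants before aggregating?
#' @return A `bipartite_matrix`: binary integer matrix, rows = families
#'   (alphabetical), columns = clades (alphabetical), with attribute
#'   `order_mode = "unordered"`.
#' @export
build_matrix <- function(records, maps, native_only = FALSE) {
  stopifnot(inherits(maps, "taxon_maps"))
  unmapped_b <- setdiff(unique(records$bird_species), names(maps$bird_to_clade))
  unmapped_p <- setdiff(unique(records$plant_species), names(maps$plant_to_family))
  if (length(unmapped_b) + length(unmapped_p) > 0) {
    stop("unmapped species: ",
         paste(c(unmapped_b, unmapped_p), collapse = ", "))
  }
  if (native_only) records <- records[records$plant_native, , drop = FALSE]
  if (nrow(records) == 0) stop("no records left after filtering")
  fam <- maps$plant_to_family[records$plant_species]
  cla <- maps$bird_to_clade[records$bird_species]
  cells <- table(factor(fam), factor(cla))
  cells <- matrix(as.integer(cells > 0), nrow = nrow(cells),
                  dimnames = dimnames(cells))
  cells <- cells[rowSums(cells) > 0, colSums(cells) > 0, drop = FALSE]
  if (length(cells) == 0 || sum(cells) == 0) {
    stop("empty matrix after construction")
  }
  new_bipartite_matrix(cells, "unordered")
}

#' Reorder a bipartite matrix
#'
#' `mode = "degree"` sorts rows and columns by descending link count, ties
#' broken alphabetically by label (the ordering used to display nestedness).
#' `mode = "given"` applies externally supplied permutations, e.g. a
#' phylogenetic tip order from [read_tip_order()].
#'
#' @param matrix A `bipartite_matrix`.
#' @param mode `"degree"` or `"given"`.
#' @param row_order,col_order For `mode = "given"`: character vectors that are
#'   permutations of the current row/column labels. Either may be `NULL` to
#'   leave that margin untouched.
#' @return The reordered `bipartite_matrix` with `order_mode` set to the mode.
#' @export
order_matrix <- function(matrix, mode = c("degree", "given"),
                         row_order = NULL, col_order = NULL) {
  mode <- match.arg(mode)
  m <- unclass_matrix(matrix)
  if (mode == "degree") {
    ro <- order(-rowSums(m), rownames(m))
    co <- order(-colSums(m), colnames(m))
    out <- m[ro, co, drop = FALSE]
  } else {
    check_perm <- function(ord, have, what) {
      if (is.null(ord)) return(have)
      extra <- setdiff(ord, have); miss <- setdiff(have, ord)
      if (length(extra) + length(miss) > 0 || length(ord) != length(have)) {
        stop(what, " order is not a permutation; missing: ",
             paste(miss, collapse = ", "), "; extra: ",
             paste(extra, collapse = ", "))
      }
      ord
    }
    ro <- check_perm(row_order, rownames(m), "row")
    co <- check_perm(col_order, colnames(m), "column")
    out <- m[ro, co, drop = FALSE]
  }
  new_bipartite_matrix(out, mode)
}

#' Read a phylogenetic tip order from a Newick file
#'
#' Returns tip labels in left-to-right traversal order of a single Newick
#' tree; branch lengths are ignored. The result can be passed to
#' [order_matrix()] as a fixed (phylogenetic) node order.
#'
#' @param path Path to a file containing exactly one Newick tree.
#' @return Character vector of tip labels.
#' @export
read_tip_order <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- cumsum((strsplit(txt, "")[[1]] == "(") -
                  (strsplit(txt, "")[[1]] == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0) {
    stop("unbalanced parentheses in Newick at character ",
         if (any(depth < 0)) which(depth < 0)[1] else length(depth))
  }
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    stop("file contains ", length(tr), " trees; exactly one expected")
  }
  if (!inherits(tr, "phylo")) stop("could not parse a tree from ", path)
  # ape numbers tips in their order of appearance in the Newick string,
  # which is the left-to-right traversal order
  tr$tip.label
}

#' Write a bipartite matrix to CSV
#'
#' Layout: first row holds the hummingbird clade labels, first column the
#' plant family labels, cells are 0/1.
#'
#' @param matrix A `bipartite_matrix`.
#' @param path Output path.
#' @export
write_matrix_csv <- function(matrix, path) {
  m <- unclass_matrix(matrix)
  df <- data.frame(family = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bipartite matrix from CSV
#'
#' Inverse of [write_matrix_csv()]; labels, ordering and cells round-trip
#' exactly.
#'
#' @param path Path to a matrix CSV (first column family labels, header row
#'   clade labels, binary cells).
#' @param order_mode Ordering state to record on the result.
#' @return A `bipartite_matrix`.
#' @export
read_matrix_csv <- function(path, order_mode = "given") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!all(m %in% c(0L, 1L))) stop("matrix cells must be 0/1")
  new_bipartite_matrix(m, order_mode)
}

#' Total number of links in a bipartite matrix
#'
#' @param matrix A `bipartite_matrix` (or plain binary matrix).
#' @return Integer link count.
#' @export
link_count <- function(matrix) sum(unclass_matrix(matrix))

unclass_matrix <- function(m) {
  attr(m, "order_mode") <- NULL
  class(m) <- "matrix"
  m
}

#' @export
print.bipartite_matrix <- function(x, ...) {
  cat(sprintf("bipartite matrix: %d plant families x %d hummingbird clades, %d links (fill %.3f), order: %s\n",
              nrow(x), ncol(x), sum(x), mean(x),
              attr(x, "order_mode")))
  invisible(x)
}
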