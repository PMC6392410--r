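#' Read a per-species biogeography table
#'
#' Columns: `species`, `clade` (one of [hummingbird_clades()]), the region
#' presence flags `nearctic`, `neotropical`, `austral` (0/1 or TRUE/FALSE),
#' `lat_min`, `lat_max` (degrees, southern latitudes negative), `elev_min`,
#' `elev_max` (metres) and `center` (center of diversification, `"North
#' America"` or `"South America"`). Species recorded only on islands may
#' carry no mainland-region flag at all; such rows are kept in the table but
#' excluded from region-based summaries and models.
#'
#' @param path CSV path.
#' @return A data frame of class `species_biogeo`.
#' @export
read_biogeo <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("species", "clade", "nearctic", "neotropical", "austral",
              "lat_min", "lat_max", "elev_min", "elev_max", "center")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("biogeography table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("nearctic", "neotropical", "austral")) {
    df[[col]] <- as.logical(df[[col]])
    if (anyNA(df[[col]])) stop("unparsable flag in column ", col)
  }
  bad <- setdiff(unique(df$clade), hummingbird_clades())
  if (length(bad) > 0) stop("unknown clade(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$center), c("North America", "South America"))
  if (length(bad) > 0) stop("unknown center(s): ", paste(bad, collapse = ", "))
  if (any(df$lat_max < df$lat_min)) stop("lat_max < lat_min for some species")
  if (any(df$elev_max < df$elev_min)) stop("elev_max < elev_min for some species")
  class(df) <- c("species_biogeo", class(df))
  df
}

n_regions <- function(table) {
  table$nearctic + table$neotropical + table$austral
}

#' Region occupancy counts and percentages
#'
#' Tallies how the species distribute over the Nearctic, Neotropical and
#' Austral regions: per-region totals, the exclusively-Nearctic and
#' Nearctic-plus-Neotropical sets (jointly the "Nearctic-related" species),
#' the completely and partially Austral sets, species in two or more regions,
#' and species with no mainland-region flag. Percentages are over the full
#' table size.
#'
#' @param table A `species_biogeo` data frame.
#' @return A data frame with columns `category`, `count`, `percent`.
#' @export
species_region_summary <- function(table) {
  stopifnot(nrow(table) > 0)
  n <- nrow(table)
  counts <- c(
    nearctic = sum(table$nearctic),
    neotropical = sum(table$neotropical),
    austral = sum(table$austral),
    nearctic_exclusive = sum(table$nearctic & !table$neotropical & !table$austral),
    nearctic_and_neotropical = sum(table$nearctic & table$neotropical),
    nearctic_related = sum(table$nearctic),
    austral_complete = sum(table$austral & !table$neotropical & !table$nearctic),
    austral_partial = sum(table$austral & (table$neotropical | table$nearctic)),
    austral_related = sum(table$austral),
    multi_region = sum(n_regions(table) >= 2),
    no_region = sum(n_regions(table) == 0)
  )
  data.frame(category = names(counts), count = as.integer(counts),
             percent = 100 * counts / n, row.names = NULL)
}

#' Clade-level biogeographic summary
#'
#' For each clade: the percentage of its species carrying each region flag
#' (flags are not exclusive, so percentages need not sum to 100), the modal
#' center of diversification, means and sample (n-1) standard deviations of
#' the latitudinal and elevational limits, and the latitudinal/elevational
#' range of the clade computed as the difference of the clade means (not the
#' mean of per-species ranges).
#'
#' @param table A `species_biogeo` data frame.
#' @return A data frame with one row per clade present in the table.
#' @export
clade_summary <- function(table) {
  stopifnot(nrow(table) > 0, !anyNA(table$clade))
  do.call(rbind, lapply(split(table, table$clade), function(g) {
    msd <- function(x) c(mean(x), if (nrow(g) > 1) stats::sd(x) else 0)
    lat_max <- msd(g$lat_max); lat_min <- msd(g$lat_min)
    elev_min <- msd(g$elev_min); elev_max <- msd(g$elev_max)
    centers <- table(g$center)
    data.frame(
      clade = g$clade[1], n_species = nrow(g),
      pct_nearctic = 100 * mean(g$nearctic),
      pct_neotropical = 100 * mean(g$neotropical),
      pct_austral = 100 * mean(g$austral),
      diversification_center = names(centers)[which.max(centers)],
      mean_lat_max = lat_max[1], sd_lat_max = lat_max[2],
      mean_lat_min = lat_min[1], sd_lat_min = lat_min[2],
      mean_lat_range = lat_max[1] - lat_min[1],
      mean_elev_min = elev_min[1], sd_elev_min = elev_min[2],
      mean_elev_max = elev_max[1], sd_elev_max = elev_max[2],
      mean_elev_range = elev_max[1] - elev_min[1],
      row.names = NULL)
  }))
}

#' Floral syndrome composition of the matrix families
#'
#' Counts and percentages of the three pollination-syndrome categories over
#' the plant families present in the matrix rows.
#'
#' @param maps A [taxon_maps()] with `family_syndrome` filled in.
#' @param matrix A `bipartite_matrix` whose rows are plant families.
#' @return A data frame with columns `syndrome`, `count`, `percent`.
#' @export
syndrome_summary <- function(maps, matrix) {
  stopifnot(inherits(maps, "taxon_maps"))
  if (is.null(maps$family_syndrome)) stop("taxon maps carry no syndromes")
  fams <- rownames(unclass_matrix(matrix))
  missing <- setdiff(fams, names(maps$family_syndrome))
  if (length(missing) > 0) {
    stop("families without syndrome annotation: ",
         paste(missing, collapse = ", "))
  }
  syn <- factor(maps$family_syndrome[fams], levels = syndrome_levels())
  counts <- table(syn)
  data.frame(syndrome = names(counts), count = as.integer(counts),
             percent = 100 * as.integer(counts) / length(fams),
             row.names = NULL)
}
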