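# Builds the synthetic stand-in fixtures under inst/extdata/. The empirical
# supplementary tables of the source data set are not redistributable here,
# so these stand-ins are constructed to satisfy the published marginal
# constraints (matrix dimensions and link counts, native-filter effects,
# clade-level region percentages and region-combination counts, per-clade
# latitudinal/elevational means, and the niche-conservatism GLM contingency
# structure). Everything is deterministic.
#
# Run from the package root: Rscript data-raw/make_fixtures.R

library(hummnet)
set.seed(20190227)
out <- file.path("inst", "extdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## ---- interaction records -------------------------------------------------
# Clades ordered from most to least generalist; a family of native degree d
# connects to the first d clades, giving a perfectly nested native backbone.
clade_rank <- c("Emeralds", "Bees", "Mountain Gems", "Hermits", "Coquettes",
                "Mangoes", "Brilliants", "Topazes", "Patagona")

core13 <- c("Asteraceae", "Bromeliaceae", "Gesneriaceae", "Campanulaceae",
            "Rubiaceae", "Lamiaceae", "Ericaceae", "Marcgraviaceae",
            "Solanaceae", "Malvaceae", "Fabaceae", "Loranthaceae",
            "Heliconiaceae")
# families whose exotic members add links that the native filter removes
mixed <- data.frame(family = c("Myrtaceae", "Rutaceae", "Strelitziaceae"),
                    native_deg = c(2, 1, 2), full_deg = c(8, 5, 6))
# families visited only through exotic species (dropped by the native filter)
exotic_only <- data.frame(family = c("Musaceae", "Oleaceae", "Pittosporaceae",
                                     "Vitaceae", "Xanthorrhoeaceae"),
                          deg = c(4, 2, 1, 2, 1))
# filler native families: degree profile summing with the named families to
# 385 native links over 100 native families, with exactly three clades
# connected to more than 50 native families
filler_degs <- rep(c(8, 7, 6, 5, 4, 3, 2, 1), c(4, 4, 5, 6, 10, 14, 20, 21))
stopifnot(length(filler_degs) == 84,
          sum(filler_degs) + 13 * 9 + sum(mixed$native_deg) == 385)
filler <- sprintf("Family%03d", seq_along(filler_degs))

birds <- paste0(rep(gsub(" ", "", clade_rank), each = 3), "_bird", 1:3)
bird_map <- setNames(rep(clade_rank, each = 3), birds)

records <- list()
emit <- function(family, ranks, native, sp_suffix = "sp1") {
  if (length(ranks) == 0) return()
  bird <- paste0(gsub(" ", "", clade_rank[ranks]), "_bird",
                 (seq_along(ranks) %% 3) + 1)
  records[[length(records) + 1]] <<- data.frame(
    bird_species = bird,
    plant_species = paste0(family, "_", sp_suffix),
    source_id = paste0("src", (seq_along(ranks) %% 7) + 1),
    plant_native = native)
}
for (f in core13) emit(f, 1:9, TRUE)
for (i in seq_len(nrow(mixed))) {
  emit(mixed$family[i], seq_len(mixed$native_deg[i]), TRUE)
  emit(mixed$family[i], (mixed$native_deg[i] + 1):mixed$full_deg[i],
       FALSE, "x1")
}
for (i in seq_len(nrow(exotic_only))) {
  emit(exotic_only$family[i], seq_len(exotic_only$deg[i]), FALSE, "x1")
}
for (i in seq_along(filler)) emit(filler[i], seq_len(filler_degs[i]), TRUE)
# duplicates and an exotic visit to an already-native cell: both must be
# no-ops for the binary matrix
emit("Fabaceae", 1:3, TRUE, "sp2")
emit("Fabaceae", 1, FALSE, "x9")
records <- do.call(rbind, records)
records <- records[sample.int(nrow(records)), ]

plants <- unique(records$plant_species)
plant_map <- setNames(sub("_(sp|x)[0-9]+$", "", plants), plants)

all_families <- unique(plant_map)
syn <- setNames(rep("non-ornithophilous", length(all_families)), all_families)
# 100 native families split 14 / 36 / 50 across the syndromes; the core and
# a slice of the fillers are the bird-adapted ones
native_fams <- c(core13, mixed$family, filler)
syn[c(core13, filler[1])] <- "ornithophilous"
syn[filler[2:37]] <- "intermediate"
stopifnot(sum(syn[native_fams] == "ornithophilous") == 14,
          sum(syn[native_fams] == "intermediate") == 36,
          sum(syn[native_fams] == "non-ornithophilous") == 50)

write.csv(records, file.path(out, "synthetic_records.csv"),
          row.names = FALSE, quote = FALSE)
write.csv(data.frame(species = names(bird_map), group = unname(bird_map)),
          file.path(out, "synthetic_bird_clades.csv"),
          row.names = FALSE, quote = FALSE)
write.csv(data.frame(species = names(plant_map), group = unname(plant_map)),
          file.path(out, "synthetic_plant_families.csv"),
          row.names = FALSE, quote = FALSE)
write.csv(data.frame(family = names(syn), syndrome = unname(syn)),
          file.path(out, "synthetic_family_syndromes.csv"),
          row.names = FALSE, quote = FALSE)

maps <- taxon_maps(bird_map, plant_map, syn)
full <- build_matrix(records, maps, native_only = FALSE)
nat <- build_matrix(records, maps, native_only = TRUE)
stopifnot(nrow(full) == 105, link_count(full) == 409,
          nrow(nat) == 100, link_count(nat) == 385,
          sum(rowSums(unclass(nat)) == 9) == 13,
          sum(colSums(unclass(nat)) > 50) == 3)
write_matrix_csv(order_matrix(full, "degree"),
                 file.path(out, "synthetic_matrix_full.csv"))

## ---- biogeography table --------------------------------------------------
# Flag layout per clade: islanders carry no mainland-region flag; the
# remaining counts reproduce the published per-clade region percentages,
# the exclusive/shared region totals, and (through the center assignment)
# the niche-conservatism GLM statistics.
flag_block <- function(n_island, n_exclN, n_exclA, n_NNeo, n_ANeo, n_triple,
                       n_total) {
  n_neo_only <- n_total - n_island - n_exclN - n_exclA - n_NNeo - n_ANeo -
    n_triple
  stopifnot(n_neo_only >= 0)
  kind <- rep(c("island", "exclN", "exclA", "NNeo", "ANeo", "triple", "Neo"),
              c(n_island, n_exclN, n_exclA, n_NNeo, n_ANeo, n_triple,
                n_neo_only))
  data.frame(
    kind = kind,
    nearctic = kind %in% c("exclN", "NNeo", "triple"),
    neotropical = kind %in% c("NNeo", "ANeo", "triple", "Neo"),
    austral = kind %in% c("exclA", "ANeo", "triple"))
}
blocks <- list(
  Bees = flag_block(3, 1, 2, 11, 1, 0, 33),
  Brilliants = flag_block(0, 0, 0, 0, 3, 0, 38),
  Coquettes = flag_block(0, 1, 2, 0, 11, 0, 53),
  Emeralds = flag_block(7, 1, 0, 14, 5, 1, 96),
  Hermits = flag_block(0, 0, 0, 1, 0, 0, 26),
  Mangoes = flag_block(5, 0, 0, 2, 1, 0, 27),
  `Mountain Gems` = flag_block(0, 0, 0, 6, 0, 0, 15),
  Patagona = flag_block(0, 0, 0, 0, 1, 0, 1),
  Topazes = flag_block(0, 0, 0, 0, 0, 0, 3))

# center of diversification: all Bees / Mountain Gems, plus a handful of
# northern-origin species inside the southern clades
centers <- list(
  Bees = function(b) rep("North America", nrow(b)),
  `Mountain Gems` = function(b) rep("North America", nrow(b)),
  Coquettes = function(b) ifelse(b$kind == "ANeo" |
                                   seq_len(nrow(b)) %in% which(b$kind == "Neo")[1:2],
                                 "North America", "South America"),
  Hermits = function(b) ifelse(b$kind == "NNeo" |
                                 seq_len(nrow(b)) %in% which(b$kind == "Neo")[1],
                               "North America", "South America"),
  Mangoes = function(b) ifelse(b$kind %in% c("NNeo", "ANeo") |
                                 seq_len(nrow(b)) %in% which(b$kind == "Neo")[1],
                               "North America", "South America"),
  Emeralds = function(b) ifelse(seq_len(nrow(b)) %in%
                                  c(which(b$kind == "NNeo")[1],
                                    which(b$kind == "Neo")[1]),
                                "North America", "South America"))
default_center <- function(b) rep("South America", nrow(b))

# per-clade latitudinal / elevational targets (mean max lat, mean min lat,
# mean min elev, mean max elev) and generation sds
lat_elev <- list(
  Bees = c(19.300, 7.567, 551.833, 2327.333, 21.131, 19.772, 604.715, 792.586),
  `Mountain Gems` = c(13.667, 2.667, 621.333, 2251.667, 13.308, 16.387, 548.216, 922.848),
  Emeralds = c(9.878, -0.011, 296.889, 1657.500, 11.355, 14.835, 408.318, 874.586),
  Patagona = c(0, -35.000, 0, 3660, 0, 0, 0, 0),
  Coquettes = c(0.453, -11.548, 1608.208, 2807.453, 11.360, 13.929, 1205.671, 1344.139),
  Brilliants = c(3.579, -6.895, 1640.789, 2973.947, 6.954, 8.953, 907.763, 819.316),
  Mangoes = c(7.182, -13.591, 427.500, 1674.318, 11.839, 12.308, 599.042, 958.464),
  Hermits = c(4.538, -11.923, 69.846, 1130.346, 11.704, 11.527, 186.879, 648.366),
  Topazes = c(3.333, -18.000, 83.333, 1166.667, 13.317, 15.010, 144.338, 585.946))

scale_to_mean <- function(x, target) {
  if (length(x) == 1) return(target)
  if (target == 0) return(x - mean(x))
  x * target / mean(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rows <- lapply(names(blocks), function(cl) {
  b <- blocks[[cl]]
  n <- nrow(b)
  t <- lat_elev[[cl]]
  lat_max <- stats::rnorm(n, t[1], t[5])
  lat_max <- lat_max - mean(lat_max) + t[1]
  lat_range <- scale_to_mean(abs(stats::rnorm(n, t[1] - t[2], 5)) + 1,
                             t[1] - t[2])
  elev_min <- scale_to_mean(abs(stats::rnorm(n, max(t[3], 1), t[7] / 2)) + 1,
                            max(t[3], 1e-9))
  elev_range <- scale_to_mean(abs(stats::rnorm(n, t[4] - t[3], t[8] / 2)) + 1,
                              t[4] - t[3])
  if (n == 1) { lat_max <- t[1]; lat_range <- t[1] - t[2]
                elev_min <- t[3]; elev_range <- t[4] - t[3] }
  ctr <- (centers[[cl]] %||% default_center)(b)
  data.frame(
    species = sprintf("%s_sp%03d", gsub(" ", "", cl), seq_len(n)),
    clade = cl,
    nearctic = as.integer(b$nearctic),
    neotropical = as.integer(b$neotropical),
    austral = as.integer(b$austral),
    lat_min = round(lat_max - lat_range, 3), lat_max = round(lat_max, 3),
    elev_min = round(elev_min, 3), elev_max = round(elev_min + elev_range, 3),
    center = ctr)
})
bio <- do.call(rbind, rows)
write.csv(bio, file.path(out, "synthetic_biogeo.csv"),
          row.names = FALSE, quote = FALSE)

## ---- verification --------------------------------------------------------
bio2 <- read_biogeo(file.path(out, "synthetic_biogeo.csv"))
rs <- species_region_summary(bio2)
get <- function(cat, col) rs[rs$category == cat, col]
stopifnot(nrow(bio2) == 292,
          get("neotropical", "count") == 270,
          abs(get("neotropical", "percent") - 92.5) < 0.05,
          get("nearctic_related", "count") == 38,
          get("austral_related", "count") == 27,
          get("nearctic_exclusive", "count") == 3,
          get("austral_complete", "count") == 4)
cs <- clade_summary(bio2)
stopifnot(abs(cs$pct_nearctic[cs$clade == "Bees"] - 36.364) < 0.001,
          abs(cs$mean_lat_range[cs$clade == "Bees"] - 11.733) < 0.001)
fit <- fit_niche_glm(bio2, "center", "logit")
lrt <- lr_chi_test(fit)
stopifnot(abs(fit$odds_ratios["centerNorth America"] - 9.080) < 0.001,
          abs(lrt$chi - 46.114) < 0.001, lrt$df == 1)
fit_cl <- fit_niche_glm(bio2, "clade", "logit")
lrt_cl <- lr_chi_test(fit_cl)
stopifnot(abs(lrt_cl$chi - 21.887) < 0.001, lrt_cl$df == 7)
cat("fixtures written and verified\n")
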