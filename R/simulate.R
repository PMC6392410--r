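#' Configuration for the synthetic network generator
#'
#' Defaults emulate the scale of the compiled continental data set: 292
#' hummingbird species in 9 clades, 1287 plant species in 100 families, and a
#' species-level fill of about 0.012 (roughly 4500 interactions). The latent
#' nestedness strength `eta` defaults to 2, which produces the clearly nested
#' aggregated matrices typical of mutualistic networks; `n_blocks = 0` means
#' no imposed modular structure.
#'
#' @param n_bird_species,n_plant_species Species counts.
#' @param n_clades,n_families Group counts (clades capped at the nine named
#'   clades).
#' @param target_fill Target fill of the species-level matrix, in (0, 1);
#'   realised fill is accepted within +/-10% by rejection sampling.
#' @param eta Nestedness strength (>= 0): interaction odds scale with
#'   exp(eta * (u_i + v_j)) for latent generalism scores u, v.
#' @param n_blocks Number of modules imposed on clades/families (0 = none).
#' @param block_affinity In [0, 1]: between-block interaction probabilities
#'   are multiplied by (1 - block_affinity), so larger values give stronger
#'   modular structure.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `network_config`.
#' @export
network_config <- function(n_bird_species = 292, n_plant_species = 1287,
                           n_clades = 9, n_families = 100,
                           target_fill = 0.012, eta = 2,
                           n_blocks = 0, block_affinity = 0.8, seed = 1) {
  stopifnot(target_fill > 0, target_fill < 1,
            n_clades <= n_bird_species, n_families <= n_plant_species,
            n_clades <= length(hummingbird_clades()),
            eta >= 0, block_affinity >= 0, block_affinity <= 1)
  structure(as.list(environment()), class = "network_config")
}

# Zipf-ish group assignment guaranteeing every group is non-empty.
assign_groups <- function(n_items, n_groups) {
  w <- (seq_len(n_groups))^-1
  g <- c(seq_len(n_groups),
         sample.int(n_groups, n_items - n_groups, replace = TRUE, prob = w))
  g[sample.int(n_items)]
}

#' Generate synthetic visitation records
#'
#' Simulates a species-level interaction matrix from a latent-generalism
#' model: species get scores u_i, v_j ~ N(0, 1) and interact with
#' probability plogis(alpha + eta (u_i + v_j)), with alpha calibrated so the
#' expected fill matches `target_fill`; with blocks, between-block
#' probabilities are damped by (1 - block_affinity). Species are assigned to
#' clades and families with heavy-tailed group sizes. One record is emitted
#' per realised interaction; draws whose fill misses `target_fill` by more
#' than 10% are rejected and redrawn.
#'
#' @param config A [network_config()].
#' @return List with `records` (data frame as from
#'   [read_interaction_records()]) and `maps` (a [taxon_maps()] whose
#'   syndromes follow the observed 14/36/50 ornithophilous / intermediate /
#'   non-ornithophilous split).
#' @export
generate_records <- function(config) {
  stopifnot(inherits(config, "network_config"))
  local_seed(config$seed, {
    nb <- config$n_bird_species; np <- config$n_plant_species
    bird_clade_idx <- assign_groups(nb, config$n_clades)
    plant_family_idx <- assign_groups(np, config$n_families)
    birds <- sprintf("bird_%03d", seq_len(nb))
    plants <- sprintf("plant_%04d", seq_len(np))
    clades <- hummingbird_clades()[seq_len(config$n_clades)]
    families <- sprintf("Family%03d", seq_len(config$n_families))

    u <- stats::rnorm(nb); v <- stats::rnorm(np)
    eta_term <- config$eta * outer(v, u, "+")   # plants in rows
    damp <- matrix(1, np, nb)
    if (config$n_blocks > 0) {
      clade_block <- (seq_len(config$n_clades) - 1) %% config$n_blocks + 1
      fam_block <- (seq_len(config$n_families) - 1) %% config$n_blocks + 1
      same <- outer(fam_block[plant_family_idx], clade_block[bird_clade_idx], "==")
      damp[!same] <- 1 - config$block_affinity
    }
    mean_fill <- function(alpha) mean(stats::plogis(alpha + eta_term) * damp)
    alpha <- stats::uniroot(function(a) mean_fill(a) - config$target_fill,
                            c(-40, 40))$root
    p <- stats::plogis(alpha + eta_term) * damp
    for (try in 1:50) {
      m <- matrix(stats::runif(length(p)) < p, np, nb)
      fill <- mean(m)
      if (abs(fill - config$target_fill) <= 0.1 * config$target_fill) break
      if (try == 50) stop("could not realise target fill within 10%")
    }
    ones <- which(m, arr.ind = TRUE)
    records <- data.frame(
      bird_species = birds[ones[, 2]],
      plant_species = plants[ones[, 1]],
      source_id = "synthetic",
      plant_native = TRUE,
      stringsAsFactors = FALSE)
    syn_counts <- round(config$n_families * c(0.14, 0.36, 0.50))
    syn_counts[3] <- config$n_families - sum(syn_counts[1:2])
    syndromes <- stats::setNames(rep(syndrome_levels(), syn_counts), families)
    maps <- taxon_maps(stats::setNames(clades[bird_clade_idx], birds),
                       stats::setNames(families[plant_family_idx], plants),
                       syndromes)
    list(records = records, maps = maps)
  })
}

#' Configuration for the synthetic biogeography generator
#'
#' Defaults emulate the compiled per-species table: clade sizes as in the
#' data set (292 species over the nine clades), centers of diversification
#' North America for Bees and Mountain Gems and South America otherwise, and
#' colonization odds (odds that a species occupies two or more biogeographic
#' regions) of about 1.07 vs 0.118 - an odds ratio near 9 between northern
#' and southern centers.
#'
#' @param n_per_clade Named integer vector of species per clade.
#' @param clade_centers Named character vector clade -> center.
#' @param colonization_odds Named numeric vector center -> odds of
#'   multi-region distribution (positive).
#' @param lat_mean,lat_sd,lat_range_mean,lat_range_sd Latitude parameters
#'   (degrees) for the northern limit and latitudinal span.
#' @param elev_min_mean,elev_min_sd,elev_range_mean,elev_range_sd Elevation
#'   parameters (metres).
#' @param seed Integer seed.
#' @return A list of class `biogeo_config`.
#' @export
biogeo_config <- function(
    n_per_clade = c(Bees = 33, Brilliants = 38, Coquettes = 53,
                    Emeralds = 96, Hermits = 26, Mangoes = 27,
                    "Mountain Gems" = 15, Patagona = 1, Topazes = 3),
    clade_centers = NULL,
    colonization_odds = c("North America" = 1.07, "South America" = 0.118),
    lat_mean = 10, lat_sd = 12, lat_range_mean = 12, lat_range_sd = 8,
    elev_min_mean = 600, elev_min_sd = 500,
    elev_range_mean = 1400, elev_range_sd = 600,
    seed = 1) {
  stopifnot(all(colonization_odds > 0),
            all(names(n_per_clade) %in% hummingbird_clades()))
  if (is.null(clade_centers)) {
    clade_centers <- stats::setNames(
      ifelse(names(n_per_clade) %in% c("Bees", "Mountain Gems"),
             "North America", "South America"),
      names(n_per_clade))
  }
  structure(as.list(environment()), class = "biogeo_config")
}

#' Generate a synthetic biogeography table
#'
#' Each species inherits its clade's center of diversification and draws its
#' multi-region "success" from the center's colonization odds. Successes
#' occupy the Neotropics plus the Nearctic (northern center) or Austral
#' (southern center) region; failures are Neotropical only. Latitudinal and
#' elevational limits are drawn from the configured normal distributions
#' with min <= max enforced.
#'
#' @param config A [biogeo_config()].
#' @return A `species_biogeo` data frame.
#' @export
generate_biogeo <- function(config) {
  stopifnot(inherits(config, "biogeo_config"))
  local_seed(config$seed, {
    clade <- rep(names(config$n_per_clade), config$n_per_clade)
    n <- length(clade)
    center <- unname(config$clade_centers[clade])
    odds <- unname(config$colonization_odds[center])
    success <- stats::runif(n) < odds / (1 + odds)
    northern <- center == "North America"
    nearctic <- success & northern
    austral <- (success & !northern) | clade == "Patagona"
    neotropical <- rep(TRUE, n)
    lat_max <- stats::rnorm(n, config$lat_mean, config$lat_sd)
    lat_range <- abs(stats::rnorm(n, config$lat_range_mean, config$lat_range_sd))
    elev_min <- abs(stats::rnorm(n, config$elev_min_mean, config$elev_min_sd))
    elev_range <- abs(stats::rnorm(n, config$elev_range_mean, config$elev_range_sd))
    df <- data.frame(
      species = sprintf("%s_sp%03d", gsub(" ", "", clade),
                        stats::ave(seq_len(n), clade, FUN = seq_along)),
      clade = clade,
      nearctic = nearctic, neotropical = neotropical, austral = austral,
      lat_min = lat_max - lat_range, lat_max = lat_max,
      elev_min = elev_min, elev_max = elev_min + elev_range,
      center = center,
      stringsAsFactors = FALSE)
    class(df) <- c("species_biogeo", class(df))
    df
  })
}
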