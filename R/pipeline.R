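# Deterministic per-stage seed derived from the master seed and stage name,
# kept inside the 32-bit integer range.
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(master) * 7919 + h * 104729) %% (.Machine$integer.max - 1)) + 1L
}

#' Run the full network analysis end-to-end
#'
#' Executes matrix construction, degree-distribution fits, NODF (sorted and,
#' when an external order is supplied, fixed), the three null ensembles for
#' nestedness, modularity consensus with node roles and ER/FF significance,
#' biogeographic and syndrome summaries, and the niche-conservatism GLMs.
#' Per-stage CSV outputs plus a single `summary.json` are written to
#' `out_dir`. All randomised stages draw their seeds deterministically from
#' `seed`, so identical calls give identical outputs.
#'
#' @param records Data frame of visitation records
#'   ([read_interaction_records()]).
#' @param maps A [taxon_maps()].
#' @param biogeo Optional `species_biogeo` table; when supplied the biogeo
#'   summaries and GLMs run.
#' @param out_dir Output directory (created if needed).
#' @param native_only Analyse the native-plants-only matrix?
#' @param row_order,col_order Optional fixed (e.g. phylogenetic) orders for
#'   the matrix rows/columns; enables fixed-order NODF.
#' @param nodf_reps Null replicates per model for nestedness.
#' @param mod_nulls Null replicates per model for modularity.
#' @param sa_runs Annealing runs for the modularity consensus.
#' @param threshold Consensus assignment threshold.
#' @param schedule An [sa_schedule()].
#' @param seed Master seed.
#' @return Invisibly, a list with every stage result.
#' @export
run_pipeline <- function(records, maps, biogeo = NULL, out_dir,
                         native_only = TRUE,
                         row_order = NULL, col_order = NULL,
                         nodf_reps = 1000, mod_nulls = 100, sa_runs = 50,
                         threshold = 0.9, schedule = sa_schedule(),
                         seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(seed = seed)

  mat_full <- build_matrix(records, maps, native_only = FALSE)
  mat <- if (native_only) build_matrix(records, maps, native_only = TRUE) else mat_full
  write_matrix_csv(order_matrix(mat_full, "degree"),
                   file.path(out_dir, "matrix_full.csv"))
  write_matrix_csv(order_matrix(mat, "degree"),
                   file.path(out_dir, "matrix.csv"))
  out$matrix_full <- mat_full
  out$matrix <- mat

  fits <- fit_degree_models(
    cumulative_distribution(degree_sequence(mat, "combined")))
  fit_df <- do.call(rbind, lapply(fits$fits, function(f) data.frame(
    model = f$model,
    params = paste(sprintf("%s=%.4g", names(f$params), f$params),
                   collapse = ";"),
    rss = f$rss, aic = f$aic, selected = identical(f$model, fits$best))))
  utils::write.csv(fit_df, file.path(out_dir, "degree_fits.csv"),
                   row.names = FALSE)
  out$degree_fit <- fits

  nodf_sorted <- nodf(mat, "sorted")
  out$nodf_sorted <- nodf_sorted
  fixed_mat <- NULL
  if (!is.null(row_order) || !is.null(col_order)) {
    fixed_mat <- order_matrix(mat, "given", row_order = row_order,
                              col_order = col_order)
    out$nodf_fixed <- nodf(fixed_mat, "fixed")
  }

  stats_list <- list(nodf_sorted = function(m) nodf(m, "sorted")$nodf_total)
  if (!is.null(fixed_mat)) {
    stats_list$nodf_fixed <- function(m) nodf(m, "fixed")$nodf_total
  }
  null_rows <- list()
  out$nestedness_nulls <- list()
  for (stat_name in names(stats_list)) {
    target <- if (stat_name == "nodf_fixed") fixed_mat else mat
    for (model in c("ER", "CE", "FF")) {
      ens <- null_ensemble(target, stats_list[[stat_name]], model = model,
                           n_reps = nodf_reps,
                           seed = stage_seed(seed, paste0(stat_name, model)))
      out$nestedness_nulls[[paste(stat_name, model, sep = "_")]] <- ens
      null_rows[[length(null_rows) + 1]] <- data.frame(
        statistic = stat_name, model = model, observed = ens$observed,
        null_mean = ens$null_mean, null_sd = ens$null_sd, ses = ens$ses,
        p = ens$p_value)
    }
  }
  utils::write.csv(do.call(rbind, null_rows),
                   file.path(out_dir, "nestedness_nulls.csv"),
                   row.names = FALSE)

  msig <- modularity_significance(mat, n_er = mod_nulls, n_ff = mod_nulls,
                                  n_runs = sa_runs, schedule = schedule,
                                  seed = stage_seed(seed, "modularity"))
  out$modularity <- msig
  graph <- bipartite_to_graph(mat)
  roles <- node_roles(graph, msig$consensus$reference)
  roles$consensus_module <- unname(msig$consensus$assigned_modules[roles$node])
  utils::write.csv(roles, file.path(out_dir, "membership.csv"),
                   row.names = FALSE)
  out$roles <- roles

  if (!is.null(maps$family_syndrome)) {
    out$syndromes <- syndrome_summary(maps, mat)
    utils::write.csv(out$syndromes, file.path(out_dir, "syndromes.csv"),
                     row.names = FALSE)
  }

  if (!is.null(biogeo)) {
    out$region_summary <- species_region_summary(biogeo)
    out$clade_summary <- clade_summary(biogeo)
    utils::write.csv(out$region_summary,
                     file.path(out_dir, "region_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(out$clade_summary,
                     file.path(out_dir, "clade_summary.csv"),
                     row.names = FALSE)
    out$glm_center <- fit_niche_glm(biogeo, "center", "logit")
    out$glm_clade <- fit_niche_glm(biogeo, "clade", "logit")
    out$glm_center_test <- lr_chi_test(out$glm_center)
    out$glm_clade_test <- lr_chi_test(out$glm_clade)
    out$contrasts <- pairwise_contrasts(out$glm_clade)
    utils::write.csv(out$contrasts, file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE)
  }

  summary <- list(
    seed = seed,
    links_full = link_count(mat_full),
    links = link_count(mat),
    n_families = nrow(mat),
    n_clades = ncol(mat),
    degree_best_model = fits$best,
    nodf_sorted = nodf_sorted$nodf_total,
    nodf_fixed = if (!is.null(fixed_mat)) out$nodf_fixed$nodf_total,
    nestedness = lapply(out$nestedness_nulls, function(e) {
      list(model = e$model, null_mean = e$null_mean, ses = e$ses, p = e$p_value)
    }),
    modularity = list(
      mean_m = msig$consensus$mean_m, sd_m = msig$consensus$sd_m,
      ses_er = msig$er$ses, p_er = msig$er$p_value,
      ses_ff = msig$ff$ses, p_ff = msig$ff$p_value),
    glm = if (!is.null(biogeo)) list(
      center_odds_ratio = unname(out$glm_center$odds_ratios["centerNorth America"]),
      center_chi = out$glm_center_test$chi,
      center_df = out$glm_center_test$df,
      clade_chi = out$glm_clade_test$chi,
      clade_df = out$glm_clade_test$df)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
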