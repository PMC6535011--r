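#' Declarative configuration for the synthetic end-to-end pipeline
#'
#' Every tunable parameter of the pipeline surfaces here with its
#' documented default; unknown names are rejected. The defaults describe
#' a desk-scale study: a 48 x 48 landscape with two standardized climate
#' layers (a temperature-like east-west gradient and a rainfall-like
#' north-south gradient), 15 roost populations of 20 individuals, 2000
#' neutral + 20 climate-adaptive loci at moderate differentiation, three
#' pseudo-GCM warming scenarios, and group-specific occurrence sets.
#'
#' @param ... named overrides of the defaults listed in the function
#'   definition.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    ## landscape
    grid_rows = 48, grid_cols = 48, autocorrelation_range = 6,
    noise_sd = 0.5,
    ## pseudo-GCM warming shifts (per layer: temperature +, rainfall -)
    gcm_deltas = list(c(1.2, -0.5), c(1.5, -0.5), c(1.8, -0.5)),
    ## population genetics
    n_populations = 15, inds_per_population = 20,
    n_neutral_loci = 2000, n_adaptive_loci = 20,
    fst_target = 0.1, adaptive_slope = 2, missing_rate = 0,
    ## GEA
    k_max = 20, sd_threshold = 3, q_threshold = 0.05,
    ## classification
    t_intermediate = 0.25, majority = 0.6,
    ## ENM: groups diverge on the temperature axis (bio1) and share a
    ## rainfall-axis preference (bio2), as in a forest specialist; the
    ## hot-dry group is the scarcer record class, as in the real surveys
    n_occurrences_hot = 60, n_occurrences_cold = 120,
    occ_beta = 2, occ_shared = 2.5, occ_intercept = -3,
    n_background = 2000, tss_cutoff = 0.4, n_replicates = NULL,
    algorithms = c("envelope", "logistic", "maxent"),
    ## connectivity
    ibr_beta = 1, ibr_noise_sd = 0.5, n_perm = 999,
    ## stage toggles
    stages = c("simulate", "gea", "classify", "enm", "connect", "rescue"))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(over)] <- over  # whole-value replacement (no list merging)
  if (any(c("enm", "connect", "rescue") %in% cfg$stages) &&
      !all(c("gea", "classify") %in% cfg$stages) &&
      "simulate" %in% cfg$stages)
    stop("group-level stages require the gea and classify stages")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Check that a set of pipeline inputs is mutually consistent
#'
#' Verifies raster co-registration, that occurrence points fall inside
#' the raster extent, and that genotype sample ids agree with the sample
#' table.
#'
#' @param stacks list of raster_stack objects (may be length 1).
#' @param occurrences optional data.frame of points (x, y).
#' @param gm optional genotype_matrix.
#' @param samples optional sample table (id, lon, lat).
#' @return character vector of problems; empty when everything is
#'   consistent.
#' @export
validate_inputs <- function(stacks = list(), occurrences = NULL,
                            gm = NULL, samples = NULL) {
  problems <- character(0)
  if (length(stacks) > 1) {
    base <- stacks[[1]]
    for (i in seq_along(stacks)[-1])
      if (!same_geometry(base, stacks[[i]]))
        problems <- c(problems,
                      sprintf("raster stack %d is not co-registered", i))
  }
  if (!is.null(occurrences) && length(stacks) >= 1) {
    out <- !in_extent(stacks[[1]], occurrences$x, occurrences$y)
    if (any(out))
      problems <- c(problems, sprintf(
        "%d occurrence point(s) outside the raster extent", sum(out)))
  }
  if (!is.null(gm) && !is.null(samples)) {
    missing_ids <- setdiff(gm$sample_ids, samples$id)
    if (length(missing_ids))
      problems <- c(problems, paste0(
        "genotyped ids absent from sample table: ",
        paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  problems
}

#' Run the synthetic pipeline end-to-end
#'
#' Executes simulate -> GEA -> classification -> group-wise ensemble
#' niche models (full, hot_dry, cold_wet) -> range change / overlap /
#' niche overlap -> connectivity -> evolutionary rescue, with every
#' random step seeded from `config$seed`. Writes stage outputs (CSV,
#' ESRI ASCII grids, JSON summary) into `outdir` when given.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @return list with per-stage results and a `summary` list (per-group
#'   n, AUC, TSS, percent suitable present/future, percent change, plus
#'   niche overlap, range overlap and rescue summaries).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  res <- list(config = cfg)
  t0 <- Sys.time()
  say <- function(fmt, ...) message(sprintf(paste0("[%5.1fs] ", fmt),
                                            as.numeric(Sys.time() - t0,
                                                       units = "secs"), ...))

  ## -- simulate ------------------------------------------------------
  say("simulate: %dx%d landscape, %d individuals, %d loci",
      cfg$grid_rows, cfg$grid_cols,
      cfg$n_populations * cfg$inds_per_population,
      cfg$n_neutral_loci + cfg$n_adaptive_loci)
  lc <- landscape_config(grid_rows = cfg$grid_rows,
                         grid_cols = cfg$grid_cols,
                         autocorrelation_range = cfg$autocorrelation_range,
                         noise_sd = cfg$noise_sd, seed = cfg$seed)
  present <- generate_climate_rasters(lc, n_layers = 2)
  futures <- lapply(seq_along(cfg$gcm_deltas), function(i)
    generate_future_rasters(present, cfg$gcm_deltas[[i]]))
  ## roost locations: one valid cell per population
  ok <- which(valid_mask(present), arr.ind = TRUE)
  pop_cells <- with_seed(cfg$seed + 1,
    ok[sample.int(nrow(ok), cfg$n_populations), , drop = FALSE])
  pop_xy <- cell_to_xy(present, pop_cells[, 1], pop_cells[, 2])
  ind_pop <- rep(seq_len(cfg$n_populations),
                 each = cfg$inds_per_population)
  env_pop <- extract_env(present, pop_xy[, "x"], pop_xy[, "y"])
  climate <- apply(env_pop[ind_pop, , drop = FALSE], 2, standardize)
  pm <- population_model(
    n_populations = cfg$n_populations,
    inds_per_population = cfg$inds_per_population,
    n_neutral_loci = cfg$n_neutral_loci,
    n_adaptive_loci = cfg$n_adaptive_loci,
    fst_target = cfg$fst_target, adaptive_slope = cfg$adaptive_slope,
    missing_rate = cfg$missing_rate, seed = cfg$seed + 2)
  gm <- simulate_genotypes(pm, climate)
  gm$coords <- cbind(pop_xy[ind_pop, "x"], pop_xy[ind_pop, "y"])
  occ <- list(
    hot_dry = simulate_occurrences(
      present, c(`(Intercept)` = cfg$occ_intercept,
                 bio1 = cfg$occ_beta, bio2 = cfg$occ_shared),
      cfg$n_occurrences_hot, seed = cfg$seed + 3),
    cold_wet = simulate_occurrences(
      present, c(`(Intercept)` = cfg$occ_intercept,
                 bio1 = -cfg$occ_beta, bio2 = cfg$occ_shared),
      cfg$n_occurrences_cold, seed = cfg$seed + 4))
  occ$all <- data.frame(x = c(occ$hot_dry$points$x, occ$cold_wet$points$x),
                        y = c(occ$hot_dry$points$y, occ$cold_wet$points$y))
  res$simulate <- list(present = present, futures = futures, gm = gm,
                       occurrences = occ, pop_cells = pop_cells,
                       climate = climate)
  if (!"gea" %in% cfg$stages) return(finish_pipeline(res, outdir))

  ## -- gea -----------------------------------------------------------
  gmc <- impute_missing(gm)
  K <- select_K(gmc, k_max = cfg$k_max)
  say("gea: K = %d latent factors", K)
  rda <- fit_rda(gmc, climate)
  rda_set <- rda_outliers(rda, gmc, climate,
                          sd_threshold = cfg$sd_threshold)
  lat <- fit_latent_association(gmc, climate, K = K)
  lat_set <- latent_candidates(lat, q_threshold = cfg$q_threshold)
  cand <- intersect_candidates(rda_set, lat_set)
  say("gea: %d RDA + %d latent -> %d intersection candidates",
      nrow(rda_set), nrow(lat_set), nrow(cand))
  res$gea <- list(K = K, rda = rda, rda_set = rda_set, latent = lat,
                  latent_set = lat_set, candidates = cand)
  if (!"classify" %in% cfg$stages) return(finish_pipeline(res, outdir))

  ## -- classify ------------------------------------------------------
  scores <- score_individuals(gmc, cand, climate)
  assign_ind <- classify_individuals(scores, t = cfg$t_intermediate)
  assign_pop <- classify_populations(assign_ind, majority = cfg$majority)
  say("classify: %s", paste(names(table(assign_ind$label)),
                            table(assign_ind$label), collapse = ", "))
  res$classify <- list(scores = scores, individuals = assign_ind,
                       populations = assign_pop)
  if (!"enm" %in% cfg$stages) return(finish_pipeline(res, outdir))

  ## -- enm -----------------------------------------------------------
  groups <- list(all = occ$all, hot_dry = occ$hot_dry,
                 cold_wet = occ$cold_wet)
  enm <- list(); table1 <- list()
  for (g in names(groups)) {
    ens <- fit_enm(present, groups[[g]], algorithms = cfg$algorithms,
                   n_background = cfg$n_background,
                   tss_cutoff = cfg$tss_cutoff,
                   n_replicates = cfg$n_replicates,
                   seed = cfg$seed + 10)
    pres <- predict_raster(ens, present)
    fut <- project_ensemble(ens, futures)
    rc <- range_change(pres$binary, fut$binary)
    say("enm[%s]: AUC %.3f TSS %.3f, %.1f%% -> %.1f%% suitable", g,
        ens$evaluation$auc, ens$evaluation$tss,
        rc$percent_present, rc$percent_future)
    enm[[g]] <- list(ensemble = ens, present = pres, future = fut,
                     range_change = rc)
    table1[[g]] <- list(n = nrow(attr(ens, "presences")),
                        auc = ens$evaluation$auc,
                        tss = ens$evaluation$tss,
                        percent_present = rc$percent_present,
                        percent_future = rc$percent_future,
                        percent_change = rc$percent_change)
  }
  ## combined adaptive ranges and overlap statistics
  comb_pres <- combine_ranges(enm$hot_dry$present$binary,
                              enm$cold_wet$present$binary)
  comb_fut <- combine_ranges(enm$hot_dry$future$binary,
                             enm$cold_wet$future$binary)
  rc_comb <- range_change(comb_pres, comb_fut)
  d_groups <- schoener_d(enm$hot_dry$present$continuous,
                         enm$cold_wet$present$continuous)
  ovl_pres <- range_overlap(enm$hot_dry$present$binary,
                            enm$cold_wet$present$binary)
  ovl_fut <- range_overlap(enm$hot_dry$future$binary,
                           enm$cold_wet$future$binary)
  loss <- function(rc) max(-rc$percent_change, 0)
  res$enm <- list(groups = enm, combined = rc_comb,
                  schoener_d = d_groups,
                  overlap_present = ovl_pres, overlap_future = ovl_fut,
                  loss_full = loss(table1$all),
                  loss_combined = loss(rc_comb),
                  loss_reduction = percent_reduction(
                    max(loss(table1$all), 1e-9), loss(rc_comb)))
  res$summary <- list(table1 = table1,
                      combined_range_change = rc_comb$percent_change,
                      schoener_d = d_groups,
                      loss_reduction = res$enm$loss_reduction)
  if (!"connect" %in% cfg$stages) return(finish_pipeline(res, outdir))

  ## -- connect -------------------------------------------------------
  ## two landscape layers (forest-like, slope-like) -> candidate surfaces
  land <- generate_climate_rasters(
    landscape_config(grid_rows = cfg$grid_rows, grid_cols = cfg$grid_cols,
                     gradient_direction = pi / 4,
                     autocorrelation_range = cfg$autocorrelation_range,
                     noise_sd = 2, seed = cfg$seed + 20), n_layers = 2)
  tab <- data.frame(value = c(-3, 0, 3), cost = c(1, 30, 100))
  surf_forest <- reclassify_to_resistance(
    layer_values(land, 1), tab, interpolate = TRUE)
  surf_slope <- reclassify_to_resistance(
    layer_values(land, 2), tab, interpolate = TRUE)
  surf_comb <- combine_surfaces(list(surf_forest, surf_slope))
  candidates <- list(forest = surf_forest, slope = surf_slope,
                     forest_slope = surf_comb)
  graphs <- lapply(candidates, build_graph)
  rdist <- lapply(graphs, effective_resistance, focal = pop_cells)
  ## generator's IBR component: genetic distances consistent with the
  ## combined surface
  gen_dist <- simulate_ibr_distances(rdist$forest_slope,
                                     beta = cfg$ibr_beta,
                                     noise_sd = cfg$ibr_noise_sd,
                                     seed = cfg$seed + 21)
  ibr <- ibr_regression(gen_dist, rdist, n_perm = cfg$n_perm,
                        seed = cfg$seed + 22)
  say("connect: best surface '%s' (R2 = %.3f)", ibr$surface[1],
      ibr$r_squared[1])
  res$connect <- list(surfaces = candidates, resistance = rdist,
                      genetic = gen_dist, ibr = ibr)
  res$summary$ibr_best_surface <- ibr$surface[1]
  res$summary$ibr_r_squared <- ibr$r_squared[1]
  if (!"rescue" %in% cfg$stages) return(finish_pipeline(res, outdir))

  ## -- rescue --------------------------------------------------------
  pop_labels <- res$classify$populations$label[
    match(sprintf("pop%02d", seq_len(cfg$n_populations)),
          res$classify$populations$population)]
  if (sum(pop_labels == "hot_dry") >= 1 &&
      sum(pop_labels == "cold_wet") >= 1) {
    best <- candidates[[ibr$surface[1]]]
    resc <- rescue_potential(best, pop_cells, pop_labels)
    res$rescue <- resc
    res$summary$rescue_mean_resistance <-
      mean(resc$target_summary$mean_resistance)
    say("rescue: %d hot_dry -> %d cold_wet locations",
        sum(pop_labels == "hot_dry"), sum(pop_labels == "cold_wet"))
  } else {
    res$rescue <- NULL
    say("rescue: skipped (need both hot_dry and cold_wet populations)")
  }
  finish_pipeline(res, outdir)
}

## write machine-readable outputs and return
finish_pipeline <- function(res, outdir) {
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    if (!is.null(res$simulate)) {
      write_ascii_grid(res$simulate$present, file.path(outdir, "present"))
      write_genepop(res$simulate$gm, file.path(outdir, "genotypes.gen"))
    }
    if (!is.null(res$gea))
      write_candidates(res$gea$candidates,
                       file.path(outdir, "candidates.csv"))
    if (!is.null(res$classify))
      write_assignments(res$classify$individuals,
                        file.path(outdir, "individuals.csv"),
                        file.path(outdir, "populations.csv"))
    if (!is.null(res$summary))
      jsonlite::write_json(res$summary,
                           file.path(outdir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg <- res$config; class(cfg) <- NULL
    cfg$algorithms <- as.list(cfg$algorithms)
    jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(res)
}
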