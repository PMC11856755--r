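#' Pipeline run configuration
#'
#' Collects every numeric setting of the workflow in one serializable
#' object. Stage seeds are derived from `master_seed` by fixed offsets so
#' any stage can be replayed in isolation.
#'
#' @param recipe A [world_recipe()] for the synthetic world, or `NULL`
#'   when `layer_paths`/`occurrence_path` point at real inputs.
#' @param layer_paths Named character vector of `.asc` layer paths
#'   (ignored when `recipe` is given).
#' @param occurrence_path Occurrence CSV path (ignored when `recipe` is
#'   given).
#' @param thinning_target Moran's I ceiling (default 0.2).
#' @param thinning_floor Minimum records kept by thinning.
#' @param r_max,vif_max Screening thresholds (defaults 0.8 and 10).
#' @param rm_values RM ladder for tuning.
#' @param fc_values Feature-class subsets for tuning.
#' @param hinge_knots,threshold_knots Knot counts for H/T features.
#' @param buffer_km,background_size Background sampling settings.
#' @param n_reps Replicate runs (default 20).
#' @param test_fraction Held-out share (default 0.25).
#' @param agreement_level Replicate-consistency level (default 0.95).
#' @param boyce_windows Windows for the Boyce index (default 101).
#' @param master_seed Master seed.
#' @return A `run_config`.
#' @export
run_config <- function(recipe = world_recipe(),
                       layer_paths = NULL, occurrence_path = NULL,
                       thinning_target = 0.2, thinning_floor = 30,
                       r_max = 0.8, vif_max = 10,
                       rm_values = seq(0.5, 2.5, by = 0.5),
                       fc_values = c("L", "LQ", "LT", "LQT", "LQH"),
                       hinge_knots = 8, threshold_knots = 8,
                       buffer_km = 1500, background_size = 2000,
                       n_reps = 20, test_fraction = 0.25,
                       agreement_level = 0.95, boyce_windows = 101,
                       master_seed = 42L) {
  stopifnot(thinning_target > 0, r_max > 0, r_max <= 1, vif_max > 1,
            test_fraction > 0, test_fraction < 1,
            agreement_level > 0, agreement_level <= 1)
  structure(as.list(environment()), class = "run_config")
}

stage_seed <- function(config, stage) {
  offsets <- c(background = 11L, screen = 23L, tune = 37L, replicates = 53L,
               evaluate = 71L, absences = 89L)
  config$master_seed + unname(offsets[stage])
}

obj_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# contribution callback for screening: refit a small linear/quadratic
# model on the surviving candidates and take permutation contributions
screen_contribution_fun <- function(pres_values, background, seed) {
  function(codes) {
    bg <- background
    bg$values <- bg$values[, codes, drop = FALSE]
    m <- fit_maxent(pres_values[, codes, drop = FALSE], bg,
                    feature_spec("LQ"), rm = 1)
    percent_contribution(m, pres_values[, codes, drop = FALSE], seed = seed)
  }
}

#' Run the full suitability-modeling pipeline
#'
#' Chains every stage: occurrence partition, per-cell deduplication,
#' Moran's I thinning, predictor screening, (rm, fc) tuning by AICc with
#' significance and omission filters, replicated fitting with random
#' test splits, the evaluation panel, max-TSS binarization with
#' latitude-weighted area budgets, replicate consistency and SD maps,
#' and — when future stacks are available — per-GCM projection, the
#' multi-GCM combination, and change maps.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, grids (.asc), tables
#'   (CSV) and the manifest are written there.
#' @return A `pipeline_run` list; see components in the manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  # --- inputs -------------------------------------------------------
  if (!is.null(config$recipe)) {
    world <- make_world(config$recipe)
    stack <- world$stack; occ_raw <- world$occurrences
    future <- world$future; truth <- world$truth
  } else {
    if (is.null(config$layer_paths) || is.null(config$occurrence_path))
      stop("need either a recipe or layer_paths + occurrence_path")
    for (p in c(config$layer_paths, config$occurrence_path))
      if (!file.exists(p)) stop(sprintf("missing input: %s", p))
    stack <- read_ascii_stack(config$layer_paths)
    occ_raw <- read_occurrences(config$occurrence_path)
    future <- NULL; truth <- NULL
  }
  say("inputs: %d records, %d layers", nrow(occ_raw), length(stack$layers))
  # --- curation -----------------------------------------------------
  part <- partition_datasets(occ_raw)
  say("partition: %d basic, %d expanded-only, %d excluded",
      sum(part$partition == "basic"), sum(part$partition == "expanded_only"),
      sum(part$partition == "excluded"))
  modeling <- modeling_records(part, "expanded")
  dedup <- dedupe_to_cells(modeling, stack$layers[[1]])
  say("dedupe: %d -> %d records", nrow(modeling), nrow(dedup))
  thin <- thin_by_morans(dedup, stack, target = config$thinning_target,
                         floor = config$thinning_floor)
  say("thinning: %d -> %d records, max Moran's I %.3f", nrow(dedup),
      nrow(thin$records), max(thin$morans_i, na.rm = TRUE))
  occ <- thin$records
  # --- background + screening --------------------------------------
  background <- sample_background(occ, stack, buffer_km = config$buffer_km,
                                  m = config$background_size,
                                  seed = stage_seed(config, "background"))
  pres_values_all <- stack_extract(stack, occ$lon, occ$lat)
  screen <- screen_variables(
    background$values,
    screen_contribution_fun(pres_values_all, background,
                            stage_seed(config, "screen")),
    r_max = config$r_max, vif_max = config$vif_max)
  say("screening: retained %s", paste(screen$retained, collapse = ", "))
  keep <- screen$retained
  sstack <- suit_stack(stack$layers[keep])
  sbackground <- background
  sbackground$values <- background$values[, keep, drop = FALSE]
  pres_values <- pres_values_all[, keep, drop = FALSE]
  # --- tuning -------------------------------------------------------
  candidates <- expand.grid(rm = config$rm_values, fc = config$fc_values,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tune <- tune_candidates(candidates, pres_values,
                          occ[, c("lon", "lat")], sbackground, sstack,
                          test_fraction = config$test_fraction,
                          seed = stage_seed(config, "tune"),
                          hinge_knots = config$hinge_knots,
                          threshold_knots = config$threshold_knots)
  champ <- tune$champion
  say("champion: rm %.2f, fc %s (AICc %.2f, k %d)", champ$rm, champ$fc,
      champ$aicc, champ$k)
  # --- replicated fit ----------------------------------------------
  reps <- replicate_runs(pres_values, sbackground, sstack,
                         feature_spec(champ$fc, config$hinge_knots,
                                      config$threshold_knots),
                         rm = champ$rm, n_reps = config$n_reps,
                         test_fraction = config$test_fraction,
                         base_seed = stage_seed(config, "replicates"))
  # --- evaluation (per replicate, then averaged) -------------------
  eval_rows <- lapply(seq_along(reps$replicates), function(r) {
    rep <- reps$replicates[[r]]
    ev <- evaluate_model(rep$model, pres_values[rep$test_idx, , drop = FALSE],
                         pres_values[-rep$test_idx, , drop = FALSE],
                         rep$grid,
                         occ[rep$test_idx, c("lon", "lat")],
                         seed = stage_seed(config, "evaluate") + r)
    report_row(ev)
  })
  eval_table <- do.call(rbind, eval_rows)
  panel <- colMeans(eval_table)
  say("evaluation (mean of %d reps): AUC %.3f, TSS %.3f, Boyce %.3f",
      nrow(eval_table), panel["auc"], panel["tss"], panel["boyce"])
  threshold <- unname(panel["threshold"])
  # --- near-current maps -------------------------------------------
  areas <- cell_area_km2(reps$mean)
  binary_now <- binarize(reps$mean, threshold)
  budget_now <- area_budget(binary_now, areas)
  rep_grids <- lapply(reps$replicates, `[[`, "grid")
  consistency <- consistency_map(rep_grids, threshold,
                                 config$agreement_level)
  sdg <- sd_map(rep_grids)
  say("near-current: %.4g km2 suitable (%.2f%%), %.1f%% consistent",
      budget_now$suitable_km2, budget_now$suitable_pct,
      consistency$consistent_pct)
  # --- future ensemble ---------------------------------------------
  scenario <- NULL
  if (!is.null(future)) {
    per_gcm <- lapply(future, function(fs) {
      fss <- suit_stack(fs$layers[keep])
      grids <- lapply(reps$replicates, function(rep)
        predict(rep$model, fss, type = "cloglog"))
      # replicate mean per GCM
      acc <- grids[[1]]$values * 0
      for (g in grids) acc <- acc + g$values
      grid_like(grids[[1]], acc / length(grids))
    })
    comb <- multi_gcm_combine(per_gcm, threshold)
    binary_future <- binarize(comb$mean, threshold)
    budget_future <- area_budget(binary_future, areas)
    chg <- change_map(binary_now, binary_future, areas)
    say("future ensemble: %.4g km2 suitable (%+.2f%%)",
        budget_future$suitable_km2,
        100 * (budget_future$suitable_km2 - budget_now$suitable_km2) /
          budget_now$suitable_km2)
    scenario <- list(per_gcm = per_gcm, mean = comb$mean,
                     agreement = comb$agreement, binary = binary_future,
                     budget = budget_future, change = chg)
  }
  run <- list(config = config, partition = part, thinning = thin,
              occurrences = occ, background = background, screen = screen,
              tuning = tune, replicates = reps, eval_table = eval_table,
              panel = as.list(panel), threshold = threshold,
              binary_now = binary_now, budget_now = budget_now,
              consistency = consistency, sd = sdg, scenario = scenario,
              truth = truth, log = log_lines)
  run$manifest <- build_manifest(run)
  class(run) <- "pipeline_run"
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

build_manifest <- function(run) {
  h <- list(
    config = obj_hash(run$config),
    occurrences = obj_hash(run$occurrences),
    screen = obj_hash(run$screen$retained),
    champion = obj_hash(run$tuning$champion[, c("rm", "fc")]),
    mean_grid = obj_hash(run$replicates$mean$values),
    panel = obj_hash(run$eval_table),
    binary_now = obj_hash(run$binary_now$values),
    scenario = if (is.null(run$scenario)) NA_character_
               else obj_hash(run$scenario$mean$values))
  list(hashes = h, master_seed = run$config$master_seed,
       n_records = nrow(run$occurrences),
       retained = run$screen$retained,
       champion_rm = run$tuning$champion$rm,
       champion_fc = run$tuning$champion$fc,
       threshold = run$threshold)
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_ascii_grid(run$replicates$mean, file.path(out_dir, "suitability_mean.asc"))
  write_ascii_grid(run$sd, file.path(out_dir, "suitability_sd.asc"))
  write_ascii_grid(run$binary_now, file.path(out_dir, "binary_now.asc"))
  utils::write.csv(run$eval_table, file.path(out_dir, "evaluation.csv"),
                   row.names = FALSE)
  utils::write.csv(run$tuning$scores, file.path(out_dir, "candidates.csv"),
                   row.names = FALSE)
  write_occurrences(run$occurrences, file.path(out_dir, "occurrences_thinned.csv"))
  if (!is.null(run$scenario)) {
    write_ascii_grid(run$scenario$mean, file.path(out_dir, "future_mean.asc"))
    write_ascii_grid(run$scenario$agreement,
                     file.path(out_dir, "future_agreement.asc"))
    write_ascii_grid(run$scenario$change$map, file.path(out_dir, "change_map.asc"))
  }
  writeLines(c(run$log, "", vapply(names(run$manifest$hashes), function(k)
    sprintf("%s %s", k, run$manifest$hashes[[k]]), character(1))),
    file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' Human-readable run report
#'
#' Prints the screening table, candidate grid with the champion line,
#' the evaluation metric panel, and the area/change budgets.
#'
#' @param run A `pipeline_run`.
#' @param ... Unused.
#' @export
print.pipeline_run <- function(run, ...) {
  cat("== suitability pipeline run ==\n")
  cat(sprintf("records: %d (after thinning), Moran's I max %.3f\n",
              nrow(run$occurrences), max(run$thinning$morans_i, na.rm = TRUE)))
  cat(sprintf("retained variables: %s\n",
              paste(run$screen$retained, collapse = ", ")))
  ch <- run$tuning$champion
  cat(sprintf("champion: rm = %.2f, fc = %s, k = %d, AICc = %.2f\n",
              ch$rm, ch$fc, ch$k, ch$aicc))
  p <- run$panel
  cat(sprintf(paste0("panel (test data, mean of %d reps): OR_mtp %.3f, OR_10 %.3f, ",
                     "AUC %.3f, AUC-ratio %.3f,\n  TSS %.3f, Kappa %.3f, ",
                     "Boyce %.3f, Jaccard %.3f, Sorensen %.3f\n"),
              nrow(run$eval_table), p$or_mtp, p$or_10, p$auc, p$auc_ratio,
              p$tss, p$kappa, p$boyce, p$jaccard, p$sorensen))
  cat(sprintf("max-TSS threshold: %.3f\n", run$threshold))
  b <- run$budget_now
  cat(sprintf("near-current: suitable %.4g km2 (%.2f%% of land), consistent %.1f%%\n",
              b$suitable_km2, b$suitable_pct, run$consistency$consistent_pct))
  if (!is.null(run$scenario)) {
    bf <- run$scenario$budget
    d <- bf$suitable_km2 - b$suitable_km2
    cat(sprintf("future ensemble: suitable %.4g km2 (%+.4g km2, %+.2f%%)\n",
                bf$suitable_km2, d, 100 * d / b$suitable_km2))
    a <- run$scenario$change$areas_km2
    cat(sprintf("change classes (km2): unchanged-suitable %.4g, unchanged-unsuitable %.4g, gained %.4g, lost %.4g\n",
                a["unchanged_suitable"], a["unchanged_unsuitable"],
                a["gained"], a["lost"]))
  }
  invisible(run)
}
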