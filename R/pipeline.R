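# End-to-end experiment: occurrence cleaning -> predictor selection ->
# ensemble fitting -> per-scenario projection & binarization -> range
# dynamics -> overlays and summaries, for many species over one current and
# several future scenarios.

species_name <- function(sp) if (inherits(sp, "virtual_species")) sp$name else attr(sp, "species")

# md5 of a numeric table, via a canonical CSV serialization
table_checksum <- function(df) {
  tf <- tempfile(fileext = ".csv")
  on.exit(unlink(tf))
  utils::write.csv(format(df, digits = 12), tf, row.names = FALSE)
  unname(tools::md5sum(tf))
}

#' Run the full range-dynamics experiment
#'
#' For each species: clean occurrences (uncertainty filter + spatial
#' thinning), generate pseudo-absences outside the presence envelope, select
#' predictors (jackknife importance + Pearson pruning), evaluate and screen
#' the requested algorithms, build the TSS-weighted ensemble, project a
#' suitability map per scenario, binarize at the MSS threshold, and compute
#' range dynamics against the current scenario. Then overlay the binary
#' ranges and total suitability across species, difference future vs current
#' totals, and summarize RRI/RSI per scenario.
#'
#' @param stacks Named list of [env_stack()]s; element `current_label` is the
#'   baseline, all others are future scenarios.
#' @param species List of [virtual_species()] (occurrences are sampled from
#'   the current stack) and/or [occurrence_set()]s.
#' @param n_occurrences Presences sampled per virtual species (default 300).
#' @param current_label Name of the current scenario (default `"current"`).
#' @param algorithms Algorithm names to evaluate (see [algorithm_registry()]).
#' @param thin_km,uncertainty_km Occurrence cleaning settings (10 and 5).
#' @param corr_threshold Collinearity pruning threshold (default 0.7).
#' @param sre_q Envelope tail quantile (default 0.025).
#' @param n_splits,train_frac,tss_min,auc_min Evaluation settings
#'   (5 splits, 70/30, TSS > 0.6 / AUC > 0.8 screening).
#' @param threshold_mode `"per_scenario"` recalibrates the MSS threshold from
#'   the ensemble scores at the training locations under each scenario's
#'   projection; `"current"` reuses the current-scenario threshold everywhere.
#' @param contrasts Scenario pairs for paired t-tests (see
#'   [summarize_scenarios()]); default: consecutive future-scenario pairs.
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param out_dir Optional output directory; when given, suitability and
#'   binary maps (ESRI ASCII), evaluation/dynamics tables (CSV) and the run
#'   manifest (JSON) are written there.
#' @return A `pipeline_result` list: `suitability` (species x scenario maps),
#'   `ranges` (binary maps), `dynamics` (data frame), `evaluations`,
#'   `retained` predictor codes per species, `overlays`, `totals`, `changes`,
#'   `summary`, `n_maps`, and `manifest`.
#' @export
run_pipeline <- function(stacks, species, n_occurrences = 300,
                         current_label = "current",
                         algorithms = c("sre", "glm", "cart"),
                         thin_km = 10, uncertainty_km = 5,
                         corr_threshold = 0.7, sre_q = 0.025,
                         n_splits = 5, train_frac = 0.7,
                         tss_min = 0.6, auc_min = 0.8,
                         threshold_mode = c("per_scenario", "current"),
                         contrasts = NULL, seed = 1, out_dir = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  if (!current_label %in% names(stacks))
    stop("no stack named '", current_label, "' among the scenarios")
  if (sum(names(stacks) == current_label) != 1)
    stop("exactly one current scenario required")
  current <- stacks[[current_label]]
  future_labels <- setdiff(names(stacks), current_label)
  scen_labels <- c(current_label, future_labels)

  stage <- function(stage_name, sp_name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage_name, "' failed for species '", sp_name, "': ",
           conditionMessage(e), call. = FALSE))
  }

  suitability <- list(); ranges <- list(); evaluations <- list()
  retained <- list(); dyn_rows <- list()

  for (i in seq_along(species)) {
    sp <- species[[i]]
    nm <- species_name(sp)
    sp_seed <- seed + 101 * i

    occ <- stage("occurrences", nm, {
      o <- if (inherits(sp, "virtual_species"))
        sample_occurrences(sp, current, n_occurrences, seed = sp_seed)
      else sp
      o <- filter_uncertainty(o, max_km = uncertainty_km)
      if (thin_km > 0) o <- spatial_thin(o, min_km = thin_km, seed = sp_seed)
      o
    })

    pa <- stage("pseudo_absences", nm, {
      pres_vals <- extract_cells(current,
                                 cell_index(current$grid, occ$lon, occ$lat)$linear)
      env_envelope <- fit_envelope(pres_vals, q = sre_q)
      generate_pseudo_absences(current, occ, env_envelope, seed = sp_seed + 1)
    })
    training <- stage("training_table", nm, build_training_table(current, occ, pa))

    codes <- stage("predictor_selection", nm, {
      report <- jackknife_importance("cart", training, seed = sp_seed + 2)
      corr <- pearson_matrix(training)
      prune_collinear(corr, report, threshold = corr_threshold)
    })
    retained[[nm]] <- codes
    table_sel <- training[c("label", codes)]

    evals <- stage("evaluation", nm, lapply(algorithms, function(a)
      evaluate_algorithm(a, table_sel, n_splits = n_splits,
                         train_frac = train_frac, seed = sp_seed + 3,
                         tss_min = tss_min, auc_min = auc_min)))
    evaluations[[nm]] <- evals
    ens <- stage("ensemble", nm, build_ensemble(evals, table_sel))

    maps <- stage("projection", nm, {
      out <- list()
      for (lab in scen_labels) {
        m <- predict_map(ens, stacks[[lab]])
        m$species <- nm
        out[[lab]] <- m
      }
      out
    })
    suitability[[nm]] <- maps

    pres_cells <- cell_index(current$grid, occ$lon, occ$lat)$linear
    pa_cells <- cell_index(current$grid, pa$lon, pa$lat)$linear
    bins <- stage("binarization", nm, {
      # MSS threshold from the ensemble's scores at the training locations,
      # recalibrated per scenario unless threshold_mode = "current"
      out <- list()
      for (lab in scen_labels) {
        m <- maps[[lab]]
        pres_scores <- m$values[pres_cells]
        abs_scores <- m$values[pa_cells]
        tau <- if (threshold_mode == "current" && lab != current_label)
          out[[current_label]]$threshold_used
        else mss_threshold(pres_scores[!is.na(pres_scores)],
                           abs_scores[!is.na(abs_scores)])
        b <- binarize(m, tau)
        b$species <- nm
        out[[lab]] <- b
      }
      out
    })
    ranges[[nm]] <- bins

    for (lab in future_labels) {
      d <- stage("dynamics", nm, range_dynamics(bins[[current_label]], bins[[lab]]))
      dyn_rows[[paste(nm, lab)]] <- data.frame(
        species = nm, scenario = lab, SR = d$SR, expansion = d$expansion,
        contraction = d$contraction, RCS = d$RCS, RFS = d$RFS,
        RRI = d$RRI, RSI = d$RSI)
    }
  }

  dynamics <- do.call(rbind, c(dyn_rows, make.row.names = FALSE))

  overlays <- lapply(stats::setNames(scen_labels, scen_labels), function(lab)
    overlay_counts(lapply(ranges, `[[`, lab)))
  totals <- lapply(stats::setNames(scen_labels, scen_labels), function(lab)
    total_suitability(lapply(suitability, `[[`, lab)))
  changes <- lapply(stats::setNames(future_labels, future_labels), function(lab)
    suitability_change(totals[[lab]], totals[[current_label]]))

  if (is.null(contrasts) && length(future_labels) >= 2)
    contrasts <- Map(c, future_labels[-length(future_labels)], future_labels[-1])
  summary <- summarize_scenarios(dynamics, contrasts = contrasts %||% list())

  n_maps <- length(species) * length(scen_labels)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rangedyn")),
    seed = seed,
    settings = list(n_occurrences = n_occurrences, algorithms = algorithms,
                    thin_km = thin_km, uncertainty_km = uncertainty_km,
                    corr_threshold = corr_threshold, sre_q = sre_q,
                    n_splits = n_splits, train_frac = train_frac,
                    tss_min = tss_min, auc_min = auc_min,
                    threshold_mode = threshold_mode),
    species = vapply(species, species_name, character(1)),
    scenarios = scen_labels, n_maps = n_maps,
    checksums = list(dynamics = table_checksum(dynamics)))

  result <- structure(
    list(suitability = suitability, ranges = ranges, dynamics = dynamics,
         evaluations = evaluations, retained = retained, overlays = overlays,
         totals = totals, changes = changes, summary = summary,
         n_maps = n_maps, manifest = manifest),
    class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d species x %d scenarios = %d suitability maps\n",
              length(x$suitability), length(x$manifest$scenarios), x$n_maps))
  print(x$summary)
  invisible(x)
}

# write maps, tables and the manifest; records file checksums in manifest.json
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$suitability)) {
    for (lab in names(result$suitability[[nm]])) {
      m <- result$suitability[[nm]][[lab]]
      write_ascii_grid(m$values, m$grid,
                       file.path(out_dir, sprintf("suit_%s_%s.asc", nm, lab)))
      b <- result$ranges[[nm]][[lab]]
      write_ascii_grid(ifelse(is.na(b$presence), NA, b$presence * 1), b$grid,
                       file.path(out_dir, sprintf("range_%s_%s.asc", nm, lab)))
    }
  }
  utils::write.csv(result$dynamics, file.path(out_dir, "dynamics.csv"),
                   row.names = FALSE)
  evals <- do.call(rbind, lapply(names(result$evaluations), function(nm)
    do.call(rbind, lapply(result$evaluations[[nm]], function(e)
      data.frame(species = nm, algorithm = e$algorithm, tss = e$tss,
                 auc = e$auc, included = e$included)))))
  utils::write.csv(evals, file.path(out_dir, "evaluations.csv"), row.names = FALSE)
  manifest <- result$manifest
  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest$checksums$files <- as.list(tools::md5sum(files))
  names(manifest$checksums$files) <- basename(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
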