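# End-to-end orchestration: synthetic or user-supplied ranges + tree in,
# one classed result object (optionally a CSV output tree) out.

.default_config <- function() {
  list(
    grid = list(bbox = NULL, cell_km = 100, lat_ts = 30, lon0 = NULL),
    gam = list(family = "gaussian", k = 10),
    spatial = list(n_classes = 10, n_perm = 200, rule = "equal_width",
                   max_cells = 3000, alternative = "two.sided"),
    compare = list(method = "rma", swap = FALSE),
    seed = 1
  )
}

.merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a list, fills in documented defaults
#' (100 km cells, 10 distance classes, 200 permutations, gaussian GAM with
#' k = 10, RMA comparison) and collects *all* problems before failing, so a
#' broken config is reported once, completely.  Unknown top-level keys
#' raise warnings, not errors.
#'
#' Exactly one of `scenario` (synthetic mode, see [scenario_config()]) and
#' `inputs` (paths `ranges`, `tree`, optional `groups` CSV with columns
#' `species,group`) must be present.
#'
#' @param config Path to a YAML file, or a nested list.
#' @return A validated, completed config list of class `latgrad_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML file path")
  known <- c("scenario", "inputs", "grid", "gam", "spatial", "compare",
             "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    warning("unknown config key(s) ignored: ", paste(unknown, collapse = ", "))
  errors <- character(0)
  err <- function(...) errors <<- c(errors, paste0(...))

  has_scenario <- !is.null(config$scenario)
  has_inputs <- !is.null(config$inputs)
  if (has_scenario == has_inputs)
    err("exactly one of `scenario` and `inputs` must be given")

  full <- .merge_config(.default_config(), config)

  if (has_inputs) {
    for (k in c("ranges", "tree")) {
      if (is.null(full$inputs[[k]])) {
        err("inputs$", k, " is required")
      } else if (!file.exists(full$inputs[[k]])) {
        err("inputs$", k, " does not exist: ", full$inputs[[k]])
      }
    }
    if (is.null(full$grid$bbox))
      err("grid$bbox is required when using `inputs`")
  }
  if (has_scenario && !has_inputs) {
    sc <- tryCatch(
      do.call(scenario_config,
              c(full$scenario[setdiff(names(full$scenario), "seed")],
                list(seed = full$seed))),
      error = function(e) {
        err("scenario: ", conditionMessage(e))
        NULL
      })
    full$scenario <- sc
    if (!is.null(sc) && is.null(full$grid$bbox)) full$grid$bbox <- sc$bbox
  }
  if (!is.numeric(full$grid$cell_km) || full$grid$cell_km <= 0)
    err("grid$cell_km must be a positive number")
  if (!full$gam$family %in% c("gaussian", "poisson"))
    err("gam$family must be \"gaussian\" or \"poisson\"")
  if (!is.numeric(full$gam$k) || full$gam$k < 3)
    err("gam$k must be a number >= 3")
  if (!is.numeric(full$spatial$n_classes) || full$spatial$n_classes < 1)
    err("spatial$n_classes must be a positive integer")
  if (!is.numeric(full$spatial$n_perm) || full$spatial$n_perm < 1)
    err("spatial$n_perm must be a positive integer")
  if (!full$compare$method %in% c("rma", "ma"))
    err("compare$method must be \"rma\" or \"ma\"")
  if (!is.numeric(full$seed) || length(full$seed) != 1L)
    err("seed must be a single integer")

  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  class(full) <- c("latgrad_config", "list")
  full
}

.fit_response <- function(cm, response, cfg) {
  keep <- if (response == "richness") {
    cm$occupied
  } else {
    cm$occupied & is.finite(cm$mrd)
  }
  y <- if (response == "richness") cm$richness[keep] else cm$mrd[keep]
  fam <- if (response == "mrd") "gaussian" else cfg$gam$family
  fit <- fit_smooth(cm$latitude_deg[keep], y, family = fam, k = cfg$gam$k)
  list(fit = fit, keep = which(keep))
}

#' Run the full latitudinal-gradient analysis
#'
#' Executes the whole pipeline: synthetic generation (scenario mode) or
#' range/tree reading (inputs mode), equal-area gridding and rasterization,
#' per-cell richness and mean root distance, penalized-spline smooths of
#' both against latitude, Moran's I correlograms of the model residuals, of
#' total richness and of the basal/derived quartile richness surfaces, and
#' the Pearson + model-II comparison of total against basal and derived.
#' With a species-to-group table the per-cell metrics, smooths and residual
#' correlograms are additionally computed per group (e.g. per family).
#'
#' All randomness flows from the config's single master seed, split per
#' stage, so two runs with the same config are identical (including their
#' written CSVs).
#'
#' @param config A config list or YAML path (see [validate_config()]).
#' @param out_dir Optional output directory for CSVs and `manifest.json`;
#'   defaults to `config$out_dir` if set.
#' @return Object of class `latgrad_run`; see the package vignette for the
#'   component list.
#' @export
latgrad_run <- function(config, out_dir = NULL) {
  cfg <- validate_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  seed <- as.integer(cfg$seed)

  # --- data stage
  groups <- NULL
  truth <- NULL
  if (!is.null(cfg$scenario)) {
    syn <- generate_scenario(cfg$scenario)
    tree <- syn$tree; ranges <- syn$ranges; truth <- syn$truth
  } else {
    ranges <- read_ranges(cfg$inputs$ranges)
    tree <- read_newick(cfg$inputs$tree)
    if (!is.null(cfg$inputs$groups)) {
      groups <- utils::read.csv(cfg$inputs$groups, stringsAsFactors = FALSE)
      if (!all(c("species", "group") %in% names(groups)))
        stop("groups file must have columns species,group")
    }
  }

  # --- grid stage
  grid <- build_grid(cfg$grid$bbox, cell_km = cfg$grid$cell_km,
                     lon0 = cfg$grid$lon0, lat_ts = cfg$grid$lat_ts)
  pm <- rasterize(ranges, grid)

  # --- metrics stage
  rd <- root_distances(tree)
  matched <- match_species(rd, pm)
  cm <- cell_metrics(pm, matched$rd, grid)
  split <- quartile_split(matched$rd)

  # --- smooth stage
  g_rich <- .fit_response(cm, "richness", cfg)
  g_mrd <- .fit_response(cm, "mrd", cfg)

  # --- spatial stage
  sp <- cfg$spatial
  coords_rich <- as.matrix(cm[g_rich$keep, c("x_km", "y_km")])
  coords_mrd <- as.matrix(cm[g_mrd$keep, c("x_km", "y_km")])
  cg <- function(vals, coords, s) {
    correlogram(vals, coords, n_classes = sp$n_classes, n_perm = sp$n_perm,
                seed = s, max_cells = sp$max_cells, rule = sp$rule,
                alternative = sp$alternative)
  }
  correlog_resid_richness <- cg(residuals(g_rich$fit), coords_rich, seed + 11L)
  correlog_resid_mrd <- cg(residuals(g_mrd$fit), coords_mrd, seed + 12L)
  correlog_total <- cg(cm$richness[g_rich$keep], coords_rich, seed + 13L)
  correlog_basal <- cg(cm$basal_richness[g_rich$keep], coords_rich, seed + 13L)
  correlog_derived <- cg(cm$derived_richness[g_rich$keep], coords_rich,
                         seed + 13L)

  # --- comparison stage
  comp <- cfg$compare
  compare_basal <- compare_correlograms(correlog_total, correlog_basal,
                                        method = comp$method,
                                        swap = isTRUE(comp$swap))
  compare_derived <- compare_correlograms(correlog_total, correlog_derived,
                                          method = comp$method,
                                          swap = isTRUE(comp$swap))
  occ <- g_rich$keep
  pearson <- c(
    basal = pearson_r(cm$richness[occ], cm$basal_richness[occ]),
    derived = pearson_r(cm$richness[occ], cm$derived_richness[occ])
  )

  # --- optional per-group fan-out
  group_results <- NULL
  if (!is.null(groups)) {
    group_results <- list()
    for (g in unique(groups$group)) {
      sp_g <- intersect(groups$species[groups$group == g], colnames(pm))
      if (length(sp_g) < 4L) {
        warning("group ", g, " has fewer than 4 gridded species; skipped")
        next
      }
      pm_g <- pm[, sp_g, drop = FALSE]
      rd_g <- matched$rd[intersect(names(matched$rd), sp_g)]
      cm_g <- cell_metrics(pm_g, rd_g, grid)
      gr <- .fit_response(cm_g, "richness", cfg)
      gm <- .fit_response(cm_g, "mrd", cfg)
      group_results[[g]] <- list(
        cell_metrics = cm_g,
        gam_richness = gr$fit,
        gam_mrd = gm$fit,
        correlog_resid_richness = cg(
          residuals(gr$fit),
          as.matrix(cm_g[gr$keep, c("x_km", "y_km")]),
          seed + 30L + match(g, unique(groups$group)))
      )
    }
  }

  # cell metrics carries projected coords for downstream spatial stages
  manifest <- list(
    package = "latgrad",
    version = as.character(utils::packageVersion("latgrad")),
    mode = if (!is.null(cfg$scenario)) "scenario" else "inputs",
    seed = seed,
    stage_seeds = list(scenario = seed, correlog_residuals = seed + 11:12,
                       correlog_richness = seed + 13L),
    n_species = ncol(pm),
    n_cells = nrow(pm),
    n_occupied_cells = sum(cm$occupied),
    n_cells_with_mrd = sum(is.finite(cm$mrd) & cm$occupied),
    n_matched_species = matched$drop_report$n_matched,
    n_unmatched_species = matched$drop_report$n_unmatched_species,
    n_basal = length(split$basal),
    n_derived = length(split$derived),
    config = .config_echo(cfg)
  )

  res <- structure(
    list(config = cfg, grid = grid, presence = pm, tree = tree,
         truth = truth, rd = rd, matched = matched,
         cell_metrics = cm, quartiles = split,
         gam_richness = g_rich$fit, gam_mrd = g_mrd$fit,
         gam_cells = list(richness = g_rich$keep, mrd = g_mrd$keep),
         correlog_resid_richness = correlog_resid_richness,
         correlog_resid_mrd = correlog_resid_mrd,
         correlog_total = correlog_total,
         correlog_basal = correlog_basal,
         correlog_derived = correlog_derived,
         compare_basal = compare_basal,
         compare_derived = compare_derived,
         pearson = pearson,
         groups = group_results,
         manifest = manifest),
    class = "latgrad_run"
  )
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

# config echo with function-free, JSON-serializable entries
.config_echo <- function(cfg) {
  cfg <- unclass(cfg)
  if (!is.null(cfg$scenario)) cfg$scenario <- unclass(cfg$scenario)
  cfg
}

#' Write the CSV output tree of a run
#'
#' Emits `cell_metrics.csv`, the sparse presence triplets
#' (`presence.csv`: cell_id,species,1), `rd_table.csv`, per-response GAM
#' summary and fitted/residual tables, every correlogram, the comparison
#' table, a drop report and `manifest.json`.
#'
#' @param run A `latgrad_run`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "latgrad_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)

  cm <- run$cell_metrics
  cells <- cbind(cm[, c("cell_id", "x_km", "y_km",
                        "latitude_deg", "longitude_deg")])
  w(cells, "cell_table.csv")
  w(cm, "cell_metrics.csv")
  idx <- which(run$presence, arr.ind = TRUE)
  w(data.frame(cell_id = cm$cell_id[idx[, 1L]],
               species = colnames(run$presence)[idx[, 2L]],
               present = 1L), "presence.csv")
  w(data.frame(species = names(run$rd), rd = as.integer(run$rd)),
    "rd_table.csv")

  gam_sum <- do.call(rbind, lapply(c("richness", "mrd"), function(r) {
    f <- run[[paste0("gam_", r)]]
    data.frame(response = r, family = f$family, k = f$k,
               lambda = f$lambda, edf = f$edf,
               deviance_explained = f$deviance_explained,
               p_value = f$p_value)
  }))
  w(gam_sum, "gam_summary.csv")
  for (r in c("richness", "mrd")) {
    f <- run[[paste0("gam_", r)]]
    w(data.frame(cell_id = cm$cell_id[run$gam_cells[[r]]],
                 observed = f$y, fitted = f$fitted,
                 residual = residuals(f)),
      paste0("gam_cells_", r, ".csv"))
  }
  for (nm in c("correlog_resid_richness", "correlog_resid_mrd",
               "correlog_total", "correlog_basal", "correlog_derived")) {
    w(as.data.frame(run[[nm]]), paste0(nm, ".csv"))
  }
  comp <- do.call(rbind, lapply(c("basal", "derived"), function(s) {
    f <- run[[paste0("compare_", s)]]
    data.frame(subset = s, method = f$method, slope = f$slope,
               intercept = f$intercept, r_squared = f$r_squared,
               se_slope = f$se_slope, se_r2 = f$se_r_squared,
               n_classes = f$n, pearson_r_cells = unname(run$pearson[s]))
  }))
  w(comp, "comparison.csv")

  dr <- run$matched$drop_report
  writeLines(c(
    sprintf("matched species: %d", dr$n_matched),
    sprintf("matrix species lacking RD (%d): %s", dr$n_unmatched_species,
            paste(dr$unmatched_species, collapse = ", ")),
    sprintf("tree tips lacking ranges (%d): %s", dr$n_unmatched_tips,
            paste(dr$unmatched_tips, collapse = ", "))
  ), file.path(dir, "drop_report.txt"))

  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' @export
print.latgrad_run <- function(x, ...) {
  m <- x$manifest
  cat("Latitudinal gradient analysis (", m$mode, " mode, seed ", m$seed,
      ")\n", sep = "")
  cat(sprintf("  %d species on %d cells (%d occupied, %d with MRD)\n",
              m$n_species, m$n_cells, m$n_occupied_cells,
              m$n_cells_with_mrd))
  cat(sprintf("  richness ~ latitude: %.1f%% deviance explained, p = %s\n",
              100 * x$gam_richness$deviance_explained,
              format.pval(x$gam_richness$p_value)))
  cat(sprintf("  MRD ~ latitude:      %.1f%% deviance explained, p = %s\n",
              100 * x$gam_mrd$deviance_explained,
              format.pval(x$gam_mrd$p_value)))
  invisible(x)
}

#' @export
summary.latgrad_run <- function(object, ...) {
  x <- object
  print(x)
  cat("\nBasal/derived decomposition (RD quartiles ",
      x$quartiles$q1, " / ", x$quartiles$q3, "):\n", sep = "")
  cat(sprintf("  %d basal, %d derived of %d matched species\n",
              length(x$quartiles$basal), length(x$quartiles$derived),
              x$manifest$n_matched_species))
  cat(sprintf("  Pearson r (cells): total~basal %.3f, total~derived %.3f\n",
              x$pearson["basal"], x$pearson["derived"]))
  for (s in c("basal", "derived")) {
    f <- x[[paste0("compare_", s)]]
    cat(sprintf("  %s slope (%s): %.3f ± %.3f, R² = %.3f\n",
                s, toupper(f$method), f$slope, f$se_slope, f$r_squared))
  }
  mx <- function(cg) max(abs(cg$moran_i), na.rm = TRUE)
  cat(sprintf("  max |Moran's I| of residuals: richness %.3f, MRD %.3f\n",
              mx(x$correlog_resid_richness), mx(x$correlog_resid_mrd)))
  invisible(x)
}

#' @export
plot.latgrad_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$gam_richness, ylab = "species richness",
       main = "Richness vs latitude")
  plot(x$gam_mrd, ylab = "mean root distance", main = "MRD vs latitude")
  plot(x$correlog_resid_richness, main = "Residual correlogram (richness)")
  plot(x$correlog_resid_mrd, main = "Residual correlogram (MRD)")
  invisible(x)
}
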