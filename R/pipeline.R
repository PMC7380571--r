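#' Pipeline run configuration
#'
#' Collects every input path, threshold and seed of an end-to-end run, so a
#' run is fully described by one object and can be reproduced bit-for-bit.
#' Either the four input paths (feature table, metadata, tree, controls) or
#' an in-memory [generate_study()] result must be supplied.
#'
#' @param table_path,metadata_path,tree_path,controls_path input file paths
#'   (TSV / TSV / newick / TSV).
#' @param study optional in-memory study (list with `table`, `metadata`,
#'   `tree`, `controls`) used instead of the paths.
#' @param table_orientation orientation of the feature-table file.
#' @param depth explicit rarefaction depth; when NULL the depth is derived
#'   from the titration controls at `target_fraction`. An explicit depth
#'   (e.g. a previously established exclusion threshold such as 1362) skips
#'   curve fitting and is recorded as "explicit" in the manifest.
#' @param target_fraction target fraction of correctly assigned control
#'   reads for the limit-of-detection threshold (default 0.9).
#' @param rarefy_seed seed of the rarefaction subsample.
#' @param metrics beta-diversity metrics to compute.
#' @param prevalence core-microbiome prevalence threshold (default 0.30).
#' @param body_sites body sites forming the fish union in accounting.
#' @param driver_sites body sites run through the driver analysis.
#' @param covariates covariate columns, in order of entry (sequential sums
#'   of squares make the order part of the analysis).
#' @param n_perm PERMANOVA permutation count.
#' @param perm_seed PERMANOVA permutation seed.
#' @param accumulation_n_perm orderings averaged for permuted accumulation
#'   curves and saturation sizes.
#' @param growth a [growth_params()] for deriving fish age; NULL skips
#'   biometrics derivation (then `age_yr`/`condition_k` must already be in
#'   the metadata).
#' @param out_dir output directory for stage artifacts and the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(table_path = NULL, metadata_path = NULL,
                            tree_path = NULL, controls_path = NULL,
                            study = NULL,
                            table_orientation = "samples",
                            depth = NULL, target_fraction = 0.9,
                            rarefy_seed = 1L,
                            metrics = c("unweighted_unifrac",
                                        "weighted_unifrac"),
                            prevalence = 0.30,
                            body_sites = c("gill", "skin", "digesta"),
                            driver_sites = c("gill", "skin", "digesta",
                                             "GI", "pyloric_ceca"),
                            covariates = c("age_yr", "fork_length_mm",
                                           "mass_kg", "condition_k",
                                           "chlorophyll_a", "pressure",
                                           "salinity", "temperature"),
                            n_perm = 999L, perm_seed = 1L,
                            accumulation_n_perm = 50L,
                            growth = growth_params(L_inf = 400, k = 0.45,
                                                   t0 = -0.8),
                            out_dir = tempfile("mucodiv_run_")) {
  cfg <- as.list(environment())
  if (is.null(study) &&
      (is.null(table_path) || is.null(metadata_path) || is.null(tree_path)))
    stop("either `study` or the table/metadata/tree paths must be given")
  class(cfg) <- "pipeline_config"
  cfg
}

.stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the study's analysis order — QC/rarefaction, alpha and beta
#' diversity, diversity accounting, driver analysis — persisting every
#' stage's artifacts under `config$out_dir` together with a machine-readable
#' manifest (`manifest.json`) that records seeds, thresholds, the
#' excluded-sample list and md5 hashes of all outputs. Rerunning the same
#' configuration reproduces identical hashes for all deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the rarefied `table`, `metadata`, `tree`,
#'   stage results (`qc`, `alpha`, `beta`, `accounting`, `drivers`) and the
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("mucodiv")),
                   seeds = list(rarefy = cfg$rarefy_seed,
                                permanova = cfg$perm_seed))

  # --- inputs ---------------------------------------------------------------
  inputs <- .stage_error("load", {
    if (!is.null(cfg$study)) cfg$study
    else list(
      table = read_feature_table(cfg$table_path, cfg$table_orientation),
      metadata = read_sample_metadata(cfg$metadata_path),
      tree = read_phylogeny(cfg$tree_path),
      controls = if (!is.null(cfg$controls_path))
        read_titration_controls(cfg$controls_path))
  })
  aligned <- .stage_error("align", align_table_tree(inputs$table, inputs$tree))
  manifest$dropped_features <- length(aligned$dropped_features)
  manifest$dropped_leaves <- length(aligned$dropped_leaves)

  # --- qc / rarefaction -----------------------------------------------------
  qc <- .stage_error("qc", {
    if (!is.null(cfg$depth)) {
      list(depth = as.integer(cfg$depth), source = "explicit", curve = NULL)
    } else {
      if (is.null(inputs$controls))
        stop("no titration controls and no explicit depth")
      curve <- fit_lod_curve(inputs$controls)
      list(depth = exclusion_threshold(curve, cfg$target_fraction),
           source = sprintf("titration (target fraction %g)",
                            cfg$target_fraction),
           curve = curve)
    }
  })
  rar <- .stage_error("rarefy",
    rarefy_table(aligned$table, qc$depth, cfg$rarefy_seed))
  manifest$rarefaction <- list(depth = qc$depth, source = qc$source,
                               excluded_samples = rar$dropped_samples$sample_id)
  md <- inputs$metadata[inputs$metadata$sample_id %in% rownames(rar$table), ,
                        drop = FALSE]
  if (!is.null(cfg$growth) &&
      !all(c("age_yr", "condition_k") %in% names(md)))
    md <- add_biometrics(md, cfg$growth)

  # --- diversity ------------------------------------------------------------
  alpha <- .stage_error("alpha",
    alpha_diversity(rar$table, aligned$tree))
  utils::write.table(alpha, file.path(cfg$out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  beta <- list()
  for (metric in cfg$metrics) {
    beta[[metric]] <- .stage_error(metric,
      beta_distance_matrix(rar$table, aligned$tree, metric))
    write_distance_matrix(beta[[metric]],
                          file.path(cfg$out_dir, paste0(metric, ".tsv")))
  }

  # --- accounting -----------------------------------------------------------
  accounting <- .stage_error("accounting", {
    types <- intersect(unique(md$sample_type), setdiff(sample_types(),
                                                       "control"))
    gamma <- lapply(stats::setNames(types, types), function(tp)
      gamma_richness(rar$table, md$sample_id[md$sample_type == tp]))
    gamma$total <- gamma_richness(rar$table, md$sample_id)
    ratio <- tryCatch(host_env_ratio_events(rar$table, md,
                                            body_sites = cfg$body_sites),
                      error = function(e) NULL)
    uniq <- tryCatch(uniqueness_by_event(rar$table, md,
                                         body_sites = cfg$body_sites),
                     error = function(e) NULL)
    core <- lapply(stats::setNames(types, types), function(tp)
      core_features(rar$table, md, tp, cfg$prevalence))
    sat <- lapply(stats::setNames(types, types), function(tp)
      saturation_n(rar$table, md$sample_id[md$sample_type == tp],
                   policy = "permuted", n_perm = cfg$accumulation_n_perm,
                   seed = cfg$rarefy_seed))
    list(gamma = gamma, ratio = ratio, uniqueness = uniq, core = core,
         saturation = sat)
  })
  jsonlite::write_json(
    list(gamma = accounting$gamma,
         ratio = if (!is.null(accounting$ratio))
           accounting$ratio[c("mean", "range")],
         uniqueness_mean = if (!is.null(accounting$uniqueness))
           as.list(accounting$uniqueness$mean_fraction),
         saturation_n = lapply(accounting$saturation, function(s)
           list(n = s$n, sd = s$sd))),
    file.path(cfg$out_dir, "accounting.json"),
    auto_unbox = TRUE, digits = NA)

  # --- drivers --------------------------------------------------------------
  drivers <- .stage_error("drivers", {
    out <- list()
    for (site in intersect(cfg$driver_sites, unique(md$sample_type))) {
      site_md <- md[md$sample_type == site, , drop = FALSE]
      design <- site_md[, cfg$covariates, drop = FALSE]
      site_res <- list()
      for (metric in c("shannon", "faith_pd")) {
        vals <- alpha$value[alpha$metric == metric]
        names(vals) <- alpha$sample_id[alpha$metric == metric]
        y <- vals[site_md$sample_id]
        logt <- metric == "faith_pd"
        gate <- tryCatch(glm_gate(y, design, log_transform = logt),
                         error = function(e) NULL)
        # collinearity is reported through the per-covariate VIF column of
        # the fit rather than as a console warning during the batch run
        fit <- if (!is.null(gate) && gate$admitted)
          suppressWarnings(fit_glm(y, design, log_transform = logt,
                                   gate = gate))
        site_res[[metric]] <- list(gate = gate, fit = fit)
      }
      for (metric in cfg$metrics) {
        cc <- stats::complete.cases(design)   # same policy as the GLM gate
        ids_cc <- site_md$sample_id[cc]
        dm_site <- beta[[metric]][ids_cc, ids_cc]
        design_cc <- design[cc, , drop = FALSE]
        rownames(design_cc) <- ids_cc
        site_res[[metric]] <- tryCatch(
          permanova(dm_site, design_cc,
                    stats::reformulate(cfg$covariates),
                    n_perm = cfg$n_perm, seed = cfg$perm_seed),
          error = function(e) NULL)
      }
      out[[site]] <- site_res
    }
    out
  })
  .write_driver_tables(drivers, cfg$out_dir)

  # --- manifest -------------------------------------------------------------
  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest$outputs <- as.list(stats::setNames(
    unname(tools::md5sum(file.path(cfg$out_dir, files))), files))
  manifest$config <- list(depth = cfg$depth,
                          target_fraction = cfg$target_fraction,
                          prevalence = cfg$prevalence,
                          body_sites = cfg$body_sites,
                          covariates = cfg$covariates,
                          n_perm = cfg$n_perm)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(table = rar$table, metadata = md, tree = aligned$tree,
                 qc = qc, alpha = alpha, beta = beta,
                 accounting = accounting, drivers = drivers,
                 manifest = manifest, out_dir = cfg$out_dir))
}

# flat per-site driver summary tables mirroring the per-covariate
# sign/p-value layout of the study's driver tables
.write_driver_tables <- function(drivers, out_dir) {
  glm_rows <- list()
  perm_rows <- list()
  for (site in names(drivers)) {
    for (metric in names(drivers[[site]])) {
      res <- drivers[[site]][[metric]]
      if (metric %in% c("shannon", "faith_pd")) {
        gate <- res$gate
        if (is.null(gate)) next
        row <- data.frame(site = site, metric = metric,
                          shapiro_p = gate$shapiro_p,
                          breusch_pagan_p = gate$breusch_pagan_p,
                          admitted = gate$admitted,
                          stringsAsFactors = FALSE)
        if (!is.null(res$fit)) {
          row$r_squared <- res$fit$r_squared
          row$f_statistic <- res$fit$f_statistic
          row$p_value <- res$fit$p_value
          for (i in seq_len(nrow(res$fit$coefficients))) {
            cf <- res$fit$coefficients[i, ]
            row[[paste0(cf$term, "_p")]] <- cf$p_value
            row[[paste0(cf$term, "_sign")]] <- cf$sign
          }
        }
        glm_rows[[length(glm_rows) + 1L]] <- row
      } else if (inherits(res, "permanova")) {
        tab <- res$table[!res$table$term %in% c("Residual", "Total"), ]
        perm_rows[[length(perm_rows) + 1L]] <- data.frame(
          site = site, metric = metric, term = tab$term, R2 = tab$R2,
          F = tab$F, p_value = tab$p_value,
          overall_p = res$overall_p, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(glm_rows)) {
    all_cols <- unique(unlist(lapply(glm_rows, names)))
    glm_rows <- lapply(glm_rows, function(r) {
      r[setdiff(all_cols, names(r))] <- NA
      r[all_cols]
    })
    utils::write.table(do.call(rbind, glm_rows),
                       file.path(out_dir, "drivers_glm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(perm_rows))
    utils::write.table(do.call(rbind, perm_rows),
                       file.path(out_dir, "drivers_permanova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
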