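#' Load and validate a run configuration
#'
#' The run configuration is a YAML (or R list) describing the whole
#' experiment: the brains (id, group, transport mode, seed), phantom
#' geometry overrides, segmentation threshold, spread sampling, lymph-node
#' images and which stages to run. Validation happens before any
#' computation.
#'
#' @param config path to a YAML file, or a list.
#' @return the validated config list, with defaults filled in.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$brains) || length(config$brains) == 0)
    abort("config must list at least one brain")
  valid_groups <- c("L30", "L90", "S30", "S90")
  for (b in config$brains) {
    if (is.null(b$id) || is.null(b$group) || is.null(b$mode))
      abort("every brain needs id, group and mode")
    if (!b$group %in% valid_groups)
      abort(sprintf("brain '%s': group must be one of %s", b$id,
                    paste(valid_groups, collapse = ", ")))
    if (!b$mode %in% c("diffusive", "advective"))
      abort(sprintf("brain '%s': mode must be diffusive or advective", b$id))
  }
  config$seed <- config$seed %||% 1L
  config$threshold <- config$threshold %||% "auto"
  config$sample_n <- config$sample_n %||% "all"
  config$stages <- config$stages %||%
    c("simulate", "register", "reconstruct", "segment", "spread",
      "lymphnode", "stats")
  config$phantom <- config$phantom %||% list()
  config
}

phantom_spec_from_config <- function(config, brain) {
  ph <- config$phantom
  args <- list(mode = brain$mode,
               seed = brain$seed %||% (config$seed + 100L))
  for (f in c("shape", "in_plane_um", "axial_um", "D", "t_min", "reach_um",
              "deposit_um", "misalign_sigma_px", "misalign_sigma_deg",
              "noise_sigma", "brightness_jitter"))
    if (!is.null(ph[[f]])) args[[f]] <- ph[[f]]
  do.call(phantom_spec, args)
}

write_csv_quiet <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Run the full reconstruction and quantification pipeline
#'
#' Executes the requested stages in order — simulate, register, reconstruct,
#' segment, spread, lymphnode, stats — writing CSV outputs plus a run log
#' into `outdir`. Every random choice is seeded from the config, so two runs
#' of the same config produce bit-identical CSVs.
#'
#' Stage failures abort with the stage name and cause. The hemisphere-count
#' Wilcoxon test is computed whenever >= 3 brains are available but is
#' always flagged with a small-n caveat: group sizes at this design's scale
#' do not support a reliable paired analysis.
#'
#' @param config path to a YAML run configuration or a list
#'   (see [load_run_config()]).
#' @param outdir output directory.
#' @return (invisibly) a list with the main result tables: `counts`,
#'   `distances`, `spread_summary`, `comparison`, `lymphnode`, `stats`.
#' @export
run_pipeline <- function(config, outdir) {
  config <- load_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  res <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e))))
  }

  brains <- list()
  if ("simulate" %in% stages) stage("simulate", {
    for (b in config$brains) {
      spec <- phantom_spec_from_config(config, b)
      ph <- generate_phantom(spec)
      brains[[b$id]] <- list(meta = b, spec = spec, stack = ph$stack,
                             truth = ph$truth)
    }
  })

  if ("register" %in% stages) stage("register", {
    for (id in names(brains)) {
      reg <- register_stack(brains[[id]]$stack)
      brains[[id]]$stack <- reg$stack
      brains[[id]]$transforms <- reg$transforms
      write_transforms_csv(reg$transforms,
                           file.path(outdir,
                                     sprintf("transforms_%s.csv", id)))
    }
  })

  if ("reconstruct" %in% stages) stage("reconstruct", {
    for (id in names(brains)) {
      st <- equalize_brightness(brains[[id]]$stack, "nuclei")
      vol <- assemble_volume(st)
      brains[[id]]$volume <- vol
      for (ax in c("coronal", "sagittal", "horizontal"))
        write_projection_png(maximum_projection(vol, ax, "tracer"),
                             file.path(outdir,
                                       sprintf("mip_%s_%s.png", id, ax)))
    }
  })

  if ("segment" %in% stages) stage("segment", {
    counts <- NULL
    for (id in names(brains)) {
      vol <- brains[[id]]$volume
      bin <- binarize_tracer(vol, "tracer", config$threshold)
      brains[[id]]$binary <- bin
      mid <- (dim(bin$positive)[3] + 1) / 2
      sep <- midline_polyline(mid, dim(bin$positive)[2])
      inj_col <- brains[[id]]$spec$injection[3]
      split <- split_hemispheres(bin, sep,
                                 ipsi_side = if (inj_col < mid) "left"
                                             else "right")
      counts <- dplyr::bind_rows(counts, dplyr::bind_cols(
        tibble(brain_id = id, group = brains[[id]]$meta$group,
               threshold = bin$threshold), split))
    }
    res$counts <- counts
    write_csv_quiet(counts, file.path(outdir, "hemisphere_counts.csv"))
  })

  if ("spread" %in% stages) stage("spread", {
    dists <- NULL
    for (id in names(brains)) {
      ds <- distance_sample(brains[[id]]$binary, brain_id = id,
                            group = brains[[id]]$meta$group,
                            n = config$sample_n, seed = config$seed)
      dists <- dplyr::bind_rows(dists, ds)
    }
    res$distances <- dists
    write_csv_quiet(dists, file.path(outdir, "distances.csv"))
    summ <- summarize_spread(dists)
    res$spread_summary <- summ
    write_csv_quiet(summ$by_group, file.path(outdir,
                                             "spread_group_summary.csv"))
    write_csv_quiet(summ$by_brain, file.path(outdir,
                                             "spread_brain_medians.csv"))
  })

  if ("lymphnode" %in% stages && !is.null(config$lymphnode)) {
    stage("lymphnode", {
      ln <- NULL
      for (im in config$lymphnode$images) {
        g <- generate_lymphnode_image(
          n_tracer = im$n_tracer, n_autofluor = im$n_autofluor,
          seed = im$seed %||% config$seed)
        corr <- correct_autofluorescence(g$image[, , "green"],
                                         g$image[, , "red"])
        q <- suppressWarnings(
          count_tracer_pixels(corr, node_class = im$node_class %||% "DCLN-left"))
        ln <- dplyr::bind_rows(ln, dplyr::bind_cols(
          tibble(image_id = im$id, group = im$group,
                 true_tracer_px = g$truth$tracer_pixels), q))
      }
      res$lymphnode <- ln
      write_csv_quiet(ln, file.path(outdir, "lymphnode_counts.csv"))
    })
  }

  if ("stats" %in% stages) stage("stats", {
    stats_rows <- NULL
    if (!is.null(res$distances) &&
        dplyr::n_distinct(res$distances$group) >= 2) {
      cmp <- compare_spread(res$distances)
      res$comparison <- cmp
      stats_rows <- dplyr::bind_rows(
        stats_rows,
        dplyr::mutate(tidy(cmp), analysis = "spread"))
    }
    if (!is.null(res$counts) && nrow(res$counts) >= 3) {
      w <- tryCatch(wilcoxon_signed_rank(res$counts$ipsi, res$counts$contra),
                    error = function(e) NULL)
      if (!is.null(w))
        stats_rows <- dplyr::bind_rows(stats_rows, tibble(
          comparison = "ipsi vs contra (all brains)", test = w$method,
          statistic = w$statistic, p_value = w$p_value,
          analysis = "hemisphere_counts (caveat: small n)"))
    }
    if (!is.null(res$lymphnode) &&
        dplyr::n_distinct(res$lymphnode$group) == 2) {
      gg <- split(res$lymphnode$pixel_count, res$lymphnode$group)
      if (all(vapply(gg, length, 0L) >= 1) &&
          sum(lengths(gg)) >= 3) {
        mw <- mann_whitney_u(gg[[1]], gg[[2]])
        stats_rows <- dplyr::bind_rows(stats_rows, tibble(
          comparison = paste(names(gg)[1], "vs", names(gg)[2]),
          test = mw$method, statistic = mw$statistic, p_value = mw$p_value,
          analysis = "lymphnode_counts (unpaired)"))
      }
    }
    res$stats <- stats_rows
    if (!is.null(stats_rows))
      write_csv_quiet(stats_rows, file.path(outdir, "stats_report.csv"))
  })

  log <- list(package = "tracer3d",
              version = as.character(utils::packageVersion("tracer3d")),
              seed = config$seed, threshold = config$threshold,
              sample_n = config$sample_n, stages = stages,
              brains = lapply(config$brains, function(b)
                list(id = b$id, group = b$group, mode = b$mode)))
  yaml::write_yaml(log, file.path(outdir, "run_log.yaml"))
  res$brains <- brains
  invisible(res)
}
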