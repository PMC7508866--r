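#' Default pipeline configuration
#'
#' Encodes the default simulated study: two OA-induction models (MMT,
#' mechanical; MIA, chemical), three animals per model, each contributing a
#' healthy contralateral surface and an OA surface -- four analysis groups
#' of three samples. The planted OA effects mirror the magnitudes the
#' method is designed to resolve: per-axis wavelength stretches around
#' 1.2-1.4 (deformation ratios 0.2-0.4) and an angular-sector imbalance in
#' the mechanical model only. Slides plant group-wise colour fractions,
#' cell densities and Mankin operator scores.
#'
#' @param out_dir Output directory of the run.
#' @param seed Integer master seed; every per-sample seed derives from it.
#' @return A nested configuration list, JSON-serializable via
#'   [write_config()].
#' @export
default_config <- function(out_dir = "oatopo_run", seed = 20260921) {
  list(
    seed = as.integer(seed),
    paths = list(out_dir = out_dir),
    simulate = list(
      n_per_model = 3L,
      surface = list(n_rows = 512L, n_cols = 512L, step = 1,
                     base_wavelength_x = 12, base_wavelength_y = 15,
                     amplitude = 1, phase_jitter = 1, noise_sd = 0.05),
      models = list(
        MMT = list(stretch_x = 1.213, stretch_y = 1.205, sector_imbalance = 0.5),
        MIA = list(stretch_x = 1.353, stretch_y = 1.417, sector_imbalance = 0)),
      slide = list(width = 640L, height = 640L, pixel_size = 1,
                   cell_radius = 5, mask_fraction = 0.5,
                   background_intensity = 30),
      slide_groups = list(
        MMT_Healthy = list(n_cells = 120L,
                           color_fractions = c(red = 0.15, yellow = 0.30, green = 0.25)),
        MMT_OA = list(n_cells = 90L,
                      color_fractions = c(red = 0.25, yellow = 0.28, green = 0.17)),
        MIA_Healthy = list(n_cells = 120L,
                           color_fractions = c(red = 0.15, yellow = 0.30, green = 0.25)),
        MIA_OA = list(n_cells = 75L,
                      color_fractions = c(red = 0.30, yellow = 0.22, green = 0.13))),
      mankin = list(MMT_Healthy = 2L, MMT_OA = 4L, MIA_Healthy = 2L,
                    MIA_OA = 5L)),
    topology = list(smooth_sigma = 1.5, min_prominence = 0, detrend = FALSE,
                    percent = FALSE),
    histology = list(value_floor = 0.15, saturation_floor = 0.2),
    stats = list(
      alpha = 0.05,
      comparisons = list(
        list(variable = "eps_x", groups = c("MMT_OA", "MIA_OA")),
        list(variable = "eps_y", groups = c("MMT_OA", "MIA_OA")),
        list(variable = "I_x", groups = c("MMT_Healthy", "MMT_OA")),
        list(variable = "I_y", groups = c("MMT_Healthy", "MMT_OA")),
        list(variable = "I_x", groups = c("MIA_Healthy", "MIA_OA")),
        list(variable = "I_y", groups = c("MIA_Healthy", "MIA_OA")),
        list(variable = "I_x", groups = c("MMT_OA", "MIA_OA")),
        list(variable = "I_y", groups = c("MMT_OA", "MIA_OA")),
        list(variable = "red_fraction", groups = c("MMT_Healthy", "MMT_OA")),
        list(variable = "red_fraction", groups = c("MIA_Healthy", "MIA_OA")),
        list(variable = "cellularity", groups = c("MMT_Healthy", "MMT_OA")),
        list(variable = "cellularity", groups = c("MIA_Healthy", "MIA_OA")),
        list(variable = "mankin", groups = c("MMT_Healthy", "MMT_OA")),
        list(variable = "mankin", groups = c("MIA_Healthy", "MIA_OA")))))
}

#' Read / write a pipeline configuration
#'
#' @param config Configuration list.
#' @param path JSON file path.
#' @return The configuration list (reader) or `path` invisibly (writer).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

write_metrics_csv <- function(df, path) {
  df$value <- fmt_num(df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

append_skipped <- function(out_dir, stage, sample, reason) {
  path <- file.path(out_dir, "skipped.csv")
  row <- data.frame(stage = stage, sample = sample,
                    reason = gsub("[,\n]", ";", reason),
                    stringsAsFactors = FALSE)
  utils::write.table(row, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path),
                     quote = FALSE)
}

read_skipped <- function(out_dir) {
  path <- file.path(out_dir, "skipped.csv")
  if (!file.exists(path)) {
    return(data.frame(stage = character(), sample = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

update_manifest <- function(config, stage, files) {
  out_dir <- config$paths$out_dir
  path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    list(tool = "oatopo",
         version = as.character(utils::packageVersion("oatopo")),
         seed = config$seed, config = config, stages = list())
  }
  files <- files[file.exists(files)]
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- basename(names(hashes))
  manifest$stages[[stage]] <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = hashes)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

group_names <- function(config) {
  unlist(lapply(names(config$simulate$models),
                function(m) paste(m, c("Healthy", "OA"), sep = "_")))
}

#' Simulate the default study
#'
#' Writes paired healthy/OA height maps per animal, one synthetic slide
#' per analysis group and sample, per-sample Mankin operator scores, the
#' planted ground truth and a manifest. Existing outputs are never
#' silently overwritten.
#'
#' @param config Configuration list, see [default_config()].
#' @param force Overwrite an existing run directory.
#' @return Invisibly, the list of files written.
#' @export
run_simulate <- function(config, force = FALSE) {
  out_dir <- config$paths$out_dir
  surf_dir <- file.path(out_dir, "surfaces")
  slide_dir <- file.path(out_dir, "slides")
  if (dir.exists(surf_dir) && !force) {
    oat_stop(sprintf("simulation outputs already exist under %s (use force = TRUE)",
                     out_dir), "oatopo_validation")
  }
  for (d in c(out_dir, surf_dir, slide_dir)) {
    if (!dir.exists(d)) {
      dir.create(d, recursive = TRUE)
      message("created ", d)
    }
  }
  unlink(file.path(out_dir, "skipped.csv"))
  sim <- config$simulate
  files <- character()
  truth <- list(models = sim$models, slides = list())

  # surfaces: one healthy/OA pair per animal
  for (mi in seq_along(sim$models)) {
    model <- names(sim$models)[mi]
    eff <- sim$models[[model]]
    for (a in seq_len(sim$n_per_model)) {
      sargs <- sim$surface
      sargs$seed <- config$seed %% 1000000L + 1000L * mi + a
      hspec <- do.call(surface_spec, sargs)
      pr <- generate_pair(pair_spec(hspec, stretch_x = eff$stretch_x,
                                    stretch_y = eff$stretch_y,
                                    sector_imbalance = eff$sector_imbalance))
      fh <- file.path(surf_dir, sprintf("%s_%02d_healthy.csv", model, a))
      fo <- file.path(surf_dir, sprintf("%s_%02d_oa.csv", model, a))
      write_height_map(pr$healthy, fh)
      write_height_map(pr$oa, fo)
      files <- c(files, fh, fo, paste0(c(fh, fo), ".json"))
    }
  }

  # slides + mankin scores per analysis group and sample
  mankin_rows <- list()
  for (gi in seq_along(sim$slide_groups)) {
    grp <- names(sim$slide_groups)[gi]
    gpar <- sim$slide_groups[[grp]]
    for (a in seq_len(sim$n_per_model)) {
      sargs <- sim$slide
      sargs$n_cells <- gpar$n_cells
      sargs$color_fractions <- unlist(gpar$color_fractions)
      sargs$seed <- config$seed %% 1000000L + 20000L + 1000L * gi + a
      sl <- generate_slide(do.call(slide_spec, sargs))
      fi <- file.path(slide_dir, sprintf("%s_%02d.png", grp, a))
      fm <- file.path(slide_dir, sprintf("%s_%02d_mask.png", grp, a))
      ft <- file.path(slide_dir, sprintf("%s_%02d_truth.json", grp, a))
      write_slide(sl$image, fi)
      write_mask(sl$mask, fm)
      gt <- sl$ground_truth
      gt$cell_centers <- NULL
      jsonlite::write_json(gt, ft, auto_unbox = TRUE, digits = NA)
      truth$slides[[sprintf("%s_%02d", grp, a)]] <- gt
      files <- c(files, fi, fm, ft, paste0(c(fi, fm), ".json"))

      base <- sim$mankin[[grp]]
      triple <- pmin(14L, pmax(0L, base + c(-1L, 0L, 1L)))
      triple <- withr::with_seed(sargs$seed + 1L, sample(triple))
      mankin_rows[[length(mankin_rows) + 1L]] <- data.frame(
        group = grp, sample = a, op1 = triple[1], op2 = triple[2],
        op3 = triple[3], stringsAsFactors = FALSE)
    }
  }
  fman <- file.path(out_dir, "mankin_scores.csv")
  utils::write.csv(do.call(rbind, mankin_rows), fman, row.names = FALSE,
                   quote = FALSE)
  ftruth <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, ftruth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  fcfg <- file.path(out_dir, "config.json")
  write_config(config, fcfg)
  files <- c(files, fman, ftruth, fcfg)
  update_manifest(config, "simulate", files)
  invisible(files)
}

#' Topology stage: wavelengths, deformation ratios, cohesion indices
#'
#' Reads every healthy/OA surface pair, estimates the per-axis mean
#' inter-maxima wavelengths, the pair's deformation ratios and each
#' member's sector wavelengths and cohesion indices, and writes the
#' long-format metrics table. Per-sample failures (e.g. an undefined
#' wavelength) are logged to `skipped.csv` and do not abort the batch.
#'
#' @param config Configuration list.
#' @return Invisibly, the metrics data frame.
#' @export
run_topology <- function(config) {
  out_dir <- config$paths$out_dir
  surf_dir <- file.path(out_dir, "surfaces")
  if (!dir.exists(surf_dir)) {
    oat_stop("topology stage: no surfaces/ directory; run the simulate stage first",
             "oatopo_validation")
  }
  topt <- config$topology
  rows <- list()
  for (model in names(config$simulate$models)) {
    for (a in seq_len(config$simulate$n_per_model)) {
      id <- sprintf("%s_%02d", model, a)
      res <- tryCatch({
        h <- read_height_map(file.path(surf_dir, paste0(id, "_healthy.csv")))
        o <- read_height_map(file.path(surf_dir, paste0(id, "_oa.csv")))
        if (isTRUE(topt$detrend)) {
          h <- detrend_height_map(h)
          o <- detrend_height_map(o)
        }
        wph <- surface_wavelengths(h, topt$smooth_sigma, topt$min_prominence)
        wpo <- surface_wavelengths(o, topt$smooth_sigma, topt$min_prominence)
        eps <- deformation_ratio(wpo, wph)
        ih <- cohesion_index(sector_wavelengths(h, topt$smooth_sigma,
                                                topt$min_prominence))
        io <- cohesion_index(sector_wavelengths(o, topt$smooth_sigma,
                                                topt$min_prominence))
        rbind(
          data.frame(group = paste0(model, "_Healthy"), sample = a,
                     variable = c("lambda_x", "lambda_y", "I_x", "I_y"),
                     value = c(wph$lambda_x, wph$lambda_y, ih$I_x, ih$I_y),
                     stringsAsFactors = FALSE),
          data.frame(group = paste0(model, "_OA"), sample = a,
                     variable = c("lambda_x", "lambda_y", "eps_x", "eps_y",
                                  "I_x", "I_y"),
                     value = c(wpo$lambda_x, wpo$lambda_y, eps$eps_x,
                               eps$eps_y, io$I_x, io$I_y),
                     stringsAsFactors = FALSE))
      }, oatopo_error = function(e) {
        append_skipped(out_dir, "topology", id, conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L) {
    oat_stop("topology stage: every sample failed", "oatopo_validation")
  }
  metrics <- do.call(rbind, rows)
  path <- file.path(out_dir, "topology_metrics.csv")
  write_metrics_csv(metrics, path)
  update_manifest(config, "topology", path)
  invisible(metrics)
}

#' Histology stage: colour fractions, cellularity, Mankin, profile intensity
#'
#' Segments each slide, applies the mask, measures the birefringence
#' colour fractions and the cellularity, aggregates the operator Mankin
#' scores and samples a mid-slide profile line. Failures are logged and
#' skipped, as in the topology stage.
#'
#' @param config Configuration list.
#' @return Invisibly, the metrics data frame.
#' @export
run_histology <- function(config) {
  out_dir <- config$paths$out_dir
  slide_dir <- file.path(out_dir, "slides")
  if (!dir.exists(slide_dir)) {
    oat_stop("histology stage: no slides/ directory; run the simulate stage first",
             "oatopo_validation")
  }
  hopt <- config$histology
  mank <- utils::read.csv(file.path(out_dir, "mankin_scores.csv"),
                          stringsAsFactors = FALSE)
  rows <- list()
  for (grp in names(config$simulate$slide_groups)) {
    for (a in seq_len(config$simulate$n_per_model)) {
      id <- sprintf("%s_%02d", grp, a)
      res <- tryCatch({
        img <- read_slide(file.path(slide_dir, paste0(id, ".png")))
        mask <- segment_cartilage(img)
        masked <- apply_mask(img, mask)
        bf <- birefringence_fractions(masked, mask,
                                      value_floor = hopt$value_floor,
                                      saturation_floor = hopt$saturation_floor)
        cel <- count_cells(img, mask,
                           expected_cell_radius_um = config$simulate$slide$cell_radius)
        d <- dim(img$rgb)
        prof <- profile_line_intensity(img, c(1, d[2] %/% 2), c(d[1], d[2] %/% 2))
        ops <- mank[mank$group == grp & mank$sample == a, c("op1", "op2", "op3")]
        mk <- aggregate_mankin(as.numeric(ops[1, ]))
        data.frame(group = grp, sample = a,
                   variable = c("red_fraction", "yellow_fraction",
                                "green_fraction", "cell_count", "cellularity",
                                "mankin", "profile_intensity"),
                   value = c(bf$red_fraction, bf$yellow_fraction,
                             bf$green_fraction, cel$cell_count,
                             cel$cellularity, mk$mean, prof$mean_intensity),
                   stringsAsFactors = FALSE)
      }, oatopo_error = function(e) {
        append_skipped(out_dir, "histology", id, conditionMessage(e))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L) {
    oat_stop("histology stage: every slide failed", "oatopo_validation")
  }
  metrics <- do.call(rbind, rows)
  path <- file.path(out_dir, "histology_metrics.csv")
  write_metrics_csv(metrics, path)
  update_manifest(config, "histology", path)
  invisible(metrics)
}

#' Statistics stage: group summaries and nonparametric comparisons
#'
#' For every configured comparison, builds the measurement groups from the
#' metrics tables, runs the Kruskal-Wallis omnibus test and -- for sets of
#' three or more groups -- Dunn post-hoc tests with Bonferroni correction.
#' Two-group comparisons are flagged on the omnibus p; larger sets on the
#' adjusted pairwise p.
#'
#' @param config Configuration list.
#' @return Invisibly, list with `summary` and `comparisons` data frames.
#' @export
run_stats <- function(config) {
  out_dir <- config$paths$out_dir
  paths <- file.path(out_dir, c("topology_metrics.csv", "histology_metrics.csv"))
  have <- file.exists(paths)
  if (!any(have)) {
    oat_stop("stats stage: no metrics tables; run the topology/histology stages first",
             "oatopo_validation")
  }
  metrics <- do.call(rbind, lapply(paths[have], utils::read.csv,
                                   stringsAsFactors = FALSE))
  alpha <- config$stats$alpha
  sum_rows <- list()
  cmp_rows <- list()
  for (v in unique(metrics$variable)) {
    sub <- metrics[metrics$variable == v, ]
    gs <- lapply(split(sub$value, sub$group), function(x) x)
    groups <- lapply(names(gs), function(g) measurement_group(g, gs[[g]]))
    s <- summarize_groups(groups)
    s <- cbind(variable = v, s, stringsAsFactors = FALSE)
    sum_rows[[length(sum_rows) + 1L]] <- s
  }
  for (cmp in config$stats$comparisons) {
    v <- cmp$variable
    labels <- cmp$groups
    sub <- metrics[metrics$variable == v & metrics$group %in% labels, ]
    present <- intersect(labels, unique(sub$group))
    if (length(present) < 2L) {
      append_skipped(out_dir, "stats",
                     paste0(v, ":", paste(labels, collapse = "+")),
                     "fewer than two groups with data")
      next
    }
    groups <- lapply(present, function(g)
      measurement_group(g, sub$value[sub$group == g]))
    res <- tryCatch({
      kw <- kruskal_wallis(groups)
      dn <- dunn_bonferroni(groups, alpha = alpha)
      if (length(groups) == 2L) dn$significant <- kw$p < alpha
      cbind(variable = v, comparison = paste(present, collapse = "+"),
            dn, H = kw$H, p_omnibus = kw$p, stringsAsFactors = FALSE)
    }, oatopo_error = function(e) {
      append_skipped(out_dir, "stats",
                     paste0(v, ":", paste(labels, collapse = "+")),
                     conditionMessage(e))
      NULL
    })
    if (!is.null(res)) cmp_rows[[length(cmp_rows) + 1L]] <- res
  }
  summary_df <- do.call(rbind, sum_rows)
  comparisons_df <- if (length(cmp_rows)) do.call(rbind, cmp_rows) else
    data.frame()
  for (cc in c("mean", "sd")) summary_df[[cc]] <- fmt_num(summary_df[[cc]])
  if (nrow(comparisons_df)) {
    for (cc in c("z", "p_raw", "p_adj", "H", "p_omnibus")) {
      comparisons_df[[cc]] <- fmt_num(comparisons_df[[cc]])
    }
  }
  fs <- file.path(out_dir, "stats_summary.csv")
  fc <- file.path(out_dir, "stats_comparisons.csv")
  utils::write.csv(summary_df, fs, row.names = FALSE, quote = TRUE)
  utils::write.csv(comparisons_df, fc, row.names = FALSE, quote = TRUE)
  update_manifest(config, "stats", c(fs, fc))
  invisible(list(summary = summary_df, comparisons = comparisons_df))
}

#' Report stage: human-readable run summary
#'
#' Renders per-variable "mean (SD)" tables, the comparison flags and the
#' list of skipped samples into a plain-text report. Regenerating the
#' report without rerunning upstream stages reproduces it byte for byte.
#'
#' @param config Configuration list.
#' @return Invisibly, the report file path.
#' @export
run_report <- function(config) {
  out_dir <- config$paths$out_dir
  fs <- file.path(out_dir, "stats_summary.csv")
  fc <- file.path(out_dir, "stats_comparisons.csv")
  if (!file.exists(fs) || !file.exists(fc)) {
    oat_stop("report stage: missing stats outputs (stats_summary.csv / stats_comparisons.csv); run the stats stage first",
             "oatopo_validation")
  }
  summary_df <- utils::read.csv(fs, stringsAsFactors = FALSE)
  comparisons_df <- utils::read.csv(fc, stringsAsFactors = FALSE)
  skipped <- read_skipped(out_dir)
  lines <- c("oatopo run report",
             sprintf("seed: %d", config$seed),
             "")
  for (v in unique(summary_df$variable)) {
    s <- summary_df[summary_df$variable == v, ]
    lines <- c(lines, sprintf("== %s ==", v),
               sprintf("  %-14s n = %d   mean (SD) = %s", s$label, s$n,
                       s$rendered))
    cmp <- comparisons_df[comparisons_df$variable == v, , drop = FALSE]
    if (nrow(cmp)) {
      lines <- c(lines, "  comparisons:",
                 sprintf("    %s vs %s: H = %s, p = %s, adjusted p = %s%s",
                         cmp$group_a, cmp$group_b, cmp$H, cmp$p_omnibus,
                         cmp$p_adj,
                         ifelse(cmp$significant, "  [significant]", "")))
    }
    lines <- c(lines, "")
  }
  if (nrow(skipped)) {
    lines <- c(lines, "skipped samples:",
               sprintf("  [%s] %s: %s", skipped$stage, skipped$sample,
                       skipped$reason))
  } else {
    lines <- c(lines, "skipped samples: none")
  }
  path <- file.path(out_dir, "report.txt")
  writeLines(lines, path)
  update_manifest(config, "report", path)
  invisible(path)
}

#' Run the full pipeline
#'
#' simulate -> topology -> histology -> stats -> report, in order.
#'
#' @param config Configuration list; see [default_config()].
#' @param force Passed to [run_simulate()].
#' @return Invisibly, the report path.
#' @export
run_pipeline <- function(config, force = FALSE) {
  run_simulate(config, force = force)
  run_topology(config)
  run_histology(config)
  run_stats(config)
  run_report(config)
}
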