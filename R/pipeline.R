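# End-to-end pipeline: one YAML/JSON config drives synthesize ->
# compose/evaluate -> behavior -> heatmap -> weather -> featuremap, with a
# manifest recording the seed and configuration hash for reproducibility.

PIPELINE_STAGES <- c("synthesize", "compose", "evaluate", "behavior",
                     "heatmap", "weather", "featuremap")

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    stages = as.list(stats::setNames(rep(TRUE, length(PIPELINE_STAGES)),
                                     PIPELINE_STAGES)),
    sim = list(n_days = 8L, frame_interval = 300,
               frame_width = 2139L, frame_height = 1281L),
    compositor = list(n_images = 6L, frame_width = 320L, frame_height = 240L,
                      n_birds_range = c(1L, 3L), write_images = TRUE),
    evaluate = list(iou_threshold = 0.5, jitter_px = 2, drop_rate = 0.1),
    behavior = list(score_threshold = 0.5),
    heatmap = list(beta = 0.01, lambda = 0.1, cell_size = 200),
    weather = list(noise_sd = 0.25),
    featuremap = list(h = 16L, w = 16L, d = 32L, out_dim = 8L)
  )
}

#' Load and validate a pipeline run configuration
#'
#' Reads a YAML or JSON config file, rejects unknown keys, and merges it
#' over the package defaults.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`), or `NULL` for the
#'   defaults.
#' @return validated config list of class `run_config`.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
            else jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    assert_that(length(unknown) == 0,
                paste("unknown config keys:", paste(unknown, collapse = ", ")))
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && is.list(user[[k]])) {
        unknown2 <- setdiff(names(user[[k]]), names(cfg[[k]]))
        assert_that(length(unknown2) == 0,
                    paste0("unknown config keys under '", k, "': ",
                           paste(unknown2, collapse = ", ")))
        cfg[[k]][names(user[[k]])] <- user[[k]]
      } else {
        cfg[[k]] <- user[[k]]
      }
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order inside `out_dir`,
#' writing per-stage artifacts and a manifest with the seed and the MD5 of
#' the effective config. Rerunning with the same config reproduces all
#' deterministic outputs. A stage failure halts the run with a
#' stage-tagged error; artifacts of completed stages are retained.
#'
#' @param config a `run_config` from [load_run_config()], or `NULL` for
#'   defaults.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- if (is.null(config)) load_run_config() else config
  out_dir <- out_dir %||% cfg$out_dir
  assert_that(!is.null(out_dir), "an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  manifest <- list(package_version = as.character(utils::packageVersion("egretwatch")),
                   seed = seed, stages = list())
  cfg_path <- file.path(out_dir, "run_config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))

  stage <- function(name, code) {
    if (!isTRUE(cfg$stages[[name]])) return(invisible(NULL))
    tryCatch(code, error = function(e)
      stop_ew(sprintf("[stage %s] %s", name, conditionMessage(e))))
  }

  env <- new.env()
  stage("synthesize", {
    sc <- sim_config(
      frame_width = cfg$sim$frame_width, frame_height = cfg$sim$frame_height,
      day_span = seq(as.Date("2019-09-23"), by = "day",
                     length.out = cfg$sim$n_days),
      frame_interval = cfg$sim$frame_interval, rng_seed = seed)
    sim <- simulate_detections(sc)
    env$sim_config <- sc
    env$records <- sim$records
    env$ledger <- sim$ledger
    write_detections_csv(sim$records, file.path(out_dir, "detections.csv"))
    write_ledger(sim$ledger, file.path(out_dir, "ledger.json"))
    manifest$stages$synthesize <- list(n_records = nrow(sim$records))
  })

  stage("compose", {
    ds <- generate_dataset(
      file.path(out_dir, "dataset"), n_images = cfg$compositor$n_images,
      frame_width = cfg$compositor$frame_width,
      frame_height = cfg$compositor$frame_height,
      seed = seed, n_birds_range = cfg$compositor$n_birds_range,
      write_images = isTRUE(cfg$compositor$write_images))
    env$dataset <- ds
    manifest$stages$compose <- list(n_images = cfg$compositor$n_images)
  })

  stage("evaluate", {
    assert_that(!is.null(env$dataset), "evaluate requires the compose stage")
    gts <- do.call(rbind, lapply(seq_along(env$dataset$annotations),
      function(i) {
        df <- env$dataset$annotations[[i]]
        if (nrow(df)) cbind(image_id = i, df) else NULL
      }))
    dets <- with_seed(child_seed(seed, "mockdets"), {
      keep <- stats::runif(nrow(gts)) > cfg$evaluate$drop_rate
      d <- gts[keep, , drop = FALSE]
      j <- cfg$evaluate$jitter_px
      d$x_min <- d$x_min + stats::runif(nrow(d), -j, j)
      d$x_max <- d$x_max + stats::runif(nrow(d), -j, j)
      d$y_min <- d$y_min + stats::runif(nrow(d), -j, j)
      d$y_max <- d$y_max + stats::runif(nrow(d), -j, j)
      d$score <- stats::runif(nrow(d), 0.5, 1)
      d
    })
    names(dets)[names(dets) == "species"] <- "label"
    gts2 <- gts; names(gts2)[names(gts2) == "species"] <- "label"
    ev <- evaluate_detections(dets, gts2, cfg$evaluate$iou_threshold)
    utils::write.csv(
      do.call(rbind, lapply(names(ev$curves), function(cl)
        cbind(class = cl, ev$curves[[cl]]))),
      file.path(out_dir, "pr_curves.csv"), row.names = FALSE)
    jsonlite::write_json(list(per_class = as.list(ev$per_class), map = ev$map),
                         file.path(out_dir, "eval.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$stages$evaluate <- list(map = ev$map)
  })

  stage("behavior", {
    assert_that(!is.null(env$records), "behavior requires the synthesize stage")
    thr <- cfg$behavior$score_threshold
    counts <- lapply(c("all", "great_egret", "little_egret"), function(sp)
      daily_count(env$records, sp, thr))
    names(counts) <- c("all", "great_egret", "little_egret")
    cdf <- data.frame(date = counts$all$date, all = counts$all$count,
                      great_egret = counts$great_egret$count,
                      little_egret = counts$little_egret$count)
    utils::write.csv(cdf, file.path(out_dir, "daily_counts.csv"),
                     row.names = FALSE)
    r <- pearson(counts$great_egret, counts$little_egret)
    sg <- daily_schedule(env$records, "great_egret", score_threshold = thr)
    sl <- daily_schedule(env$records, "little_egret", score_threshold = thr)
    sched <- merge(sg, sl, by = "date", suffixes = c("_great", "_little"))
    utils::write.csv(sched, file.path(out_dir, "schedule.csv"),
                     row.names = FALSE)
    ht <- schedule_tests(sched$departure_min_great, sched$departure_min_little,
                         sched$return_min_great, sched$return_min_little)
    jsonlite::write_json(
      list(pearson_great_little = r,
           ht1_p = ht$ht1$p_value, ht2_p = ht$ht2$p_value),
      file.path(out_dir, "behavior.json"), auto_unbox = TRUE, digits = NA)
    env$counts <- counts
    manifest$stages$behavior <- list(pearson = r)
  })

  stage("heatmap", {
    assert_that(!is.null(env$records), "heatmap requires the synthesize stage")
    grid <- cell_grid(env$sim_config$frame_width, env$sim_config$frame_height,
                      cfg$heatmap$cell_size)
    hg <- period_heatmap(env$records, grid, "great_egret",
                         beta = cfg$heatmap$beta, lam = cfg$heatmap$lambda)
    hl <- period_heatmap(env$records, grid, "little_egret",
                         beta = cfg$heatmap$beta, lam = cfg$heatmap$lambda)
    fields <- rbind(
      data.frame(cell_row = rep(seq_len(grid$n_rows), grid$n_cols),
                 cell_col = rep(seq_len(grid$n_cols), each = grid$n_rows),
                 species = "great_egret", value = hg$field),
      data.frame(cell_row = rep(seq_len(grid$n_rows), grid$n_cols),
                 cell_col = rep(seq_len(grid$n_cols), each = grid$n_rows),
                 species = "little_egret", value = hl$field))
    utils::write.csv(fields, file.path(out_dir, "heatmap_fields.csv"),
                     row.names = FALSE)
    bg <- generate_background(env$sim_config$frame_width,
                              env$sim_config$frame_height,
                              child_seed(seed, "hm_bg"))
    write_image(render_heatmap(hg$field, hl$field, grid, bg),
                file.path(out_dir, "heatmap.png"))
    manifest$stages$heatmap <- list(beta = cfg$heatmap$beta,
                                     lambda = cfg$heatmap$lambda)
  })

  stage("weather", {
    assert_that(!is.null(env$sim_config), "weather requires the synthesize stage")
    # the regression needs n >= 15 days; use a 62-day span regardless of
    # the (possibly shorter) detection simulation span
    wc <- sim_config(day_span = seq(as.Date("2019-09-23"), by = "day",
                                    length.out = 62L), rng_seed = seed)
    sw <- simulate_weather(wc, noise_sd = cfg$weather$noise_sd)
    write_weather_csv(sw$weather, file.path(out_dir, "weather.csv"))
    wr <- weather_regression(sw$weather)
    write_regression_report(wr, file.path(out_dir, "weather_report.md"))
    manifest$stages$weather <- list(r_squared = wr$report$r_squared,
                                     f_p_value = wr$report$f_p_value)
  })

  stage("featuremap", {
    fs <- simulate_feature_stack(child_seed(seed, "fmstack"),
                                 h = cfg$featuremap$h, w = cfg$featuremap$w,
                                 d = cfg$featuremap$d,
                                 out_dim = cfg$featuremap$out_dim)
    stack <- feature_stack(fs$features, fs$A)
    img <- generate_background(16 * cfg$featuremap$w, 16 * cfg$featuremap$h,
                               child_seed(seed, "fm_bg"))
    viz <- featuremap_visualize(stack, img)
    write_image(viz$overlay$image, file.path(out_dir, "featuremap.png"))
    manifest$stages$featuremap <- list(explained = viz$pca$explained)
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
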