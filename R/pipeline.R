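#' Full pipeline configuration
#'
#' One declarative description of an end-to-end run: phantom simulation,
#' conventional TIE reconstruction, dataset assembly, GAN training,
#' inference and metric evaluation.  The configuration round-trips
#' losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]), and a single global seed fans out to
#' per-stage seeds by fixed offsets so stages can be rerun independently
#' yet reproducibly.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param phantom `"bead"` or `"cell"`.
#' @param n_fields Number of phantom objects to simulate.
#' @param shape Grid side in pixels (one number; fields are square).
#' @param z_min,z_max,z_step Defocus scan in micrometres.
#' @param fine_dz_um Half-spacing of the fine bracketing pair recorded
#'   around focus and used (only) for the conventional-TIE ground-truth
#'   solve; the coarse scan planes alone under-resolve the axial
#'   derivative of strong phase objects.  `NULL` disables the extra
#'   planes.
#' @param optical An [optical_config()].
#' @param tie A [tie_config()].
#' @param gan A [gan_config()].
#' @param metrics A [metrics_config()].
#' @param split `c(train, validation, test)` pair counts, or `NULL` for
#'   a 70/15/15 object split.
#' @param seed Global seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "tieqpi_run", phantom = c("bead", "cell"),
                            n_fields = 20, shape = 128,
                            z_min = -60, z_max = 60, z_step = 15, fine_dz_um = 1,
                            optical = optical_config(),
                            tie = tie_config(),
                            gan = gan_config(tile = shape),
                            metrics = metrics_config(),
                            split = NULL, seed = 1L) {
  phantom <- match.arg(phantom)
  stopifnot(n_fields >= 1, z_step > 0, z_max > z_min)
  structure(list(out_dir = out_dir, phantom = phantom,
                 n_fields = as.integer(n_fields), shape = as.integer(shape),
                 z_min = z_min, z_max = z_max, z_step = z_step,
                 fine_dz_um = fine_dz_um,
                 optical = optical, tie = tie, gan = gan, metrics = metrics,
                 split = split, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' The built-in smoke profile
#'
#' A small configuration (64 x 64 tiles, 12 bead fields, 3 epochs) that
#' exercises every pipeline stage in minutes; useful for continuous
#' integration and for checking an installation.
#'
#' @param out_dir Output directory.
#' @param seed Global seed.
#' @return A [pipeline_config()].
#' @export
smoke_profile <- function(out_dir = tempfile("tieqpi_smoke"), seed = 1L) {
  pipeline_config(
    out_dir = out_dir, phantom = "bead", n_fields = 12, shape = 64,
    z_min = -30, z_max = 30, z_step = 15,
    gan = gan_config(tile = 64, base_channels = 16, epochs = 3,
                     batch_size = 4, seed = seed),
    split = NULL, seed = seed)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(unclass(x), strip)
    }
    x
  }
  yaml::write_yaml(strip(unclass(config)), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    out_dir = raw$out_dir, phantom = raw$phantom,
    n_fields = raw$n_fields, shape = raw$shape,
    z_min = raw$z_min, z_max = raw$z_max, z_step = raw$z_step,
    fine_dz_um = raw$fine_dz_um,
    optical = do.call(optical_config,
                      raw$optical[setdiff(names(raw$optical), "pitch_um")]),
    tie = do.call(tie_config, raw$tie),
    gan = do.call(gan_config, raw$gan),
    metrics = do.call(metrics_config, raw$metrics),
    split = if (is.null(raw$split)) NULL else unlist(raw$split),
    seed = raw$seed)
  cfg
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 101L, reconstruct = 211L, dataset = 307L,
               train = 401L, infer = 503L, evaluate = 601L)
  config$seed + offsets[[stage]]
}

pipeline_log <- function(config, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  cat(line, "\n", file = file.path(config$out_dir, "pipeline.log"),
      append = TRUE)
}

#' Run the pipeline end to end
#'
#' Executes the requested stages in order
#' (`simulate -> reconstruct -> dataset -> train -> infer -> evaluate`),
#' each reading only the configuration and the previous stage's on-disk
#' artifacts, and each skipped when its outputs already exist (unless
#' `force`).  `stages = character(0)` only validates the configuration.
#'
#' Artifacts under `config$out_dir`: `stacks/` (TIFF + YAML per object),
#' `phases/` (conventional TIE ground truth), `pairs.rds` (the dataset
#' tibble), `model.rds` (checkpoint), `inferred/` (single-shot phase
#' maps for the test split) and `report.csv` / `summary.csv` (the metric
#' sweep).
#'
#' @param config A [pipeline_config()].
#' @param stages Character subset of the six stage names (in any order;
#'   they run in pipeline order).
#' @param force Re-run stages whose outputs already exist.
#' @return Invisibly, a list of the paths written per stage.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "reconstruct", "dataset",
                                    "train", "infer", "evaluate"),
                         force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "reconstruct", "dataset", "train", "infer",
                  "evaluate")
  stages <- all_stages[all_stages %in% stages]
  if (length(stages) == 0) return(invisible(list()))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  z_scan <- seq(config$z_min, config$z_max, by = config$z_step)
  z <- z_scan
  if (!is.null(config$fine_dz_um)) {
    z <- sort(unique(c(z, c(-1, 0, 1) * config$fine_dz_um)))
  }
  out <- list()

  stack_dir <- file.path(config$out_dir, "stacks")
  phase_dir <- file.path(config$out_dir, "phases")
  pairs_path <- file.path(config$out_dir, "pairs.rds")
  model_path <- file.path(config$out_dir, "model.rds")
  infer_dir <- file.path(config$out_dir, "inferred")
  report_path <- file.path(config$out_dir, "report.csv")

  stack_paths <- function() {
    file.path(stack_dir, sprintf("%s%03d.tiff", config$phantom,
                                 seq_len(config$n_fields)))
  }

  if ("simulate" %in% stages) {
    paths <- stack_paths()
    if (force || !all(file.exists(paths))) {
      t0 <- Sys.time()
      dir.create(stack_dir, showWarnings = FALSE)
      shape <- c(config$shape, config$shape)
      fields <- simulate_fields(config, shape)
      for (i in seq_along(fields)) {
        st <- generate_stack(fields[[i]], z, config$optical,
                             source_id = sprintf("%s%03d", config$phantom, i))
        write_stack(st, paths[i])
      }
      pipeline_log(config, "simulate",
                   sprintf("%d %s stacks (seed %d) in %.1fs",
                           config$n_fields, config$phantom,
                           stage_seed(config, "simulate"),
                           as.numeric(Sys.time() - t0, units = "secs")))
    } else {
      pipeline_log(config, "simulate", "outputs exist, skipping")
    }
    out$simulate <- paths
  }

  if ("reconstruct" %in% stages) {
    spaths <- stack_paths()
    if (!all(file.exists(spaths))) {
      stop("missing stacks; run the 'simulate' stage first (run_pipeline(config, 'simulate'))",
           call. = FALSE)
    }
    ppaths <- file.path(phase_dir, basename(spaths))
    if (force || !all(file.exists(ppaths))) {
      t0 <- Sys.time()
      dir.create(phase_dir, showWarnings = FALSE)
      for (i in seq_along(spaths)) {
        st <- read_stack(spaths[i], config$optical)
        ph <- tie_solve(st, config$tie, config$optical)
        write_phase(ph, ppaths[i])
      }
      pipeline_log(config, "reconstruct",
                   sprintf("%d TIE phase maps in %.1fs", length(spaths),
                           as.numeric(Sys.time() - t0, units = "secs")))
    } else {
      pipeline_log(config, "reconstruct", "outputs exist, skipping")
    }
    out$reconstruct <- ppaths
  }

  if ("dataset" %in% stages) {
    spaths <- stack_paths()
    ppaths <- file.path(phase_dir, basename(spaths))
    if (!all(file.exists(spaths)) || !all(file.exists(ppaths))) {
      stop("missing stacks or phases; run 'simulate' and 'reconstruct' first",
           call. = FALSE)
    }
    if (force || !file.exists(pairs_path)) {
      t0 <- Sys.time()
      stacks <- lapply(spaths, read_stack, config = config$optical)
      phases <- lapply(ppaths, read_phase)
      split <- config$split
      if (is.null(split)) {
        ids <- length(stacks)
        n_pairs <- ids * length(z_scan)
        per <- length(z_scan)
        n_tr <- floor(0.7 * ids) * per
        n_va <- floor(0.15 * ids) * per
        split <- c(n_tr, n_va, n_pairs - n_tr - n_va)
      }
      pairs <- build_pairs(stacks, phases, z_selection = z_scan,
                            split_sizes = split,
                           seed = stage_seed(config, "dataset"))
      saveRDS(pairs, pairs_path)
      pipeline_log(config, "dataset",
                   sprintf("%d pairs (%s) in %.1fs", nrow(pairs),
                           paste(table(pairs$split)[c("train", "validation",
                                                      "test")],
                                 collapse = "/"),
                           as.numeric(Sys.time() - t0, units = "secs")))
    } else {
      pipeline_log(config, "dataset", "outputs exist, skipping")
    }
    out$dataset <- pairs_path
  }

  if ("train" %in% stages) {
    if (!file.exists(pairs_path)) {
      stop("missing dataset; run the 'dataset' stage first", call. = FALSE)
    }
    if (force || !file.exists(model_path)) {
      t0 <- Sys.time()
      pairs <- readRDS(pairs_path)
      gcfg <- config$gan
      gcfg$seed <- stage_seed(config, "train")
      model <- gan_train(pairs, gcfg,
                         pitch_um = config$optical$pitch_um)
      save_gan(model, model_path)
      pipeline_log(config, "train",
                   sprintf("%d epochs, best val SSIM %s in %.1fs",
                           nrow(model$history),
                           ifelse(is.finite(model$best$val_ssim),
                                  sprintf("%.4f", model$best$val_ssim), "NA"),
                           as.numeric(Sys.time() - t0, units = "secs")))
    } else {
      pipeline_log(config, "train", "outputs exist, skipping")
    }
    out$train <- model_path
  }

  if ("infer" %in% stages) {
    if (!file.exists(model_path) || !file.exists(pairs_path)) {
      stop("missing model or dataset; run 'train' first", call. = FALSE)
    }
    done <- file.exists(infer_dir) && length(list.files(infer_dir)) > 0
    if (force || !done) {
      t0 <- Sys.time()
      dir.create(infer_dir, showWarnings = FALSE)
      model <- load_gan(model_path)
      pairs <- readRDS(pairs_path)
      test <- pairs[pairs$split == "test", ]
      for (i in seq_len(nrow(test))) {
        frame <- denormalize_tile(test$intensity[[i]], test$i_norm[[i]])
        ph <- gan_infer(model, frame)
        write_phase(ph, file.path(infer_dir,
                                  sprintf("%s_z%+03.0f.tiff",
                                          test$source_id[i], test$z_um[i])))
      }
      pipeline_log(config, "infer",
                   sprintf("%d single-shot phase maps in %.1fs", nrow(test),
                           as.numeric(Sys.time() - t0, units = "secs")))
    } else {
      pipeline_log(config, "infer", "outputs exist, skipping")
    }
    out$infer <- infer_dir
  }

  if ("evaluate" %in% stages) {
    spaths <- stack_paths()
    ppaths <- file.path(phase_dir, basename(spaths))
    if (!file.exists(model_path) || !file.exists(pairs_path) ||
        !all(file.exists(ppaths))) {
      stop("missing model, dataset or phases; run earlier stages first",
           call. = FALSE)
    }
    if (force || !file.exists(report_path)) {
      t0 <- Sys.time()
      model <- load_gan(model_path)
      pairs <- readRDS(pairs_path)
      test_ids <- unique(pairs$source_id[pairs$split == "test"])
      keep <- vapply(spaths, function(p) {
        yaml::read_yaml(sidecar_path(p))$source_id %in% test_ids
      }, logical(1))
      stacks <- lapply(spaths[keep], read_stack, config = config$optical)
      truths <- lapply(ppaths[keep], read_phase)
      report <- evaluate_sweep(model, stacks, truths, config$metrics,
                               config$tie, z_planes = z_scan)
      write.csv(report, report_path, row.names = FALSE)
      agg <- summarize_metrics(report)
      write.csv(agg$summary, file.path(config$out_dir, "summary.csv"),
                row.names = FALSE)
      pipeline_log(config, "evaluate",
                   sprintf("%d records over %d test stacks in %.1fs",
                           nrow(report), sum(keep),
                           as.numeric(Sys.time() - t0, units = "secs")))
    } else {
      pipeline_log(config, "evaluate", "outputs exist, skipping")
    }
    out$evaluate <- report_path
  }
  invisible(out)
}

# Phantom fields for the simulate stage, seeded from the global seed.
simulate_fields <- function(config, shape) {
  seed <- stage_seed(config, "simulate")
  half_um <- shape[1] * config$optical$pitch_um / 2
  if (config$phantom == "bead") {
    with_seed(seed, lapply(seq_len(config$n_fields), function(i) {
      off <- runif(2, -0.25, 0.25) * half_um
      make_bead_field(bead_spec(centers = list(off)), shape, config$optical)
    }))
  } else {
    lapply(seq_len(config$n_fields), function(i) {
      radius_um <- min(7, 0.72 * half_um)
      make_cell_field(
        cell_spec(seed = seed + i,
                  cell_radius_um = radius_um,
                  smoothness_um = max(0.6, radius_um / 2.5)),
        shape, config$optical)
    })
  }
}
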