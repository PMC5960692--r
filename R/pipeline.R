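#' End-to-end run configuration
#'
#' Bundles the per-stage configurations of a full analysis run
#' (simulate -> preprocess -> categorize -> correlate -> decode) plus the
#' output directory and master seed.  Stage sub-configs are validated by
#' their own constructors.
#'
#' @param out_dir run directory (created by [run_pipeline()]).
#' @param stages character vector of stages to execute, in pipeline
#'   order; subsets are allowed but each stage needs its predecessors'
#'   artifacts in memory, so subsets must be a prefix of the full order.
#' @param synth a [synth_config()] (or preset name string).
#' @param dff a [dff_params()].
#' @param categorize a [categorize_config()].
#' @param decode a [decode_config()].
#' @param filter_threshold delta-F/F activity filter applied after
#'   preprocessing (see [filter_active_units()]); `NA` disables it.
#' @param bleach_correct subtract fitted bleaching decays.
#' @param decode_train_step stride (frames) between decoding train times.
#' @param seed master seed; overrides the seeds of the sub-configs.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir,
                       stages = c("simulate", "preprocess", "categorize",
                                  "correlate", "decode"),
                       synth = synth_config(),
                       dff = dff_params(),
                       categorize = categorize_config(),
                       decode = decode_config(),
                       filter_threshold = 0.75,
                       bleach_correct = TRUE,
                       decode_train_step = 5L,
                       seed = 1L) {
  if (is.character(synth)) synth <- synth_preset(synth)
  order_all <- c("simulate", "preprocess", "categorize", "correlate", "decode")
  stages <- match.arg(stages, order_all, several.ok = TRUE)
  if (!identical(stages, order_all[seq_along(stages)]))
    stop("stages must be a prefix of: ", paste(order_all, collapse = " -> "))
  synth$seed <- as.integer(seed)
  decode$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, stages = stages, synth = synth,
                 dff = dff, categorize = categorize, decode = decode,
                 filter_threshold = filter_threshold,
                 bleach_correct = bleach_correct,
                 decode_train_step = as.integer(decode_train_step),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `read_run_config()` returns a validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  raw <- lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x)
  raw$synth$category_mix <- as.list(raw$synth$category_mix)
  yaml::write_yaml(raw, path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$synth$category_mix <- unlist(raw$synth$category_mix)
  run_config(out_dir = raw$out_dir, stages = unlist(raw$stages),
             synth = do.call(synth_config, raw$synth),
             dff = do.call(dff_params, raw$dff),
             categorize = do.call(categorize_config, raw$categorize),
             decode = do.call(decode_config, raw$decode),
             filter_threshold = raw$filter_threshold,
             bleach_correct = raw$bleach_correct,
             decode_train_step = raw$decode_train_step,
             seed = raw$seed)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writing every artifact into the
#' run directory together with a manifest (`manifest.json`) listing each
#' file with its MD5 content hash, the stage that produced it, the master
#' seed and the package version.  Reruns with an identical configuration
#' are byte-identical.  On a stage failure the pipeline halts, partial
#' artifacts are retained and the manifest records the failure point.
#'
#' @param config a [run_config()].
#' @return the run directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("odortrace")),
                   stages = list(), files = list(), status = "running")
  files <- character()
  register <- function(stage, paths) {
    for (p in paths) files[basename(p)] <<- stage
  }
  write_manifest <- function() {
    manifest$files <- lapply(names(files), function(f) {
      list(file = f, stage = unname(files[f]),
           md5 = unname(tools::md5sum(file.path(config$out_dir, f))))
    })
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_run_config(config, cfg_path)
  register("config", cfg_path)

  env <- new.env()
  stage_fns <- list(
    simulate = function() {
      sim <- generate_traceset(config$synth)
      env$ts_raw <- sim$traceset
      env$gt <- sim$ground_truth
      p1 <- file.path(config$out_dir, "traceset_raw.csv")
      p2 <- file.path(config$out_dir, "ground_truth.csv")
      write_traceset(env$ts_raw, p1)
      write_ground_truth(env$gt, p2)
      register("simulate", c(p1, paste0(p1, ".meta.json"), p2))
    },
    preprocess = function() {
      ts <- preprocess_traces(env$ts_raw, config$dff,
                              bleach_correct = config$bleach_correct)
      if (!is.na(config$filter_threshold))
        ts <- suppressMessages(
          filter_active_units(ts, config$filter_threshold))
      env$ts <- ts
      p1 <- file.path(config$out_dir, "traceset_dff.csv")
      write_traceset(ts, p1)
      paths <- c(p1, paste0(p1, ".meta.json"))
      fits <- attr(ts, "bleach_fits")
      if (!is.null(fits)) {
        p2 <- file.path(config$out_dir, "bleach_fits.csv")
        write_bleach_fits(fits, p2)
        paths <- c(paths, p2)
      }
      flog <- attr(ts, "filter_log")
      if (!is.null(flog)) {
        p3 <- file.path(config$out_dir, "filter_log.csv")
        data.table::fwrite(flog, p3)
        paths <- c(paths, p3)
      }
      register("preprocess", paths)
    },
    categorize = function() {
      res <- suppressMessages(categorize_traceset(env$ts, config$categorize))
      env$categories <- res
      fr <- category_fractions(res, group_by = "animal")
      p1 <- file.path(config$out_dir, "categories.csv")
      p2 <- file.path(config$out_dir, "category_fractions.csv")
      p3 <- file.path(config$out_dir, "category_summary.csv")
      data.table::fwrite(res$per_trial, p1)
      data.table::fwrite(fr$fractions, p2)
      data.table::fwrite(fr$summary, p3)
      register("categorize", c(p1, p2, p3))
    },
    correlate = function() {
      ts <- env$ts
      pw <- pairwise_window_corr(ts)
      paths <- character()
      for (nm in c("odor_vs_odor", "post_vs_post", "odor_vs_post")) {
        p <- file.path(config$out_dir, paste0("pairwise_", nm, ".csv"))
        out <- as.data.frame(pw[[nm]])
        data.table::fwrite(cbind(trial = rownames(pw[[nm]]), out), p)
        paths <- c(paths, p)
      }
      # full time-resolved matrix + bootstrap trace for the first
      # non-solvent odorant's trial pair
      odor1 <- setdiff(unique(ts$trials$odor), config$synth$solvent)[1L]
      tr <- which(ts$trials$odor == odor1)
      if (length(tr) >= 2L) {
        m <- corr_matrix(ts, tr[1L], tr[2L])
        pm <- file.path(config$out_dir, "corr_matrix_trial12.csv")
        write_corr_matrix(m, pm)
        bt <- bootstrap_corr(ts, tr[1L], tr[2L],
                             ref_window = time_window(ts, 1, 2),
                             n_boot = 200, seed = config$seed)
        pb <- file.path(config$out_dir, "corr_trace_bootstrap.csv")
        data.table::fwrite(data.frame(frame = seq_along(bt$value) - 1L,
                                      r = bt$value, boot_mean = bt$boot_mean,
                                      boot_sd = bt$boot_sd), pb)
        paths <- c(paths, pm, paste0(pm, ".p.csv"), paste0(pm, ".meta.json"),
                   pb)
      }
      register("correlate", paths)
    },
    decode = function() {
      cfg <- config$decode
      cfg$train_step <- config$decode_train_step
      res <- decode_analysis(env$ts, cfg)
      dir <- file.path(config$out_dir, "decode")
      write_decode_result(res, dir)
      register("decode", file.path("decode",
                                   c("success.csv", "stim_avg.csv",
                                     "provenance.json")))
    })

  for (stage in config$stages) {
    ok <- tryCatch({ stage_fns[[stage]](); TRUE },
                   error = function(e) {
                     manifest$status <<- paste0("failed at stage '", stage,
                                                "': ", conditionMessage(e))
                     FALSE
                   })
    manifest$stages[[stage]] <- if (ok) "ok" else "failed"
    if (!ok) {
      write_manifest()
      stop("pipeline halted at stage '", stage, "' (see manifest.json)")
    }
  }
  manifest$status <- "complete"
  write_manifest()
  invisible(config$out_dir)
}

#' Summarize a completed run directory
#'
#' Reads the artifacts of a [run_pipeline()] run and assembles a summary:
#' category-fraction medians, pairwise correlation diagonals, and the
#' decoding curve with its chance band.  Sections whose artifacts are
#' missing are omitted with a notice.
#'
#' @param run_dir the run directory.
#' @return object of class `pipeline_report` (a list of sections), with a
#'   print method.
#' @export
pipeline_report <- function(run_dir) {
  have <- function(f) file.exists(file.path(run_dir, f))
  rd <- function(f) as.data.frame(data.table::fread(file.path(run_dir, f)))
  report <- list(run_dir = run_dir)
  if (have("manifest.json"))
    report$manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"),
                                           simplifyVector = TRUE)
  if (have("category_summary.csv")) {
    report$category_summary <- rd("category_summary.csv")
  } else message("report: categorize artifacts missing; section omitted")
  if (have("pairwise_odor_vs_post.csv")) {
    t1 <- rd("pairwise_odor_vs_post.csv")
    rn <- t1$trial
    m <- as.matrix(t1[, -1, drop = FALSE])
    rownames(m) <- rn
    report$odor_vs_post_diag <- stats::setNames(diag(m), rn)
  } else message("report: correlation artifacts missing; section omitted")
  if (have(file.path("decode", "stim_avg.csv"))) {
    report$decode <- rd(file.path("decode", "stim_avg.csv"))
  } else message("report: decoding artifacts missing; section omitted")
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== pipeline report:", x$run_dir, "==\n")
  if (!is.null(x$manifest))
    cat("status:", x$manifest$status, "| seed:", x$manifest$seed, "\n")
  if (!is.null(x$category_summary)) {
    cat("\nresponse-category fractions (median across animals):\n")
    print(x$category_summary, row.names = FALSE)
  }
  if (!is.null(x$odor_vs_post_diag)) {
    cat("\nodor vs post-odor pattern correlation (diagonal):\n")
    print(round(x$odor_vs_post_diag, 3))
  }
  if (!is.null(x$decode)) {
    cat("\ndecoding (stimulus-window success by train frame):\n")
    above <- if ("chance_upper" %in% names(x$decode))
      sum(x$decode$stim_avg > x$decode$chance_upper) else NA
    cat(sprintf("  max %.3f; train times above chance bound: %s / %d\n",
                max(x$decode$stim_avg), above, nrow(x$decode)))
  }
  invisible(x)
}
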