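#' Pipeline configuration
#'
#' One nested configuration driving an end-to-end run: synthesize (or
#' ingest WFDB records) -> denoise -> slice -> balance -> encode -> train
#' -> evaluate. Every stage seed is derived deterministically from the
#' master seed, so a run is reproducible from this object alone.
#'
#' @param source `"synth"` or `"wfdb"`.
#' @param header_paths WFDB `.hea` paths (when `source = "wfdb"`).
#' @param lead Lead index fed to the classifier. Default 1 (first lead).
#' @param synth A [synth_config()] (when `source = "synth"`).
#' @param noise A [noise_spec()] or `NULL` for no added noise.
#' @param denoise_cfg An [iceemdan_config()], or `NULL` to skip denoising.
#' @param threshold A [threshold_params()].
#' @param slicing A [slice_config()].
#' @param smote A [smote_config()], or `NULL` to skip balancing.
#' @param imaging An [imaging_config()].
#' @param image_scale Amplitude multiplier before image encoding (ADC
#'   gain, so the recurrence threshold keeps its raw-unit meaning).
#' @param net A [fusion_config()].
#' @param training A [train_config()].
#' @param test_fraction,val_fraction Partition fractions.
#' @param seed Master seed; overrides the seeds of all nested configs.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(source = c("synth", "wfdb"),
                            header_paths = character(), lead = 1L,
                            synth = synth_config(duration_s = 120,
                                                 class_mix = c(N = 0.55, S = 0.12,
                                                               V = 0.15, F = 0.1,
                                                               Q = 0.08)),
                            noise = NULL,
                            denoise_cfg = iceemdan_config(),
                            threshold = threshold_params(),
                            slicing = slice_config(),
                            smote = smote_config(),
                            imaging = imaging_config(),
                            image_scale = 200,
                            net = fusion_config(),
                            training = train_config(),
                            test_fraction = 0.2, val_fraction = 0.3,
                            seed = 1L) {
  source <- match.arg(source)
  if (source == "wfdb" && !length(header_paths))
    stop("source = \"wfdb\" needs header_paths")
  seed <- as.integer(seed)
  synth$seed <- derive_seed(seed, "synth")
  if (!is.null(noise)) noise$seed <- derive_seed(seed, "noise")
  if (!is.null(denoise_cfg)) denoise_cfg$seed <- derive_seed(seed, "denoise")
  if (!is.null(smote)) smote$seed <- derive_seed(seed, "smote")
  training$seed <- derive_seed(seed, "training")
  structure(list(source = source, header_paths = header_paths, lead = lead,
                 synth = synth, noise = noise, denoise_cfg = denoise_cfg,
                 threshold = threshold, slicing = slicing, smote = smote,
                 imaging = imaging, image_scale = image_scale, net = net,
                 training = training, test_fraction = test_fraction,
                 val_fraction = val_fraction, seed = seed),
            class = "pipeline_config")
}

# content-addressed stage cache: key = md5 of (stage name, config digest,
# input digest); value stored as RDS under the run directory.
stage_cached <- function(run_dir, stage, key_obj, compute) {
  dir.create(file.path(run_dir, "cache"), showWarnings = FALSE, recursive = TRUE)
  key <- digest_obj(list(stage = stage, key = key_obj))
  path <- file.path(run_dir, "cache", paste0(stage, "-", key, ".rds"))
  if (file.exists(path)) {
    return(structure(readRDS(path), from_cache = TRUE))
  }
  val <- tryCatch(compute(), error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  saveRDS(val, path)
  val
}

digest_obj <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(obj, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes every stage in order, caching each intermediate artifact in
#' `run_dir/cache` keyed by the configuration and input digests — a rerun
#' with an identical configuration reuses the cache. A failing stage
#' aborts with the stage named. Writes the evaluation report (JSON +
#' confusion CSV) and the training history into `run_dir`.
#'
#' @param cfg A [pipeline_config()].
#' @param run_dir Output directory.
#' @param verbose Print stage progress.
#' @return List with `fit` (the trained model), `report` (an
#'   `eval_report`), `partitions`, and `run_dir`.
#' @export
run_pipeline <- function(cfg, run_dir = tempfile("ecgfusion-run-"),
                         verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  say("stage: ingest")
  records <- stage_cached(run_dir, "ingest", cfg[c("source", "header_paths", "synth", "noise")], function() {
    if (cfg$source == "synth") {
      rec <- generate_clean_record(cfg$synth)
      if (!is.null(cfg$noise)) rec <- add_noise(rec, cfg$noise)
      list(rec)
    } else {
      lapply(cfg$header_paths, read_record)
    }
  })

  say("stage: denoise")
  denoised <- stage_cached(run_dir, "denoise",
                           list(cfg$denoise_cfg, cfg$threshold, cfg$lead,
                                digest_obj(records)), function() {
    lapply(records, function(rec) {
      if (is.null(cfg$denoise_cfg)) return(rec)
      x <- denoise_record(rec$signal[, cfg$lead], cfg$denoise_cfg,
                          cfg$threshold, fs = rec$fs)
      rec$signal[, cfg$lead] <- as.numeric(x)
      rec
    })
  })

  say("stage: segment")
  segset <- stage_cached(run_dir, "segment",
                         list(cfg$slicing, cfg$lead, digest_obj(denoised)),
                         function() {
    sets <- lapply(denoised, make_segments, cfg = cfg$slicing, lead = cfg$lead)
    segment_set(do.call(rbind, lapply(sets, function(s) s$segments)),
                unlist(lapply(sets, function(s) as.character(s$labels))))
  })

  say("stage: partition + balance")
  parts <- stage_cached(run_dir, "partition",
                        list(cfg$smote, cfg$test_fraction, cfg$val_fraction,
                             cfg$seed, digest_obj(segset)), function() {
    partition_segments(segset, cfg$test_fraction, cfg$val_fraction,
                       seed = derive_seed(cfg$seed, "partition"),
                       smote_cfg = cfg$smote)
  })

  say("stage: encode")
  enc <- stage_cached(run_dir, "encode",
                      list(cfg$imaging, cfg$image_scale, digest_obj(parts)),
                      function() {
    lapply(parts, encode_segments, cfg = cfg$imaging, scale = cfg$image_scale)
  })

  say("stage: train")
  fit <- stage_cached(run_dir, "train",
                      list(cfg$training, cfg$net, digest_obj(parts)),
                      function() {
    model <- fusion_model(cfg$net, seed = cfg$training$seed)
    fit_fusion(parts$train$segments, enc$train, parts$train$labels,
               model = model, cfg = cfg$training,
               val = list(segments = parts$val$segments, images = enc$val,
                          labels = parts$val$labels),
               verbose = verbose)
  })

  say("stage: evaluate")
  report <- evaluate_model(fit, parts$test$segments, enc$test,
                           parts$test$labels)
  write_eval_report(report, file.path(run_dir, "report.json"),
                    file.path(run_dir, "confusion.csv"))
  utils::write.csv(fit$history, file.path(run_dir, "history.csv"),
                   row.names = FALSE)
  list(fit = fit, report = report, partitions = parts, run_dir = run_dir)
}
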