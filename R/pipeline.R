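pipeline_config_schema <- function() {
  list(
    seed = "integer", rate = "number", out_dir = "path",
    protocol = names(formals(protocol_spec)),
    noise = setdiff(names(formals(noise_spec)), "seed"),
    filters = c("notch_freq", "notch_quality", "low", "high", "order",
                "envelope_cutoff", "zero_phase", "ica_input"),
    ica = c("n_components", "max_iter", "tol"),
    split = c("train_fraction", "stratified"),
    classify = c("classifiers", "tasks", "bpnn_epochs")
  )
}

#' Validate a pipeline configuration
#'
#' Checks every key (top level and within each block) against the schema and
#' rejects unknown ones; cross-stage constraints (for example more ICA
#' components than electrode channels) fail here, before any stage runs.
#'
#' @param config Named list of per-stage parameter blocks; anything omitted
#'   takes its documented default.
#' @return The validated config, with defaults filled in.
#' @export
validate_pipeline_config <- function(config = list()) {
  schema <- pipeline_config_schema()
  bad <- setdiff(names(config), names(schema))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in c("protocol", "noise", "filters", "ica", "split", "classify")) {
    bad <- setdiff(names(config[[blk]]), schema[[blk]])
    if (length(bad)) {
      stop("unknown key(s) in `", blk, "`: ", paste(bad, collapse = ", "))
    }
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$rate <- config$rate %||% 1000
  config$protocol <- do.call(protocol_spec, config$protocol %||% list())
  config$noise_args <- config$noise %||% list()
  filters <- config$filters %||% list()
  filters$ica_input <- match.arg(filters$ica_input %||% "envelope",
                                 c("envelope", "bandpass"))
  config$filters <- filters
  ica <- config$ica %||% list()
  ica$n_components <- ica$n_components %||% 8L
  n_electrodes <- 16L
  if (ica$n_components > n_electrodes) {
    stop("ICA components (", ica$n_components, ") exceed the ",
         n_electrodes, " electrode channels")
  }
  config$ica <- ica
  config$split <- config$split %||% list()
  cls <- config$classify %||% list()
  cls$classifiers <- cls$classifiers %||% c("rf", "svm", "bpnn")
  cls$tasks <- cls$tasks %||% c("five_class", "ten_class")
  config$classify <- cls
  config
}

write_matrix_txt <- function(m, path) {
  utils::write.table(format(m, digits = 15, scientific = TRUE, trim = TRUE),
                     path, sep = " ", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, preprocess, source separation, feature extraction
#' and classification in order, writing every intermediate artifact plus a
#' manifest (stage order, per-stage derived seeds, MD5 hash of each artifact,
#' package version) into `out_dir`. Rerunning with the same config reproduces
#' every artifact hash.
#'
#' @param config Named list accepted by [validate_pipeline_config()], or a
#'   path to a YAML file holding one.
#' @param out_dir Output directory (created if needed).
#' @param verbose Print per-stage timing.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("perifemg_run_"),
                         verbose = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a config file requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("perifemg")),
                   seed = cfg$seed, stages = list())
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() Sys.time()
  stage_seed <- function(i) derive_seed(cfg$seed, i * 1000L)
  add_stage <- function(name, seed, files, t0) {
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(
      name = name, seed = seed,
      artifacts = as.list(tools::md5sum(files)),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    say("stage %-10s %.1fs", name, as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  # 1. simulate
  t0 <- tic()
  noise <- do.call(noise_spec, cfg$noise_args)
  sess <- simulate_session(cfg$protocol, build_mixing_matrix(), noise,
                           rate = cfg$rate, seed = stage_seed(1L))
  rec_path <- file.path(out_dir, "recording.txt")
  lab_path <- file.path(out_dir, "labels.tsv")
  write_recording(sess$recording, rec_path)
  write_labels(sess$epochs, lab_path)
  add_stage("simulate", stage_seed(1L), c(rec_path, lab_path), t0)

  # 2. preprocess
  t0 <- tic()
  f <- cfg$filters
  chain <- preprocess_chain(
    sess$recording,
    notch_freq = f$notch_freq %||% 50, notch_quality = f$notch_quality %||% 30,
    low = f$low %||% 20, high = f$high %||% 350, order = f$order %||% 4,
    envelope_cutoff = f$envelope_cutoff %||% 10,
    zero_phase = f$zero_phase %||% TRUE, keep_stages = TRUE
  )
  ica_in <- if (f$ica_input == "bandpass") attr(chain, "stages")$bandpass else chain
  clean_path <- file.path(out_dir, "clean.txt")
  write_recording(chain, clean_path)
  add_stage("preprocess", NA, clean_path, t0)

  # 3. source separation
  t0 <- tic()
  fit <- suppressWarnings(
    fit_ica(ica_in, n_components = cfg$ica$n_components,
            seed = stage_seed(3L), max_iter = cfg$ica$max_iter %||% 400L,
            tol = cfg$ica$tol %||% 1e-5)
  )
  comps_path <- file.path(out_dir, "comps.txt")
  w_path <- file.path(out_dir, "W.txt")
  write_matrix_txt(fit$components, comps_path)
  write_matrix_txt(fit$W, w_path)
  add_stage("ica", stage_seed(3L), c(comps_path, w_path), t0)

  # 4. features
  t0 <- tic()
  fm <- extract_feature_matrix(fit$components, sess$epochs, cfg$rate)
  feat_path <- file.path(out_dir, "features.tsv")
  write_features(fm, feat_path)
  add_stage("features", NA, feat_path, t0)

  # 5. classify
  t0 <- tic()
  reports <- lapply(cfg$classify$tasks, function(task) {
    res <- run_benchmark(fm, task, cfg$classify$classifiers,
                         train_fraction = cfg$split$train_fraction %||% 0.8,
                         stratified = cfg$split$stratified %||% TRUE,
                         seed = stage_seed(5L),
                         bpnn_epochs = cfg$classify$bpnn_epochs %||% 400L)
    lapply(seq_len(nrow(res)), function(i) {
      rep <- res$report[[i]]
      list(task = res$task[i], classifier = res$classifier[i],
           accuracy = res$accuracy[i], recall = res$recall[i],
           f1 = res$f1[i], averaging = res$averaging[i],
           classes = rep$classes,
           confusion = unname(apply(rep$confusion, 1L, as.integer,
                                    simplify = FALSE)))
    })
  })
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(unlist(reports, recursive = FALSE), report_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add_stage("classify", stage_seed(5L), report_path, t0)

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$out_dir <- out_dir
  invisible(manifest)
}
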