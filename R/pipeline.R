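#' @title End-to-end pipeline
#' @description Orchestrates generate -> extract -> train -> evaluate as a
#'   single reproducible run driven by one configuration and one master
#'   seed, writing stage artifacts (WAV cohort, manifest CSV, predictions
#'   CSV, metrics JSON, artifact index with content hashes) under an output
#'   directory.
#' @name pipeline
NULL

#' Build a pipeline configuration
#'
#' Defaults reproduce the study-scale settings: the full 104-participant
#' cohort design, 9 folds, 8 replicates, 5 repetitions, early-stopping
#' patience 20. `smoke = TRUE` selects the reduced validation
#' configuration (3 folds, 2 replicates, 1 repetition, scaled-down
#' networks) that exercises every stage end-to-end on one CPU.
#'
#' @param out_dir workspace directory for all artifacts.
#' @param seed master seed.
#' @param smoke use the reduced smoke-scale protocol.
#' @param cohort a [cohort_config()]; defaults to the study design.
#' @param n_folds,n_replicates,n_repetitions protocol sizes.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, smoke = FALSE,
                            cohort = NULL,
                            n_folds = if (smoke) 3L else 9L,
                            n_replicates = if (smoke) 2L else 8L,
                            n_repetitions = if (smoke) 1L else 5L) {
  if (is.null(cohort)) cohort <- cohort_config(seed = derive_seed(seed, "cohort"))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 smoke = isTRUE(smoke), cohort = cohort,
                 n_folds = as.integer(n_folds),
                 n_replicates = as.integer(n_replicates),
                 n_repetitions = as.integer(n_repetitions),
                 configs = default_protocol_configs(smoke = smoke)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed`, `smoke`, `n_folds`, `n_replicates`,
#' `n_repetitions`, and `cohort` (with `n_per_class`, `repetitions`,
#' `vocalization_types`). Missing keys fall back to the defaults of
#' [pipeline_config()].
#'
#' @param path YAML file.
#' @param out_dir workspace directory.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir) {
  y <- yaml::read_yaml(path)
  cohort <- NULL
  if (!is.null(y$cohort)) {
    cohort <- cohort_config(
      n_per_class = y$cohort$n_per_class %||% c(34L, 19L, 29L, 22L),
      repetitions = y$cohort$repetitions %||% 2L,
      vocalization_types = y$cohort$vocalization_types %||%
        c("ae", "sa", "counting"),
      seed = derive_seed(y$seed %||% 1L, "cohort"))
  }
  base <- pipeline_config(out_dir, seed = y$seed %||% 1L,
                          smoke = isTRUE(y$smoke), cohort = cohort)
  for (k in c("n_folds", "n_replicates", "n_repetitions")) {
    if (!is.null(y[[k]])) base[[k]] <- as.integer(y[[k]])
  }
  base
}

#' Run the whole pipeline
#'
#' Generates the synthetic cohort, extracts features for every recording,
#' runs the k-fold double-validation protocol, and writes `manifest.csv`,
#' `predictions.csv`, `metrics.json` and `artifacts.json` (path + MD5 per
#' artifact) under the configured output directory.
#'
#' @param config a [pipeline_config()].
#' @param write_audio write the cohort WAV files (default `TRUE`; with
#'   `FALSE` waveforms stay in memory, which is faster for throwaway runs).
#' @param verbose print stage progress.
#' @return the `mmrc_protocol_result`, invisibly, with an extra
#'   `artifacts` attribute.
#' @export
run_pipeline <- function(config, write_audio = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  audio_dir <- file.path(config$out_dir, "audio")

  if (verbose) message("stage 1/3: synthesizing cohort")
  cohort <- tryCatch(
    generate_cohort(config$cohort, audio_dir, write_audio = write_audio),
    error = function(e) stop("stage 'generate' failed: ",
                             conditionMessage(e)))

  if (verbose) message("stage 2/3: extracting features")
  features <- tryCatch(
    extract_manifest_features(cohort$manifest, cohort$recordings),
    error = function(e) stop("stage 'extract' failed: ",
                             conditionMessage(e)))

  if (verbose) message("stage 3/3: training protocol")
  result <- tryCatch(
    run_protocol(cohort$manifest, features, configs = config$configs,
                 n_folds = config$n_folds,
                 n_replicates = config$n_replicates,
                 n_repetitions = config$n_repetitions,
                 seed = config$seed, verbose = verbose),
    error = function(e) stop("stage 'train' failed: ", conditionMessage(e)))

  preds <- do.call(rbind, lapply(result$repetitions, `[[`, "predictions"))
  pred_path <- file.path(config$out_dir, "predictions.csv")
  utils::write.csv(preds, pred_path, row.names = FALSE)
  metrics_path <- file.path(config$out_dir, "metrics.json")
  jsonlite::write_json(
    list(aggregate = result$aggregate,
         per_repetition = lapply(result$repetitions, function(r) {
           r$metrics[c("accuracy", "rmse", "fp_rate", "fn_rate", "auc", "n")]
         })),
    metrics_path, auto_unbox = TRUE, digits = NA, na = "null")

  artifact_paths <- c(cohort$manifest_path, pred_path, metrics_path)
  artifacts <- data.frame(path = artifact_paths,
                          md5 = unname(tools::md5sum(artifact_paths)),
                          stringsAsFactors = FALSE)
  jsonlite::write_json(artifacts, file.path(config$out_dir, "artifacts.json"))
  attr(result, "artifacts") <- artifacts
  invisible(result)
}

#' Train a deployable classifier bundle
#'
#' Trains the six (vocalization, feature kind) classifier slots once on a
#' simple speaker-disjoint 70/15/15 split of all participants, keeping the
#' best of `n_replicates` seeded replicates per slot together with the
#' slot's normalization statistics and padding reference length. The
#' bundle is what [predict_single()] consumes.
#'
#' @param manifest cohort manifest data.frame.
#' @param features features from [extract_manifest_features()].
#' @param configs slot configurations ([default_protocol_configs()]).
#' @param n_replicates replicates per slot.
#' @param seed master seed.
#' @return object of class `mmrc_bundle`.
#' @export
train_bundle <- function(manifest, features,
                         configs = default_protocol_configs(smoke = TRUE),
                         n_replicates = 2L, seed = 1L) {
  cls <- participant_classes(manifest)
  pids <- names(cls)
  m <- length(pids)
  n_val <- max(1L, floor(0.15 * m + 0.5))
  ord <- with_seed(derive_seed(seed, "bundle"), sample(pids))
  sets <- list(train = ord[seq_len(m - 2L * n_val)],
               val1 = ord[(m - 2L * n_val + 1L):(m - n_val)],
               val2 = ord[(m - n_val + 1L):m])
  types <- intersect(c("ae", "sa", "counting"),
                     unique(manifest$vocalization_type))
  slots <- list()
  for (voc in types) {
    for (kind in c("td", "ti")) {
      tf <- make_slot_transform(manifest, features, voc, sets$train, kind,
                                configs$mvn_scope %||% "train")
      get_xy <- function(ids) {
        rows <- rows_for(manifest, voc, ids)
        list(x = tf$transform(rows), y = unname(cls[manifest$participant_id[rows]]))
      }
      tr <- get_xy(sets$train); v1 <- get_xy(sets$val1); v2 <- get_xy(sets$val2)
      shape <- if (kind == "ti") ncol(tr$x) else c(tf$ref_len, ncol(tr$x[[1]]))
      reps <- train_replicates(tr$x, tr$y, v1$x, v1$y, v2$x, v2$y,
                               config_args = configs[[kind]][[voc]],
                               input_shape = shape,
                               n_replicates = n_replicates,
                               seed = derive_seed(seed, "bundle", voc, kind))
      best <- select_best(reps)
      slots[[paste(voc, kind, sep = ".")]] <-
        list(model = reps[[best]]$model, stats = tf$stats,
             ref_len = tf$ref_len)
    }
  }
  structure(list(slots = slots, types = types, seed = seed),
            class = "mmrc_bundle")
}

#' Estimate the mMRC score for one participant
#'
#' Takes up to six recordings (three vocalization types, two repetitions
#' each; any available subset works) and propagates them through the
#' trained bundle and the full fusion hierarchy: per-recording
#' probabilities, repetition fusion, feature-kind fusion, vocalization
#' fusion, argmax.
#'
#' @param recordings list of `voc_recording` objects (with waveforms) or
#'   WAV file paths; vocalization types are taken from the objects or, for
#'   paths, must be given in `types`.
#' @param bundle an [train_bundle()] result.
#' @param types character vector of vocalization types parallel to
#'   `recordings` when these are file paths.
#' @return list with `mmrc` (integer 0..3), `probs` (length-4 vector) and
#'   `dyspnea_score` (`1 - probs[1]`).
#' @export
predict_single <- function(recordings, bundle, types = NULL) {
  stopifnot(inherits(bundle, "mmrc_bundle"), length(recordings) >= 1)
  recs <- lapply(seq_along(recordings), function(i) {
    r <- recordings[[i]]
    if (inherits(r, "voc_recording")) return(r)
    wav <- read_wav(r)
    if (is.null(types)) stop("vocalization types must be given for paths")
    new_recording(wav$samples, "single", types[i], i, 0L)
  })
  voc_vecs <- list()
  for (voc in bundle$types) {
    of_type <- Filter(function(r) r$vocalization_type == voc, recs)
    if (length(of_type) == 0) next
    kind_vecs <- list()
    for (kind in c("td", "ti")) {
      slot <- bundle$slots[[paste(voc, kind, sep = ".")]]
      if (is.null(slot)) next
      per_rec <- lapply(of_type, function(r) {
        feats <- extract_features(r)
        if (kind == "ti") {
          x <- apply_mvn(matrix(feats$ti, nrow = 1), slot$stats)
        } else {
          x <- list(pad_to_reference(apply_mvn(feats$td, slot$stats),
                                     slot$ref_len))
        }
        as.vector(predict_proba(slot$model, x))
      })
      kind_vecs[[kind]] <- five_rule_combine(per_rec)
    }
    if (length(kind_vecs) == 0) next
    voc_vecs[[voc]] <- fuse_feature_types(kind_vecs$td, kind_vecs$ti)
  }
  if (length(voc_vecs) == 0) stop("no usable recordings")
  final <- do.call(fuse_vocalizations,
                   list(ae = voc_vecs$ae, sa = voc_vecs$sa,
                        counting = voc_vecs$counting))
  list(mmrc = predict_mmrc(final), probs = final,
       dyspnea_score = 1 - final[1])
}
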