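#' @title Speaker-disjoint k-fold protocol with double validation
#' @description Participants are dealt into k folds (default 9; for 104
#'   participants: five folds of 12 and four of 11). Each partition uses
#'   its fold as the test set and splits the remaining participants into
#'   training, validation-1 (early stopping) and validation-2 (replicate
#'   selection) subsets at 70/15/15. Every classifier is trained several
#'   times per partition (default 8) with distinct initialization seeds and
#'   the replicate with the highest mean validation accuracy is kept. All
#'   splits are by participant, never by recording, so no speaker appears
#'   in more than one subset. The whole procedure is repeated (default 5
#'   times) and metrics are averaged.
#' @name kfold
NULL

#' Assign participants to folds
#'
#' Folds are as equal as possible (larger folds first: 104 participants in
#' 9 folds gives sizes 12,12,12,12,12,11,11,11,11) and stratified by mMRC
#' class when `classes` is supplied: within each class, shuffled
#' participants are dealt to the fold with the most remaining capacity.
#'
#' @param participant_ids character vector of unique participant IDs.
#' @param n_folds number of folds (default 9).
#' @param seed shuffling seed.
#' @param classes optional integer class per participant (same order as
#'   `participant_ids`) for stratification.
#' @return object of class `fold_plan`: `n_folds`, `sizes`, and
#'   `assignments` (named integer vector participant -> fold).
#' @export
make_fold_plan <- function(participant_ids, n_folds = 9L, seed = 1L,
                           classes = NULL) {
  n <- length(participant_ids)
  stopifnot(n >= 1, !anyDuplicated(participant_ids))
  if (n_folds > n) stop("more folds than participants")
  n_folds <- as.integer(n_folds)
  base <- n %/% n_folds
  extra <- n %% n_folds
  sizes <- as.integer(rep(base, n_folds) +
                        c(rep(1L, extra), rep(0L, n_folds - extra)))
  capacity <- sizes
  assignment <- integer(n)
  with_seed(derive_seed(seed, "folds"), {
    if (is.null(classes)) classes <- rep(0L, n)
    for (cls in sort(unique(classes))) {
      members <- sample(which(classes == cls))
      for (i in members) {
        f <- which.max(capacity) # ties resolve to the lowest fold index
        assignment[i] <- f
        capacity[f] <- capacity[f] - 1L
      }
    }
  })
  structure(list(n_folds = as.integer(n_folds), sizes = sizes,
                 assignments = stats::setNames(assignment, participant_ids)),
            class = "fold_plan")
}

#' Split one partition into test / train / val1 / val2 participant sets
#'
#' The fold itself is the test set; the remaining m participants are
#' shuffled (seeded) and split 70/15/15, with
#' `n_val = floor(0.15 m + 0.5)` in each validation subset and the rest in
#' training. The four subsets are pairwise disjoint and cover all
#' participants.
#'
#' @param plan a [make_fold_plan()] result.
#' @param fold_index which fold plays the test role.
#' @param seed shuffling seed for the 70/15/15 split.
#' @return list with character vectors `test`, `train`, `val1`, `val2`.
#' @export
split_partition <- function(plan, fold_index, seed = 1L) {
  stopifnot(inherits(plan, "fold_plan"),
            fold_index >= 1, fold_index <= plan$n_folds)
  ids <- names(plan$assignments)
  test <- ids[plan$assignments == fold_index]
  rest <- ids[plan$assignments != fold_index]
  m <- length(rest)
  n_val <- floor(0.15 * m + 0.5)
  if (n_val < 1 || m - 2L * n_val < 1) {
    stop("too few participants to populate train/val1/val2")
  }
  rest <- with_seed(derive_seed(seed, "split", fold_index), sample(rest))
  list(test = test,
       train = rest[seq_len(m - 2L * n_val)],
       val1 = rest[(m - 2L * n_val + 1L):(m - n_val)],
       val2 = rest[(m - n_val + 1L):m])
}

#' Train seeded replicates of one classifier
#'
#' Trains `n_replicates` models with identical data and configuration but
#' distinct initialization/shuffling seeds (derived deterministically from
#' `seed` and the replicate index). A replicate that aborts is recorded as
#' failed and excluded from selection.
#'
#' @param x_train,y_train,x_val1,y_val1,x_val2,y_val2 slot data; labels in
#'   0..3.
#' @param config_args list of [model_config()] arguments (without
#'   `input_shape`/`seed`).
#' @param input_shape input shape passed to [model_config()].
#' @param n_replicates number of replicates (default 8).
#' @param seed base seed.
#' @return list of replicate records: `model`, `history`, `val1_acc`,
#'   `val2_acc`, `ok`, `error`.
#' @export
train_replicates <- function(x_train, y_train, x_val1, y_val1,
                             x_val2, y_val2, config_args, input_shape,
                             n_replicates = 8L, seed = 1L) {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates), function(r) {
    rep_seed <- derive_seed(seed, "replicate", r)
    tryCatch({
      cfg <- do.call(model_config,
                     c(config_args,
                       list(input_shape = input_shape, seed = rep_seed)))
      fit <- train_model(build_model(cfg), x_train, y_train, x_val1, y_val1)
      list(model = fit$model, history = fit$history,
           val1_acc = model_accuracy(fit$model,
                                     as_model_input(fit$model, x_val1),
                                     y_val1),
           val2_acc = model_accuracy(fit$model,
                                     as_model_input(fit$model, x_val2),
                                     y_val2),
           ok = TRUE, error = NULL)
    }, error = function(e) {
      list(model = NULL, history = NULL, val1_acc = NA_real_,
           val2_acc = NA_real_, ok = FALSE, error = conditionMessage(e))
    })
  })
}

#' Select the replicate with the best validation generalization
#'
#' Argmax of the mean of validation-1 and validation-2 accuracy; ties go to
#' the lowest replicate index. Failed replicates are skipped.
#'
#' @param replicates list from [train_replicates()].
#' @return index of the selected replicate.
#' @export
select_best <- function(replicates) {
  ok <- vapply(replicates, function(r) isTRUE(r$ok), logical(1))
  if (!any(ok)) stop("all replicates failed")
  score <- vapply(replicates, function(r) {
    if (isTRUE(r$ok)) (r$val1_acc + r$val2_acc) / 2 else -Inf
  }, numeric(1))
  which.max(score) # first maximum = lowest index on ties
}

# --- slot data assembly -----------------------------------------------------

rows_for <- function(manifest, voc, participants) {
  which(manifest$vocalization_type == voc &
          manifest$participant_id %in% participants)
}

gather_ti <- function(features, rows) {
  do.call(rbind, lapply(features[rows], `[[`, "ti"))
}

gather_td <- function(features, rows) {
  lapply(features[rows], `[[`, "td")
}

# fit MVN + reference length on the training rows of one slot, return a
# transform closure for any rows
make_slot_transform <- function(manifest, features, voc, train_ids, kind,
                                mvn_scope = "train") {
  scope_ids <- if (mvn_scope == "all") {
    unique(manifest$participant_id)
  } else {
    train_ids
  }
  fit_rows <- rows_for(manifest, voc, scope_ids)
  if (kind == "ti") {
    stats <- fit_mvn(gather_ti(features, fit_rows), scope = mvn_scope)
    list(stats = stats, ref_len = NA_integer_,
         transform = function(rows) {
           apply_mvn(gather_ti(features, rows), stats)
         })
  } else {
    mats <- gather_td(features, fit_rows)
    stats <- fit_mvn(mats, scope = mvn_scope)
    ref_len <- max(vapply(mats, nrow, integer(1)))
    list(stats = stats, ref_len = ref_len,
         transform = function(rows) {
           lapply(gather_td(features, rows), function(m) {
             pad_to_reference(apply_mvn(m, stats), ref_len)
           })
         })
  }
}

participant_classes <- function(manifest) {
  agg <- manifest[!duplicated(manifest$participant_id),
                  c("participant_id", "mmrc_reference")]
  stats::setNames(as.integer(agg$mmrc_reference), agg$participant_id)
}

#' Run the full k-fold double-validation protocol
#'
#' For every repetition: draw a (stratified) fold plan, and for every
#' partition train one classifier per (vocalization type, feature kind)
#' slot with `n_replicates` seeded replicates, keep the best replicate by
#' mean validation accuracy, and score the held-out test participants
#' through the fusion hierarchy (repetitions -> feature kinds ->
#' vocalizations -> argmax). Normalization statistics and the zero-padding
#' reference length are computed from each partition's training subset only
#' (default scope), never from test data. Pooled predictions cover every
#' participant exactly once per repetition.
#'
#' @param manifest cohort manifest data.frame (see [read_manifest()]).
#' @param features per-row feature list from [extract_manifest_features()].
#' @param configs slot configurations, see [default_protocol_configs()].
#' @param n_folds,n_replicates,n_repetitions protocol sizes (paper
#'   defaults 9, 8, 5).
#' @param seed master seed; the whole protocol is a pure function of it.
#' @param verbose print per-partition progress.
#' @return object of class `mmrc_protocol_result`: per-repetition
#'   `predictions` data.frames and `metrics`, plus `aggregate` (mean
#'   metrics across repetitions).
#' @export
run_protocol <- function(manifest, features,
                         configs = default_protocol_configs(),
                         n_folds = 9L, n_replicates = 8L,
                         n_repetitions = 5L, seed = 1L, verbose = FALSE) {
  stopifnot(nrow(manifest) == length(features))
  types <- intersect(c("ae", "sa", "counting"),
                     unique(manifest$vocalization_type))
  if (length(types) == 0) stop("manifest contains no known vocalization type")
  cls <- participant_classes(manifest)
  pids <- names(cls)
  mvn_scope <- configs$mvn_scope %||% "train"

  repetition_results <- lapply(seq_len(n_repetitions), function(rep_i) {
    rep_seed <- derive_seed(seed, "repetition", rep_i)
    plan <- make_fold_plan(pids, n_folds, seed = rep_seed,
                           classes = unname(cls))
    pred_rows <- list()
    partitions <- list()
    for (f in seq_len(plan$n_folds)) {
      if (verbose) {
        message(sprintf("repetition %d, partition %d/%d",
                        rep_i, f, plan$n_folds))
      }
      sp <- split_partition(plan, f, seed = rep_seed)
      slot_models <- list()
      slot_info <- list()
      for (voc in types) {
        for (kind in c("td", "ti")) {
          tf <- make_slot_transform(manifest, features, voc, sp$train,
                                    kind, mvn_scope)
          get_xy <- function(ids) {
            rows <- rows_for(manifest, voc, ids)
            list(x = tf$transform(rows),
                 y = cls[manifest$participant_id[rows]],
                 rows = rows)
          }
          tr <- get_xy(sp$train); v1 <- get_xy(sp$val1); v2 <- get_xy(sp$val2)
          shape <- if (kind == "ti") {
            ncol(tr$x)
          } else {
            c(tf$ref_len, ncol(tr$x[[1]]))
          }
          reps <- train_replicates(
            tr$x, unname(tr$y), v1$x, unname(v1$y), v2$x, unname(v2$y),
            config_args = configs[[kind]][[voc]], input_shape = shape,
            n_replicates = n_replicates,
            seed = derive_seed(rep_seed, "slot", f, voc, kind))
          best <- select_best(reps)
          key <- paste(voc, kind, sep = ".")
          slot_models[[key]] <- reps[[best]]$model
          slot_info[[key]] <- list(
            best_replicate = best,
            val_acc = vapply(reps, function(r) {
              (r$val1_acc + r$val2_acc) / 2
            }, numeric(1)),
            transform = tf)
        }
      }
      # score the held-out participants through the fusion hierarchy
      for (pid in sp$test) {
        voc_vecs <- list()
        for (voc in types) {
          kind_vecs <- list()
          for (kind in c("td", "ti")) {
            key <- paste(voc, kind, sep = ".")
            rows <- rows_for(manifest, voc, pid)
            if (length(rows) == 0) next
            x <- slot_info[[key]]$transform$transform(rows)
            p <- predict_proba(slot_models[[key]], x)
            kind_vecs[[kind]] <- five_rule_combine(
              lapply(seq_len(nrow(p)), function(i) p[i, ]))
          }
          if (length(kind_vecs) == 0) next
          voc_vecs[[voc]] <- fuse_feature_types(kind_vecs$td, kind_vecs$ti)
        }
        final <- do.call(fuse_vocalizations,
                         list(ae = voc_vecs$ae, sa = voc_vecs$sa,
                              counting = voc_vecs$counting))
        pred_rows[[length(pred_rows) + 1L]] <- data.frame(
          participant_id = pid,
          reference_mmrc = unname(cls[pid]),
          estimated_mmrc = predict_mmrc(final),
          p0 = final[1], p1 = final[2], p2 = final[3], p3 = final[4],
          dyspnea_score = 1 - final[1],
          repetition = rep_i, fold = f,
          stringsAsFactors = FALSE)
      }
      partitions[[f]] <- list(split = sp, slots = slot_info)
    }
    predictions <- do.call(rbind, pred_rows)
    es <- evaluation_set(predictions$reference_mmrc,
                         predictions$estimated_mmrc,
                         predictions$dyspnea_score)
    list(repetition = rep_i, plan = plan, partitions = partitions,
         predictions = predictions, metrics = metrics_report(es))
  })

  agg_names <- c("accuracy", "rmse", "fp_rate", "fn_rate", "auc")
  aggregate <- lapply(stats::setNames(nm = agg_names), function(nm) {
    mean(vapply(repetition_results, function(r) r$metrics[[nm]],
                numeric(1)))
  })
  structure(list(repetitions = repetition_results, aggregate = aggregate,
                 seed = seed, n_folds = n_folds,
                 n_replicates = n_replicates,
                 n_repetitions = n_repetitions),
            class = "mmrc_protocol_result")
}

#' Default per-slot classifier configurations
#'
#' The time-independent slots are MLPs with plain softmax heads and
#' learning rate 0.001: two 20-unit hidden layers for /ae-ae/, one 20-unit
#' layer for /sa-sa/, one 30-unit layer for counting. The time-dependent
#' slots use the stick-breaking head and learning rate 0.0001: a CNN
#' (blocks of two 5-wide convolutions with 32 filters plus max-pooling,
#' then a 64-unit dense layer) for /ae-ae/ and /sa-sa/, and a CNN-LSTM
#' (two conv blocks, a 64-unit LSTM read out at the last frame, a 64-unit
#' dense layer) for counting. `smoke = TRUE` returns a scaled-down variant
#' (coarser time decimation, one conv block, 16 filters, tighter epoch cap)
#' for end-to-end validation runs on a single CPU.
#'
#' @param smoke use the reduced smoke-test sizes.
#' @return nested list `list(ti = ..., td = ..., mvn_scope = "train")`.
#' @export
default_protocol_configs <- function(smoke = FALSE) {
  mlp <- function(hidden) {
    list(model_family = "mlp", hidden_layers = hidden,
         learning_rate = 0.001, use_stick_breaking = FALSE,
         max_epochs = if (smoke) 300L else 500L, batch_size = 32L,
         patience = 20L)
  }
  cnn <- list(model_family = "cnn",
              conv_blocks = if (smoke) 1L else 3L,
              kernel_size = 5L,
              n_filters = if (smoke) 16L else 32L,
              hidden_layers = if (smoke) 32L else 64L,
              input_decimation = if (smoke) 8L else 2L,
              learning_rate = 0.0001, use_stick_breaking = TRUE,
              max_epochs = if (smoke) 80L else 500L, batch_size = 32L,
              patience = 20L)
  cnn_lstm <- list(model_family = "cnn_lstm",
                   conv_blocks = if (smoke) 1L else 2L,
                   kernel_size = 5L,
                   n_filters = if (smoke) 16L else 32L,
                   lstm_units = if (smoke) 32L else 64L,
                   hidden_layers = if (smoke) 32L else 64L,
                   input_decimation = if (smoke) 12L else 2L,
                   learning_rate = 0.0001, use_stick_breaking = TRUE,
                   max_epochs = if (smoke) 50L else 500L,
                   batch_size = if (smoke) 64L else 32L,
                   patience = 20L)
  list(ti = list(ae = mlp(c(20L, 20L)), sa = mlp(20L), counting = mlp(30L)),
       td = list(ae = cnn, sa = cnn, counting = cnn_lstm),
       mvn_scope = "train")
}
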