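#' Feature extraction for a set of recordings
#'
#' Preprocess (cough-synchronised segmentation + high-pass) and extract the
#' HHT feature vector of every recording, assembled into a `feature_table`.
#'
#' @param recordings list of `lung_recording`.
#' @param duration_s segment length in seconds.
#' @param n_imf,noise_std,ensemble_size,seed,bin_hz see [extract_features()].
#' @return a `feature_table` with one row per recording.
#' @export
extract_dataset <- function(recordings, duration_s = 15, n_imf = 10L,
                            noise_std = 0.015, ensemble_size = 100L,
                            seed = 1L, bin_hz = 1) {
  feats <- lapply(recordings, function(rec) {
    segs <- preprocess_recording(rec, duration_s = duration_s)
    extract_features(segs, n_imf = n_imf, noise_std = noise_std,
                     ensemble_size = ensemble_size, seed = seed,
                     bin_hz = bin_hz)
  })
  feature_table(feats)
}

#' Channel selection and repeated-split classification in one call
#'
#' The full decision pipeline downstream of feature extraction: min-max
#' normalization, reliefF weighting, negative-weight pruning, channel
#' ranking by summed weight, restriction to the top channels, selection of
#' the top-n features there, and repeated stratified 70/30 SVM evaluation.
#'
#' By default (`in_split = TRUE`) the normalization and the whole selection
#' chain are refitted on the training part of every split and applied to
#' the held-out part with the training parameters, so the reported metrics
#' carry no selection bias. `in_split = FALSE` performs selection once on
#' the full table before splitting (the cheaper protocol; its metrics are
#' optimistic on small samples). The returned `ranking`, `weights` and
#' `selected` always describe the full-table analysis, which is what the
#' channel-selection question asks.
#'
#' @param table a `feature_table` with binary labels.
#' @param n_top number of features fed to the classifier.
#' @param n_channels number of top-ranked channels to keep.
#' @param k reliefF nearest-neighbour count.
#' @param n_repeats,test_frac,seed,grid,grid_once see [repeated_eval()].
#' @param classifier see [repeated_eval()].
#' @param in_split refit normalization and feature selection inside each
#'   training split (default) instead of once on the full table.
#' @param permute_labels evaluate the permutation null instead: see
#'   [repeated_eval()].
#' @return list with `ranking` (a `channel_ranking`), `selected` (feature
#'   names), `weights` (pruned `relieff_weights`) and `eval`
#'   (an `eval_result`).
#' @export
classify_features <- function(table, n_top = 25L, n_channels = 4L, k = 10L,
                              n_repeats = 1000L, test_frac = 0.3, seed = 1L,
                              grid = default_svm_grid(), grid_once = FALSE,
                              classifier = "svm", in_split = TRUE,
                              permute_labels = FALSE) {
  info <- table$info
  select_cols <- function(x, y) {
    tbl <- structure(list(features = x, info = info, label = y,
                          subject_id = rownames(x)),
                     class = "feature_table")
    norm <- suppressWarnings(minmax_normalize(tbl))
    wp <- suppressWarnings(prune_negative(relieff_weights(norm, k = k)))
    ranking <- rank_channels(wp)
    top_ch <- ranking$channel[seq_len(min(n_channels, nrow(ranking)))]
    n_avail <- sum(wp$info$channel %in% top_ch)
    sel <- select_top(wp, channels = top_ch, n = min(n_top, n_avail))
    list(sel = sel, ranges = attr(norm, "ranges"), ranking = ranking,
         weights = wp, norm = norm)
  }

  full <- select_cols(table$features, table$label)

  if (in_split) {
    prepare <- function(x_tr, y_tr, x_te) {
      fit <- select_cols(x_tr, y_tr)
      te <- apply_normalization(
        structure(list(features = x_te, info = info), class = "feature_table"),
        fit$ranges)
      list(train = fit$norm$features[, fit$sel, drop = FALSE],
           test = te$features[, fit$sel, drop = FALSE])
    }
    ev <- repeated_eval(table$features, table$label, n_repeats = n_repeats,
                        test_frac = test_frac, seed = seed, grid = grid,
                        grid_once = grid_once, classifier = classifier,
                        prepare = prepare, permute_labels = permute_labels)
  } else {
    ev <- repeated_eval(full$norm$features[, full$sel, drop = FALSE],
                        table$label, n_repeats = n_repeats,
                        test_frac = test_frac, seed = seed, grid = grid,
                        grid_once = grid_once, classifier = classifier,
                        permute_labels = permute_labels)
  }
  list(ranking = full$ranking, selected = full$sel, weights = full$weights,
       eval = ev)
}

#' Relabel a feature table for one of the two binary severity tasks
#'
#' `"mild-vs-rest"` contrasts mild against moderate + severe;
#' `"moderate-vs-severe"` drops mild samples and contrasts moderate
#' against severe.
#'
#' @param table a `feature_table` with labels in mild/moderate/severe.
#' @param task which binary contrast to build.
#' @return the `feature_table` with a two-level `label` factor (second
#'   level = the more severe group).
#' @export
binary_task <- function(table, task = c("mild-vs-rest", "moderate-vs-severe")) {
  task <- match.arg(task)
  lab <- as.character(table$label)
  if (task == "mild-vs-rest") {
    new <- ifelse(lab == "mild", "mild", "moderate+severe")
    table$label <- factor(new, levels = c("mild", "moderate+severe"))
  } else {
    keep <- lab %in% c("moderate", "severe")
    table$features <- table$features[keep, , drop = FALSE]
    table$subject_id <- table$subject_id[keep]
    table$label <- factor(lab[keep], levels = c("moderate", "severe"))
  }
  table
}
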