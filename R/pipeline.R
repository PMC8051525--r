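#' Assemble per-subject features into a wide table
#'
#' Binds per-subject long feature tibbles (as produced by
#' [itm_features()], [mfdfa_features()] or [ft_features()]) into the
#' subjects-by-features table the modeling stage consumes.
#'
#' @param feature_list named list of long feature tibbles, one per
#'   subject; names are subject ids.
#' @return A tibble with `subject_id` plus one numeric column per feature.
#' @export
features_to_wide <- function(feature_list) {
  stopifnot(length(feature_list) >= 1L, !is.null(names(feature_list)))
  purrr::imap_dfr(feature_list, function(tb, id) {
    tibble::tibble(subject_id = id, feature = tb$feature, value = tb$value)
  }) |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
}

#' Median imputation from the training table
#'
#' Replaces missing feature values in both tables by the training-set
#' median of that feature (features that are entirely missing in training
#' are dropped from both).  Undefined segment means upstream (sentinel
#' `NA`s) are resolved here so the tree learner sees complete tables.
#'
#' @param train,test wide feature tables with a `subject_id` column.
#' @return A list with imputed `train` and `test` tibbles.
#' @export
impute_from_train <- function(train, test) {
  feats <- setdiff(names(train), "subject_id")
  drop <- character(0)
  for (f in feats) {
    med <- stats::median(train[[f]], na.rm = TRUE)
    if (is.na(med)) { drop <- c(drop, f); next }
    train[[f]][is.na(train[[f]])] <- med
    test[[f]][is.na(test[[f]])] <- med
  }
  if (length(drop)) {
    warning("dropping feature(s) entirely missing in training: ",
            paste(utils::head(drop, 5), collapse = ", "),
            if (length(drop) > 5) sprintf(" (+%d more)", length(drop) - 5) else "")
    train <- train[setdiff(names(train), drop)]
    test <- test[setdiff(names(test), drop)]
  }
  list(train = train, test = test)
}

#' Train/test method comparison across cognitive subscores
#'
#' The out-of-sample protocol: for each subscore, fit a CART regression
#' tree on the training-epoch features ([fit_cart()], `minsplit = 4`),
#' choose the complexity parameter by seeded 10-fold cross-validation
#' with the 1-SE rule ([cv_select_cp()]), prune, predict the subscore
#' from the test-epoch features, and correlate predictions with the
#' actual scores ([pearson_with_t()]).
#'
#' @param train,test wide feature tables (`subject_id` + features) from
#'   the two epochs; identical feature names and subjects required.
#' @param scores tibble with `subject_id` plus one numeric column per
#'   subscore (see [read_scores()]).
#' @param subscores subscore columns to model.
#' @param seed integer seed; fold assignments use `seed + i` for the i-th
#'   subscore so the whole report is deterministic.
#' @param method label recorded in the report (e.g. "itm", "mfdfa", "ft").
#' @param minsplit,k CART and CV controls.
#' @return A `correlation_report`: one row per subscore with columns
#'   `subscore`, `method`, `r`, `t`, `df`, `p`, `degenerate`,
#'   `selected_cp`, `n_leaves`, `used_features`.  Fitted models are
#'   attached as the `models` attribute.
#' @export
run_method_comparison <- function(train, test, scores,
                                  subscores = subscore_names(),
                                  seed, method = "features",
                                  minsplit = 4L, k = 10L) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(identical(sort(names(train)), sort(names(test))))
  if (!identical(train$subject_id, test$subject_id)) {
    stop("train/test tables must list the same subjects in the same order", call. = FALSE)
  }
  missing_subj <- setdiff(train$subject_id, scores$subject_id)
  if (length(missing_subj)) {
    stop("no score row for subject(s): ", paste(missing_subj, collapse = ", "), call. = FALSE)
  }
  scores <- scores[match(train$subject_id, scores$subject_id), , drop = FALSE]
  imp <- impute_from_train(train, test)
  models <- list()
  rows <- purrr::imap_dfr(rlang::set_names(subscores), function(sub, nm) {
    i <- match(sub, subscores)
    d_train <- dplyr::mutate(imp$train, .response = scores[[sub]])
    fit <- fit_cart(d_train, ".response", minsplit = minsplit)
    fit <- cv_select_cp(d_train, ".response", fit, k = k, seed = seed + i)
    pruned <- prune_cart(fit, fit$selected_cp)
    pred <- predict(pruned, imp$test)
    res <- pearson_with_t(pred, scores[[sub]])
    models[[sub]] <<- pruned
    dplyr::bind_cols(
      tibble::tibble(subscore = sub, method = method),
      res[c("r", "t", "df", "p", "degenerate")],
      tibble::tibble(
        selected_cp = fit$selected_cp,
        n_leaves = n_tree_leaves(pruned$tree),
        used_features = paste(tree_features(pruned$tree), collapse = ";")
      )
    )
  })
  out <- structure(rows, class = c("correlation_report", class(rows)))
  attr(out, "models") <- models
  out
}

#' @describeIn run_method_comparison bar chart of out-of-sample r per
#'   subscore (degenerate rows shown as zero-height, marked).
#' @param object a `correlation_report`.
#' @param ... unused.
#' @export
autoplot.correlation_report <- function(object, ...) {
  d <- dplyr::mutate(object,
                     r_plot = ifelse(is.na(.data$r), 0, .data$r),
                     sig = !is.na(.data$p) & .data$p < 0.05)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$subscore, y = .data$r_plot,
                                  fill = .data$sig)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::facet_wrap(~method) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65", `TRUE` = "#2c7fb8"),
                               labels = c(`FALSE` = "p >= 0.05", `TRUE` = "p < 0.05")) +
    ggplot2::labs(x = NULL, y = "out-of-sample Pearson r", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Study configuration
#'
#' Collects every knob of the end-to-end pipeline in one validated
#' object.  Defaults mirror the study design: training epoch `[90, 120)`
#' s, test epoch `[210, 240)` s, `minsplit = 4`, 10-fold CV, and the
#' method-specific defaults of [itm_within_grid()], [itm_between_grid()],
#' [mfdfa_params()] and [eeg_bands()].
#'
#' @param method one of "itm", "mfdfa", "ft".
#' @param leads lead subset to analyse, or `NULL` for all leads
#'   (the ITM study design uses [study_leads()]).
#' @param train_window,test_window numeric `c(start_s, end_s)`.
#' @param within_delays,between_delays,mfdfa,bands,taper_fraction
#'   method-specific parameters.
#' @param minsplit,k CART / CV controls.
#' @param seed integer seed (mandatory).
#' @param subscores subscores to model.
#' @return A list of class `study_config`.
#' @export
study_config <- function(method = c("itm", "mfdfa", "ft"),
                         leads = NULL,
                         train_window = study_windows()$train,
                         test_window = study_windows()$test,
                         within_delays = itm_within_grid(),
                         between_delays = itm_between_grid(),
                         mfdfa = mfdfa_params(),
                         bands = eeg_bands(),
                         taper_fraction = 0,
                         minsplit = 4L, k = 10L,
                         seed,
                         subscores = subscore_names()) {
  method <- match.arg(method)
  if (missing(seed)) stop("`seed` is mandatory in a study config", call. = FALSE)
  stopifnot(length(train_window) == 2L, length(test_window) == 2L,
            train_window[1] < train_window[2], test_window[1] < test_window[2])
  structure(
    list(method = method, leads = leads,
         train_window = train_window, test_window = test_window,
         within_delays = within_delays, between_delays = between_delays,
         mfdfa = mfdfa, bands = bands, taper_fraction = taper_fraction,
         minsplit = as.integer(minsplit), k = as.integer(k),
         seed = as.integer(seed), subscores = subscores),
    class = "study_config"
  )
}

epoch_features <- function(epoch, config) {
  switch(config$method,
         itm = itm_features(epoch, config$within_delays, config$between_delays),
         mfdfa = mfdfa_features(epoch, config$mfdfa),
         ft = ft_features(epoch, config$bands, config$taper_fraction))
}

#' Run the whole study pipeline
#'
#' For each subject: restrict to the lead subset, cut the training and
#' test epochs, extract the configured feature family from each, then run
#' the CART + 1-SE + out-of-sample correlation comparison across
#' subscores.  Fully deterministic given `config$seed`.
#'
#' @param records named list of [eeg_record()]s, one per subject (names
#'   are subject ids), each covering both epoch windows.
#' @param scores score tibble (`subject_id` + subscore columns); every
#'   subject must have a row.
#' @param config a [study_config()].
#' @param out_dir optional directory: writes `features_train.csv`,
#'   `features_test.csv`, `report.csv`, plain-text tree dumps and the
#'   resolved configuration.
#' @return A list: `report` (the `correlation_report`), `train`, `test`
#'   (wide feature tables), `models`, `config`.
#' @export
run_study <- function(records, scores, config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("`records` must be a named list (names = subject ids)", call. = FALSE)
  }
  need_dur <- max(config$train_window[2], config$test_window[2])
  for (id in names(records)) {
    r <- records[[id]]
    if (!inherits(r, "eeg_record")) stop("record for subject ", id, " is not an eeg_record", call. = FALSE)
    if (eeg_duration(r) + 1e-9 < need_dur) {
      stop(sprintf("subject %s: recording (%.3g s) does not cover both windows (need %g s)",
                   id, eeg_duration(r), need_dur), call. = FALSE)
    }
    if (!id %in% scores$subject_id) stop("subject ", id, " has no score row", call. = FALSE)
  }
  long <- list()
  wide_of <- function(window, tag) {
    fl <- purrr::map(records, function(r) {
      if (!is.null(config$leads)) r <- select_leads(r, config$leads)
      epoch_features(extract_epoch(r, window[1], window[2]), config)
    })
    long[[tag]] <<- purrr::imap_dfr(fl, ~ tibble::tibble(
      subject_id = .y, feature = .x$feature, epoch_tag = tag, value = .x$value))
    features_to_wide(fl)
  }
  train <- wide_of(config$train_window, "train")
  test <- wide_of(config$test_window, "test")
  report <- run_method_comparison(train, test, scores,
                                  subscores = config$subscores,
                                  seed = config$seed, method = config$method,
                                  minsplit = config$minsplit, k = config$k)
  models <- attr(report, "models")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(dplyr::bind_rows(long), file.path(out_dir, "features_long.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(report), file.path(out_dir, "report.csv"),
                     row.names = FALSE)
    for (sub in names(models)) {
      utils::capture.output(print(models[[sub]]),
                            file = file.path(out_dir, sprintf("tree_%s.txt", sub)))
    }
    writeLines(resolved_config_text(config), file.path(out_dir, "config.txt"))
  }
  list(report = report, train = train, test = test, models = models, config = config)
}

resolved_config_text <- function(config) {
  c(sprintf("method: %s", config$method),
    sprintf("leads: %s", if (is.null(config$leads)) "all" else paste(config$leads, collapse = ",")),
    sprintf("train_window: [%g, %g)", config$train_window[1], config$train_window[2]),
    sprintf("test_window: [%g, %g)", config$test_window[1], config$test_window[2]),
    sprintf("within_delays: %s", paste(config$within_delays, collapse = ",")),
    sprintf("between_delays: %s", paste(config$between_delays, collapse = ",")),
    sprintf("mfdfa_q: %s", paste(config$mfdfa$q, collapse = ",")),
    sprintf("mfdfa_detrend_order: %d", config$mfdfa$detrend_order),
    sprintf("bands: %s", paste(sprintf("%s:%g:%g", config$bands$band,
                                       config$bands$f_lo, config$bands$f_hi),
                               collapse = ",")),
    sprintf("taper_fraction: %g", config$taper_fraction),
    sprintf("minsplit: %d", config$minsplit),
    sprintf("cv_folds: %d", config$k),
    sprintf("seed: %d", config$seed),
    sprintf("subscores: %s", paste(config$subscores, collapse = ",")))
}
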