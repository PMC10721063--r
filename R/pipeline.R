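#' Assemble a pipeline configuration
#'
#' Collects every stage's tunables into one list with the package defaults:
#' one-hot flat encoding z-scored per family on training images and globally
#' elsewhere, a 128-point Hann-window bispectrum with 50% segment overlap,
#' two reference-small backbones trained by RMSProp, CCA + DCA fusion to
#' twice the class count, and a 50-tree soft-voting bagged ensemble.
#'
#' @param scenario `"split_70_30"`, `"split_70_10_20"`, or
#'   `"train_vs_test_features"`.
#' @param seed Global seed; every stage seed is derived from it.
#' @param records Optional tibble of records (`id`, `residues`, `family`).
#'   When `NULL`, the synthetic benchmark in `generator` is used.
#' @param generator Arguments for [generate_benchmark()].
#' @param encoding List: `scheme`, `norm` (`"family"`, `"global"`, `"none"`).
#' @param bispec List: `nfft`, `segment_length`, `overlap`, `window`. These
#'   are the defaults for every backbone's view; `backbones$views` can
#'   override them per backbone.
#' @param image List: `scale`, `colormap` (input size follows the backbone).
#' @param backbones List: `n_backbones`, `name`, `input_size`, `channels`,
#'   `epochs`, `batch_size`, `learning_rate`, and optionally `views`, a list
#'   of per-backbone bispectrum overrides, and `crops`, a list of fractional
#'   signal windows. The default gives the two backbones two genuinely
#'   different views of each sequence — a 128-point grid and a zero-padded
#'   256-point grid — so that canonical correlation fusion operates on
#'   complementary feature sets. Crops augment the training images with
#'   bispectra of sub-sequences and are averaged into the extracted features
#'   at prediction time (test-time augmentation); both uses are label-free.
#' @param fusion List: `d` (`NULL` = class count), `ridge`.
#' @param classifier List: `n_cycles`, `surrogate_splits`.
#' @param output_dir Optional directory for artifacts (reports, resolved
#'   config, fused features).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = c("split_70_30", "split_70_10_20",
                                         "train_vs_test_features"),
                            seed = 1L, records = NULL,
                            generator = list(k_families = 4L,
                                             n_per_family = 60L,
                                             separability = "easy"),
                            encoding = list(scheme = "onehot-flat",
                                            norm = "family"),
                            bispec = list(nfft = 128L, segment_length = 128L,
                                          overlap = 0.75, window = "hann"),
                            image = list(scale = "log1p",
                                         colormap = "gray"),
                            backbones = list(n_backbones = 2L,
                                             name = "reference-small",
                                             input_size = 32L,
                                             channels = c(8L, 16L, 32L),
                                             epochs = 20L,
                                             batch_size = 32L,
                                             learning_rate = 0.003,
                                             views = list(
                                               list(nfft = 128L),
                                               list(nfft = 256L)),
                                             crops = list(c(0, 0.7),
                                                          c(0.3, 1))),
                            fusion = list(d = NULL, ridge = 1e-6),
                            classifier = list(n_cycles = 50L,
                                              surrogate_splits = TRUE),
                            output_dir = NULL) {
  structure(list(scenario = match.arg(scenario), seed = as.integer(seed),
                 records = records, generator = generator,
                 encoding = encoding, bispec = bispec, image = image,
                 backbones = backbones, fusion = fusion,
                 classifier = classifier, output_dir = output_dir),
            class = "pipeline_config")
}

scenario_fractions <- function(scenario) {
  switch(scenario,
         split_70_30 = c(0.7, 0, 0.3),
         split_70_10_20 = c(0.7, 0.1, 0.2),
         train_vs_test_features = c(0.7, 0, 0.3))
}

# Encode and normalize all records: family statistics for training rows,
# global pooled statistics elsewhere (keeps inference label-free).
prepare_signals <- function(records, train, config) {
  enc <- encode_records(records, scheme = config$encoding$scheme)
  if (config$encoding$norm != "none") {
    norms <- fit_family_norms(enc[train, ])
    enc_train <- normalize_records(enc[train, ], norms,
                                   mode = config$encoding$norm)
    rest <- setdiff(seq_len(nrow(enc)), train)
    enc$signal[train] <- enc_train$signal
    if (length(rest)) {
      enc_rest <- normalize_records(enc[rest, ], norms, mode = "global")
      enc$signal[rest] <- enc_rest$signal
    }
  }
  enc
}

#' Turn records into bispectrum images
#'
#' Encodes, normalizes (family statistics for training rows, global pooled
#' statistics elsewhere, per `norm`), estimates each sequence's bispectrum
#' and renders it at the backbone input size.
#'
#' @param records Record tibble.
#' @param train Row indices whose families' statistics are fitted.
#' @param config A [pipeline_config()].
#' @param bispec_override Named list merged over `config$bispec` (a
#'   backbone's view settings).
#' @param crop Optional fractional window `(from, to)` of each signal.
#' @return List: `images` (H, W, 3, N array, values 0-255), `labels`.
#' @keywords internal
records_to_images <- function(records, train, config, bispec_override = NULL,
                              crop = NULL) {
  enc <- prepare_signals(records, train, config)
  list(images = signals_to_images(enc$signal, config, bispec_override, crop),
       labels = factor(records$family))
}

signals_to_images <- function(signals, config, bispec_override = NULL,
                              crop = NULL) {
  bp <- config$bispec
  bp[names(bispec_override)] <- bispec_override
  S <- config$backbones$input_size
  imgs <- array(0, c(S, S, 3L, length(signals)))
  for (i in seq_along(signals)) {
    s <- as.numeric(signals[[i]])
    if (!is.null(crop)) {
      L <- length(s)
      s <- s[(floor(crop[1] * L) + 1L):floor(crop[2] * L)]
    }
    B <- estimate_bispectrum(s, nfft = bp$nfft,
                             segment_length = bp$segment_length,
                             overlap = bp$overlap,
                             window = bp$window)
    imgs[, , , i] <- render_image(B, height = S, width = S,
                                  scale = config$image$scale,
                                  colormap = config$image$colormap)
  }
  imgs
}

#' Run the full classification pipeline
#'
#' Executes the end-to-end procedure under the configured scenario: encode,
#' transform to bispectrum images, train each backbone head on the training
#' split and extract per-backbone features for every sequence, fuse with
#' CCA + DCA fitted on training rows, train the bagged soft-voting ensemble
#' on the fused training rows, and evaluate. `split_70_10_20` returns both a
#' validation and a test report; `train_vs_test_features` returns train,
#' test, and pooled overall reports; `split_70_30` returns the test report.
#' Evaluation-row labels are touched only by the metrics stage. All
#' randomness derives from `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result`: list of `evaluation_report`s (`reports`),
#'   the `split`, the fused [feature_matrix()] (`fused`), the ensemble, and
#'   the config.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  records <- config$records
  if (is.null(records)) {
    records <- generate_benchmark(
      k_families = config$generator$k_families,
      n_per_family = config$generator$n_per_family,
      separability = config$generator$separability,
      seed = derive_seed(config$seed, 1L)
    )$records
  }
  split <- stratified_split(records, scenario_fractions(config$scenario),
                            seed = derive_seed(config$seed, 2L))
  views <- config$backbones$views %||% list(NULL)
  crops <- config$backbones$crops %||% list()
  n_bb <- config$backbones$n_backbones
  enc <- prepare_signals(records, split$train, config)
  labels_factor <- factor(records$family)
  n_classes <- nlevels(labels_factor)
  S <- config$backbones$input_size
  ntr <- length(split$train)
  n_versions <- 1L + length(crops)

  blocks <- list()
  stack_cache <- list()
  for (b in seq_len(n_bb)) {
    view <- views[[(b - 1L) %% length(views) + 1L]]
    key <- paste(deparse(view), collapse = "")
    if (is.null(stack_cache[[key]])) {
      # one image per record for the full signal plus each crop window
      stack_cache[[key]] <- c(
        list(signals_to_images(enc$signal, config, view)),
        lapply(crops, function(cr) {
          signals_to_images(enc$signal, config, view, crop = cr)
        })
      )
    }
    xs <- stack_cache[[key]]
    xtrain <- array(0, c(S, S, 3L, ntr * n_versions))
    for (k in seq_len(n_versions)) {
      xtrain[, , , ((k - 1L) * ntr + 1L):(k * ntr)] <-
        xs[[k]][, , , split$train, drop = FALSE]
    }
    ytrain <- factor(rep(as.character(labels_factor[split$train]),
                         n_versions),
                     levels = levels(labels_factor))
    model <- build_backbone(config$backbones$name,
                            n_classes = n_classes,
                            input_size = S,
                            seed = derive_seed(config$seed, 200L + b),
                            channels = config$backbones$channels %||%
                              c(8L, 16L, 32L))
    tc <- train_config(batch_size = config$backbones$batch_size,
                       epochs = config$backbones$epochs,
                       learning_rate = config$backbones$learning_rate,
                       seed = derive_seed(config$seed, 300L + b))
    model <- train_head(model, xtrain, ytrain, tc)
    # average the head activations over the full-signal and crop renderings
    feats <- Reduce(`+`, lapply(xs, function(x) extract_features(model, x))) /
      n_versions
    nm <- sprintf("%s%d", gsub("[^a-z0-9]+", "", config$backbones$name), b)
    blocks[[nm]] <- feats
  }
  features <- feature_matrix(blocks, as.character(labels_factor))

  fused <- fuse_pipeline(features, d = config$fusion$d, train = split$train,
                         ridge = config$fusion$ridge)
  vals <- fm_values(fused)
  labels <- fused$label

  ensemble <- train_bagging(vals[split$train, , drop = FALSE],
                            labels[split$train],
                            n_cycles = config$classifier$n_cycles,
                            surrogate_splits = config$classifier$surrogate_splits,
                            seed = derive_seed(config$seed, 4L))

  eval_set <- function(rows) {
    pr <- predict_soft(ensemble, vals[rows, , drop = FALSE])
    probs <- as.matrix(pr[, paste0(".prob_", ensemble$class_order)])
    colnames(probs) <- ensemble$class_order
    evaluation_report(labels[rows], as.character(pr$.pred), probs,
                      class_order = ensemble$class_order)
  }

  reports <- switch(config$scenario,
    split_70_30 = list(test = eval_set(split$test)),
    split_70_10_20 = list(validation = eval_set(split$validation),
                          test = eval_set(split$test)),
    train_vs_test_features = list(
      train = eval_set(split$train),
      test = eval_set(split$test),
      overall = eval_set(c(split$train, split$test))
    )
  )

  result <- structure(list(reports = reports, split = split, fused = fused,
                           ensemble = ensemble, config = config),
                      class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_artifacts(result)
  result
}

write_pipeline_artifacts <- function(result) {
  dir <- result$config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  cfg$records <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  readr::write_csv(as_tibble(result$fused), file.path(dir, "fused_features.csv"))
  for (nm in names(result$reports)) {
    rep <- result$reports[[nm]]
    readr::write_csv(tidy(rep), file.path(dir, paste0("report_", nm, ".csv")))
    jsonlite::write_json(list(accuracy = rep$accuracy, n = rep$n),
                         file.path(dir, paste0("report_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> scenario:", x$config$scenario,
      "| seed:", x$config$seed, "\n")
  for (nm in names(x$reports)) {
    cat(sprintf("  %-10s accuracy %.1f%% (n = %d)\n", nm,
                x$reports[[nm]]$accuracy, x$reports[[nm]]$n))
  }
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  bind_rows(imap(x$reports, function(r, nm) {
    bind_cols(tibble(report = nm), glance(r))
  }))
}
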