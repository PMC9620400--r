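#' Load a compiled training table
#'
#' Reads the wide training-table CSV dialect: one row per sequence with
#' columns `sequence`, `lambda_nm` (semicolon-delimited peak wavelengths)
#' and `brightness` (semicolon-delimited normalized brightnesses, matched
#' to the wavelengths).  An empty `lambda_nm` cell means no fitted peaks
#' (a Dark candidate).  Malformed rows are collected into an error report
#' with their line numbers rather than failing one at a time.
#'
#' @param path CSV path.
#' @return list with `records` (long data frame `sequence`, `lambda_nm`,
#'   `brightness`, one row per peak), `sequences` (every valid sequence,
#'   including peakless ones) and `errors` (data frame `line`, `message`).
#' @export
load_training_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) stop("empty training table: ", path, call. = FALSE)
  need <- c("sequence", "lambda_nm", "brightness")
  if (!all(need %in% names(raw)))
    stop("training table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  recs <- list(); seqs <- character(0)
  errors <- list()
  for (i in seq_len(nrow(raw))) {
    line <- i + 1L  # header is line 1
    s <- toupper(trimws(raw$sequence[i]))
    if (grepl("[^ACGT]", s) || !nzchar(s)) {
      errors[[length(errors) + 1L]] <-
        data.frame(line = line, message = paste0("invalid sequence '", s, "'"))
      next
    }
    lam_str <- trimws(raw$lambda_nm[i])
    bri_str <- trimws(raw$brightness[i])
    if (!nzchar(lam_str)) { seqs <- c(seqs, s); next }
    lam <- suppressWarnings(as.numeric(strsplit(lam_str, ";")[[1L]]))
    bri <- suppressWarnings(as.numeric(strsplit(bri_str, ";")[[1L]]))
    if (length(lam) != length(bri) || anyNA(lam) || anyNA(bri)) {
      errors[[length(errors) + 1L]] <-
        data.frame(line = line,
                   message = "unparseable or mismatched peak lists")
      next
    }
    seqs <- c(seqs, s)
    recs[[length(recs) + 1L]] <-
      data.frame(sequence = s, lambda_nm = lam, brightness = bri)
  }
  list(records = if (length(recs)) do.call(rbind, recs)
                 else data.frame(sequence = character(0),
                                 lambda_nm = numeric(0),
                                 brightness = numeric(0)),
       sequences = seqs,
       errors = if (length(errors)) do.call(rbind, errors)
                else data.frame(line = integer(0), message = character(0)))
}

#' Write a training table in the wide CSV dialect
#'
#' Inverse of [load_training_table()]: peak lists are joined with
#' semicolons, peakless sequences get empty cells.
#'
#' @param records long data frame (`sequence`, `lambda_nm`, `brightness`).
#' @param path output CSV path.
#' @param all_sequences optional sequences without peaks to include.
#' @return `path`, invisibly.
#' @export
write_training_table <- function(records, path, all_sequences = NULL) {
  seqs <- unique(c(records$sequence, all_sequences))
  per <- split(records, records$sequence)
  wide <- data.frame(
    sequence = seqs,
    lambda_nm = vapply(seqs, function(s) {
      p <- per[[s]]
      if (is.null(p)) "" else paste(format(p$lambda_nm, trim = TRUE,
                                           digits = 10), collapse = ";")
    }, character(1)),
    brightness = vapply(seqs, function(s) {
      p <- per[[s]]
      if (is.null(p)) "" else paste(format(p$brightness, trim = TRUE,
                                           digits = 10), collapse = ";")
    }, character(1)))
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted ensemble to JSON
#'
#' Weights, biases, feature order, configuration and seed are written at
#' full precision so a reloaded model reproduces pair probabilities
#' bit for bit.
#'
#' @param object a fitted [agn_ensemble()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "agn_ensemble"))
  payload <- list(
    format = "agndesign-ensemble/1",
    classes = object$classes,
    feature_names = object$feature_names,
    config = object$config,
    n_train = object$n_train,
    class_counts = object$class_counts,
    pair_models = lapply(object$pair_models, function(pm) {
      list(pair = pm$pair,
           members = lapply(pm$members, function(m)
             list(w = m$w, b = m$b, subsample = m$subsample)))
    }))
  # 17 significant digits: exact binary64 round-trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a fitted ensemble from JSON
#'
#' @param path path written by [write_model()].
#' @return an `agn_ensemble`.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  if (!identical(payload$format, "agndesign-ensemble/1"))
    stop("not an agndesign ensemble file: ", path, call. = FALSE)
  pair_models <- lapply(payload$pair_models, function(pm) {
    list(pair = as.character(pm$pair),
         members = lapply(pm$members, function(m)
           list(w = as.numeric(m$w), b = as.numeric(m$b),
                subsample = as.integer(m$subsample))))
  })
  structure(list(pair_models = pair_models,
                 classes = as.character(payload$classes),
                 feature_names = as.character(payload$feature_names),
                 config = payload$config,
                 n_train = payload$n_train,
                 class_counts = as.integer(payload$class_counts)),
            class = "agn_ensemble")
}

#' Pipeline configuration
#'
#' One nested configuration object covering every stage, with a lossless
#' YAML file representation.  Unknown keys in a config file are rejected.
#'
#' @param seed master seed for all stochastic stages.
#' @param n_synthetic records to simulate when no training table is given.
#' @param label_noise synthetic label-noise rate.
#' @param curation list of [curation_config()] overrides.
#' @param cost,n_subsamples training parameters.
#' @param n_cv_folds,n_cv_repeats cross-validation parameters.
#' @param importance_repeats,importance_trees importance parameters.
#' @param design_targets classes to design for.
#' @param design_k candidates kept per target.
#' @param design_L designed sequence length.
#' @return list of class `agn_config`.
#' @export
pipeline_config <- function(seed = 1, n_synthetic = 2000, label_noise = 0.02,
                            curation = list(), cost = 0.1, n_subsamples = 10,
                            n_cv_folds = 10, n_cv_repeats = 100,
                            importance_repeats = 10, importance_trees = 100,
                            design_targets = "NIR", design_k = 124,
                            design_L = 10) {
  structure(list(seed = seed, n_synthetic = n_synthetic,
                 label_noise = label_noise, curation = curation,
                 cost = cost, n_subsamples = n_subsamples,
                 n_cv_folds = n_cv_folds, n_cv_repeats = n_cv_repeats,
                 importance_repeats = importance_repeats,
                 importance_trees = importance_trees,
                 design_targets = design_targets, design_k = design_k,
                 design_L = design_L),
            class = "agn_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of key-value overrides for [pipeline_config()].
#' @return an `agn_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config an `agn_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full design pipeline
#'
#' Executes the stages in order: simulate (or load) a training table,
#' curate labels, train the ensemble, cross-validate, score feature
#' importance, and screen the design space for each target class.  All
#' artifacts are written under `out_dir` together with a run manifest
#' recording the tool version, config hash, seed, input fingerprints and
#' per-stage timings.  Identical config + seed give identical artifacts.
#'
#' @param config an [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param training_table optional path to a curated-input CSV
#'   ([load_training_table()] dialect); when `NULL`, a synthetic dataset is
#'   generated from the planted default rules.
#' @param stages character subset of
#'   `c("curate", "train", "cv", "importance", "design")` to run (earlier
#'   stages a later stage depends on always run).
#' @return list with the in-memory artifacts (`curation`, `model`, `cv`,
#'   `misa`, `nis`, `designs`) and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile(),
                         training_table = NULL,
                         stages = c("curate", "train", "cv", "importance",
                                    "design")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "agndesign",
                   version = as.character(utils::packageVersion("agndesign")),
                   config_hash = config_hash(config), seed = config$seed,
                   inputs = list(), timings = list())
  tic <- function() proc.time()[["elapsed"]]
  art <- list()
  curc <- do.call(curation_config, config$curation)

  t0 <- tic()
  if (is.null(training_table)) {
    rules <- rule_set(label_noise = config$label_noise)
    synth <- generate_dataset(rules, n = config$n_synthetic,
                              seed = config$seed)
    labeled <- synth$data[c("sequence", "label")]
    art$curation <- structure(list(
      labeled = labeled,
      excluded = data.frame(sequence = character(0), reason = character(0)),
      config = curc), class = "agn_curation")
    art$synth <- synth
  } else {
    manifest$inputs[[training_table]] <-
      unname(tools::md5sum(training_table))
    tab <- load_training_table(training_table)
    if (nrow(tab$errors) > 0L)
      warning(nrow(tab$errors), " malformed row(s) skipped", call. = FALSE)
    art$curation <- curate_training(tab$records,
                                    all_sequences = tab$sequences,
                                    config = curc)
    labeled <- art$curation$labeled
  }
  utils::write.csv(art$curation$labeled,
                   file.path(out_dir, "labeled.csv"), row.names = FALSE)
  utils::write.csv(art$curation$excluded,
                   file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  manifest$timings$curate <- tic() - t0
  message(sprintf("curate: %d labeled, %d excluded",
                  nrow(art$curation$labeled), nrow(art$curation$excluded)))

  feats <- staple_features(labeled$sequence)
  need_model <- any(c("train", "cv", "importance", "design") %in% stages)
  if (need_model) {
    t0 <- tic()
    art$model <- agn_ensemble(feats, labeled$label, cost = config$cost,
                              n_subsamples = config$n_subsamples,
                              seed = config$seed)
    write_model(art$model, file.path(out_dir, "model.json"))
    manifest$timings$train <- tic() - t0
    message(sprintf("train: %d classifiers",
                    length(art$model$pair_models) * config$n_subsamples))
  }
  if ("cv" %in% stages) {
    t0 <- tic()
    art$cv <- agn_cv(feats, labeled$label, cost = config$cost,
                     n_folds = config$n_cv_folds,
                     n_repeats = config$n_cv_repeats, seed = config$seed)
    utils::write.csv(art$cv$report, file.path(out_dir, "cv_report.csv"),
                     row.names = FALSE)
    manifest$timings$cv <- tic() - t0
    message(sprintf("cv: mean pair accuracy %.3f",
                    mean(art$cv$report$mean_accuracy)))
  }
  if ("importance" %in% stages) {
    t0 <- tic()
    art$misa <- shadow_importance(feats, labeled$label,
                                  n_repeats = config$importance_repeats,
                                  n_trees = config$importance_trees,
                                  seed = config$seed)
    utils::write.csv(as.data.frame(art$misa),
                     file.path(out_dir, "misa.csv"), row.names = FALSE)
    freqs <- class_frequencies(feats, labeled$label)
    art$nis <- net_importance(art$misa, freqs)
    nis_long <- data.frame(
      feature = rep(rownames(art$nis), ncol(art$nis)),
      class = rep(colnames(art$nis), each = nrow(art$nis)),
      nis = as.numeric(art$nis))
    utils::write.csv(nis_long, file.path(out_dir, "nis.csv"),
                     row.names = FALSE)
    manifest$timings$importance <- tic() - t0
    message(sprintf("importance: %d selected features",
                    length(unique(art$misa$feature[art$misa$selected]))))
  }
  if ("design" %in% stages) {
    t0 <- tic()
    art$designs <- lapply(config$design_targets, function(tg) {
      dn <- design_top_k(art$model, tg, k = config$design_k,
                         L = config$design_L)
      write_design(dn,
                   csv_path = file.path(out_dir,
                                        paste0("design_", tg, ".csv")),
                   fasta_path = file.path(out_dir,
                                          paste0("design_", tg, ".fasta")))
      dn
    })
    names(art$designs) <- config$design_targets
    manifest$timings$design <- tic() - t0
    message(sprintf("design: %d target(s) x top %d",
                    length(config$design_targets), config$design_k))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  art$manifest <- manifest
  invisible(art)
}
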