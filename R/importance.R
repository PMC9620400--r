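#' Shadow-feature importance for every class pair
#'
#' For each class pair, repeats the following `n_repeats` times: draw a
#' balanced subsample, append one randomly permuted "shadow" copy of every
#' real feature column, fit a random-forest classifier (`n_trees` trees),
#' and record each real feature's importance together with the maximum
#' importance attained by any shadow column.  A feature's MISA record is
#' the mean and standard deviation of its importance over repeats, compared
#' against the mean of the per-repeat maximum shadow importance.
#' Importance is the forest's impurity-decrease attribution.
#'
#' Selection rule: a feature is selected when `misa_mean > max_shadow`;
#' for pairs containing NIR — where subsampling the tiny NIR class inflates
#' the variance of the estimate — the relaxed rule
#' `misa_mean + misa_sd >= max_shadow` is used.
#'
#' @param x sequences or staple-feature matrix.
#' @param labels class labels.
#' @param n_repeats forest fits per pair, one per balanced subsample
#'   (default 10).
#' @param n_trees trees per forest (default 100).
#' @param seed integer seed.
#' @param classes class universe (default the five color classes).
#' @return object of class `agn_misa`: data frame with columns `feature`,
#'   `pair`, `misa_mean`, `misa_sd`, `max_shadow`, `selected`.
#' @export
shadow_importance <- function(x, labels, n_repeats = 10, n_trees = 100,
                              seed = 1, classes = AGN_CLASSES) {
  feats <- as_feature_matrix(x)
  labels <- as.character(labels)
  present <- classes[classes %in% labels]
  pairs <- class_pairs(present)
  pair_seeds <- derive_seeds(seed, length(pairs))
  out <- list()
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    rows <- which(labels %in% pr)
    rec <- shadow_importance_pair(feats[rows, , drop = FALSE], labels[rows],
                                  pr, n_repeats, n_trees, pair_seeds[pi])
    out[[pair_key(pr)]] <- rec
  }
  records <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  structure(records, class = c("agn_misa", "data.frame"))
}

shadow_importance_pair <- function(feats, labels, pair, n_repeats, n_trees,
                                   seed) {
  if (length(unique(labels)) < 2L)
    stop("constant labels for pair ", pair_key(pair), call. = FALSE)
  nf <- ncol(feats)
  sub_idx <- balanced_subsamples(labels, n = n_repeats, seed = seed)
  rep_seeds <- derive_seeds(seed + 1L, n_repeats)
  imp <- matrix(NA_real_, nrow = n_repeats, ncol = nf)
  max_shadow <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    ri <- sub_idx[[r]]
    xr <- feats[ri, , drop = FALSE]
    with_seed(rep_seeds[r], {
      shadow <- apply(xr, 2L, sample)
      colnames(shadow) <- paste0("shadow_", colnames(xr))
      df <- as.data.frame(cbind(xr, shadow))
      df$.y <- factor(labels[ri])
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = n_trees, importance = "impurity",
        seed = sample.int(.Machine$integer.max, 1),
        num.threads = 1)
      iv <- fit$variable.importance
      imp[r, ] <- iv[seq_len(nf)]
      max_shadow[r] <- max(iv[nf + seq_len(nf)])
    })
  }
  rec <- data.frame(
    feature = colnames(feats),
    pair = pair_key(pair),
    misa_mean = colMeans(imp),
    misa_sd = apply(imp, 2L, stats::sd),
    max_shadow = mean(max_shadow))
  rec$selected <- select_rule(rec, nir_pair = "NIR" %in% pair)
  rec
}

select_rule <- function(rec, nir_pair) {
  if (nir_pair) rec$misa_mean + rec$misa_sd >= rec$max_shadow
  else rec$misa_mean > rec$max_shadow
}

#' Features selected as important for one class pair
#'
#' @param records an `agn_misa` table from [shadow_importance()].
#' @param pair two class names.
#' @return character vector of selected feature names.
#' @export
select_important <- function(records, pair) {
  key <- pair_key(pair)
  alt <- pair_key(rev(pair))
  rec <- records[records$pair %in% c(key, alt), , drop = FALSE]
  if (nrow(rec) == 0L) stop("no records for pair ", key, call. = FALSE)
  rec$feature[rec$selected]
}

#' Per-class mean staple-feature counts
#'
#' The class frequency table feeding the net-importance sign rule:
#' `freq[c, f]` is the mean count of feature f per sequence within class c,
#' computed on the curated training set.
#'
#' @param x sequences or staple-feature matrix.
#' @param labels class labels.
#' @return numeric matrix, classes x features.
#' @export
class_frequencies <- function(x, labels) {
  feats <- as_feature_matrix(x)
  labels <- as.character(labels)
  cls <- AGN_CLASSES[AGN_CLASSES %in% labels]
  out <- t(vapply(cls, function(cl)
    colMeans(feats[labels == cl, , drop = FALSE]),
    numeric(ncol(feats))))
  rownames(out) <- cls
  out
}

#' Net importance scores per feature and color class
#'
#' Aggregates a feature's four pairwise MISA values into one signed score
#' per color class: for class c, sum over the four pairs (c, o) of
#' `sign(freq_c(f) - freq_o(f)) * misa_mean(f, pair)`.  A positive NIS
#' means the feature both matters to the pair classifiers and is enriched
#' in class c; a negative NIS means it matters and is depleted.  Equal
#' frequencies contribute zero.
#'
#' @param records an `agn_misa` table covering all pairs.
#' @param freqs class-frequency matrix from [class_frequencies()].
#' @return object of class `agn_nis`: numeric matrix, features x classes.
#' @export
net_importance <- function(records, freqs) {
  classes <- rownames(freqs)
  feats <- unique(records$feature)
  nis <- matrix(0, nrow = length(feats), ncol = length(classes),
                dimnames = list(feats, classes))
  have <- unique(records$pair)
  need <- vapply(class_pairs(classes), pair_key, character(1))
  if (!all(need %in% have))
    stop("missing pair record(s): ",
         paste(setdiff(need, have), collapse = ", "), call. = FALSE)
  for (key in need) {
    pr <- strsplit(key, "|", fixed = TRUE)[[1L]]
    rec <- records[records$pair == key, , drop = FALSE]
    mm <- rec$misa_mean[match(feats, rec$feature)]
    s <- sign(freqs[pr[1L], feats] - freqs[pr[2L], feats])
    nis[, pr[1L]] <- nis[, pr[1L]] + s * mm
    nis[, pr[2L]] <- nis[, pr[2L]] - s * mm
  }
  structure(nis, class = c("agn_nis", "matrix", "array"))
}

#' Top staple features ranked by net importance
#'
#' Ranks features by the largest absolute NIS across classes, descending,
#' with ties broken by feature name.
#'
#' @param nis an `agn_nis` matrix from [net_importance()].
#' @param n number of features to return (default 15).
#' @return data frame: `feature`, `max_abs_nis`, then one signed NIS column
#'   per class.
#' @export
top_features <- function(nis, n = 15) {
  if (nrow(nis) == 0L) stop("empty NIS table", call. = FALSE)
  max_abs <- apply(abs(nis), 1L, max)
  o <- order(-max_abs, rownames(nis))
  take <- utils::head(o, n)
  out <- data.frame(feature = rownames(nis)[take],
                    max_abs_nis = max_abs[take])
  out <- cbind(out, as.data.frame(unclass(nis)[take, , drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' @export
print.agn_misa <- function(x, ...) {
  cat("Shadow-feature importance records:",
      length(unique(x$feature)), "features x",
      length(unique(x$pair)), "pairs;",
      sum(x$selected), "selections\n")
  print.data.frame(utils::head(x[order(-x$misa_mean), ], 10), digits = 3)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
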