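#' Balanced subsamples of a two-class table
#'
#' For an imbalanced class pair, draws `n` index sets in which the larger
#' class is randomly subsampled (without replacement) down to the size of
#' the smaller class.  Minority rows are identical across draws; each draw
#' uses a different random majority subset.  When the classes are already
#' equal-sized every draw is the full row set.
#'
#' @param labels two-level factor or character vector.
#' @param n number of subsamples (default 10).
#' @param seed integer seed; draws are reproducible from it.
#' @return list of `n` integer index vectors into `labels`, each balanced.
#' @export
balanced_subsamples <- function(labels, n = 10, seed = 1) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L)
    stop("expected exactly two classes, got ", length(lev), call. = FALSE)
  idx <- split(seq_along(labels), labels)
  sizes <- lengths(idx)
  if (any(sizes < 2L))
    stop("class '", names(sizes)[which.min(sizes)],
         "' has fewer than 2 members", call. = FALSE)
  minority <- names(which.min(sizes))
  majority <- setdiff(names(sizes), minority)
  m <- sizes[[minority]]
  seeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(i) {
    maj <- if (sizes[[majority]] == m) idx[[majority]]
           else with_seed(seeds[i], sample(idx[[majority]], m))
    sort(c(idx[[minority]], maj))
  })
}

# one L1-regularized linear margin classifier.  The penalty strength is
# expressed as a cost c (larger c = weaker penalty), mapped onto the
# glmnet lambda by lambda = 1 / (n * c) so the loss/penalty balance matches
# the usual "C * sum(loss) + ||w||_1" parameterization.  Features enter
# unscaled: staple counts share a common 0-9 scale and standardization
# would dilute the sparsity pattern.
fit_member <- function(x, y01, cost = 0.1) {
  n <- nrow(x)
  lambda <- 1 / (n * cost)
  fit <- glmnet::glmnet(x, y01, family = "binomial", alpha = 1,
                        lambda = lambda, standardize = FALSE)
  list(w = as.numeric(fit$beta), b = as.numeric(fit$a0))
}

member_margin <- function(member, x) {
  as.numeric(x %*% member$w) + member$b
}

#' Fit the one-versus-one color-class ensemble
#'
#' The central model: for each unordered pair of the five color classes
#' (Dark, Green, Red, Far Red, NIR — 10 pairs), `n_subsamples` L1-penalized
#' linear classifiers are trained, each on a different class-balanced
#' random subsample, giving `10 x n_subsamples = 100` members by default.
#' A pair's probability for its first class is the average over its members
#' of the logistic-calibrated decision margin, and consensus prediction
#' assigns the class whose worst (minimum) pairwise probability is largest.
#'
#' @param x DNA sequences (character vector) or a staple-feature count
#'   matrix as produced by [staple_features()].
#' @param labels color-class labels, one per row/sequence.
#' @param cost regularization cost c (default 0.1; smaller = sparser).
#' @param n_subsamples balanced subsamples per class pair (default 10).
#' @param seed integer seed driving all subsampling (default 1).
#' @param classes class universe and canonical order (default the five
#'   color classes); every class must have at least 2 members.
#' @return object of class `agn_ensemble`: per-pair member weights, the
#'   feature order, and training metadata.  Methods: [predict.agn_ensemble()],
#'   `print`, `summary`, `coef`.
#' @examples
#' \donttest{
#' synth <- generate_dataset(n = 500, seed = 7)
#' fit <- agn_ensemble(synth$data$sequence, synth$data$label, seed = 7)
#' predict(fit, "GGGGGACCCC")
#' }
#' @export
agn_ensemble <- function(x, labels, cost = 0.1, n_subsamples = 10,
                         seed = 1, classes = AGN_CLASSES) {
  feats <- as_feature_matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(feats))
    stop("length(labels) != number of rows", call. = FALSE)
  missing_cls <- setdiff(unique(labels), classes)
  if (length(missing_cls) > 0L)
    stop("unknown class label(s): ", paste(missing_cls, collapse = ", "),
         call. = FALSE)
  present <- classes[classes %in% labels]
  counts <- table(factor(labels, levels = present))
  if (any(counts < 2L))
    stop("every class needs >= 2 members; deficient: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  pairs <- class_pairs(present)
  pair_seeds <- derive_seeds(seed, length(pairs))
  pair_models <- list()
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    rows <- which(labels %in% pr)
    sub_idx <- balanced_subsamples(labels[rows], n = n_subsamples,
                                   seed = pair_seeds[pi])
    members <- lapply(seq_len(n_subsamples), function(i) {
      ri <- rows[sub_idx[[i]]]
      y01 <- as.integer(labels[ri] == pr[1L])  # 1 = first class of the pair
      m <- fit_member(feats[ri, , drop = FALSE], y01, cost = cost)
      m$subsample <- i
      m
    })
    pair_models[[pair_key(pr)]] <- list(pair = pr, members = members)
  }
  structure(list(
    pair_models = pair_models,
    classes = present,
    feature_names = colnames(feats),
    config = list(cost = cost, n_subsamples = n_subsamples, seed = seed),
    n_train = nrow(feats),
    class_counts = as.integer(counts)),
    class = "agn_ensemble")
}

#' Average pairwise probability for one class pair
#'
#' Each member's signed decision margin d is mapped through the logistic
#' function p = 1 / (1 + exp(-d)) and the `n_subsamples` member
#' probabilities are averaged.  The returned value is the probability of
#' `pair[1]`; the probability of `pair[2]` is its complement.
#'
#' @param object a fitted [agn_ensemble()].
#' @param pair character vector of two class names (either order).
#' @param x sequences or feature matrix.
#' @return numeric vector in \[0, 1\], one value per row of `x`.
#' @export
pair_probability <- function(object, pair, x) {
  feats <- as_feature_matrix(x, object$feature_names)
  key <- pair_key(sort_pair(object, pair))
  pm <- object$pair_models[[key]]
  if (is.null(pm)) stop("no model for pair ", paste(pair, collapse = " vs "),
                        call. = FALSE)
  p <- pair_member_probs(pm, feats)
  if (identical(pair[1L], pm$pair[1L])) p else 1 - p
}

# mean over a pair's members of the logistic-calibrated margin
pair_member_probs <- function(pm, feats) {
  mat <- sapply(pm$members, function(m) stats::plogis(member_margin(m, feats)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(feats))
  rowMeans(mat)
}

sort_pair <- function(object, pair) {
  ord <- match(pair, object$classes)
  if (any(is.na(ord))) stop("unknown class in pair: ",
                            paste(pair, collapse = ", "), call. = FALSE)
  pair[order(ord)]
}

# n x n_pairs matrix of first-class probabilities for all pairs
all_pair_probabilities <- function(object, feats) {
  keys <- names(object$pair_models)
  out <- vapply(keys, function(k) {
    pair_member_probs(object$pair_models[[k]], feats)
  }, numeric(nrow(feats)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L, dimnames = list(NULL, keys))
  out
}

# per-class consensus score: minimum over the class's pairs of its average
# probability (shared scoring rule between prediction and design)
consensus_scores <- function(object, pair_probs) {
  classes <- object$classes
  scores <- matrix(NA_real_, nrow = nrow(pair_probs), ncol = length(classes),
                   dimnames = list(NULL, classes))
  for (cl in classes) {
    cols <- vapply(object$pair_models, function(pm) cl %in% pm$pair, logical(1))
    mat <- vapply(names(object$pair_models)[cols], function(k) {
      pm <- object$pair_models[[k]]
      p <- pair_probs[, k]
      if (identical(pm$pair[1L], cl)) p else 1 - p
    }, numeric(nrow(pair_probs)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(pair_probs))
    scores[, cl] <- apply(mat, 1L, min)
  }
  scores
}

#' Predict color classes by ensemble consensus
#'
#' @param object a fitted [agn_ensemble()].
#' @param newdata sequences or staple-feature matrix.
#' @param ... unused.
#' @return data frame with `class` (consensus: the class whose minimum
#'   pairwise probability is largest; ties broken by canonical class order,
#'   lowest first, and flagged in `tie`), one `score_<class>` column per
#'   class, and one `p_<pair>` column per class pair (probability of the
#'   pair's first class).
#' @export
predict.agn_ensemble <- function(object, newdata, ...) {
  feats <- as_feature_matrix(newdata, object$feature_names)
  pp <- all_pair_probabilities(object, feats)
  sc <- consensus_scores(object, pp)
  best <- apply(sc, 1L, function(r) which.max(r))  # first max = lowest class
  tie <- apply(sc, 1L, function(r) sum(r == max(r)) > 1L)
  out <- data.frame(class = object$classes[best], tie = tie)
  colnames(sc) <- paste0("score_", colnames(sc))
  colnames(pp) <- paste0("p_", gsub("|", ".", colnames(pp), fixed = TRUE))
  cbind(out, as.data.frame(sc), as.data.frame(pp))
}

#' @export
print.agn_ensemble <- function(x, ...) {
  n_members <- sum(vapply(x$pair_models, function(pm) length(pm$members),
                          integer(1)))
  cat("One-versus-one color-class ensemble\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  %d pairs x %d subsamples = %d linear classifiers\n",
              length(x$pair_models), x$config$n_subsamples, n_members))
  cat(sprintf("  cost c = %g, trained on %d sequences, seed %d\n",
              x$config$cost, x$n_train, x$config$seed))
  invisible(x)
}

#' @export
summary.agn_ensemble <- function(object, ...) {
  sparsity <- vapply(object$pair_models, function(pm) {
    w <- vapply(pm$members, function(m) mean(m$w == 0), numeric(1))
    mean(w)
  }, numeric(1))
  out <- data.frame(pair = names(sparsity),
                    zero_weight_fraction = as.numeric(sparsity))
  rownames(out) <- NULL
  print(object)
  cat("\nWeight sparsity by pair (fraction of exactly-zero weights):\n")
  print(out, digits = 3)
  invisible(out)
}

#' @export
coef.agn_ensemble <- function(object, ...) {
  lapply(object$pair_models, function(pm) {
    w <- vapply(pm$members, function(m) m$w,
                numeric(length(object$feature_names)))
    rownames(w) <- object$feature_names
    list(weights = w, bias = vapply(pm$members, function(m) m$b, numeric(1)))
  })
}

#' Repeated stratified cross-validation of every class pair
#'
#' For each class pair and each repeat: draw a fresh balanced subsample,
#' split it into `n_folds` class-stratified folds, train on all but one
#' fold, score accuracy on the held-out fold, and average over folds.
#' The report gives the mean and standard deviation of the per-repeat
#' accuracy, capturing the variability induced by subsampling.
#'
#' @param x sequences or staple-feature matrix.
#' @param labels class labels.
#' @param cost regularization cost (default 0.1).
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats random fold/subsample draws (default 100).
#' @param seed integer seed.
#' @param classes class universe (default the five color classes).
#' @return object of class `agn_cv`: data frame with `pair`, `mean_accuracy`,
#'   `sd_accuracy`, `n_per_class`.  Pairs with a class smaller than
#'   `n_folds` are skipped with a warning.
#' @export
agn_cv <- function(x, labels, cost = 0.1, n_folds = 10, n_repeats = 100,
                   seed = 1, classes = AGN_CLASSES) {
  feats <- as_feature_matrix(x)
  labels <- as.character(labels)
  present <- classes[classes %in% labels]
  pairs <- class_pairs(present)
  pair_seeds <- derive_seeds(seed, length(pairs))
  rows_out <- list()
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    rows <- which(labels %in% pr)
    m <- min(table(labels[rows]))
    if (m < n_folds) {
      warning("skipping pair ", paste(pr, collapse = " vs "),
              ": smallest class (", m, ") < n_folds", call. = FALSE)
      next
    }
    accs <- cv_pair(feats[rows, , drop = FALSE], labels[rows], pr, cost,
                    n_folds, n_repeats, pair_seeds[pi])
    rows_out[[pair_key(pr)]] <- data.frame(
      pair = pair_key(pr), mean_accuracy = mean(accs),
      sd_accuracy = stats::sd(accs), n_per_class = m)
  }
  report <- do.call(rbind, c(rows_out, list(make.row.names = FALSE)))
  structure(list(report = report,
                 config = list(cost = cost, n_folds = n_folds,
                               n_repeats = n_repeats, seed = seed)),
            class = "agn_cv")
}

cv_pair <- function(feats, labels, pair, cost, n_folds, n_repeats, seed) {
  rep_seeds <- derive_seeds(seed, n_repeats)
  vapply(seq_len(n_repeats), function(r) {
    with_seed(rep_seeds[r], {
      bal <- balanced_subsamples(labels, n = 1,
                                 seed = sample.int(.Machine$integer.max, 1))[[1]]
      xb <- feats[bal, , drop = FALSE]
      yb <- as.integer(labels[bal] == pair[1L])
      # stratified folds: permute within class, deal out round-robin
      fold <- integer(length(yb))
      for (cls in c(0L, 1L)) {
        i <- which(yb == cls)
        fold[i][sample.int(length(i))] <- rep_len(seq_len(n_folds), length(i))
      }
      fold_acc <- vapply(seq_len(n_folds), function(f) {
        tr <- fold != f
        if (length(unique(yb[tr])) < 2L) return(NA_real_)
        mem <- fit_member(xb[tr, , drop = FALSE], yb[tr], cost = cost)
        pred <- as.integer(member_margin(mem, xb[!tr, , drop = FALSE]) > 0)
        mean(pred == yb[!tr])
      }, numeric(1))
      mean(fold_acc, na.rm = TRUE)
    })
  }, numeric(1))
}

#' @export
print.agn_cv <- function(x, ...) {
  cat(sprintf("Repeated %d-fold cross-validation (%d repeats, cost %g)\n",
              x$config$n_folds, x$config$n_repeats, x$config$cost))
  print(x$report, digits = 3)
  invisible(x)
}
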