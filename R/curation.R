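AGN_CLASSES <- c("Dark", "Green", "Red", "FarRed", "NIR")

#' Curation configuration
#'
#' Class boundaries and brightness thresholds used to turn fitted emission
#' peaks into color-class labels.  The wavelength intervals are Green
#' (lambda_p < 580 nm), an excluded gap (580-600 nm, where the cluster magic
#' number is unknown), Red (600-660 nm), Far Red (660-800 nm) and NIR
#' (> 800 nm); boundary equality goes to the longer-wavelength side of each
#' open lower bound (Red is (600, 660], Far Red (660, 800], NIR
#' (800, Inf)).  A peak is "bright" if its normalized brightness reaches
#' `bright_threshold`; peaks between `dim_fraction * bright_threshold` and
#' `bright_threshold` are "mediocre" and cause the sequence to be excluded
#' from training.
#'
#' @param green_max,gap_max,red_max,farred_max class boundaries in nm.
#' @param bright_threshold normalized brightness at or above which a peak
#'   counts as bright (default 0.15, relative to the plate control).
#' @param dim_fraction lower edge of the mediocre band as a fraction of
#'   `bright_threshold` (default 0.5).
#' @param nir_overrides_training if `TRUE`, a sequence with any bright NIR
#'   peak is labeled NIR regardless of bright peaks in other classes (the
#'   rule used when compiling NIR libraries measured on a separate
#'   instrument); if `FALSE` (default) the multiclass-exclusion rule applies
#'   to all classes alike.
#' @return a list of class `agn_curation_config`.
#' @export
curation_config <- function(green_max = 580, gap_max = 600, red_max = 660,
                            farred_max = 800, bright_threshold = 0.15,
                            dim_fraction = 0.5,
                            nir_overrides_training = FALSE) {
  b <- c(green_max, gap_max, red_max, farred_max)
  if (any(diff(b) <= 0))
    stop("class boundaries must be strictly increasing", call. = FALSE)
  if (bright_threshold <= 0) stop("bright_threshold must be > 0", call. = FALSE)
  if (dim_fraction <= 0 || dim_fraction > 1)
    stop("dim_fraction must be in (0, 1]", call. = FALSE)
  structure(list(green_max = green_max, gap_max = gap_max, red_max = red_max,
                 farred_max = farred_max,
                 bright_threshold = bright_threshold,
                 dim_fraction = dim_fraction,
                 nir_overrides_training = nir_overrides_training),
            class = "agn_curation_config")
}

#' Assign a color class to a peak wavelength
#'
#' @param lambda_nm peak wavelength(s), nm.
#' @param config a [curation_config()].
#' @return character vector over `Dark/Green/Red/FarRed/NIR` plus the
#'   gap marker `"gap"` for wavelengths inside the excluded 580-600 nm band.
#' @examples
#' classify_peak(c(550, 590, 630, 700, 1041))
#' @export
classify_peak <- function(lambda_nm, config = curation_config()) {
  if (any(lambda_nm <= 0)) stop("lambda must be positive", call. = FALSE)
  out <- character(length(lambda_nm))
  out[lambda_nm < config$green_max] <- "Green"
  out[lambda_nm >= config$green_max & lambda_nm <= config$gap_max] <- "gap"
  out[lambda_nm > config$gap_max & lambda_nm <= config$red_max] <- "Red"
  out[lambda_nm > config$red_max & lambda_nm <= config$farred_max] <- "FarRed"
  out[lambda_nm > config$farred_max] <- "NIR"
  out
}

# split a peak table row set into bright / mediocre / dim given config
peak_brightness_band <- function(brightness, config) {
  ifelse(brightness >= config$bright_threshold, "bright",
         ifelse(brightness >= config$dim_fraction * config$bright_threshold,
                "mediocre", "dim"))
}

#' Curate a training set from sequences and fitted peaks
#'
#' Applies the training-set rules: the label of a sequence is the class of
#' its brightest bright peak; sequences with no bright peak (and no mediocre
#' peak) are Dark; sequences whose bright peaks span two or more color
#' classes are excluded (`"multiclass"`); sequences whose brightest peak
#' falls in the 580-600 nm gap are excluded (`"gap"`); sequences whose
#' strongest peak is of mediocre brightness are excluded (`"mediocre"`).
#' With `nir_overrides_training = TRUE` in the config, a bright NIR peak
#' forces the NIR label and exempts the sequence from the multiclass rule.
#'
#' @param records data frame with columns `sequence`, `lambda_nm`,
#'   `brightness`: one row per fitted peak, zero rows for a sequence mean it
#'   is only present via `all_sequences`.
#' @param all_sequences optional character vector of every measured
#'   sequence, so sequences with no fitted peaks are labeled Dark.
#' @param config a [curation_config()].
#' @return list of class `agn_curation` with `labeled` (data frame
#'   `sequence`, `label`), `excluded` (data frame `sequence`, `reason`) and
#'   the `config`.  Every input sequence appears in exactly one of the two
#'   frames.
#' @export
curate_training <- function(records, all_sequences = NULL,
                            config = curation_config()) {
  stopifnot(all(c("sequence", "lambda_nm", "brightness") %in% names(records)))
  seqs <- unique(c(records$sequence, all_sequences))
  seqs <- validate_sequences(seqs)
  records$sequence <- toupper(records$sequence)

  per_seq <- split(records[c("lambda_nm", "brightness")], records$sequence)
  labels <- character(0); label_seq <- character(0)
  excl <- character(0); excl_seq <- character(0)
  for (s in seqs) {
    pk <- per_seq[[s]]
    res <- curate_one(pk, config)
    if (res$kind == "label") {
      label_seq <- c(label_seq, s); labels <- c(labels, res$value)
    } else {
      excl_seq <- c(excl_seq, s); excl <- c(excl, res$value)
    }
  }
  structure(list(
    labeled = data.frame(sequence = label_seq, label = labels),
    excluded = data.frame(sequence = excl_seq, reason = excl),
    config = config), class = "agn_curation")
}

curate_one <- function(pk, config) {
  if (is.null(pk) || nrow(pk) == 0L)
    return(list(kind = "label", value = "Dark"))
  band <- peak_brightness_band(pk$brightness, config)
  bright <- pk[band == "bright", , drop = FALSE]
  if (nrow(bright) == 0L) {
    if (any(band == "mediocre"))
      return(list(kind = "excluded", value = "mediocre"))
    return(list(kind = "label", value = "Dark"))
  }
  cls <- classify_peak(bright$lambda_nm, config)
  top <- which.max(bright$brightness)
  if (config$nir_overrides_training && any(cls == "NIR"))
    return(list(kind = "label", value = "NIR"))
  real <- unique(cls[cls != "gap"])
  if (length(real) >= 2L)
    return(list(kind = "excluded", value = "multiclass"))
  if (cls[top] == "gap")
    return(list(kind = "excluded", value = "gap"))
  list(kind = "label", value = cls[top])
}

#' @export
print.agn_curation <- function(x, ...) {
  cat("Curated training set:", nrow(x$labeled), "labeled,",
      nrow(x$excluded), "excluded\n")
  print(table(factor(x$labeled$label, levels = AGN_CLASSES)))
  if (nrow(x$excluded) > 0L) {
    cat("Exclusions:\n"); print(table(x$excluded$reason))
  }
  invisible(x)
}

#' Judge a designed sequence against its target color class
#'
#' Design-outcome rules differ from training curation: for a visible target
#' (Green, Red, Far Red) the design succeeds if the brightest bright peak
#' falls in the target class; for an NIR target it succeeds if *any* bright
#' NIR peak exists, because NIR emission is read on a separate detector and
#' cannot be brightness-ranked against visible peaks.  A sequence with both
#' a bright NIR peak and bright visible peaks carries both labels.
#'
#' @param peaks data frame with `lambda_nm` and `brightness` for the fitted
#'   peaks of one well (normalized).
#' @param target one of Green, Red, FarRed, NIR.
#' @param config a [curation_config()].
#' @return list with `success` (logical) and `labels` (character vector;
#'   `"Dark"` when no bright peak).
#' @export
evaluate_design_outcome <- function(peaks, target,
                                    config = curation_config()) {
  target <- match.arg(target, c("Green", "Red", "FarRed", "NIR"))
  if (is.null(peaks) || nrow(peaks) == 0L)
    return(list(success = FALSE, labels = "Dark"))
  bright <- peaks[peaks$brightness >= config$bright_threshold, , drop = FALSE]
  if (nrow(bright) == 0L)
    return(list(success = FALSE, labels = "Dark"))
  cls <- classify_peak(bright$lambda_nm, config)
  vis <- bright[cls %in% c("Green", "Red", "FarRed"), , drop = FALSE]
  vis_cls <- cls[cls %in% c("Green", "Red", "FarRed")]
  labels <- character(0)
  if (any(cls == "NIR")) labels <- "NIR"
  if (nrow(vis) > 0L)
    labels <- c(labels, vis_cls[which.max(vis$brightness)])
  if (length(labels) == 0L) labels <- "Dark"  # only gap peaks
  success <- if (target == "NIR") "NIR" %in% labels
             else length(labels) > 0L && labels[length(labels)] == target &&
                  nrow(vis) > 0L
  list(success = success, labels = labels)
}

#' Exact 1-D k-means and class cutoffs
#'
#' Clusters a set of peak wavelengths into `k` groups by minimizing
#' within-cluster squared deviation.  In one dimension the optimum is a
#' partition of the sorted values into contiguous blocks, found here exactly
#' by dynamic programming over split points — deterministic, with no
#' dependence on starting centroids.  Midpoints between consecutive
#' centroids are the natural class cutoffs.
#'
#' @param lambda_nm numeric vector of peak wavelengths (any 1-D sample).
#' @param k number of clusters (>= 2).
#' @return list of class `agn_cutoffs`: `centroids` (ascending),
#'   `midpoints` (length k-1), `sizes`, `withinss`, `k`.
#' @examples
#' kmeans_cutoffs(c(rep(500, 5), rep(900, 5)), k = 2)
#' @export
kmeans_cutoffs <- function(lambda_nm, k = 4) {
  if (!is.numeric(k) || k < 2) stop("k must be >= 2", call. = FALSE)
  k <- as.integer(k)
  x <- sort(lambda_nm[is.finite(lambda_nm)])
  if (length(x) < k) stop("need at least k values", call. = FALSE)
  # collapse ties to weighted unique values
  ux <- unique(x)
  w <- as.numeric(table(match(x, ux)))
  n <- length(ux)
  k_eff <- min(k, n)
  # prefix sums for O(1) weighted SSE of a block i..j
  cw <- c(0, cumsum(w))
  cwx <- c(0, cumsum(w * ux))
  cwx2 <- c(0, cumsum(w * ux^2))
  block_sse <- function(i, j) {
    sw <- cw[j + 1] - cw[i]
    sx <- cwx[j + 1] - cwx[i]
    sx2 <- cwx2[j + 1] - cwx2[i]
    sx2 - sx^2 / sw
  }
  # D[q, j]: optimal SSE of first j values in q clusters
  D <- matrix(Inf, nrow = k_eff, ncol = n)
  B <- matrix(0L, nrow = k_eff, ncol = n)  # backpointer: start of last block
  for (j in 1:n) { D[1, j] <- block_sse(1, j); B[1, j] <- 1L }
  if (k_eff > 1) for (q in 2:k_eff) {
    for (j in q:n) {
      i <- q:j  # last block starts at i
      costs <- D[q - 1, i - 1] + vapply(i, block_sse, numeric(1), j = j)
      best <- which.min(costs)
      D[q, j] <- costs[best]; B[q, j] <- i[best]
    }
  }
  # recover blocks: block q spans starts[q] .. ends[q]
  starts <- ends <- integer(k_eff)
  ends[k_eff] <- n
  for (q in k_eff:1) {
    starts[q] <- B[q, ends[q]]
    if (q > 1L) ends[q - 1L] <- starts[q] - 1L
  }
  centroids <- sizes <- withinss <- numeric(k_eff)
  for (q in 1:k_eff) {
    i0 <- starts[q]; j0 <- ends[q]
    sw <- cw[j0 + 1] - cw[i0]
    centroids[q] <- (cwx[j0 + 1] - cwx[i0]) / sw
    sizes[q] <- sw
    withinss[q] <- block_sse(i0, j0)
  }
  structure(list(centroids = centroids,
                 midpoints = (centroids[-1] + centroids[-k_eff]) / 2,
                 sizes = sizes, withinss = withinss, k = k_eff),
            class = "agn_cutoffs")
}

#' @export
print.agn_cutoffs <- function(x, ...) {
  cat("1-D k-means cutoffs (k =", x$k, ")\n")
  cat("  centroids:", paste(round(x$centroids, 1), collapse = ", "), "nm\n")
  cat("  midpoints:", paste(round(x$midpoints, 1), collapse = ", "), "nm\n")
  invisible(x)
}
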