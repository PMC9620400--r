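#' Planted staple-motif rule set
#'
#' The generative rule behind synthetic datasets: each color class c has a
#' linear score `intercept_c + sum(weight * count(motif))` over staple
#' features, and a sequence's noiseless label is the argmax of the five
#' class scores.  The default rules mirror the qualitative chemistry of the
#' real system — consecutive G pairs drive the long-wavelength (Far Red,
#' NIR) classes, C/G dimers drive Red, spaced C pairs drive Green, and
#' sequences rich in none of these stay Dark — and the default class
#' proportions mimic a real training library: Dark and Far Red large,
#' Green and Red moderate, NIR rare (3%).
#'
#' @param motifs named list (one entry per class) of named numeric weight
#'   vectors over staple-feature labels.
#' @param intercepts named numeric vector, one per class.
#' @param proportions named class proportions, summing to 1.
#' @param label_noise probability that a record's label is flipped to a
#'   uniformly drawn other class (default 0).
#' @return list of class `agn_rules`.
#' @export
rule_set <- function(motifs = NULL, intercepts = NULL, proportions = NULL,
                     label_noise = 0) {
  if (is.null(motifs))
    motifs <- list(
      Dark   = c(T_1T = 0.2),
      Green  = c(C_1C = 1.4, C_2C = 0.7),
      Red    = c(C_0G = 1.3, G_0C = 0.9),
      FarRed = c(G_1G = 1.4, G_2G = 0.8),
      NIR    = c(G_0G = 1.6))
  if (is.null(intercepts))
    intercepts <- c(Dark = 1.0, Green = 0, Red = 0, FarRed = 0, NIR = 0)
  if (is.null(proportions))
    proportions <- c(Dark = 0.40, Green = 0.12, Red = 0.15,
                     FarRed = 0.30, NIR = 0.03)
  classes <- names(motifs)
  stopifnot(length(classes) >= 2L,
            setequal(classes, names(intercepts)),
            setequal(classes, names(proportions)))
  if (any(lengths(motifs) < 1L))
    stop("every class needs at least one motif", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must sum to 1", call. = FALSE)
  if (label_noise < 0 || label_noise >= 1)
    stop("label_noise must be in [0, 1)", call. = FALSE)
  structure(list(classes = classes, motifs = motifs,
                 intercepts = intercepts[classes],
                 proportions = proportions[classes],
                 label_noise = label_noise),
            class = "agn_rules")
}

#' Serialize a rule set to JSON
#'
#' @param rules a [rule_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "agn_rules"))
  payload <- list(classes = rules$classes,
                  motifs = lapply(rules$motifs, as.list),
                  intercepts = as.list(rules$intercepts),
                  proportions = as.list(rules$proportions),
                  label_noise = rules$label_noise)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a rule set from JSON
#'
#' @param path path written by [write_rules()].
#' @return an `agn_rules` object.
#' @export
read_rules <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  rule_set(motifs = lapply(p$motifs, function(m) unlist(m)),
           intercepts = unlist(p$intercepts),
           proportions = unlist(p$proportions),
           label_noise = p$label_noise)
}

#' Class scores of sequences under a rule set
#'
#' @param seqs sequences or staple-feature matrix.
#' @param rules a [rule_set()].
#' @return numeric matrix, sequences x classes.
#' @export
rule_scores <- function(seqs, rules) {
  feats <- as_feature_matrix(seqs)
  sc <- vapply(rules$classes, function(cl) {
    w <- rules$motifs[[cl]]
    drop(feats[, names(w), drop = FALSE] %*% w) + rules$intercepts[[cl]]
  }, numeric(nrow(feats)))
  if (is.null(dim(sc)))
    sc <- matrix(sc, nrow = 1L, dimnames = list(NULL, rules$classes))
  sc
}

#' Noiseless labels under a rule set
#'
#' @inheritParams rule_scores
#' @return character vector: per sequence, the argmax class (first class in
#'   rule order on ties).
#' @export
rule_labels <- function(seqs, rules) {
  sc <- rule_scores(seqs, rules)
  rules$classes[apply(sc, 1L, which.max)]
}

# extract (x, m, y) from a motif label like "G_0G"
parse_motif <- function(label) {
  m <- regmatches(label, regexec("^([ACGT])_([0-9]+)([ACGT])$", label))[[1L]]
  if (length(m) != 4L) stop("bad motif label: ", label, call. = FALSE)
  list(x = m[2L], m = as.integer(m[3L]), y = m[4L])
}

# propose one sequence biased toward a class: random background with the
# class's strongest motif planted at a random feasible position
propose_sequence <- function(class, rules, L) {
  bg <- sample(AGN_BASES, L, replace = TRUE)
  if (class != rules$classes[1L] || rules$intercepts[[class]] <= 0) {
    w <- rules$motifs[[class]]
    mt <- parse_motif(names(w)[which.max(w)])
    if (mt$m + 2L <= L) {
      i <- sample.int(L - mt$m - 1L, 1L)
      bg[i] <- mt$x
      bg[i + mt$m + 1L] <- mt$y
    }
  }
  paste(bg, collapse = "")
}

#' Generate a labeled synthetic dataset with planted motif rules
#'
#' Sequences are drawn class-conditionally: per-class record counts are
#' fixed by quota from the rule set's proportions (so achieved proportions
#' track targets to rounding), and each record is obtained by rejection
#' sampling — propose a motif-biased random sequence, accept when the rule
#' set's argmax label equals the target class.  Label noise then flips each
#' label, independently with probability `label_noise`, to a uniformly
#' chosen other class.  The generator truth (rule set, true labels, seed)
#' travels with the dataset so downstream tests can assert against it.
#'
#' @param rules a [rule_set()] (default rules if omitted).
#' @param n number of records.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param L sequence length (default 10).
#' @param max_attempts rejection-sampling attempts per record before
#'   failing (default 1000).
#' @return object of class `agn_synth`: `data` (data frame `sequence`,
#'   `label`, `true_label`), `rules`, `seed`.
#' @examples
#' d <- generate_dataset(n = 200, seed = 1)
#' table(d$data$label)
#' @export
generate_dataset <- function(rules = rule_set(), n, seed = 1, L = 10,
                             max_attempts = 1000) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  # quota allocation: floor + largest remainders
  raw <- rules$proportions * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  with_seed(seed, {
    seqs <- character(n); true <- character(n)
    pos <- 1L
    for (cl in rules$classes) {
      need <- cnt[[cl]]
      got <- 0L
      attempts <- 0L
      while (got < need) {
        batch <- vapply(seq_len(min(4L * (need - got), 4096L)),
                        function(i) propose_sequence(cl, rules, L),
                        character(1))
        lab <- rule_labels(batch, rules)
        ok <- batch[lab == cl]
        take <- utils::head(ok, need - got)
        if (length(take) > 0L) {
          seqs[pos + got + seq_along(take) - 1L] <- take
          got <- got + length(take)
        }
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop("could not generate class '", cl,
               "': motifs too rare under the rule set", call. = FALSE)
      }
      true[pos + seq_len(need) - 1L] <- cl
      pos <- pos + need
    }
    label <- true
    if (rules$label_noise > 0) {
      flip <- stats::runif(n) < rules$label_noise
      if (any(flip)) {
        label[flip] <- vapply(true[flip], function(cl)
          sample(setdiff(rules$classes, cl), 1L), character(1),
          USE.NAMES = FALSE)
      }
    }
    perm <- sample.int(n)  # shuffle class blocks together
    structure(list(
      data = data.frame(sequence = seqs[perm], label = label[perm],
                        true_label = true[perm]),
      rules = rules, seed = seed), class = "agn_synth")
  })
}

#' @export
print.agn_synth <- function(x, ...) {
  cat("Synthetic planted-motif dataset:", nrow(x$data), "records, seed",
      x$seed, "\n")
  print(table(factor(x$data$label, levels = x$rules$classes)))
  invisible(x)
}

# class-interval lambda ranges used when emitting synthetic spectra;
# kept strictly inside the curation intervals so fit jitter cannot cross
# a class boundary
synth_lambda_range <- function(class) {
  switch(class,
         Green = c(480, 570), Red = c(610, 655), FarRed = c(670, 790),
         NIR = c(810, 1000),
         stop("no emission interval for class ", class, call. = FALSE))
}

#' Generate synthetic emission spectra for a dataset
#'
#' Each non-Dark record receives one Gaussian emission peak whose center
#' wavelength is drawn inside its class interval and whose normalized
#' brightness clears the bright threshold; Dark records get noise-only
#' spectra.  Additive Gaussian noise with standard deviation
#' `noise_sd` (relative to the reference amplitude) is applied throughout.
#'
#' @param dataset an `agn_synth` from [generate_dataset()].
#' @param noise_sd relative noise level (default 0.02).
#' @param grid wavelength grid, nm (default 400-1100 in 2 nm steps).
#' @param seed integer seed.
#' @param control_area reference (control emitter) peak area used to define
#'   normalized brightness (default 1).
#' @param brightness_range range of normalized peak brightness (area /
#'   `control_area`) for emissive records (default 0.2-1.2, comfortably
#'   above the default curation bright threshold of 0.15).
#' @return list with `spectra` (named list of `wavelength_nm`/`intensity`
#'   lists per record), `truth` (data frame `sequence`, `label`,
#'   `lambda_nm`, `area` with `NA` for Dark), `control_area`, `grid`.
#' @export
generate_spectra <- function(dataset, noise_sd = 0.02,
                             grid = seq(400, 1100, by = 2), seed = 1,
                             control_area = 1,
                             brightness_range = c(0.2, 1.2)) {
  stopifnot(inherits(dataset, "agn_synth"))
  d <- dataset$data
  n <- nrow(d)
  amp_ref <- 1
  with_seed(seed, {
    spectra <- vector("list", n)
    lam <- rep(NA_real_, n); area <- rep(NA_real_, n)
    e_grid <- HC_EV_NM / grid
    for (i in seq_len(n)) {
      y <- stats::rnorm(length(grid), 0, noise_sd * amp_ref)
      if (d$label[i] != "Dark") {
        rng <- synth_lambda_range(d$label[i])
        lam[i] <- stats::runif(1, rng[1L], rng[2L])
        sigma <- stats::runif(1, 0.03, 0.06)           # eV
        area[i] <- stats::runif(1, brightness_range[1L],
                                brightness_range[2L]) * control_area
        amp <- area[i] / (sigma * sqrt(2 * pi))
        y <- y + amp * exp(-(e_grid - HC_EV_NM / lam[i])^2 / (2 * sigma^2))
      }
      spectra[[i]] <- list(wavelength_nm = grid, intensity = y)
    }
    names(spectra) <- sprintf("well%04d", seq_len(n))
    list(spectra = spectra,
         truth = data.frame(well_id = names(spectra),
                            sequence = d$sequence, label = d$label,
                            lambda_nm = lam, area = area),
         control_area = control_area, grid = grid)
  })
}

#' Class-imbalance profile of a dataset
#'
#' @param dataset an `agn_synth` or a data frame with a `label` column.
#' @return data frame with `class`, `count`, `fraction` and `ratio`
#'   (largest class count / this class count; `Inf` for empty classes).
#' @export
imbalance_profile <- function(dataset) {
  d <- if (inherits(dataset, "agn_synth")) dataset$data else dataset
  classes <- if (inherits(dataset, "agn_synth")) dataset$rules$classes
             else AGN_CLASSES
  cnt <- table(factor(d$label, levels = classes))
  data.frame(class = names(cnt), count = as.integer(cnt),
             fraction = as.numeric(cnt) / nrow(d),
             ratio = max(cnt) / as.numeric(cnt))
}
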