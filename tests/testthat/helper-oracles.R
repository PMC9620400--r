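# Independent brute-force oracles used across tests.

# staple counts by explicit enumeration of ordered position pairs
oracle_staple <- function(seq, m_max = 8) {
  bases <- strsplit(seq, "")[[1]]
  L <- length(bases)
  counts <- stats::setNames(rep(0L, 16L * (m_max + 1L)), feature_names(m_max))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (j > i && j - i - 1L <= m_max) {
      lab <- sprintf("%s_%d%s", bases[i], j - i - 1L, bases[j])
      counts[lab] <- counts[lab] + 1L
    }
  }
  counts
}

# exact 1-D k-means by exhaustive enumeration of contiguous partitions
oracle_kmeans_1d <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  splits <- utils::combn(n - 1L, k - 1L)
  best <- NULL; best_sse <- Inf
  for (s in seq_len(ncol(splits))) {
    bounds <- c(0L, splits[, s], n)
    sse <- 0; cent <- numeric(k)
    for (q in seq_len(k)) {
      blk <- x[(bounds[q] + 1L):bounds[q + 1L]]
      cent[q] <- mean(blk)
      sse <- sse + sum((blk - cent[q])^2)
    }
    if (sse < best_sse) { best_sse <- sse; best <- cent }
  }
  list(centroids = best, sse = best_sse)
}

# evaluate under a local seed without disturbing the ambient RNG stream
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

random_seqs <- function(n, L = 10) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

# single synthetic Gaussian spectrum in energy space
make_gauss_spectrum <- function(lambda_nm, sigma_ev, amp = 100,
                                grid = seq(400, 1100, by = 2)) {
  e <- 1239.842 / grid
  rowsum <- numeric(length(grid))
  for (i in seq_along(lambda_nm))
    rowsum <- rowsum +
      amp[min(i, length(amp))] *
        exp(-(e - 1239.842 / lambda_nm[i])^2 / (2 * sigma_ev[min(i, length(sigma_ev))]^2))
  list(wavelength_nm = grid, intensity = rowsum)
}
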