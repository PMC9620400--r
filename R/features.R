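AGN_BASES <- c("A", "C", "G", "T")

#' Validate DNA sequences
#'
#' Checks that every sequence is a string over the alphabet \{A, C, G, T\}
#' (after uppercasing) and, optionally, that all sequences share a common
#' length.  RNA input (U) is rejected rather than silently mapped to T.
#'
#' @param seqs character vector of DNA sequences.
#' @param length_required integer or `NULL`; when given, every sequence must
#'   have exactly this length.
#' @return The validated (uppercased) character vector, invisibly usable
#'   downstream.
#' @examples
#' validate_sequences(c("ACGTACGTAC", "ggggccccaa"))
#' @export
validate_sequences <- function(seqs, length_required = NULL) {
  if (!is.character(seqs) || length(seqs) == 0L)
    stop("'seqs' must be a non-empty character vector", call. = FALSE)
  seqs <- toupper(seqs)
  bad <- regexpr("[^ACGT]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf(
      "invalid sequence %d ('%s'): non-ACGT character '%s' at position %d",
      i, seqs[i], substr(seqs[i], bad[i], bad[i]), bad[i]), call. = FALSE)
  }
  if (!is.null(length_required)) {
    nl <- nchar(seqs)
    if (any(nl != length_required)) {
      i <- which(nl != length_required)[1L]
      stop(sprintf("sequence %d has length %d, expected %d",
                   i, nl[i], length_required), call. = FALSE)
    }
  }
  seqs
}

#' Names of staple features in canonical order
#'
#' A staple feature `X_mY` counts ordered pairs of nucleobases X and Y
#' separated by m arbitrary bases, read 5' to 3'.  The canonical ordering is
#' X outermost (A, C, G, T), then Y, then the gap m innermost, so for
#' `m_max = 8` the 144 labels run `A_0A`, `A_1A`, ..., `A_8A`, `A_0C`, ...,
#' `T_8T`.  `X_mY` and `Y_mX` are distinct features: the pair is directional.
#'
#' @param m_max largest gap considered (default 8, giving 144 features for
#'   10-base sequences).
#' @return character vector of length `16 * (m_max + 1)`.
#' @examples
#' length(feature_names(8))  # 144
#' head(feature_names(0))    # adjacent dimers
#' @export
feature_names <- function(m_max = 8) {
  if (!is.numeric(m_max) || length(m_max) != 1L || m_max < 0)
    stop("'m_max' must be a single non-negative integer", call. = FALSE)
  m_max <- as.integer(m_max)
  out <- character(16L * (m_max + 1L))
  idx <- 1L
  for (x in AGN_BASES) for (y in AGN_BASES) for (m in 0:m_max) {
    out[idx] <- sprintf("%s_%d%s", x, m, y)
    idx <- idx + 1L
  }
  out
}

# Integer base codes 1..4 for a character vector of sequences of equal
# length; returns an n x L matrix.
seq_code_matrix <- function(seqs) {
  L <- nchar(seqs[1L])
  mat <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), AGN_BASES),
                nrow = length(seqs), ncol = L, byrow = TRUE)
  mat
}

#' Gapped nucleobase-pair (staple) feature counts
#'
#' Counts, for every ordered pair of bases (X, Y) and every gap
#' m = 0..`m_max`, the occurrences of X followed m+1 positions later by Y.
#' For 10-base sequences with `m_max = 8` this gives a 144-component integer
#' vector whose components sum to 45 (the number of ordered position pairs).
#'
#' @param seqs character vector of equal-length DNA sequences.
#' @param m_max largest gap (default 8; must satisfy `m_max <= L - 2`).
#' @return integer matrix, one row per sequence, columns named by
#'   [feature_names()].
#' @examples
#' staple_features("AAAAAAAAAA")["AAAAAAAAAA", "A_3A"]  # 6
#' rowSums(staple_features(c("ACGTACGTAC", "GGGGGCCCCC")))
#' @export
staple_features <- function(seqs, m_max = 8) {
  seqs <- validate_sequences(seqs)
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != L))
    stop("all sequences must have equal length", call. = FALSE)
  if (L < 2L) stop("sequences must have length >= 2", call. = FALSE)
  m_max <- as.integer(m_max)
  if (m_max > L - 2L)
    stop(sprintf("m_max = %d exceeds L - 2 = %d", m_max, L - 2L),
         call. = FALSE)
  n <- length(seqs)
  code <- seq_code_matrix(seqs)
  nf <- 16L * (m_max + 1L)
  counts <- matrix(0L, nrow = n, ncol = nf)
  # column of feature (x, y, m) in canonical (X, Y, m) order
  for (m in 0:m_max) {
    for (i in seq_len(L - 1L - m)) {
      x <- code[, i]
      y <- code[, i + m + 1L]
      col <- (x - 1L) * 4L * (m_max + 1L) + (y - 1L) * (m_max + 1L) + m + 1L
      idx <- cbind(seq_len(n), col)
      counts[idx] <- counts[idx] + 1L
    }
  }
  dimnames(counts) <- list(seqs, feature_names(m_max))
  counts
}

#' Positional one-hot encoding
#'
#' Encodes each sequence as a binary vector of length 4L with one indicator
#' slot per (position, base) combination, ordered position-major
#' (`p1_A, p1_C, p1_G, p1_T, p2_A, ...`).
#'
#' @param seqs character vector of equal-length DNA sequences.
#' @return integer matrix with `4 * L` columns; each row has exactly L ones.
#' @examples
#' one_hot("ACGT")
#' @export
one_hot <- function(seqs) {
  seqs <- validate_sequences(seqs)
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != L))
    stop("all sequences must have equal length", call. = FALSE)
  code <- seq_code_matrix(seqs)
  n <- length(seqs)
  out <- matrix(0L, nrow = n, ncol = 4L * L)
  for (p in seq_len(L)) {
    idx <- cbind(seq_len(n), (p - 1L) * 4L + code[, p])
    out[idx] <- 1L
  }
  colnames(out) <- paste0("p", rep(seq_len(L), each = 4L), "_",
                          rep(AGN_BASES, L))
  rownames(out) <- seqs
  out
}

#' Decode a one-hot matrix back to sequences
#'
#' Inverse of [one_hot()]; used for round-trip checks.
#'
#' @param mat binary matrix produced by [one_hot()].
#' @return character vector of sequences.
#' @export
decode_one_hot <- function(mat) {
  L <- ncol(mat) / 4L
  apply(mat, 1L, function(row) {
    paste(vapply(seq_len(L), function(p) {
      AGN_BASES[which(row[(p - 1L) * 4L + 1:4] == 1L)]
    }, character(1L)), collapse = "")
  })
}

#' Read DNA sequences from FASTA or plain text
#'
#' FASTA files (first non-blank character `>`) and one-sequence-per-line
#' plain text are both accepted.  Sequences are uppercased and validated.
#'
#' @param path file path.
#' @return named character vector of sequences (names from FASTA headers or
#'   line numbers).
#' @export
read_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no sequences in ", path, call. = FALSE)
  if (startsWith(lines[1L], ">")) {
    hdr <- grepl("^>", lines)
    id <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], id[!hdr]),
                   paste, character(1L), collapse = "")
    names(seqs) <- sub("^>\\s*", "", lines[hdr])[as.integer(names(seqs))]
  } else {
    seqs <- lines
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  validate_sequences(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  nm <- names(seqs)
  if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
  writeLines(paste0(">", nm, "\n", seqs), path)
  invisible(path)
}
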