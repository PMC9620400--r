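# decode 0-based enumeration indices into an n x L base-code matrix
# (codes 1..4 = A, C, G, T), lexicographic in the index
index_to_codes <- function(idx0, L) {
  n <- length(idx0)
  code <- matrix(0L, nrow = n, ncol = L)
  rem <- idx0
  for (p in L:1) {
    code[, p] <- as.integer(rem %% 4) + 1L
    rem <- rem %/% 4
  }
  code
}

codes_to_strings <- function(code) {
  n <- nrow(code)
  chars <- matrix(AGN_BASES[code], nrow = n)
  do.call(paste0, lapply(seq_len(ncol(chars)), function(p) chars[, p]))
}

# staple counts straight from a base-code matrix (avoids string round-trip
# when screening the full sequence space)
staple_counts_from_codes <- function(code, m_max = 8) {
  n <- nrow(code); L <- ncol(code)
  counts <- matrix(0, nrow = n, ncol = 16L * (m_max + 1L))
  for (m in 0:m_max) {
    for (i in seq_len(max(0L, L - 1L - m))) {  # gaps beyond L-2 count zero
      col <- (code[, i] - 1L) * 4L * (m_max + 1L) +
             (code[, i + m + 1L] - 1L) * (m_max + 1L) + m + 1L
      idx <- cbind(seq_len(n), col)
      counts[idx] <- counts[idx] + 1
    }
  }
  colnames(counts) <- feature_names(m_max)
  counts
}

#' Enumerate the full sequence space
#'
#' All 4^L DNA sequences of length L in lexicographic order (A < C < G < T).
#' Guarded at L <= 12 to prevent accidental blowups; the design screen
#' ([design_top_k()]) streams the space in blocks instead of materializing
#' it.
#'
#' @param L sequence length, 1-12 (default 10 gives 1,048,576 sequences).
#' @return character vector of length 4^L.
#' @examples
#' enumerate_space(2)
#' @export
enumerate_space <- function(L = 10) {
  if (!is.numeric(L) || L < 1 || L > 12)
    stop(sprintf(
      "L must be between 1 and 12 (L = %s would enumerate 4^%s sequences)",
      L, L), call. = FALSE)
  L <- as.integer(L)
  codes_to_strings(index_to_codes(seq_len(4^L) - 1, L))
}

# score a feature block for a target class: per-pair average probability of
# the target, then the minimum over the target's pairs
score_block <- function(object, feats, target) {
  keys <- names(object$pair_models)[
    vapply(object$pair_models, function(pm) target %in% pm$pair, logical(1))]
  per_pair <- vapply(keys, function(k) {
    pm <- object$pair_models[[k]]
    p <- pair_member_probs(pm, feats)
    if (identical(pm$pair[1L], target)) p else 1 - p
  }, numeric(nrow(feats)))
  if (is.null(dim(per_pair)))
    per_pair <- matrix(per_pair, nrow = 1L, dimnames = list(NULL, keys))
  list(score = apply(per_pair, 1L, min), per_pair = per_pair)
}

#' Score one sequence for a target color class
#'
#' The design score of a sequence for a target class is the minimum, over
#' the four class pairs containing the target, of the pair's average
#' probability of the target class.  Ranking by this score prefers
#' sequences that no competing class can claim.
#'
#' @param object a fitted [agn_ensemble()].
#' @param seq a DNA sequence (or several).
#' @param target the target color class.
#' @return data frame with `sequence`, `target`, `score` and one
#'   `p_<pair>` column per relevant pair.
#' @export
score_sequence <- function(object, seq, target) {
  target <- match.arg(target, object$classes)
  if (is.character(seq)) {
    # code-matrix path tolerates sequences shorter than the gap range
    m_max <- length(object$feature_names) / 16L - 1L
    seq <- toupper(seq)
    feats <- staple_counts_from_codes(
      seq_code_matrix(validate_sequences(seq)), m_max)
    rownames(feats) <- seq
  } else feats <- as_feature_matrix(seq, object$feature_names)
  sb <- score_block(object, feats, target)
  pp <- as.data.frame(sb$per_pair)
  names(pp) <- paste0("p_", gsub("|", ".", names(pp), fixed = TRUE))
  cbind(data.frame(sequence = if (is.character(seq)) toupper(seq)
                              else rownames(feats),
                   target = target, score = sb$score), pp)
}

#' Exhaustive design screen for a target color class
#'
#' Streams the whole 4^L sequence space in blocks, scores every sequence
#' with [score_sequence()]'s rule, and keeps the `k` best.  Ties are broken
#' lexicographically, so results are fully deterministic.  Memory use is
#' bounded by the block size, not by 4^L.
#'
#' @param object a fitted [agn_ensemble()].
#' @param target target color class.
#' @param k number of sequences to keep (default 124, one 384-well plate
#'   split three ways plus controls).
#' @param L sequence length (default 10).
#' @param block_size sequences scored per block (default 65536).
#' @param exclude optional character vector of sequences to drop from the
#'   ranking (e.g. the training library).
#' @return object of class `agn_design`: data frame `ranked` with `rank`,
#'   `sequence`, `score` and per-pair probabilities, plus run metadata.
#' @export
design_top_k <- function(object, target, k = 124, L = 10,
                         block_size = 65536, exclude = NULL) {
  target <- match.arg(target, object$classes)
  if (L < 1 || L > 12) stop("L must be between 1 and 12", call. = FALSE)
  L <- as.integer(L)
  total <- 4^L
  if (k > total) stop("k exceeds the 4^L sequence space", call. = FALSE)
  if (!is.null(exclude)) exclude <- toupper(exclude)
  pool_idx <- numeric(0)
  pool_score <- numeric(0)
  start <- 0
  while (start < total) {
    size <- min(block_size, total - start)
    idx0 <- start + seq_len(size) - 1
    feats <- staple_counts_from_codes(index_to_codes(idx0, L))
    sc <- score_block(object, feats, target)$score
    cand_idx <- c(pool_idx, idx0)
    cand_score <- c(pool_score, sc)
    # enumeration index order IS lexicographic order: stable tie-break
    o <- order(-cand_score, cand_idx)
    keep_n <- min(length(o), k + length(exclude))
    pool_idx <- cand_idx[o[seq_len(keep_n)]]
    pool_score <- cand_score[o[seq_len(keep_n)]]
    start <- start + size
  }
  seqs <- codes_to_strings(index_to_codes(pool_idx, L))
  if (!is.null(exclude)) {
    keep <- !(seqs %in% exclude)
    seqs <- seqs[keep]; pool_score <- pool_score[keep]
  }
  seqs <- head(seqs, k); pool_score <- head(pool_score, k)
  detail <- score_sequence(object, seqs, target)
  ranked <- cbind(data.frame(rank = seq_along(seqs)), detail)
  structure(list(ranked = ranked, target = target, k = k, L = L,
                 enumeration_size = total,
                 model_config = object$config),
            class = "agn_design")
}

#' @export
print.agn_design <- function(x, ...) {
  cat(sprintf("Design screen: top %d of %s length-%d sequences for %s\n",
              x$k, format(x$enumeration_size, big.mark = ","), x$L, x$target))
  print(utils::head(x$ranked[c("rank", "sequence", "score")], 10), digits = 4)
  if (nrow(x$ranked) > 10) cat("  ...\n")
  invisible(x)
}

#' Write a design run to CSV and FASTA
#'
#' @param design an `agn_design` from [design_top_k()].
#' @param csv_path,fasta_path output paths (`NULL` to skip either).
#' @return invisibly, the ranked data frame.
#' @export
write_design <- function(design, csv_path = NULL, fasta_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(design$ranked, csv_path, row.names = FALSE)
  if (!is.null(fasta_path)) {
    seqs <- design$ranked$sequence
    names(seqs) <- sprintf("%s_rank%03d_score%.4f", design$target,
                           design$ranked$rank, design$ranked$score)
    write_fasta(seqs, fasta_path)
  }
  invisible(design$ranked)
}
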