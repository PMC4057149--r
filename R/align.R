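## Windowed complementarity alignment of the full miRNA against a 25-nt
## target window, in the style of miRanda's modified Smith-Waterman: the
## seed-paired columns are anchored (never realigned), the miRNA 3' region is
## locally aligned against the upstream part of the window with G:U wobble
## allowed, and the column opposite miRNA position 1 contributes only when it
## pairs. Scores are annotations: perfect-seed sites are accepted by class.

#' Alignment scoring parameters
#'
#' miRanda-like magnitudes. `min_report_score` applies to reported sites in
#' [find_target_sites()]; with the default of 0 every perfect-seed site is
#' kept (its anchored seed columns alone score positive), so the alignment
#' score annotates rather than filters.
#'
#' @param match_score Watson-Crick pair score (> wobble_score).
#' @param wobble_score G:U pair score (> 0), 3' columns only.
#' @param mismatch_penalty Mismatch score (< 0).
#' @param gap_open,gap_extend Affine gap penalties (gap_open <= gap_extend < 0).
#' @param min_report_score Minimum alignment score for a reported site.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(match_score = 5, wobble_score = 2,
                             mismatch_penalty = -3, gap_open = -8,
                             gap_extend = -2, min_report_score = 0) {
  stopifnot(match_score > wobble_score, wobble_score > 0,
            mismatch_penalty < 0, gap_open <= gap_extend, gap_extend < 0)
  structure(list(match_score = match_score, wobble_score = wobble_score,
                 mismatch_penalty = mismatch_penalty, gap_open = gap_open,
                 gap_extend = gap_extend, min_report_score = min_report_score),
            class = "alignment_params")
}

## Pair score of one miRNA base against one target base outside the seed:
## WC -> match, G:U -> wobble, anything else (incl. N) -> mismatch penalty.
pair_score <- function(mi, tg, params) {
  cls <- pair_class(mi, tg)
  ifelse(cls == "wc", params$match_score,
         ifelse(cls == "wobble", params$wobble_score,
                params$mismatch_penalty))
}

#' Align the full miRNA against the 25-nt window around a seed match
#'
#' The window ends one base downstream (target 3') of the seed core, at the
#' position opposite miRNA position 1, and extends up to 25 nt upstream
#' (truncating at transcript ends). Anchored seed columns score Watson-Crick
#' matches or the mismatch penalty (no wobble in the seed); the miRNA 3'
#' segment is Smith-Waterman-aligned (affine gaps, wobble allowed) against
#' the reversed upstream window; the position-1 column adds its pair score
#' only when positive.
#'
#' @param tseq Canonical RNA transcript sequence (a string).
#' @param seed_match One row from [scan_seed_matches()].
#' @param mir A `mirna` object.
#' @param params [alignment_params()].
#' @return List with `score`, `window_start`, `window_end` (half-open,
#'   transcript-local) and `paired_positions`: a character vector over miRNA
#'   positions 1..L with values in `{"wc","wobble","mismatch","gap","unpaired"}`.
#' @export
align_window <- function(tseq, seed_match, mir, params = alignment_params()) {
  tlen <- nchar(tseq)
  p <- seed_match$core_start              # 0-based start of the 6mer core
  stopifnot(p >= 0L, p + 6L <= tlen)
  w_end <- min(tlen, p + 7L)
  w_start <- max(0L, w_end - 25L)

  mchars <- seq_chars(mir$sequence)
  L <- length(mchars)
  tchars <- seq_chars(tseq)
  states <- rep("unpaired", L)

  # seed columns: miRNA position k pairs target 0-based index p + 7 - k
  # (1-based index p + 8 - k); the m8 column is anchored when the reported
  # seed region includes it
  seed_pos <- if (seed_match$t_start < p) 2:8 else 2:7
  seed_score <- 0
  for (k in seed_pos) {
    tg <- tchars[p + 8L - k]
    wc <- pair_class(mchars[k], tg) == "wc"
    seed_score <- seed_score +
      if (wc) params$match_score else params$mismatch_penalty
    states[k] <- if (wc) "wc" else "mismatch"
  }

  # position-1 column (target 0-based p + 6), only if inside the window;
  # contributes when it pairs, never penalises (local-alignment semantics)
  m1_score <- 0
  if (p + 6L < w_end) {
    s1 <- pair_score(mchars[1], tchars[p + 7L], params)
    if (s1 > 0) {
      m1_score <- s1
      states[1] <- pair_class(mchars[1], tchars[p + 7L])
    }
  }

  # 3' extension: miRNA positions beyond the anchored seed vs the reversed
  # upstream window segment (antiparallel geometry)
  m_end <- max(seed_pos)
  ext <- list(score = 0)
  up_to <- p + 6L - m_end                  # 0-based last upstream index
  if (m_end < L && up_to >= w_start) {
    # target 0-based indices [w_start, p + 6 - m_end], reversed
    tg_seg <- rev(tchars[(w_start + 1L):(p + 6L - m_end + 1L)])
    q_seg <- mchars[(m_end + 1L):L]
    ext <- sw_local(q_seg, tg_seg, params)
    if (ext$score > 0) {
      for (j in seq_along(ext$q_state)) {
        if (ext$q_state[j] != "unpaired") {
          states[m_end + j] <- ext$q_state[j]
        }
      }
    }
  }

  list(score = seed_score + m1_score + ext$score,
       window_start = w_start, window_end = w_end,
       paired_positions = states)
}

## Smith-Waterman local alignment with affine gaps of query q (miRNA 3'
## segment) vs target t (reversed upstream window). Returns the best local
## score (>= 0) and per-query-position pairing states from the traceback.
sw_local <- function(q, t, params) {
  n <- length(q); m <- length(t)
  if (n == 0L || m == 0L) {
    return(list(score = 0, q_state = rep("unpaired", n)))
  }
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)       # best score ending in a pair
  X <- matrix(NEG, n + 1L, m + 1L)     # gap in target (query base unpaired)
  Y <- matrix(NEG, n + 1L, m + 1L)     # gap in query
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    s_row <- pair_score(q[i], t, params)
    for (j in seq_len(m)) {
      diag_best <- max(M[i, j], X[i, j], Y[i, j], 0)
      M[i + 1L, j + 1L] <- diag_best + s_row[j]
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + params$gap_open,
                               X[i, j + 1L] + params$gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + params$gap_open,
                               Y[i + 1L, j] + params$gap_extend)
      if (M[i + 1L, j + 1L] > best) {
        best <- M[i + 1L, j + 1L]; bi <- i; bj <- j
      }
    }
  }
  q_state <- rep("unpaired", n)
  if (best > 0) {
    # traceback from the best pair-ending cell
    i <- bi; j <- bj; mat <- "M"
    while (i > 0L && j > 0L) {
      if (mat == "M") {
        q_state[i] <- pair_class(q[i], t[j])
        if (q_state[i] == "none") q_state[i] <- "mismatch"
        prev <- c(M = M[i, j], X = X[i, j], Y = Y[i, j], S = 0)
        mat <- names(prev)[which.max(prev)]
        i <- i - 1L; j <- j - 1L
        if (mat == "S") break
      } else if (mat == "X") {
        q_state[i] <- "gap"
        from_open <- M[i, j + 1L] + params$gap_open
        from_ext <- X[i, j + 1L] + params$gap_extend
        mat <- if (from_open >= from_ext) "M" else "X"
        i <- i - 1L
      } else { # Y: gap in query, consumes target only
        from_open <- M[i + 1L, j] + params$gap_open
        from_ext <- Y[i + 1L, j] + params$gap_extend
        mat <- if (from_open >= from_ext) "M" else "Y"
        j <- j - 1L
      }
    }
  }
  list(score = best, q_state = q_state)
}
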