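## MRE discovery: seed-class matching followed by a windowed miRanda-style
## complementarity alignment. Seed classes follow TargetScan conventions:
##
##   6mer     target pairs miRNA 2-7
##   7mer-m8  target pairs miRNA 2-8
##   7mer-A1  target pairs miRNA 2-7 and carries an A opposite position 1
##   8mer     target pairs miRNA 2-8 and carries an A opposite position 1
##
## plus "mismatch-compensatory": one mismatch in the seed (positions 2-8 or
## 2-7) rescued by perfect Watson-Crick pairing of miRNA positions 13-18
## inside the alignment window. Seed pairing is Watson-Crick only; G:U wobble
## scores only in the 3' region, as in miRanda.

SITE_CLASSES <- c("8mer", "7mer-m8", "7mer-A1", "6mer", "mismatch-compensatory")

#' Construct a miRNA object with derived seed subsequences
#'
#' Positions use the standard 1-based miRNA convention: the seed is positions
#' 2-7 (6mer) or 2-8 (7mer), and the 3' compensatory block is positions 13-18.
#'
#' @param id miRNA identifier.
#' @param sequence RNA (or DNA) sequence, 5'->3', length >= 18 so that
#'   position 18 exists.
#' @return A `mirna` object with fields `id`, `sequence` (canonical RNA),
#'   `seed6` (2-7), `seed7` (2-8), `three_prime_block` (13-18).
#' @export
mirna <- function(id, sequence) {
  sequence <- canonical_rna(sequence, paste0("miRNA ", id))
  if (nchar(sequence) < 18L) {
    stop("miRNA ", id, " is shorter than 18 nt (", nchar(sequence),
         "); positions up to 18 are required", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence,
                 seed6 = substr(sequence, 2L, 7L),
                 seed7 = substr(sequence, 2L, 8L),
                 three_prime_block = substr(sequence, 13L, 18L)),
            class = "mirna")
}

#' Target-side seed patterns for each perfect-seed site class
#'
#' Patterns are given in target 5'->3' orientation: the 6mer pattern is the
#' reverse complement of miRNA positions 2-7, 7mer-m8 of positions 2-8, and
#' the A1 classes append the target-side `A` anchor opposite miRNA position 1
#' (an adenine anchor regardless of the miRNA's own position-1 base).
#'
#' @param x A `mirna` object, or a raw sequence string (>= 8 nt).
#' @return Named character vector with elements `6mer`, `7mer-m8`, `7mer-A1`,
#'   `8mer`.
#' @export
seed_target_patterns <- function(x) {
  if (!inherits(x, "mirna")) {
    seq <- canonical_rna(x, "miRNA")
    if (nchar(seq) < 8L) {
      stop("miRNA sequence shorter than 8 nt: no position 8", call. = FALSE)
    }
    x <- list(seed6 = substr(seq, 2L, 7L), seed7 = substr(seq, 2L, 8L))
  }
  p6 <- revcomp_rna(x$seed6)
  p7 <- revcomp_rna(x$seed7)
  c("6mer" = p6, "7mer-m8" = p7,
    "7mer-A1" = paste0(p6, "A"), "8mer" = paste0(p7, "A"))
}

## All 0-based start positions of `pat` in `seq`, including overlapping
## occurrences (a zero-width lookahead; plain fixed matching would skip a
## self-overlapping seed pattern). Patterns carrying the never-pairs
## sentinel (complement of N) cannot match at all.
fixed_matches0 <- function(seq, pat) {
  if (grepl("*", pat, fixed = TRUE)) return(integer())
  hits <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits) - 1L
}

#' Scan a transcript for seed matches of one miRNA
#'
#' Every occurrence of a seed pattern yields one match; overlapping matches of
#' different classes at the same locus collapse to the most specific class
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer). With `allow_mismatch = TRUE`, loci where
#' the target pairs miRNA positions 2-7 (optionally extended to 2-8) with
#' exactly one mismatch are additionally reported as class
#' `mismatch-compensatory`, but only when the target perfectly Watson-Crick
#' pairs miRNA positions 13-18 somewhere in the upstream part of the
#' alignment window.
#'
#' @param transcript One-row data.frame (or list) with `id` and `sequence`.
#' @param mir A `mirna` object.
#' @param allow_mismatch Report one-mismatch compensatory sites?
#' @return Data.frame with columns `mirna_id`, `transcript_id`, `t_start`,
#'   `t_end` (half-open, transcript-local), `site_class`,
#'   `n_seed_mismatches`, and `core_start` (position of the 6mer core, used
#'   internally by the aligner).
#' @export
scan_seed_matches <- function(transcript, mir, allow_mismatch = FALSE) {
  stopifnot(inherits(mir, "mirna"))
  tseq <- canonical_rna(transcript$sequence,
                        paste0("transcript ", transcript$id))
  tlen <- nchar(tseq)
  pats <- seed_target_patterns(mir)
  p6 <- pats[["6mer"]]
  comp_m8 <- unname(.COMP[substr(mir$sequence, 8L, 8L)])
  tchars <- seq_chars(tseq)

  res <- list()
  core_hits <- if (tlen >= 6L) fixed_matches0(tseq, p6) else integer()
  if (length(core_hits)) {
    m8_ok <- core_hits > 0L & tchars[pmax(core_hits, 1L)] == comp_m8
    a1_ok <- core_hits + 6L < tlen & tchars[pmin(core_hits + 7L, tlen)] == "A"
    cls <- ifelse(m8_ok & a1_ok, "8mer",
           ifelse(m8_ok, "7mer-m8",
           ifelse(a1_ok, "7mer-A1", "6mer")))
    t_start <- ifelse(m8_ok, core_hits - 1L, core_hits)
    t_end <- ifelse(a1_ok, core_hits + 7L, core_hits + 6L)
    res$perfect <- data.frame(
      mirna_id = mir$id, transcript_id = transcript$id,
      t_start = as.integer(t_start), t_end = as.integer(t_end),
      site_class = cls, n_seed_mismatches = 0L,
      core_start = as.integer(core_hits), stringsAsFactors = FALSE)
  }

  if (allow_mismatch && tlen >= 6L) {
    pchars <- seq_chars(p6)
    block <- revcomp_rna(mir$three_prime_block)
    starts <- 0:(tlen - 6L)
    mm <- integer(length(starts))
    for (j in 0:5) mm <- mm + (tchars[starts + 1L + j] != pchars[j + 1L])
    cand <- starts[mm == 1L]
    keep <- vapply(cand, function(p) {
      w_end <- min(tlen, p + 7L)
      w_start <- max(0L, w_end - 25L)
      # upstream (target 5') part of the window, where miRNA 3' pairing sits
      if (p - w_start < 6L) return(FALSE)
      up <- substr(tseq, w_start + 1L, p)
      length(fixed_matches0(up, block)) > 0L
    }, logical(1))
    cand <- cand[keep]
    if (length(cand)) {
      # include the m8 column in the reported seed region when it also pairs,
      # matching the "position 2-8 or 2-7" one-mismatch definition
      m8_ok <- cand > 0L & tchars[pmax(cand, 1L)] == comp_m8
      res$mismatch <- data.frame(
        mirna_id = mir$id, transcript_id = transcript$id,
        t_start = as.integer(ifelse(m8_ok, cand - 1L, cand)),
        t_end = as.integer(cand + 6L),
        site_class = "mismatch-compensatory", n_seed_mismatches = 1L,
        core_start = as.integer(cand), stringsAsFactors = FALSE)
    }
  }

  if (length(res) == 0L) {
    return(data.frame(mirna_id = character(), transcript_id = character(),
                      t_start = integer(), t_end = integer(),
                      site_class = character(), n_seed_mismatches = integer(),
                      core_start = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$t_start, out$core_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find target sites of one miRNA on one transcript
#'
#' Composes [scan_seed_matches()] and [align_window()]. Perfect-seed classes
#' are reported whenever their alignment score reaches `min_report_score`
#' (default 0, i.e. the seed match itself is sufficient); mismatch sites are
#' reported only when the 13-18 compensatory block pairs perfectly.
#' Conservation and AGO flags start out unknown (`NA`).
#'
#' @param transcript One-row data.frame (or list) with `id`, `sequence` and
#'   optionally `biotype` and `gene_id`.
#' @param mir A `mirna` object.
#' @param params Alignment parameters, see [alignment_params()].
#' @param allow_mismatch Report one-mismatch compensatory sites?
#' @return Site data.frame (columns of `write_sites_tsv()`), sorted by
#'   `(transcript_id, t_start, mirna_id)`.
#' @export
find_target_sites <- function(transcript, mir, params = alignment_params(),
                              allow_mismatch = FALSE) {
  matches <- scan_seed_matches(transcript, mir, allow_mismatch)
  if (nrow(matches) == 0L) return(empty_site_table())
  tseq <- canonical_rna(transcript$sequence, "transcript")
  aligned <- lapply(seq_len(nrow(matches)), function(i) {
    align_window(tseq, matches[i, ], mir, params)
  })
  gene_id <- if (!is.null(transcript$gene_id) && !is.na(transcript$gene_id))
    transcript$gene_id else transcript$id
  biotype <- if (!is.null(transcript$biotype)) transcript$biotype
             else NA_character_
  out <- data.frame(
    transcript_id = transcript$id, gene_id = gene_id, biotype = biotype,
    mirna_id = mir$id, site_class = matches$site_class,
    t_start = matches$t_start, t_end = matches$t_end,
    window_start = vapply(aligned, function(a) a$window_start, integer(1)),
    window_end = vapply(aligned, function(a) a$window_end, integer(1)),
    alignment_score = vapply(aligned, function(a) a$score, numeric(1)),
    n_seed_mismatches = matches$n_seed_mismatches,
    conserved = NA, ago_supported = NA, stringsAsFactors = FALSE)
  out <- out[out$alignment_score >= params$min_report_score, , drop = FALSE]
  out <- out[order(out$transcript_id, out$t_start, out$mirna_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict target sites for every transcript x miRNA combination
#'
#' @param transcripts Data.frame with columns `id`, `sequence`, and optionally
#'   `biotype`, `gene_id` (as from [read_fasta()]).
#' @param mirnas Data.frame with `id`, `sequence`, or a list of `mirna`
#'   objects.
#' @param params Alignment parameters.
#' @param mismatch_mode Which biotypes get the one-mismatch compensatory
#'   search: `"lncRNA"` (default), `"none"` or `"all"`.
#' @param verbose Log per-transcript progress?
#' @return Concatenated site table, deterministically ordered.
#' @export
predict_all <- function(transcripts, mirnas, params = alignment_params(),
                        mismatch_mode = c("lncRNA", "none", "all"),
                        verbose = FALSE) {
  mismatch_mode <- match.arg(mismatch_mode)
  mirs <- as_mirna_list(mirnas)
  if (length(mirs) == 0L || nrow(transcripts) == 0L) return(empty_site_table())
  tables <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, , drop = FALSE]
    allow <- switch(mismatch_mode,
                    none = FALSE, all = TRUE,
                    lncRNA = identical(tr$biotype, "lncRNA"))
    rows <- lapply(mirs, find_target_sites, transcript = tr, params = params,
                   allow_mismatch = allow)
    tables[[i]] <- do.call(rbind, rows)
    if (verbose) {
      message(sprintf("scanned %s: %d site(s)", tr$id, nrow(tables[[i]])))
    }
  }
  out <- do.call(rbind, tables)
  if (is.null(out) || nrow(out) == 0L) return(empty_site_table())
  out <- out[order(out$transcript_id, out$t_start, out$mirna_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

as_mirna_list <- function(mirnas) {
  if (is.data.frame(mirnas)) {
    lapply(seq_len(nrow(mirnas)), function(i)
      mirna(mirnas$id[i], mirnas$sequence[i]))
  } else if (length(mirnas) && inherits(mirnas[[1]], "mirna")) {
    mirnas
  } else if (length(mirnas) == 0L) {
    list()
  } else {
    stop("mirnas must be a data.frame with id/sequence or a list of mirna objects")
  }
}
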