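## Projection of genomic annotation intervals (conserved blocks, AGO CLIP
## clusters) into spliced transcript coordinates, and flagging of target
## sites. Flags are tri-state: TRUE / FALSE / NA (no data for that
## transcript), serialised as 1/0/NA.

#' Project genomic intervals into transcript coordinates
#'
#' Each genomic interval is intersected with the model's exons; every exonic
#' piece becomes one transcript-local interval (intervals split by introns
#' yield several pieces). On minus-strand models coordinates are reversed so
#' position 0 is the transcript 5' end. Intervals on a different chromosome
#' are skipped with a warning.
#'
#' @param model A `transcript_model`.
#' @param intervals Data.frame of genomic intervals (`chrom`, `start`, `end`,
#'   0-based half-open; optional `label`).
#' @return Data.frame with `transcript_id`, `start`, `end` (transcript-local,
#'   half-open), `source_label`; sorted by `start`.
#' @export
project_to_transcript <- function(model, intervals) {
  stopifnot(inherits(model, "transcript_model"))
  out <- list()
  if (nrow(intervals) > 0L) {
    off_chrom <- intervals$chrom != model$chrom
    if (any(off_chrom)) {
      warning(sum(off_chrom), " interval(s) on a different chromosome than ",
              model$transcript_id, " skipped", call. = FALSE)
      intervals <- intervals[!off_chrom, , drop = FALSE]
    }
  }
  if (nrow(intervals) == 0L) {
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), source_label = character(),
                      stringsAsFactors = FALSE))
  }
  ex <- model$exons
  # cumulative spliced offset of each exon in transcript (5'->3') order
  lens <- ex$end - ex$start
  n_ex <- nrow(ex)
  if (model$strand == "+") {
    offs <- cumsum(c(0L, lens))[seq_len(n_ex)]
  } else {
    # transcript order is reverse-genomic
    offs_rev <- cumsum(c(0L, rev(lens)))[seq_len(n_ex)]
    offs <- rev(offs_rev)                  # offs[i] = offset of genomic exon i
  }
  labels <- if (!is.null(intervals$label)) intervals$label
            else rep("", nrow(intervals))
  k <- 1L
  for (i in seq_len(nrow(intervals))) {
    g_s <- intervals$start[i]; g_e <- intervals$end[i]
    for (j in seq_len(n_ex)) {
      o_s <- max(g_s, ex$start[j]); o_e <- min(g_e, ex$end[j])
      if (o_s >= o_e) next
      if (model$strand == "+") {
        t_s <- offs[j] + (o_s - ex$start[j])
        t_e <- offs[j] + (o_e - ex$start[j])
      } else {
        t_s <- offs[j] + (ex$end[j] - o_e)
        t_e <- offs[j] + (ex$end[j] - o_s)
      }
      out[[k]] <- data.frame(transcript_id = model$transcript_id,
                             start = as.integer(t_s), end = as.integer(t_e),
                             source_label = labels[i],
                             stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), source_label = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Map a transcript-local interval back to genomic space
#'
#' Inverse of [project_to_transcript()]; used for round-trip checks.
#'
#' @param model A `transcript_model`.
#' @param start,end Transcript-local half-open interval.
#' @return Data.frame of genomic pieces (`chrom`, `start`, `end`), genomically
#'   ascending.
#' @export
transcript_to_genomic <- function(model, start, end) {
  stopifnot(start >= 0L, end <= model$spliced_length, start < end)
  ex <- model$exons
  lens <- ex$end - ex$start
  order_tx <- if (model$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  offs <- cumsum(c(0L, lens[order_tx]))
  out <- list()
  for (t in seq_along(order_tx)) {
    j <- order_tx[t]
    seg_s <- max(start, offs[t]); seg_e <- min(end, offs[t + 1L])
    if (seg_s >= seg_e) next
    if (model$strand == "+") {
      g_s <- ex$start[j] + (seg_s - offs[t])
      g_e <- ex$start[j] + (seg_e - offs[t])
    } else {
      g_s <- ex$end[j] - (seg_e - offs[t])
      g_e <- ex$end[j] - (seg_s - offs[t])
    }
    out[[length(out) + 1L]] <- data.frame(chrom = model$chrom,
                                          start = as.integer(g_s),
                                          end = as.integer(g_e),
                                          stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flag sites whose seed region lies in a conserved block
#'
#' Conserved blocks shorter than `min_block_len` (default 8 nt) are discarded
#' before flagging. A site is conserved iff its seed region
#' `[t_start, t_end)` is entirely contained in one retained block. Sites on
#' transcripts with no conservation data keep `NA`.
#'
#' @param sites Site data.frame.
#' @param conserved Data.frame of transcript-local intervals
#'   (`transcript_id`, `start`, `end`).
#' @param min_block_len Minimum retained block length in nt.
#' @param covered_transcripts Transcripts the conservation data covers;
#'   defaults to the transcripts appearing in `conserved` (before the length
#'   filter).
#' @return `sites` with the `conserved` flag set; cardinality unchanged.
#' @export
mark_conserved <- function(sites, conserved, min_block_len = 8L,
                           covered_transcripts = unique(conserved$transcript_id)) {
  if (nrow(sites) == 0L) return(sites)
  keep <- (conserved$end - conserved$start) >= min_block_len
  blocks <- conserved[keep, , drop = FALSE]
  covered <- sites$transcript_id %in% covered_transcripts
  sites$conserved[covered] <- FALSE
  idx <- which(covered)
  if (length(idx) && nrow(blocks)) {
    site_r <- IRanges::IRanges(start = sites$t_start[idx] + 1L,
                               end = sites$t_end[idx])
    block_r <- IRanges::IRanges(start = blocks$start + 1L, end = blocks$end)
    hits <- IRanges::findOverlaps(site_r, block_r, type = "within")
    same_tx <- sites$transcript_id[idx][S4Vectors::queryHits(hits)] ==
      blocks$transcript_id[S4Vectors::subjectHits(hits)]
    sites$conserved[idx[unique(S4Vectors::queryHits(hits)[same_tx])]] <- TRUE
  }
  sites
}

#' Flag sites whose seed region overlaps an AGO interaction interval
#'
#' A single base of overlap between the seed region and any AGO CLIP interval
#' suffices (CLIP cluster boundaries are fuzzy). Sites on transcripts outside
#' the AGO data keep `NA`.
#'
#' @param sites Site data.frame.
#' @param ago Data.frame of transcript-local intervals (`transcript_id`,
#'   `start`, `end`).
#' @param covered_transcripts Transcripts the AGO data covers; defaults to
#'   those appearing in `ago`.
#' @return `sites` with the `ago_supported` flag set.
#' @export
mark_ago_supported <- function(sites, ago,
                               covered_transcripts = unique(ago$transcript_id)) {
  if (nrow(sites) == 0L) return(sites)
  covered <- sites$transcript_id %in% covered_transcripts
  sites$ago_supported[covered] <- FALSE
  idx <- which(covered)
  if (length(idx) && nrow(ago)) {
    site_r <- IRanges::IRanges(start = sites$t_start[idx] + 1L,
                               end = sites$t_end[idx])
    ago_r <- IRanges::IRanges(start = ago$start + 1L, end = ago$end)
    hits <- IRanges::findOverlaps(site_r, ago_r, minoverlap = 1L)
    same_tx <- sites$transcript_id[idx][S4Vectors::queryHits(hits)] ==
      ago$transcript_id[S4Vectors::subjectHits(hits)]
    sites$ago_supported[idx[unique(S4Vectors::queryHits(hits)[same_tx])]] <- TRUE
  }
  sites
}

#' Read transcript-local annotation intervals from a 3-column TSV
#'
#' Alternative to genomic BED + GTF projection: a headered TSV with columns
#' `transcript_id`, `start`, `end` already in transcript coordinates.
#'
#' @param path Path to the TSV.
#' @return Data.frame with `transcript_id`, `start`, `end`, `source_label`.
#' @export
read_transcript_intervals <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "start", "end") %in% colnames(df)))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start < 0L | df$start >= df$end)) {
    stop("invalid transcript interval (need 0 <= start < end) in ", path,
         call. = FALSE)
  }
  if (is.null(df$source_label)) df$source_label <- ""
  df[, c("transcript_id", "start", "end", "source_label"), drop = FALSE]
}

#' Project a genomic annotation BED into transcript space for many models
#'
#' @param models List of `transcript_model`s (see [read_transcript_models()]).
#' @param bed Genomic intervals from [read_bed()].
#' @return Combined transcript-local interval data.frame.
#' @export
project_annotation <- function(models, bed) {
  pieces <- lapply(models, function(m) {
    suppressWarnings(project_to_transcript(m, bed[bed$chrom == m$chrom, ,
                                                  drop = FALSE]))
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), source_label = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
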