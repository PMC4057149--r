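## Readers and writers for every external representation the pipeline touches:
## FASTA sequences, BED intervals, GTF exon models, expression tables and the
## site / pair TSV dialects. All internal coordinates are 0-based half-open
## (BED convention); 1-based coordinates appear only in human-readable text.

#' Read sequences from a FASTA file
#'
#' Sequences are uppercased. For `biotype = "miRNA"` the sequence is
#' additionally normalised from DNA to RNA spelling (T -> U); transcript
#' sequences keep their spelling because all downstream comparisons are
#' alphabet-agnostic (see [canonical_rna()]).
#'
#' @param path Path to a FASTA file.
#' @param biotype One of `"miRNA"`, `"lncRNA"`, `"protein_coding"`.
#' @return A data.frame with columns `id`, `sequence`, `biotype`.
#' @export
read_fasta <- function(path, biotype = c("lncRNA", "protein_coding", "miRNA")) {
  biotype <- match.arg(biotype)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      biotype = character(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- duplicated(ids)
  if (any(dup)) {
    stop("duplicate sequence id in ", path, ": ", ids[dup][1], call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (biotype == "miRNA") seqs <- chartr("T", "U", seqs)
  bad <- grepl("[^ACGUTN]", seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("illegal character in record '%s' (entry %d) of %s",
                 ids[i], i, path), call. = FALSE)
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record '", ids[which(empty)[1]], "' in ", path,
         call. = FALSE)
  }
  data.frame(id = unname(ids), sequence = unname(seqs), biotype = biotype,
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records Data.frame with columns `id` and `sequence` (as returned by
#'   [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read genomic intervals from a BED3/BED6 file
#'
#' Coordinates are kept exactly as in BED: 0-based half-open. Strand comes
#' from column 6 when present, otherwise `"."`; the name column 4 becomes
#' `label` (empty string when absent).
#'
#' @param path Path to a BED file.
#' @return Data.frame with columns `chrom`, `start`, `end`, `strand`, `label`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L)) {
    stop("BED line ", which(n < 3L)[1], ": fewer than 3 columns", call. = FALSE)
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop("BED line ", which(bad)[1], ": non-numeric coordinates", call. = FALSE)
  }
  bad <- start < 0L | start >= end
  if (any(bad)) {
    stop("BED line ", which(bad)[1], ": requires 0 <= start < end (got ",
         start[which(bad)[1]], ", ", end[which(bad)[1]], ")", call. = FALSE)
  }
  label <- vapply(seq_along(fields), function(i)
    if (n[i] >= 4L) fields[[i]][4L] else "", "")
  strand <- vapply(seq_along(fields), function(i)
    if (n[i] >= 6L) fields[[i]][6L] else ".", "")
  ok <- strand %in% c("+", "-", ".")
  if (!all(ok)) {
    stop("BED line ", which(!ok)[1], ": invalid strand '",
         strand[which(!ok)[1]], "'", call. = FALSE)
  }
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             label = label, stringsAsFactors = FALSE)
}

#' Write genomic intervals to a BED6 file
#'
#' @param intervals Data.frame as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(intervals$chrom, intervals$start, intervals$end,
                   ifelse(nzchar(intervals$label), intervals$label, "."),
                   0L, intervals$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene/miRNA x tissue expression table
#'
#' Expects a TSV whose header row names the tissues and whose first column
#' holds row identifiers. Missing cells (`NA` or empty) are kept as missing,
#' never coerced to zero: absence of evidence about a tissue is not evidence
#' of absence of expression.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with row and column names; `NA` marks missing.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L) {
    stop("ragged expression table ", path, ": line ",
         which(nf != nf[1])[1], " has ", nf[which(nf != nf[1])[1]],
         " fields, expected ", nf[1], call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate row id in ", path, ": ", ids[duplicated(ids)][1],
         call. = FALSE)
  }
  tissues <- colnames(df)[-1]
  if (anyDuplicated(tissues)) {
    stop("duplicate tissue column in ", path, call. = FALSE)
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  if (any(mat < 0, na.rm = TRUE)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance for '", ids[bad[1]], "' in tissue '",
         tissues[bad[2]], "'", call. = FALSE)
  }
  rownames(mat) <- ids
  mat
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_column Name of the leading identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path, id_column = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read transcript exon models from a GTF/GFF file
#'
#' Keeps `exon` features only; exons are grouped per transcript and stored
#' genomically ascending regardless of strand (orientation is resolved at
#' projection time). Coordinates are converted to the internal 0-based
#' half-open convention.
#'
#' @param path Path to a GTF/GFF file.
#' @return Named list of transcript models; each model is a list with
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `biotype`, `exons`
#'   (data.frame `start`,`end`, 0-based half-open) and `spliced_length`.
#' @export
read_transcript_models <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(gr) == 0L) return(list())
  tid <- as.character(gr$transcript_id)
  if (any(is.na(tid) | !nzchar(tid))) {
    stop("exon feature without transcript_id in ", path, call. = FALSE)
  }
  gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else tid
  gid[is.na(gid)] <- tid[is.na(gid)]
  biotype <- if (!is.null(gr$gene_biotype)) as.character(gr$gene_biotype)
             else rep(NA_character_, length(gr))
  out <- lapply(split(seq_along(gr), tid), function(idx) {
    sub <- gr[idx]
    chrom <- as.character(GenomicRanges::seqnames(sub))
    strand <- as.character(GenomicRanges::strand(sub))
    if (length(unique(chrom)) > 1L || length(unique(strand)) > 1L) {
      stop("transcript ", tid[idx[1]], " mixes chromosomes or strands",
           call. = FALSE)
    }
    ex <- data.frame(start = GenomicRanges::start(sub) - 1L,
                     end = GenomicRanges::end(sub))
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("overlapping exons in transcript ", tid[idx[1]], call. = FALSE)
    }
    rownames(ex) <- NULL
    transcript_model(tid[idx[1]], gid[idx[1]], chrom[1],
                     if (strand[1] %in% c("+", "-")) strand[1] else "+",
                     ex, biotype = biotype[idx[1]])
  })
  out[order(names(out))]
}

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data.frame with 0-based half-open `start`,`end`, genomically
#'   ascending and non-overlapping.
#' @param biotype Optional biotype label.
#' @return A `transcript_model` list.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             biotype = NA_character_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$start >= exons$end)) stop("empty exon in ", transcript_id)
  if (nrow(exons) > 1L && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("overlapping exons in ", transcript_id)
  }
  rownames(exons) <- NULL
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons,
                 biotype = biotype,
                 spliced_length = sum(exons$end - exons$start)),
            class = "transcript_model")
}

## Column order of the site table; fixed so outputs are byte-stable.
SITE_COLUMNS <- c("transcript_id", "gene_id", "biotype", "mirna_id",
                  "site_class", "t_start", "t_end", "window_start",
                  "window_end", "alignment_score", "n_seed_mismatches",
                  "conserved", "ago_supported")

PAIR_COLUMNS <- c("lnc_id", "mrna_id", "n_shared_miRNAs", "shared_miRNA_list",
                  "shared_MREs", "total_MREs_lnc", "ceRNA_score", "p_value",
                  "q_value")

## Tri-state flags travel as 1/0/NA in TSVs and logical NA-able in memory.
flag_to_chr <- function(x) ifelse(is.na(x), "NA", ifelse(x, "1", "0"))
chr_to_flag <- function(x) ifelse(is.na(x) | x == "NA", NA, x == "1")

#' Write a target-site table to TSV
#'
#' @param sites Site data.frame (see [find_target_sites()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  sites <- empty_site_table(sites)
  df <- sites[, SITE_COLUMNS, drop = FALSE]
  df$conserved <- flag_to_chr(df$conserved)
  df$ago_supported <- flag_to_chr(df$ago_supported)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a target-site table written by [write_sites_tsv()]
#'
#' @param path Path to the TSV.
#' @return Site data.frame.
#' @export
read_sites_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("t_start", "t_end", "window_start", "window_end",
                "n_seed_mismatches")) df[[col]] <- as.integer(df[[col]])
  df$alignment_score <- as.numeric(df$alignment_score)
  df$conserved <- chr_to_flag(df$conserved)
  df$ago_supported <- chr_to_flag(df$ago_supported)
  df[, SITE_COLUMNS, drop = FALSE]
}

#' Write a ceRNA pair table to TSV
#'
#' Pairs are written in the order produced by [build_pairs()]: shared-miRNA
#' count descending, then p-value ascending, then ids.
#'
#' @param pairs Pair data.frame (see [build_pairs()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  pairs <- empty_pair_table(pairs)
  utils::write.table(pairs[, PAIR_COLUMNS, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ceRNA pair table written by [write_pairs_tsv()]
#'
#' @param path Path to the TSV.
#' @return Pair data.frame.
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("n_shared_miRNAs", "shared_MREs", "total_MREs_lnc")) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("ceRNA_score", "p_value", "q_value")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$shared_miRNA_list[is.na(df$shared_miRNA_list)] <- ""
  df[, PAIR_COLUMNS, drop = FALSE]
}

empty_site_table <- function(sites = NULL) {
  if (!is.null(sites) && nrow(sites) > 0L) return(sites)
  data.frame(transcript_id = character(), gene_id = character(),
             biotype = character(), mirna_id = character(),
             site_class = character(), t_start = integer(),
             t_end = integer(), window_start = integer(),
             window_end = integer(), alignment_score = numeric(),
             n_seed_mismatches = integer(), conserved = logical(),
             ago_supported = logical(), stringsAsFactors = FALSE)
}

empty_pair_table <- function(pairs = NULL) {
  if (!is.null(pairs) && nrow(pairs) > 0L) return(pairs)
  data.frame(lnc_id = character(), mrna_id = character(),
             n_shared_miRNAs = integer(), shared_miRNA_list = character(),
             shared_MREs = integer(), total_MREs_lnc = integer(),
             ceRNA_score = numeric(), p_value = numeric(),
             q_value = numeric(), stringsAsFactors = FALSE)
}
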