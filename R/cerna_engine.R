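## ceRNA scoring. For a candidate lncRNA-mRNA pair targeted by common
## miRNAs:
##
##   ceRNA score = (MREs on the lncRNA for shared miRNAs) /
##                 (all MREs on the lncRNA)
##
## and an upper-tail hypergeometric p-value on the shared-miRNA count:
##
##   p = sum_{i = m_c}^{min(m_p, m_n)}
##         C(m_p, i) C(M_T - m_p, m_n - i) / C(M_T, m_n)
##
## with M_T the miRNA universe size, m_p / m_n the numbers of miRNAs
## targeting the mRNA / lncRNA, and m_c the number shared.

#' Aggregate a site table into per-transcript MRE counts
#'
#' Exact duplicate sites (same transcript, miRNA, coordinates and class) are
#' counted once, so re-annotated or concatenated tables aggregate
#' idempotently.
#'
#' @param site_table Site data.frame from [predict_all()] (optionally
#'   pre-filtered on the conservation / AGO flags).
#' @return An `mre_index`: list with `counts` (data.frame `transcript_id`,
#'   `mirna_id`, `n`), `totals` (named integer vector per transcript) and
#'   `mirna_sets` (named list of miRNA-id character vectors).
#' @export
aggregate_mres <- function(site_table) {
  if (nrow(site_table) == 0L) {
    return(structure(list(counts = data.frame(transcript_id = character(),
                                              mirna_id = character(),
                                              n = integer(),
                                              stringsAsFactors = FALSE),
                          totals = integer(0) , mirna_sets = list()),
                     class = "mre_index"))
  }
  key <- paste(site_table$transcript_id, site_table$mirna_id,
               site_table$t_start, site_table$t_end, site_table$site_class,
               sep = "\r")
  dedup <- site_table[!duplicated(key), , drop = FALSE]
  tab <- stats::aggregate(list(n = rep(1L, nrow(dedup))),
                          by = list(transcript_id = dedup$transcript_id,
                                    mirna_id = dedup$mirna_id),
                          FUN = sum)
  tab <- tab[order(tab$transcript_id, tab$mirna_id), , drop = FALSE]
  rownames(tab) <- NULL
  totals <- tapply(tab$n, tab$transcript_id, sum)
  totals <- stats::setNames(as.integer(totals), names(totals))
  sets <- lapply(split(tab$mirna_id, tab$transcript_id), sort)
  structure(list(counts = tab, totals = totals, mirna_sets = sets),
            class = "mre_index")
}

#' ceRNA score of a candidate lncRNA
#'
#' Ratio of the candidate lncRNA's MREs attributable to shared miRNAs over
#' all of its MREs. Lies in (0, 1]; equals 1 iff every MRE on the lncRNA
#' belongs to a shared miRNA.
#'
#' @param shared_mre_count MREs on the lncRNA for miRNAs shared with the
#'   mRNA.
#' @param total_mre_lnc All MREs on the lncRNA (> 0).
#' @return Numeric score.
#' @export
cerna_score <- function(shared_mre_count, total_mre_lnc) {
  if (any(total_mre_lnc <= 0)) {
    stop("cerna_score requires total_mre_lnc > 0", call. = FALSE)
  }
  shared_mre_count / total_mre_lnc
}

#' Upper-tail hypergeometric p-value for a shared-miRNA count
#'
#' Probability that two miRNA sets of sizes `m_p` and `m_n`, drawn without
#' replacement from a universe of `M_T` miRNAs, share at least `m_c`
#' members. Computed in log space (via `lchoose` and a log-sum-exp) for
#' numerical stability; `m_c = 0` returns exactly 1. Vectorised over its
#' arguments.
#'
#' @param M_T Universe size.
#' @param m_p miRNAs targeting the mRNA.
#' @param m_n miRNAs targeting the lncRNA.
#' @param m_c Shared miRNAs.
#' @return p-value(s) in (0, 1].
#' @export
hypergeom_pvalue <- function(M_T, m_p, m_n, m_c) {
  args <- data.frame(M_T, m_p, m_n, m_c)
  with(args, {
    if (any(m_c < 0 | m_c > pmin(m_p, m_n))) {
      stop("require 0 <= m_c <= min(m_p, m_n)", call. = FALSE)
    }
    if (any(m_p > M_T | m_n > M_T | m_p < 0 | m_n < 0)) {
      stop("require 0 <= m_p, m_n <= M_T", call. = FALSE)
    }
  })
  vapply(seq_len(nrow(args)), function(r) {
    M_T <- args$M_T[r]; m_p <- args$m_p[r]
    m_n <- args$m_n[r]; m_c <- args$m_c[r]
    if (m_c == 0) return(1)
    i <- m_c:min(m_p, m_n)
    lg <- lchoose(m_p, i) + lchoose(M_T - m_p, m_n - i) - lchoose(M_T, m_n)
    mx <- max(lg)
    min(1, exp(mx) * sum(exp(lg - mx)))
  }, numeric(1))
}

#' Parameters for ceRNA pair construction
#'
#' @param M_T miRNA universe size; `NA` (default) means the number of
#'   distinct miRNAs observed across both MRE indexes. Must be at least the
#'   largest observed per-transcript miRNA count.
#' @param min_shared Minimum shared-miRNA count `m_c` for a reported pair.
#' @param fdr Add Benjamini-Hochberg q-values?
#' @return A list of class `cerna_params`.
#' @export
cerna_params <- function(M_T = NA_integer_, min_shared = 1L, fdr = TRUE) {
  stopifnot(min_shared >= 1L)
  structure(list(M_T = M_T, min_shared = as.integer(min_shared), fdr = fdr),
            class = "cerna_params")
}

#' Build candidate ceRNA pairs from lncRNA and mRNA MRE indexes
#'
#' One pair per (lncRNA, mRNA) combination sharing at least `min_shared`
#' miRNAs. Output is sorted by shared-miRNA count descending, then p-value
#' ascending, then ids — the shared-miRNA ordering users browse by.
#'
#' @param mre_index_lnc,mre_index_mrna `mre_index` objects from
#'   [aggregate_mres()].
#' @param params [cerna_params()].
#' @param pairs Optional data.frame (`lnc_id`, `mrna_id`) restricting which
#'   combinations are evaluated (e.g. pre-designated pairs); default is the
#'   full cross product.
#' @return Pair data.frame with the columns of `write_pairs_tsv()`.
#' @export
build_pairs <- function(mre_index_lnc, mre_index_mrna,
                        params = cerna_params(), pairs = NULL) {
  lnc_sets <- mre_index_lnc$mirna_sets
  mrna_sets <- mre_index_mrna$mirna_sets
  if (length(lnc_sets) == 0L || length(mrna_sets) == 0L) {
    return(empty_pair_table())
  }
  if (is.null(pairs)) {
    pairs <- expand.grid(lnc_id = names(lnc_sets), mrna_id = names(mrna_sets),
                         stringsAsFactors = FALSE)
  }
  all_mirnas <- unique(c(mre_index_lnc$counts$mirna_id,
                         mre_index_mrna$counts$mirna_id))
  M_T <- if (is.na(params$M_T)) length(all_mirnas) else params$M_T
  max_margin <- max(lengths(lnc_sets), lengths(mrna_sets))
  if (M_T < max_margin) {
    stop("M_T (", M_T, ") smaller than an observed miRNA margin (",
         max_margin, ")", call. = FALSE)
  }
  cnt <- mre_index_lnc$counts
  lnc_counts <- split(stats::setNames(cnt$n, cnt$mirna_id), cnt$transcript_id)

  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    lnc <- pairs$lnc_id[i]; mrna <- pairs$mrna_id[i]
    sl <- lnc_sets[[lnc]]; sm <- mrna_sets[[mrna]]
    if (is.null(sl) || is.null(sm)) next
    shared <- sort(intersect(sl, sm))
    m_c <- length(shared)
    if (m_c < params$min_shared) next
    m_n <- length(sl); m_p <- length(sm)
    shared_mre <- sum(lnc_counts[[lnc]][shared])
    total <- unname(mre_index_lnc$totals[[lnc]])
    rows[[i]] <- data.frame(
      lnc_id = lnc, mrna_id = mrna, n_shared_miRNAs = m_c,
      shared_miRNA_list = paste(shared, collapse = ","),
      shared_MREs = as.integer(shared_mre), total_MREs_lnc = total,
      ceRNA_score = cerna_score(shared_mre, total),
      p_value = hypergeom_pvalue(M_T, m_p, m_n, m_c),
      q_value = NA_real_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) return(empty_pair_table())
  out <- out[order(-out$n_shared_miRNAs, out$p_value, out$lnc_id,
                   out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  if (params$fdr) out <- adjust_fdr(out)
  out
}

#' Benjamini-Hochberg q-values for a pair table
#'
#' @param pairs Pair data.frame with a `p_value` column.
#' @return `pairs` with `q_value` filled in (step-up BH over all rows).
#' @export
adjust_fdr <- function(pairs) {
  if (nrow(pairs) > 0L) {
    pairs$q_value <- stats::p.adjust(pairs$p_value, method = "BH")
  }
  pairs
}

#' Recompute an MRE index under flag filters
#'
#' Conserved-only / AGO-only modes restrict the site table before
#' aggregation, so both the shared-MRE numerator and the total-MRE
#' denominator reflect the restriction.
#'
#' @param site_table Site data.frame.
#' @param conserved_only Keep only sites flagged conserved.
#' @param ago_only Keep only sites flagged AGO-supported.
#' @return Filtered site table.
#' @export
filter_sites <- function(site_table, conserved_only = FALSE,
                         ago_only = FALSE) {
  if (conserved_only) {
    site_table <- site_table[!is.na(site_table$conserved) &
                             site_table$conserved, , drop = FALSE]
  }
  if (ago_only) {
    site_table <- site_table[!is.na(site_table$ago_supported) &
                             site_table$ago_supported, , drop = FALSE]
  }
  site_table
}
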