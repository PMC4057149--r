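## Tissue co-expression reports for ceRNA pairs. The ceRNA effect is
## strongest when the competing RNAs are present at near-equimolar
## concentration and the shared miRNAs are co-expressed, so for each tissue
## the report carries both abundances, a detectability flag, a fold-window
## equimolarity flag, and the shared miRNAs detected in that tissue. Missing
## expression is "unknown": flags are FALSE (never guessed TRUE) and the
## abundance stays NA.

#' Expression-report parameters
#'
#' @param expr_threshold Minimum abundance (e.g. FPKM) for a gene to count
#'   as expressed in a tissue.
#' @param mirna_threshold Minimum abundance for a shared miRNA to count as
#'   co-expressed (units of the supplied miRNA table).
#' @param fold_window Maximum fold difference for the near-equimolar flag.
#' @return A list of class `expression_params`.
#' @export
expression_params <- function(expr_threshold = 1.0, mirna_threshold = 1.0,
                              fold_window = 2.0) {
  stopifnot(expr_threshold >= 0, mirna_threshold >= 0, fold_window >= 1)
  structure(list(expr_threshold = expr_threshold,
                 mirna_threshold = mirna_threshold,
                 fold_window = fold_window),
            class = "expression_params")
}

#' Near-equimolar abundance flag
#'
#' TRUE iff both abundances are strictly positive and within `fold_window`
#' fold of each other. Symmetric in its arguments and monotone in
#' `fold_window`.
#'
#' @param a,b Non-negative abundances.
#' @param fold_window Maximum allowed fold ratio (>= 1).
#' @return Logical (vectorised).
#' @export
near_equimolar_flag <- function(a, b, fold_window = 2.0) {
  stopifnot(all(a >= 0, na.rm = TRUE), all(b >= 0, na.rm = TRUE))
  ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  out <- rep(FALSE, length(ok))
  out[ok] <- pmax(a[ok], b[ok]) / pmin(a[ok], b[ok]) <= fold_window
  out
}

#' Shared miRNAs co-expressed in one tissue
#'
#' @param shared_mirnas Character vector of shared miRNA ids.
#' @param mirna_expr miRNA expression matrix (rows = miRNAs, cols = tissues).
#' @param tissue Tissue name (must be a column of `mirna_expr`).
#' @param mirna_threshold Minimum abundance to count as co-expressed.
#' @return Lexicographically sorted character vector of co-expressed shared
#'   miRNAs; miRNAs absent from the matrix are excluded with a warning.
#' @export
coexpressed_shared_mirnas <- function(shared_mirnas, mirna_expr, tissue,
                                      mirna_threshold = 1.0) {
  if (!tissue %in% colnames(mirna_expr)) {
    stop("unknown tissue '", tissue, "'; available: ",
         paste(colnames(mirna_expr), collapse = ", "), call. = FALSE)
  }
  if (length(shared_mirnas) == 0L) return(character())
  known <- shared_mirnas %in% rownames(mirna_expr)
  if (any(!known)) {
    warning("miRNA(s) absent from expression matrix: ",
            paste(shared_mirnas[!known], collapse = ", "), call. = FALSE)
  }
  ids <- shared_mirnas[known]
  vals <- mirna_expr[ids, tissue]
  sort(ids[!is.na(vals) & vals >= mirna_threshold])
}

#' Per-tissue expression report for one ceRNA pair
#'
#' One row per tissue common to the gene and miRNA matrices (all gene-matrix
#' tissues when no miRNA matrix is given). `both_expressed` requires both
#' abundances at or above `expr_threshold`; `near_equimolar` additionally
#' requires the fold-window condition and hence implies `both_expressed`
#' thresholds are known (flags are FALSE whenever either abundance is
#' missing).
#'
#' @param pair List or one-row data.frame with `lnc_id`, `mrna_id` and
#'   optionally `shared_mirnas` (character vector, or comma-joined string as
#'   in the pair table's `shared_miRNA_list`).
#' @param gene_expr Gene expression matrix (rows = gene ids).
#' @param mirna_expr Optional miRNA expression matrix.
#' @param params [expression_params()].
#' @return Data.frame with columns `tissue`, `lnc_fpkm`, `mrna_fpkm`,
#'   `both_expressed`, `near_equimolar`, `coexpressed_shared_mirnas`
#'   (comma-joined).
#' @export
tissue_profile <- function(pair, gene_expr, mirna_expr = NULL,
                           params = expression_params()) {
  shared <- pair$shared_mirnas
  if (is.null(shared)) shared <- pair$shared_miRNA_list
  if (is.null(shared)) shared <- character()
  if (length(shared) == 1L && grepl(",", shared, fixed = TRUE)) {
    shared <- strsplit(shared, ",", fixed = TRUE)[[1]]
  }
  shared <- shared[nzchar(shared)]

  tissues <- colnames(gene_expr)
  if (!is.null(mirna_expr)) tissues <- intersect(tissues, colnames(mirna_expr))
  if (length(tissues) == 0L) stop("no common tissue between matrices",
                                  call. = FALSE)
  lookup <- function(id) {
    if (id %in% rownames(gene_expr)) {
      as.numeric(gene_expr[id, tissues])
    } else {
      warning("gene '", id, "' absent from expression matrix", call. = FALSE)
      rep(NA_real_, length(tissues))
    }
  }
  lnc <- lookup(pair$lnc_id)
  mrna <- lookup(pair$mrna_id)
  both <- !is.na(lnc) & !is.na(mrna) &
    lnc >= params$expr_threshold & mrna >= params$expr_threshold
  equi <- both & near_equimolar_flag(ifelse(is.na(lnc), 0, lnc),
                                     ifelse(is.na(mrna), 0, mrna),
                                     params$fold_window)
  coex <- vapply(tissues, function(tt) {
    if (is.null(mirna_expr) || length(shared) == 0L) return("")
    paste(suppressWarnings(
      coexpressed_shared_mirnas(shared, mirna_expr, tt,
                                params$mirna_threshold)), collapse = ",")
  }, "")
  data.frame(tissue = tissues, lnc_fpkm = lnc, mrna_fpkm = mrna,
             both_expressed = both, near_equimolar = equi,
             coexpressed_shared_mirnas = unname(coex),
             stringsAsFactors = FALSE)
}

#' Write per-tissue reports to TSV
#'
#' @param report Data.frame from [tissue_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tissue_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Spearman co-expression of a ceRNA pair across tissues
#'
#' Optional extra output: rank correlation of the two genes' abundances over
#' tissues where both are observed. Purely descriptive; no core contract
#' depends on it.
#'
#' @param report Data.frame from [tissue_profile()].
#' @return List with `rho` and `n_tissues_used` (NA when fewer than 3
#'   complete tissues).
#' @export
pair_coexpression <- function(report) {
  ok <- !is.na(report$lnc_fpkm) & !is.na(report$mrna_fpkm)
  if (sum(ok) < 3L) return(list(rho = NA_real_, n_tissues_used = sum(ok)))
  rho <- stats::cor(report$lnc_fpkm[ok], report$mrna_fpkm[ok],
                    method = "spearman")
  list(rho = rho, n_tissues_used = sum(ok))
}
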