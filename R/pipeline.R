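## End-to-end driver wiring the modules together: load inputs, predict
## sites, annotate, score pairs, report tissue co-expression. Used both
## programmatically and by the thin command-line script shipped in
## inst/cli/. All outputs are deterministic for a given config.

#' Pipeline configuration
#'
#' @param mirna_fasta,lncrna_fasta,mrna_fasta Input FASTA paths (miRNA and
#'   lncRNA required for every run; mRNA required for pair scoring).
#' @param gtf Optional GTF with exon models (needed to project genomic BEDs).
#' @param conserved_bed,ago_bed Optional genomic BED annotation.
#' @param conserved_tsv,ago_tsv Optional transcript-local annotation TSVs
#'   (`transcript_id`, `start`, `end`); alternative to the BED + GTF route.
#' @param gene_expression,mirna_expression Optional expression TSV paths.
#' @param out_dir Output directory.
#' @param align_params [alignment_params()].
#' @param cerna [cerna_params()].
#' @param expression [expression_params()].
#' @param mismatch_mode Passed to [predict_all()].
#' @param conserved_only,ago_only Restrict MRE counting to flagged sites.
#' @param n_profile_pairs Tissue reports are written for the top pairs (by
#'   the table's sort order), at most this many.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mirna_fasta, lncrna_fasta, mrna_fasta = NULL,
                            gtf = NULL, conserved_bed = NULL, ago_bed = NULL,
                            conserved_tsv = NULL, ago_tsv = NULL,
                            gene_expression = NULL, mirna_expression = NULL,
                            out_dir = "cerna_out",
                            align_params = alignment_params(),
                            cerna = cerna_params(),
                            expression = expression_params(),
                            mismatch_mode = "lncRNA",
                            conserved_only = FALSE, ago_only = FALSE,
                            n_profile_pairs = 20L) {
  structure(as.list(environment()), class = "pipeline_config")
}

validate_config <- function(config, need_mrna = TRUE) {
  required <- c(mirna_fasta = config$mirna_fasta,
                lncrna_fasta = config$lncrna_fasta)
  if (need_mrna) required <- c(required, mrna_fasta = config$mrna_fasta)
  for (nm in names(required)) {
    if (is.null(required[[nm]]) || !file.exists(required[[nm]])) {
      stop("[input validation] missing or unreadable ", nm, ": ",
           if (is.null(required[[nm]])) "(not set)" else required[[nm]],
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Run the full ceRNA pipeline
#'
#' Validates inputs first, then: predict target sites on lncRNAs and mRNAs,
#' annotate conservation / AGO support, aggregate MREs (optionally
#' restricted to flagged sites), build and score ceRNA pairs, and write the
#' site table, pair table, per-pair tissue reports and a run manifest under
#' `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress?
#' @return Invisibly, a list with `sites`, `pairs` and `reports`.
#' @export
run_full <- function(config, verbose = FALSE) {
  validate_config(config, need_mrna = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) if (verbose) message("[", ..., "]")

  mirnas <- read_fasta(config$mirna_fasta, "miRNA")
  lnc <- read_fasta(config$lncrna_fasta, "lncRNA")
  mrna <- read_fasta(config$mrna_fasta, "protein_coding")
  log_line("load: ", nrow(mirnas), " miRNAs, ", nrow(lnc), " lncRNAs, ",
           nrow(mrna), " mRNAs")

  sites <- predict_all(rbind(lnc, mrna), mirnas,
                       params = config$align_params,
                       mismatch_mode = config$mismatch_mode)
  log_line("predict: ", nrow(sites), " sites on ", nrow(lnc) + nrow(mrna),
           " transcripts")

  sites <- annotate_sites(sites, config)
  write_sites_tsv(sites, file.path(config$out_dir, "sites.tsv"))

  used <- filter_sites(sites, config$conserved_only, config$ago_only)
  lnc_index <- aggregate_mres(used[used$biotype == "lncRNA", , drop = FALSE])
  mrna_index <- aggregate_mres(used[used$biotype == "protein_coding", ,
                                    drop = FALSE])
  pairs <- build_pairs(lnc_index, mrna_index, params = config$cerna)
  log_line("score: ", nrow(pairs), " ceRNA pair(s)")
  write_pairs_tsv(pairs, file.path(config$out_dir, "pairs.tsv"))

  reports <- list()
  if (!is.null(config$gene_expression) && nrow(pairs) > 0L) {
    gene_expr <- read_expression_table(config$gene_expression)
    mirna_expr <- if (!is.null(config$mirna_expression))
      read_expression_table(config$mirna_expression) else NULL
    top <- utils::head(pairs, config$n_profile_pairs)
    for (i in seq_len(nrow(top))) {
      rep_i <- suppressWarnings(
        tissue_profile(top[i, ], gene_expr, mirna_expr,
                       params = config$expression))
      nm <- paste0("profile_", top$lnc_id[i], "_", top$mrna_id[i], ".tsv")
      write_tissue_report(rep_i, file.path(config$out_dir, nm))
      reports[[paste(top$lnc_id[i], top$mrna_id[i], sep = "|")]] <- rep_i
    }
    log_line("coexpress: ", length(reports), " tissue report(s)")
  }

  write_manifest(config, file.path(config$out_dir, "manifest.txt"),
                 counts = c(miRNAs = nrow(mirnas),
                            transcripts = nrow(lnc) + nrow(mrna),
                            sites = nrow(sites), pairs = nrow(pairs)))
  invisible(list(sites = sites, pairs = pairs, reports = reports))
}

## Set conservation / AGO flags from whichever annotation route the config
## provides (transcript-local TSV, or genomic BED projected through the GTF
## models).
annotate_sites <- function(sites, config) {
  models <- NULL
  need_models <- !is.null(config$conserved_bed) || !is.null(config$ago_bed)
  if (need_models) {
    if (is.null(config$gtf)) {
      stop("[annotate] genomic BED annotation requires a GTF of exon models",
           call. = FALSE)
    }
    models <- read_transcript_models(config$gtf)
  }
  if (!is.null(config$conserved_tsv)) {
    sites <- mark_conserved(sites, read_transcript_intervals(config$conserved_tsv))
  } else if (!is.null(config$conserved_bed)) {
    proj <- project_annotation(models, read_bed(config$conserved_bed))
    sites <- mark_conserved(sites, proj,
                            covered_transcripts = names(models))
  }
  if (!is.null(config$ago_tsv)) {
    sites <- mark_ago_supported(sites, read_transcript_intervals(config$ago_tsv))
  } else if (!is.null(config$ago_bed)) {
    proj <- project_annotation(models, read_bed(config$ago_bed))
    sites <- mark_ago_supported(sites, proj,
                                covered_transcripts = names(models))
  }
  sites
}

write_manifest <- function(config, path, counts = integer()) {
  fmt <- function(v) {
    if (is.null(v)) return("(unset)")
    if (inherits(v, c("alignment_params", "cerna_params",
                      "expression_params"))) {
      return(paste(sprintf("%s=%s", names(v), unlist(v)), collapse = " "))
    }
    paste(format(v), collapse = ",")
  }
  cks <- vapply(c("mirna_fasta", "lncrna_fasta", "mrna_fasta"), function(nm) {
    pth <- config[[nm]]
    if (is.null(pth) || !file.exists(pth)) "(unset)"
    else sprintf("%s md5=%s", pth, unname(tools::md5sum(pth)))
  }, "")
  lines <- c("ceRNAscan run manifest",
             sprintf("package_version: %s",
                     as.character(utils::packageVersion("ceRNAscan"))),
             sprintf("input_%s: %s", names(cks), cks),
             sprintf("config_%s: %s", names(config),
                     vapply(config, fmt, "")),
             sprintf("count_%s: %d", names(counts), counts))
  writeLines(lines, path)
  invisible(path)
}

#' Predict target sites only (CLI `predict-targets`)
#'
#' @param config A [pipeline_config()] (mRNA FASTA optional here).
#' @return The site table, also written to `out_dir/sites.tsv`.
#' @export
cli_predict_targets <- function(config) {
  validate_config(config, need_mrna = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  mirnas <- read_fasta(config$mirna_fasta, "miRNA")
  lnc <- read_fasta(config$lncrna_fasta, "lncRNA")
  transcripts <- if (!is.null(config$mrna_fasta))
    rbind(lnc, read_fasta(config$mrna_fasta, "protein_coding")) else lnc
  sites <- predict_all(transcripts, mirnas, params = config$align_params,
                       mismatch_mode = config$mismatch_mode)
  write_sites_tsv(sites, file.path(config$out_dir, "sites.tsv"))
  sites
}

#' Annotate an existing site table (CLI `annotate`)
#'
#' @param sites_tsv Path to a site table.
#' @param config A [pipeline_config()] carrying the annotation inputs.
#' @return The annotated site table, written to `out_dir/sites_annotated.tsv`.
#' @export
cli_annotate <- function(sites_tsv, config) {
  sites <- read_sites_tsv(sites_tsv)
  sites <- annotate_sites(sites, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_sites_tsv(sites, file.path(config$out_dir, "sites_annotated.tsv"))
  sites
}

#' Score ceRNA pairs from a site table (CLI `score`)
#'
#' @param sites_tsv Path to a (possibly annotated) site table.
#' @param config A [pipeline_config()].
#' @return The pair table, written to `out_dir/pairs.tsv`.
#' @export
cli_score <- function(sites_tsv, config) {
  sites <- read_sites_tsv(sites_tsv)
  used <- filter_sites(sites, config$conserved_only, config$ago_only)
  lnc_index <- aggregate_mres(used[used$biotype == "lncRNA", , drop = FALSE])
  mrna_index <- aggregate_mres(used[used$biotype == "protein_coding", ,
                                    drop = FALSE])
  pairs <- build_pairs(lnc_index, mrna_index, params = config$cerna)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_pairs_tsv(pairs, file.path(config$out_dir, "pairs.tsv"))
  pairs
}

#' Write a synthetic fixture bundle (CLI `simulate`)
#'
#' @param out_dir Output directory.
#' @param rng_seed Integer seed.
#' @param spec Optional [universe_spec()]; the default is a small
#'   sequence-backed universe.
#' @return `out_dir`, invisibly.
#' @export
cli_simulate <- function(out_dir, rng_seed = 1L, spec = NULL) {
  if (is.null(spec)) {
    spec <- universe_spec(n_mirnas = 12L, n_lncrnas = 3L, n_mrnas = 3L,
                          p_target = 0.4, sequences = TRUE,
                          rng_seed = rng_seed)
  }
  write_universe_bundle(make_cerna_universe(spec), out_dir)
}
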