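## Fully synthetic, seed-reproducible inputs: miRNA panels, transcripts with
## planted MREs whose exact coordinates and classes are known analytically,
## and membership-level ceRNA universes with controlled miRNA-set overlap for
## score and calibration checks. All randomness flows from one explicit seed
## per generator call; the global RNG state is saved and restored.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

RNA_BASES <- c("A", "C", "G", "U")

random_rna <- function(n) {
  paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")
}

## TRUE when the 6-mer seed matches itself at a shift of 1..5 (a periodic
## seed such as GGGGGG or ACACAC). Such seeds make "exactly one planted
## core" constructions impossible, so the panel generator avoids them.
has_self_overlap <- function(seed) {
  any(vapply(1:5, function(k)
    substr(seed, 1L, 6L - k) == substr(seed, k + 1L, 6L), logical(1)))
}

## The strings a plant of this miRNA writes verbatim into a transcript: the
## full 8mer construct (m8 complement + core + A anchor) and the reverse
## complement of the 13-18 block.
panel_member_strings <- function(seq) {
  p6 <- revcomp_rna(substr(seq, 2L, 7L))
  cm8 <- unname(.COMP[substr(seq, 8L, 8L)])
  list(p6 = p6, s8 = paste0(cm8, p6, "A"),
       block_rc = revcomp_rna(substr(seq, 13L, 18L)))
}

## A panel member is usable when no member's seed core occurs inside
## another member's fixed plant strings (or inside its own 3' block):
## such a clash would make every plant of one miRNA a spurious perfect
## site of another, which no background resampling can remove.
panel_compatible <- function(cand, accepted) {
  if (grepl(cand$p6, cand$block_rc, fixed = TRUE)) return(FALSE)
  for (o in accepted) {
    if (grepl(cand$p6, o$s8, fixed = TRUE) ||
        grepl(cand$p6, o$block_rc, fixed = TRUE) ||
        grepl(o$p6, cand$s8, fixed = TRUE) ||
        grepl(o$p6, cand$block_rc, fixed = TRUE)) return(FALSE)
  }
  TRUE
}

#' Generate a panel of synthetic miRNAs with distinct seeds
#'
#' `n` distinct 22-nt random RNA sequences whose 6-mer seeds (positions 2-7)
#' are pairwise distinct, aperiodic, and mutually compatible: a periodic
#' seed (e.g. `GGGGGG`) cannot be planted as a single unambiguous site, and
#' a seed core occurring inside another member's seed construct or 3'
#' compensatory block would make clean plants impossible, so such draws are
#' rejection-sampled away. Deterministic under `rng_seed`.
#'
#' @param n Number of miRNAs (1 <= n <= 4096, the number of distinct 6-mers;
#'   the aperiodicity and compatibility constraints lower the practical
#'   ceiling somewhat).
#' @param rng_seed Integer seed.
#' @return Data.frame with `id` (`mir-001`, ...), `sequence`, `biotype`.
#' @export
make_mirna_panel <- function(n, rng_seed = 1L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (n > 4096L) {
    stop("cannot build ", n, " distinct 6-mer seeds (only 4^6 exist)",
         call. = FALSE)
  }
  with_seed(rng_seed, {
    seqs <- character(n)
    seeds <- character(0)
    accepted <- list()
    for (i in seq_len(n)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 50000L) {
          stop("cannot find ", n, " distinct compatible 6-mer seeds",
               call. = FALSE)
        }
        s <- random_rna(22L)
        sd <- substr(s, 2L, 7L)
        if (sd %in% seeds || has_self_overlap(sd)) next
        cand <- panel_member_strings(s)
        if (panel_compatible(cand, accepted)) break
      }
      seqs[i] <- s
      seeds <- c(seeds, sd)
      accepted[[i]] <- cand
    }
    data.frame(id = sprintf("mir-%03d", seq_len(n)), sequence = seqs,
               biotype = "miRNA", stringsAsFactors = FALSE)
  })
}

#' Specification for a transcript with planted target sites
#'
#' @param transcript_length Length in nt.
#' @param planted Data.frame with `mirna_id`, `site_class` (one of the four
#'   perfect classes or `"mismatch-compensatory"`) and `position` (the
#'   `t_start` the reported site must have, 0-based).
#' @param rng_seed Integer seed.
#' @param base_probs Background base composition over A,C,G,U.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(transcript_length, planted, rng_seed = 1L,
                       base_probs = rep(0.25, 4)) {
  stopifnot(transcript_length >= 30L)
  structure(list(transcript_length = as.integer(transcript_length),
                 planted = planted, rng_seed = rng_seed,
                 base_probs = base_probs),
            class = "plant_spec")
}

## Build the literal string to splice in for one planted site, together with
## its footprint (0-based half-open) and the expected truth row. Guard bases
## around the pattern pin the site class (e.g. a non-A downstream base keeps
## a 7mer-m8 from being read as an 8mer).
plant_segment <- function(mir, site_class, pos) {
  pos <- as.integer(pos)
  pats <- seed_target_patterns(mir)
  p6 <- pats[["6mer"]]
  comp_m8 <- unname(.COMP[substr(mir$sequence, 8L, 8L)])
  pick <- function(exclude) sample(setdiff(RNA_BASES, exclude), 1L)
  block <- revcomp_rna(mir$three_prime_block)
  if (site_class == "6mer") {
    seg <- paste0(pick(comp_m8), p6, pick("A"))
    fp <- c(pos - 1L, pos + 7L)
    truth <- c(pos, pos + 6L, pos)
  } else if (site_class == "7mer-m8") {
    seg <- paste0(comp_m8, p6, pick("A"))
    fp <- c(pos, pos + 8L)
    truth <- c(pos, pos + 7L, pos + 1L)
  } else if (site_class == "7mer-A1") {
    seg <- paste0(pick(comp_m8), p6, "A")
    fp <- c(pos - 1L, pos + 7L)
    truth <- c(pos, pos + 7L, pos)
  } else if (site_class == "8mer") {
    seg <- paste0(comp_m8, p6, "A")
    fp <- c(pos, pos + 8L)
    truth <- c(pos, pos + 8L, pos + 1L)
  } else if (site_class == "mismatch-compensatory") {
    if (pos < 12L) stop("mismatch-compensatory plant needs position >= 12",
                        call. = FALSE)
    core <- seq_chars(p6)
    mut_at <- sample(2:5, 1L)
    core[mut_at] <- pick(core[mut_at])
    core1 <- paste(core, collapse = "")
    # block opposite miRNA 13-18 sits 11 nt upstream of the core, mimicking
    # the unbulged antiparallel geometry; spacer bases are filled at random
    spacer <- random_rna(4L)
    seg <- paste0(block, spacer, pick(comp_m8), core1, pick("A"))
    fp <- c(pos - 11L, pos + 7L)
    truth <- c(pos, pos + 6L, pos)
  } else {
    stop("unknown site class: ", site_class, call. = FALSE)
  }
  list(seg = seg, fp_start = fp[1], fp_end = fp[2],
       t_start = truth[1], t_end = truth[2], core_start = truth[3])
}

## Generator-side check that the assembled sequence contains exactly the
## planted loci: every exact 6mer-core occurrence and every one-mismatch
## core with its 13-18 block in the window must be a planted one. Written as
## a direct character-level scan, independent of the scanner it validates.
plants_are_exact <- function(tseq, panel_mirs, truth) {
  tchars <- seq_chars(tseq)
  L <- length(tchars)
  for (mir in panel_mirs) {
    p6 <- seq_chars(revcomp_rna(mir$seed6))
    comp_m8 <- unname(.COMP[substr(mir$sequence, 8L, 8L)])
    block <- revcomp_rna(mir$three_prime_block)
    want <- truth[truth$mirna_id == mir$id, , drop = FALSE]
    found <- list()
    for (p in 0:(L - 6L)) {
      mm <- sum(tchars[(p + 1L):(p + 6L)] != p6)
      if (mm == 0L) {
        m8 <- p > 0L && tchars[p] == comp_m8
        a1 <- p + 6L < L && tchars[p + 7L] == "A"
        cls <- if (m8 && a1) "8mer" else if (m8) "7mer-m8"
               else if (a1) "7mer-A1" else "6mer"
        found[[length(found) + 1L]] <-
          c(if (m8) p - 1L else p, if (a1) p + 7L else p + 6L, cls)
      } else if (mm == 1L) {
        w_end <- min(L, p + 7L); w_start <- max(0L, w_end - 25L)
        if (p - w_start >= 6L &&
            grepl(block, substr(tseq, w_start + 1L, p), fixed = TRUE)) {
          m8 <- p > 0L && tchars[p] == comp_m8
          found[[length(found) + 1L]] <-
            c(if (m8) p - 1L else p, p + 6L, "mismatch-compensatory")
        }
      }
    }
    if (length(found) != nrow(want)) return(FALSE)
    if (nrow(want) > 0L) {
      got <- do.call(rbind, found)
      got <- got[order(as.integer(got[, 1])), , drop = FALSE]
      want <- want[order(want$t_start), , drop = FALSE]
      if (!all(as.integer(got[, 1]) == want$t_start &
               as.integer(got[, 2]) == want$t_end &
               got[, 3] == want$site_class)) return(FALSE)
    }
  }
  TRUE
}

#' Build a transcript with planted target sites and its analytic truth
#'
#' The background is rejection-sampled (plants fixed, background redrawn)
#' until the assembled sequence contains no spurious seed match of any panel
#' miRNA — exact or one-mismatch-with-compensation — so the truth list is
#' exhaustive, not merely a lower bound.
#'
#' @param spec A [plant_spec()].
#' @param panel miRNA panel data.frame (from [make_mirna_panel()]); plants
#'   reference panel ids.
#' @param id Transcript identifier.
#' @param biotype Transcript biotype label.
#' @param max_tries Background redraws before giving up.
#' @return List with `record` (one-row data.frame `id`,`sequence`,`biotype`)
#'   and `truth` (data.frame `transcript_id`, `mirna_id`, `site_class`,
#'   `t_start`, `t_end`, `core_start`, sorted by `t_start`).
#' @export
make_transcript_with_planted_sites <- function(spec, panel, id = "tx1",
                                               biotype = "lncRNA",
                                               max_tries = 500L) {
  stopifnot(inherits(spec, "plant_spec"))
  panel_mirs <- as_mirna_list(panel)
  names(panel_mirs) <- panel$id
  with_seed(spec$rng_seed, {
    L <- spec$transcript_length
    planted <- spec$planted
    n_plants <- if (is.null(planted)) 0L else nrow(planted)
    build_segs <- function() {
      lapply(seq_len(n_plants), function(i) {
        m <- panel_mirs[[planted$mirna_id[i]]]
        if (is.null(m)) stop("planted miRNA not in panel: ",
                             planted$mirna_id[i], call. = FALSE)
        plant_segment(m, planted$site_class[i], planted$position[i])
      })
    }
    segs <- build_segs()
    if (n_plants > 0L) {
      fps <- data.frame(s = vapply(segs, `[[`, 0L, "fp_start"),
                        e = vapply(segs, `[[`, 0L, "fp_end"))
      if (any(fps$s < 0L) || any(fps$e > L)) {
        stop("planted site does not fit inside the transcript", call. = FALSE)
      }
      o <- order(fps$s)
      if (any(fps$s[o][-1] < fps$e[o][-length(o)])) {
        stop("planted sites overlap", call. = FALSE)
      }
    }
    truth <- if (n_plants > 0L) {
      data.frame(transcript_id = id,
                 mirna_id = planted$mirna_id,
                 site_class = planted$site_class,
                 t_start = vapply(segs, `[[`, 0L, "t_start"),
                 t_end = vapply(segs, `[[`, 0L, "t_end"),
                 core_start = vapply(segs, `[[`, 0L, "core_start"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(transcript_id = character(), mirna_id = character(),
                 site_class = character(), t_start = integer(),
                 t_end = integer(), core_start = integer(),
                 stringsAsFactors = FALSE)
    }
    for (try in seq_len(max_tries)) {
      # redraw both the background and the free choices inside the plant
      # segments (guard bases, spacers, mutated seed position): a clash
      # between a particular guard/spacer draw and another panel seed can
      # otherwise never be escaped
      if (try > 1L) segs <- build_segs()
      chars <- sample(RNA_BASES, L, replace = TRUE, prob = spec$base_probs)
      for (sg in segs) {
        chars[(sg$fp_start + 1L):sg$fp_end] <- seq_chars(sg$seg)
      }
      tseq <- paste(chars, collapse = "")
      if (plants_are_exact(tseq, panel_mirs, truth)) {
        truth <- truth[order(truth$t_start), , drop = FALSE]
        rownames(truth) <- NULL
        return(list(record = data.frame(id = id, sequence = tseq,
                                        biotype = biotype,
                                        stringsAsFactors = FALSE),
                    truth = truth))
      }
    }
    stop("could not realise a spurious-hit-free background in ", max_tries,
         " tries; shorten the transcript or shrink the panel", call. = FALSE)
  })
}

#' Specification of a synthetic ceRNA universe
#'
#' Emulates the statistical structure the ceRNA score and hypergeometric
#' test assume: each transcript is targeted by a miRNA subset of a universe
#' of size `n_mirnas`, with controlled overlap inside designated
#' lncRNA-mRNA pairs. With `p_both = p_target^2` (the default) membership in
#' the two members of a pair is independent — the calibration null of the
#' hypergeometric test.
#'
#' @param n_mirnas Universe size (M_T).
#' @param n_lncrnas,n_mrnas Transcript counts.
#' @param n_designated Number of designated pairs `(lnc_i, mrna_i)` whose
#'   expected statistics are recorded.
#' @param p_target Marginal probability a given miRNA targets a given
#'   transcript.
#' @param p_both Joint probability a miRNA targets both members of a
#'   designated pair (`p_target^2` = independent; larger = positive overlap).
#' @param mre_lambda Poisson mean for extra MREs per targeting miRNA (each
#'   targeting miRNA has `1 + Pois(mre_lambda)` sites).
#' @param n_tissues Number of tissues in the expression matrices.
#' @param expr_meanlog,expr_sdlog Log-normal abundance parameters.
#' @param mirna_detect_prob Probability a miRNA is detectable in a tissue.
#' @param sequences Realise actual transcript sequences with planted sites
#'   (feasible for small universes only)?
#' @param rng_seed Integer seed.
#' @return A list of class `universe_spec`.
#' @export
universe_spec <- function(n_mirnas = 24L, n_lncrnas = 4L, n_mrnas = 4L,
                          n_designated = min(n_lncrnas, n_mrnas),
                          p_target = 0.3, p_both = p_target^2,
                          mre_lambda = 0.5, n_tissues = 22L,
                          expr_meanlog = 2, expr_sdlog = 1,
                          mirna_detect_prob = 0.7, sequences = FALSE,
                          rng_seed = 1L) {
  stopifnot(n_mirnas >= 1L, n_lncrnas >= 1L, n_mrnas >= 1L,
            n_designated <= min(n_lncrnas, n_mrnas),
            p_target > 0, p_target <= 1, p_both <= p_target,
            p_both >= 0, n_tissues >= 1L)
  structure(as.list(environment()), class = "universe_spec")
}

## Membership draw for one transcript: ids of targeting miRNAs.
draw_set <- function(mirna_ids, p) mirna_ids[stats::runif(length(mirna_ids)) < p]

#' Generate a synthetic ceRNA universe
#'
#' Draws per-transcript miRNA sets and MRE counts, builds MRE indexes,
#' expression matrices, and — for designated pairs — the exact expected
#' shared/total MRE counts, ceRNA score and hypergeometric p-value implied
#' by the draw. With `sequences = TRUE` every transcript is realised as an
#' actual sequence with planted sites, so the full pipeline can be run
#' end-to-end against the recorded truth.
#'
#' @param spec A [universe_spec()].
#' @return List with `spec`, `mirnas`, `lnc_sets`, `mrna_sets`, `lnc_index`,
#'   `mrna_index`, `designated_pairs` (with expected statistics), `M_T`,
#'   `gene_expr`, `mirna_expr`, and in sequences mode also `transcripts`
#'   (data.frame) and `site_truth`.
#' @export
make_cerna_universe <- function(spec) {
  stopifnot(inherits(spec, "universe_spec"))
  with_seed(spec$rng_seed, {
    mirna_ids <- sprintf("mir-%04d", seq_len(spec$n_mirnas))
    lnc_ids <- sprintf("lnc-%04d", seq_len(spec$n_lncrnas))
    mrna_ids <- sprintf("pcg-%04d", seq_len(spec$n_mrnas))

    lnc_sets <- vector("list", spec$n_lncrnas); names(lnc_sets) <- lnc_ids
    mrna_sets <- vector("list", spec$n_mrnas); names(mrna_sets) <- mrna_ids
    nd <- spec$n_designated
    if (nd > 0L) {
      p_lnc_only <- spec$p_target - spec$p_both
      for (i in seq_len(nd)) {
        u <- stats::runif(spec$n_mirnas)
        both <- u < spec$p_both
        lnc_only <- u >= spec$p_both & u < spec$p_both + p_lnc_only
        mrna_only <- u >= spec$p_both + p_lnc_only &
          u < spec$p_both + 2 * p_lnc_only
        lnc_sets[[i]] <- mirna_ids[both | lnc_only]
        mrna_sets[[i]] <- mirna_ids[both | mrna_only]
      }
    }
    for (i in seq_len(spec$n_lncrnas)) {
      if (i > nd) lnc_sets[[i]] <- draw_set(mirna_ids, spec$p_target)
    }
    for (i in seq_len(spec$n_mrnas)) {
      if (i > nd) mrna_sets[[i]] <- draw_set(mirna_ids, spec$p_target)
    }

    draw_counts <- function(set) {
      if (length(set) == 0L) return(integer(0))
      stats::setNames(1L + stats::rpois(length(set), spec$mre_lambda), set)
    }
    lnc_counts <- lapply(lnc_sets, draw_counts)
    mrna_counts <- lapply(mrna_sets, draw_counts)

    mk_index <- function(counts_list, biotype) {
      tab <- data.frame(
        transcript_id = rep(names(counts_list), lengths(counts_list)),
        mirna_id = unlist(lapply(counts_list, names), use.names = FALSE),
        n = as.integer(unlist(counts_list, use.names = FALSE)),
        stringsAsFactors = FALSE)
      tab <- tab[order(tab$transcript_id, tab$mirna_id), , drop = FALSE]
      rownames(tab) <- NULL
      totals <- tapply(tab$n, tab$transcript_id, sum)
      totals <- stats::setNames(as.integer(totals), names(totals))
      sets <- lapply(split(tab$mirna_id, tab$transcript_id), sort)
      structure(list(counts = tab, totals = totals, mirna_sets = sets),
                class = "mre_index")
    }
    lnc_index <- mk_index(lnc_counts, "lncRNA")
    mrna_index <- mk_index(mrna_counts, "protein_coding")

    designated <- NULL
    if (nd > 0L) {
      designated <- do.call(rbind, lapply(seq_len(nd), function(i) {
        sl <- lnc_sets[[i]]; sm <- mrna_sets[[i]]
        shared <- sort(intersect(sl, sm))
        total <- sum(lnc_counts[[i]])
        shared_mre <- sum(lnc_counts[[i]][shared])
        data.frame(lnc_id = lnc_ids[i], mrna_id = mrna_ids[i],
                   m_n = length(sl), m_p = length(sm),
                   m_c = length(shared),
                   shared_MREs = as.integer(shared_mre),
                   total_MREs_lnc = as.integer(total),
                   ceRNA_score = if (total > 0) shared_mre / total else NA_real_,
                   p_value = if (length(sl) && length(sm))
                     hypergeom_pvalue(spec$n_mirnas, length(sm), length(sl),
                                      length(shared)) else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    }

    gene_ids <- c(lnc_ids, mrna_ids)
    tissues <- sprintf("tissue_%02d", seq_len(spec$n_tissues))
    gene_expr <- matrix(stats::rlnorm(length(gene_ids) * spec$n_tissues,
                                      spec$expr_meanlog, spec$expr_sdlog),
                        nrow = length(gene_ids),
                        dimnames = list(gene_ids, tissues))
    detect <- matrix(stats::runif(spec$n_mirnas * spec$n_tissues) <
                       spec$mirna_detect_prob, nrow = spec$n_mirnas)
    mirna_expr <- matrix(stats::rlnorm(spec$n_mirnas * spec$n_tissues,
                                       spec$expr_meanlog, spec$expr_sdlog),
                         nrow = spec$n_mirnas,
                         dimnames = list(mirna_ids, tissues))
    mirna_expr[!detect] <- 0

    out <- list(spec = spec, mirnas = data.frame(id = mirna_ids,
                                                 stringsAsFactors = FALSE),
                lnc_sets = lnc_sets, mrna_sets = mrna_sets,
                lnc_index = lnc_index, mrna_index = mrna_index,
                designated_pairs = designated, M_T = spec$n_mirnas,
                gene_expr = gene_expr, mirna_expr = mirna_expr)

    if (spec$sequences) {
      panel <- make_mirna_panel(spec$n_mirnas,
                                rng_seed = sample.int(2^30, 1L))
      panel$id <- mirna_ids
      out$mirnas <- panel
      realise <- function(tx_ids, counts_list, biotype) {
        recs <- list(); truths <- list()
        for (tx in tx_ids) {
          cc <- counts_list[[tx]]
          n_sites <- sum(cc)
          if (n_sites == 0L) {
            planted <- data.frame(mirna_id = character(),
                                  site_class = character(),
                                  position = integer(),
                                  stringsAsFactors = FALSE)
          } else {
            classes <- sample(c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                              n_sites, replace = TRUE)
            planted <- data.frame(
              mirna_id = rep(names(cc), cc),
              site_class = classes,
              position = 20L + 40L * (seq_len(n_sites) - 1L),
              stringsAsFactors = FALSE)
          }
          res <- make_transcript_with_planted_sites(
            plant_spec(40L * max(1L, n_sites) + 60L, planted,
                       rng_seed = sample.int(2^30, 1L)),
            panel, id = tx, biotype = biotype)
          recs[[tx]] <- res$record
          truths[[tx]] <- res$truth
        }
        list(records = do.call(rbind, recs), truth = do.call(rbind, truths))
      }
      lnc_r <- realise(lnc_ids, lnc_counts, "lncRNA")
      mrna_r <- realise(mrna_ids, mrna_counts, "protein_coding")
      out$transcripts <- rbind(lnc_r$records, mrna_r$records)
      rownames(out$transcripts) <- NULL
      out$site_truth <- rbind(lnc_r$truth, mrna_r$truth)
      rownames(out$site_truth) <- NULL
    }
    out
  })
}

#' Write a universe bundle to disk in the pipeline's own file dialects
#'
#' Emits miRNA/lncRNA/mRNA FASTA (sequences mode), expression TSVs, the
#' planted-site truth table, expected designated-pair statistics, synthetic
#' transcript-local conservation and AGO interval TSVs covering a subset of
#' the planted sites, and a plain-text manifest of the generating spec.
#'
#' @param universe Output of [make_cerna_universe()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_universe_bundle <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_expression_table(universe$gene_expr, p("gene_expression.tsv"),
                         id_column = "gene_id")
  write_expression_table(universe$mirna_expr, p("mirna_expression.tsv"),
                         id_column = "mirna_id")
  if (!is.null(universe$designated_pairs)) {
    utils::write.table(universe$designated_pairs, p("expected_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(universe$transcripts)) {
    tr <- universe$transcripts
    write_fasta(universe$mirnas, p("mirnas.fa"))
    write_fasta(tr[tr$biotype == "lncRNA", , drop = FALSE], p("lncrna.fa"))
    write_fasta(tr[tr$biotype == "protein_coding", , drop = FALSE],
                p("mrna.fa"))
    utils::write.table(universe$site_truth, p("sites_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ann <- synth_annotation_intervals(universe)
    utils::write.table(ann$conserved, p("conserved_regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ann$ago, p("ago_regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  sp <- universe$spec
  manifest <- c("generator: ceRNAscan synthetic universe",
                sprintf("%s: %s", names(sp),
                        vapply(sp, function(v) paste(format(v), collapse = ","),
                               "")))
  writeLines(manifest, p("manifest.txt"))
  invisible(dir)
}

## Synthetic transcript-local annotation: conserved blocks (>= 8 nt) around
## roughly half the planted seeds plus a too-short decoy per transcript; AGO
## intervals overlapping roughly half the seeds. Deterministic given the
## universe (hash of coordinates, no RNG).
synth_annotation_intervals <- function(universe) {
  tr <- universe$site_truth
  pickA <- tr$t_start %% 2L == 0L
  conserved <- data.frame(transcript_id = tr$transcript_id[pickA],
                          start = pmax(0L, tr$t_start[pickA] - 2L),
                          end = tr$t_end[pickA] + 2L,
                          source_label = rep("synthetic_conserved", sum(pickA)),
                          stringsAsFactors = FALSE)
  decoys <- data.frame(transcript_id = unique(tr$transcript_id),
                       start = 0L, end = 7L,
                       source_label = "short_decoy",
                       stringsAsFactors = FALSE)
  ago <- data.frame(transcript_id = tr$transcript_id[!pickA],
                    start = tr$t_start[!pickA],
                    end = tr$t_start[!pickA] + 1L,
                    source_label = rep("synthetic_ago", sum(!pickA)),
                    stringsAsFactors = FALSE)
  list(conserved = rbind(conserved, decoys), ago = ago)
}
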