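# Independent reference implementations ("oracles") used to validate the
# package: a naive all-offsets site scanner, exhaustive hypergeometric
# enumeration, and a per-base coordinate projection. Each is written as
# directly as possible and shares no code with the implementation it checks.

ORACLE_COMP <- c(A = "U", C = "G", G = "C", U = "A", N = "?")

oracle_revcomp <- function(x) {
  paste(rev(unname(ORACLE_COMP[strsplit(x, "")[[1]]])), collapse = "")
}

# Naive scanner: tests every offset of the transcript against every seed
# class of the miRNA, including the one-mismatch + 13-18 compensation rule.
# Coordinates 0-based half-open, like the package.
oracle_scan <- function(tseq, mir_seq, allow_mismatch = TRUE) {
  tseq <- chartr("T", "U", toupper(tseq))
  mir_seq <- chartr("T", "U", toupper(mir_seq))
  tch <- strsplit(tseq, "")[[1]]
  L <- length(tch)
  core <- strsplit(oracle_revcomp(substr(mir_seq, 2, 7)), "")[[1]]
  m8c <- unname(ORACLE_COMP[substr(mir_seq, 8, 8)])
  block <- oracle_revcomp(substr(mir_seq, 13, 18))
  hits <- list()
  if (L < 6) return(data.frame(t_start = integer(), t_end = integer(),
                               site_class = character(),
                               stringsAsFactors = FALSE))
  for (p in 0:(L - 6)) {
    window <- tch[(p + 1):(p + 6)]
    n_mm <- sum(window != core)
    if (n_mm == 0) {
      has_m8 <- p >= 1 && tch[p] == m8c
      has_a1 <- (p + 7) <= L && tch[p + 7] == "A"
      cls <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
             else if (has_a1) "7mer-A1" else "6mer"
      hits[[length(hits) + 1]] <- data.frame(
        t_start = if (has_m8) p - 1 else p,
        t_end = if (has_a1) p + 7 else p + 6,
        site_class = cls, stringsAsFactors = FALSE)
    } else if (n_mm == 1 && allow_mismatch) {
      w_end <- min(L, p + 7)
      w_start <- max(0, w_end - 25)
      upstream <- substr(tseq, w_start + 1, p)
      if (nchar(upstream) >= 6 && grepl(block, upstream, fixed = TRUE)) {
        has_m8 <- p >= 1 && tch[p] == m8c
        hits[[length(hits) + 1]] <- data.frame(
          t_start = if (has_m8) p - 1 else p,
          t_end = p + 6,
          site_class = "mismatch-compensatory", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(data.frame(t_start = integer(), t_end = integer(),
                      site_class = character(), stringsAsFactors = FALSE))
  }
  out[order(out$t_start), , drop = FALSE]
}

# Exhaustive hypergeometric tail: enumerate every m_n-subset of 1..M_T and
# count those sharing at least m_c members with the fixed set 1..m_p.
oracle_hyper <- function(M_T, m_p, m_n, m_c) {
  if (m_c == 0) return(1)
  if (m_n == 0) return(if (m_c == 0) 1 else 0)
  draws <- utils::combn(M_T, m_n)
  overlaps <- colSums(draws <= m_p)
  mean(overlaps >= m_c)
}

# Per-base projection oracle: walk the spliced transcript base by base,
# recording which genomic position each transcript position touches, then
# look up which transcript positions fall inside the genomic interval.
oracle_project <- function(model, g_start, g_end) {
  ex <- model$exons
  order_tx <- if (model$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  genomic_of <- integer(0)
  for (j in order_tx) {
    bases <- ex$start[j]:(ex$end[j] - 1)
    if (model$strand == "-") bases <- rev(bases)
    genomic_of <- c(genomic_of, bases)
  }
  t_pos <- which(genomic_of >= g_start & genomic_of < g_end) - 1L
  if (length(t_pos) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  t_pos <- sort(t_pos)
  # a run breaks when transcript positions jump OR the underlying genomic
  # positions are not adjacent (i.e. an exon junction): junction-spanning
  # intervals stay split into per-exon pieces
  contiguous <- diff(t_pos) == 1L &
    abs(diff(genomic_of[t_pos + 1L])) == 1L
  breaks <- c(0L, which(!contiguous), length(t_pos))
  out <- data.frame(
    start = t_pos[breaks[-length(breaks)] + 1L],
    end = t_pos[breaks[-1]] + 1L)
  out[order(out$start), , drop = FALSE]
}

# Random multi-exon transcript model on a small synthetic chromosome.
random_model <- function(id = "tx", strand = sample(c("+", "-"), 1),
                         n_exons = sample(1:4, 1)) {
  pos <- 0L
  starts <- integer(n_exons); ends <- integer(n_exons)
  for (j in seq_len(n_exons)) {
    pos <- pos + sample(5:60, 1)          # intergenic / intronic gap
    starts[j] <- pos
    pos <- pos + sample(8:50, 1)          # exon length
    ends[j] <- pos
  }
  transcript_model(id, paste0(id, "_gene"), "chrS", strand,
                   data.frame(start = starts, end = ends))
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Random miRNA sequence (22 nt) as a plain string.
random_mirna_seq <- function() random_rna_str(22L)

site_key <- function(df) {
  if (nrow(df) == 0) return(character())
  paste(df$t_start, df$t_end, df$site_class, sep = "|")
}
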