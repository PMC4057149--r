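## Canonical RNA alphabet used for all base-pair comparisons. Inputs may mix
## DNA-space transcripts and RNA-space miRNAs; every comparison happens after
## T -> U normalisation so the two spellings are equivalent.

#' Normalise a nucleotide string to the canonical RNA alphabet
#'
#' Uppercases and maps `T` to `U`. Characters outside `{A,C,G,U,N}` after
#' normalisation raise an error.
#'
#' @param x Character vector of nucleotide sequences.
#' @param what Label used in error messages.
#' @return Character vector of the same length, RNA alphabet, uppercase.
#' @export
canonical_rna <- function(x, what = "sequence") {
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop(sprintf("%s %d contains characters outside {A,C,G,U,T,N}",
                 what, which(bad)[1]), call. = FALSE)
  }
  x
}

## Complement map in RNA space. N maps to a sentinel that can never equal a
## real target base, so ambiguous positions never count as paired.
.COMP <- c(A = "U", C = "G", G = "C", U = "A", N = "*")

#' Reverse complement in RNA space
#'
#' `N` complements to a sentinel character that never matches, so ambiguity
#' codes cannot produce spurious seed matches.
#'
#' @param x A single canonical RNA string.
#' @return The reverse complement, 5'->3'.
#' @export
revcomp_rna <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(rev(unname(.COMP[chars])), collapse = "")
}

## Vectorised pair classification between a miRNA base and a target base
## (both canonical RNA). Returns "wc", "wobble" or "none".
pair_class <- function(mi, tg) {
  n <- max(length(mi), length(tg))
  mi <- rep_len(mi, n)
  tg <- rep_len(tg, n)
  out <- rep("none", n)
  out[(mi == "A" & tg == "U") | (mi == "U" & tg == "A") |
      (mi == "G" & tg == "C") | (mi == "C" & tg == "G")] <- "wc"
  out[(mi == "G" & tg == "U") | (mi == "U" & tg == "G")] <- "wobble"
  out
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
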