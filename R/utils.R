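#' @importFrom stats rnorm rpois runif rbinom setNames dist
#' @importFrom utils write.table read.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Base-wise complement and reversal for plain character vectors.
#' `N` is preserved.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

## split a sequence string into a character vector of bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## substitute base at 1-based positions with draws uniform over the 3 others
mutate_bases <- function(chars, pos) {
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  chars
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

## deterministic per-stage seed derived from a user seed; kept < 2^31
stage_seed <- function(seed, stage) {
  offs <- c(subgenomes = 11L, genotypes = 29L, reads = 47L, barcodes = 83L,
            intensity = 101L, pipeline = 131L)
  o <- offs[[stage]]
  (as.integer(seed) %% 21474836L) * 97L + o
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

## Hamming distance between two equal-length strings
hamming <- function(a, b) {
  sum(seq_chars(a) != seq_chars(b))
}

## IUPAC code for a set of bases (used for consensus ties)
iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  out <- codes[key]
  if (is.na(out)) "N" else unname(out)
}
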