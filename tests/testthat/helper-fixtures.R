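## shared fixture builders for the test suite

## deterministic random DNA string
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## substitute the bases at `pos` (1-based) deterministically (A->C->G->T->A)
sub_at <- function(seq, pos) {
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- rot[ch[pos]]
  paste(ch, collapse = "")
}

## n haplotypes derived from one ancestral sequence, each with `k` private
## substitutions at disjoint positions (pairwise difference = 2k)
planted_haplotypes <- function(len, n_hap, k, seed = 1) {
  set.seed(seed)
  anc <- rand_dna(len)
  pos <- sample(seq_len(len), n_hap * k)
  lapply(seq_len(n_hap), function(i) {
    sub_at(anc, pos[((i - 1) * k + 1):(i * k)])
  })
}

## read set data.frame from sequences
reads_df <- function(seqs, prefix = "r") {
  data.frame(read_id = sprintf("%s%03d", prefix, seq_along(seqs)),
             sequence = unlist(seqs), stringsAsFactors = FALSE)
}

## minimal variant observation row
obs_row <- function(genotype, contig = "c1", pos = 100L, ref = "A",
                    alt = "G", type = "SUB", depth = 20L, supp = 10L,
                    amplicon = "amp001") {
  data.frame(genotype_id = genotype, amplicon_id = amplicon,
             contig_id = contig, position = pos, ref = ref, alt = alt,
             type = type, site_depth = depth, alt_support = supp,
             stringsAsFactors = FALSE)
}

## a contig list entry as produced by the assembler
fake_contig <- function(contig_id, consensus, genotype_id = "g1",
                        amplicon_id = "amp001", n_reads = 10L) {
  list(contig_id = contig_id, genotype_id = genotype_id,
       consensus = consensus, amplicon_id = amplicon_id,
       member_read_ids = sprintf("%s_r%02d", contig_id, seq_len(n_reads)),
       depth = rep(n_reads, nchar(consensus)))
}

## brute-force affine-gap Smith-Waterman score (oracle for local_align);
## a gap of length L costs open + L * extend, matching the package scoring
sw_score_oracle <- function(a, b, match = 2, mismatch = -3, open = 5,
                            extend = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)     # best ending in match/mismatch
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b (consume a)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a (consume b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      best <- max(best, M[i, j])
    }
  }
  best
}
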