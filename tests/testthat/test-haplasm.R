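test_that("identical reads assemble into a single cluster", {
  reads <- reads_df(rep(rand_dna(300, seed = 1), 10))
  res <- cluster_reads(reads)
  expect_length(res$clusters, 1L)
  expect_length(res$clusters[[1]]$member_read_ids, 10L)
  expect_identical(res$clusters[[1]]$consensus, reads$sequence[1])
  expect_length(res$unassembled, 0L)
})

test_that("haplotypes below the identity threshold split at the join step", {
  ## two haplotypes at 96% identity (12 diffs over 300 bp -> 4% divergence)
  haps <- planted_haplotypes(300, 2, 6, seed = 2)
  reads <- reads_df(c(rep(haps[[1]], 5), rep(haps[[2]], 5)))
  res <- cluster_reads(reads)
  expect_length(res$clusters, 2L)
  expect_setequal(vapply(res$clusters, function(cl) length(cl$member_read_ids),
                         integer(1)), c(5L, 5L))
})

test_that("clusters below the minimum read count dissolve into singletons", {
  reads <- reads_df(rep(rand_dna(300, seed = 3), 4))
  res <- cluster_reads(reads)
  expect_length(res$clusters, 0L)
  expect_length(res$unassembled, 4L)
})

test_that("conflict splitting decomposes sub-genome haplotypes above the identity threshold", {
  ## three haplotypes at ~99% pairwise identity (2 private diffs each over
  ## 400 bp) cannot be separated by the 97% join rule, only by confirmed
  ## conflict columns
  haps <- planted_haplotypes(400, 3, 2, seed = 4)
  reads <- reads_df(c(rep(haps[[1]], 8), rep(haps[[2]], 8), rep(haps[[3]], 9)))
  res <- cluster_reads(reads)
  expect_length(res$clusters, 3L)
  sizes <- sort(vapply(res$clusters, function(cl)
    length(cl$member_read_ids), integer(1)))
  expect_identical(sizes, c(8L, 8L, 9L))
  ## consensus of each cluster reproduces one planted haplotype
  expect_setequal(vapply(res$clusters, `[[`, character(1), "consensus"),
                  unlist(haps))
  ## with splitting disabled everything co-assembles
  res0 <- cluster_reads(reads, assembly_params(split_conflicts = FALSE))
  expect_length(res0$clusters, 1L)
})

test_that("an isolated heterozygous column does not shatter a cluster", {
  ## two alleles differing at ONE position, 4 reads each: a single allelic
  ## site whose sides could not both form contigs is not split
  a <- rand_dna(300, seed = 5)
  b <- sub_at(a, 150)
  res <- cluster_reads(reads_df(c(rep(a, 4), rep(b, 4))))
  expect_length(res$clusters, 1L)
  expect_length(res$clusters[[1]]$member_read_ids, 8L)
})

test_that("clustering is a partition of the input reads", {
  set.seed(6)
  for (rep in 1:3) {
    haps <- planted_haplotypes(250, 2, 5, seed = rep)
    seqs <- unlist(lapply(sample(rep(1:2, c(7, 6))), function(i) {
      sub_at(haps[[i]], sample(250, 2))  # noisy copies
    }))
    reads <- reads_df(seqs)
    res <- cluster_reads(reads)
    got <- c(unlist(lapply(res$clusters, `[[`, "member_read_ids")),
             res$unassembled)
    expect_setequal(got, reads$read_id)
    expect_false(anyDuplicated(got) > 0)
  }
})

test_that("cluster count is stable under read shuffling", {
  haps <- planted_haplotypes(300, 3, 6, seed = 7)
  reads <- reads_df(c(rep(haps[[1]], 6), rep(haps[[2]], 6), rep(haps[[3]], 6)))
  n0 <- length(cluster_reads(reads)$clusters)
  for (s in 1:5) {
    set.seed(s)
    perm <- reads[sample(nrow(reads)), , drop = FALSE]
    expect_identical(length(cluster_reads(perm)$clusters), n0)
  }
})

test_that("consensus calls majorities, IUPAC ties, and trims thin termini", {
  base <- rand_dna(60, seed = 8)
  expect_identical(consensus(list(seqs = rep(base, 4)))$consensus, base)
  ## 3xA vs 2xG at one column -> majority A
  withA <- sub_at(base, 30)  # rotated base
  cl <- list(seqs = c(rep(base, 3), rep(withA, 2)), consensus = base)
  expect_identical(consensus(cl)$consensus, base)
  ## 3 vs 3 tie -> IUPAC code of the two bases
  cl2 <- list(seqs = c(rep(base, 3), rep(withA, 3)), consensus = base)
  cons <- consensus(cl2)$consensus
  b1 <- substr(base, 30, 30); b2 <- substr(withA, 30, 30)
  expect_identical(substr(cons, 30, 30), polysnp:::iupac_code(c(b1, b2)))
  ## terminal columns with depth < 2 are trimmed
  long <- paste0(base, "ACGTACGT")
  cl3 <- list(seqs = c(rep(base, 3), long), consensus = long)
  expect_identical(consensus(cl3)$consensus, base)
  expect_error(consensus(list(seqs = character(0))), "empty")
})

test_that("contigs are attributed via progenitors, then fallbacks, else unattributed", {
  amp_seq <- rand_dna(400, seed = 9)
  prog <- data.frame(ref_id = "amp001|P", amplicon = "amp001",
                     sequence = amp_seq, stringsAsFactors = FALSE)
  ## the EST surrogate template is a different locus region: unrelated to
  ## the progenitor ortholog but matching the second contig at ~98%
  fall_seq <- rand_dna(400)
  fall <- data.frame(ref_id = "amp001", amplicon = "amp001",
                     sequence = fall_seq, stringsAsFactors = FALSE)
  contigs <- list(
    fake_contig("exact", amp_seq),
    fake_contig("fallback_only", sub_at(fall_seq, c(100, 200, 300))))
  out <- attribute_contigs(contigs, prog, fall)
  via <- setNames(vapply(out, `[[`, character(1), "attributed_via"),
                  vapply(out, `[[`, character(1), "contig_id"))
  amp <- setNames(vapply(out, `[[`, character(1), "amplicon_id"),
                  names(via))
  expect_identical(amp[["exact"]], "amp001")
  expect_identical(via[["exact"]], "progenitor")
  expect_identical(amp[["fallback_only"]], "amp001")
  expect_identical(via[["fallback_only"]], "fallback")
  ## an unrelated contig matches nothing once chance micro-overlaps are
  ## excluded by a non-trivial overlap requirement
  stranger <- attribute_contigs(list(fake_contig("nothing", rand_dna(400))),
                                prog, fall,
                                mapping_params(min_overlap = 50L,
                                               min_identity = 0.80))
  expect_identical(stranger[[1]]$amplicon_id, "UNATTRIBUTED")
})

test_that("assembly summary reports contig and HSV statistics", {
  contigs <- list(fake_contig("c1", rand_dna(500, seed = 10), amplicon_id = "amp001"),
                  fake_contig("c2", rand_dna(500), amplicon_id = "amp001"),
                  fake_contig("c3", rand_dna(500), amplicon_id = "amp002"),
                  fake_contig("c4", rand_dna(500), amplicon_id = "amp002"))
  s <- assembly_summary(contigs, hsv = list(n_events = 10L, aligned_bp = 1090L))
  expect_equal(s$contigs_per_amplicon, 2.0)
  expect_identical(s$hsv_every_bp, 109)
  expect_identical(s$hsv_frequency, "1 HSV every 109 bp")
  s0 <- assembly_summary(contigs, hsv = list(n_events = 0L, aligned_bp = 900L))
  expect_identical(s0$hsv_frequency, "none")
})

test_that("het-column polishing restores the allele shared with siblings", {
  anc <- rand_dna(300, seed = 11)
  alt <- sub_at(anc, 150)
  sib <- sub_at(anc, c(50, 250))  # a sibling sub-genome, anc at column 150
  ## contig built from a heterozygous read set whose majority fell on alt
  contigs <- list(
    c(fake_contig("het", alt), list(seqs = c(rep(alt, 4), rep(anc, 3)))),
    c(fake_contig("sib", sib), list(seqs = rep(sib, 6))))
  out <- polish_het_columns(contigs)
  expect_identical(substr(out[[1]]$consensus, 150, 150),
                   substr(anc, 150, 150))
  ## sibling consensus untouched
  expect_identical(out[[2]]$consensus, sib)
})
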