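test_that("invalid configurations are rejected", {
  expect_error(sim_config(hsv_rate = 1.5), "rates")
  expect_error(sim_config(amplicon_length = 0), "amplicon_length")
  expect_error(sim_config(read_length = 600, amplicon_length = 500),
               "read_length")
  expect_error(sim_config(n_genotypes_per_morphotype = 1, snp_rate = 2),
               "qualification")
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_amplicons = 2, n_genotypes_per_morphotype = 3,
                    depth = 5, snp_rate = 2, diagnostic_rate = 1, seed = 42)
  expect_identical(simulate_population(cfg), simulate_population(cfg))
})

test_that("HSV truth equals the column-wise difference set of the references", {
  for (seed in c(1, 7, 23)) {
    cfg <- sim_config(n_amplicons = 2, amplicon_length = 300,
                      read_length = 250, seed = seed)
    sg <- simulate_subgenomes(cfg)
    for (amp in names(sg$references)) {
      mat <- do.call(rbind, lapply(sg$references[[amp]],
                                   function(s) strsplit(s, "")[[1]]))
      diffs <- which(apply(mat, 2, function(col) length(unique(col)) > 1))
      expect_identical(sort(sg$hsv$position[sg$hsv$amplicon == amp]),
                       as.integer(diffs))
    }
  }
})

test_that("hsv_rate = 0 yields identical sub-genomes and empty HSV truth", {
  cfg <- sim_config(n_amplicons = 2, hsv_rate = 0, seed = 3)
  sg <- simulate_subgenomes(cfg)
  for (amp in names(sg$references)) {
    expect_length(unique(unlist(sg$references[[amp]])), 1L)
  }
  expect_identical(nrow(sg$hsv), 0L)
})

test_that("pairwise HSV density matches the Poisson expectation", {
  ## 545 bp at 1 HSV / 109 bp -> expected 5 pairwise differences
  cfg <- sim_config(n_amplicons = 400, amplicon_length = 545,
                    hsv_rate = 1 / 109, primer_length = 0, seed = 11)
  sg <- simulate_subgenomes(cfg)
  counts <- vapply(sg$references, function(r) {
    sum(strsplit(r$P, "")[[1]] != strsplit(r$G1, "")[[1]])
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 545 / 109), 3 * se + 0.05)
})

test_that("SNP carrier counts follow the truncated binomial", {
  ## enumeration oracle: each of 2 allele copies carries the alt with
  ## probability f, so a genotype is a carrier with q = 1 - (1-f)^2; the
  ## carrier count is Binomial(n, q) truncated to [2, n-1]
  n <- 6; f <- 0.5
  q <- 1 - (1 - f)^2
  pk <- dbinom(0:n, n, q)
  keep <- 2:(n - 1)
  expected <- sum(keep * pk[keep + 1]) / sum(pk[keep + 1])
  set.seed(9)
  draws <- replicate(500, sum(polysnp:::draw_carriers(n, f)$dosage > 0))
  expect_true(all(draws >= 2 & draws <= n - 1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("planted variants respect their construction rules", {
  cfg <- sim_config(n_amplicons = 4, n_genotypes_per_morphotype = 6,
                    snp_rate = 6, diagnostic_rate = 2, seed = 5)
  sg <- simulate_subgenomes(cfg)
  gn <- simulate_genotypes(sg, cfg)
  expect_true(all(gn$snp_records$n_carriers >= 2 &
                  gn$snp_records$n_carriers <= 5))
  expect_true(all(gn$snp_dosages$dosage %in% 0:2))
  ## SNP / diagnostic positions never collide with HSVs
  hsv_key <- paste(sg$hsv$amplicon, sg$hsv$position)
  expect_false(any(paste(gn$snp_records$amplicon,
                         gn$snp_records$position) %in% hsv_key))
  expect_false(any(paste(gn$diagnostic_records$amplicon,
                         gn$diagnostic_records$position) %in% hsv_key))
  ## diagnostic alleles are fixed within the alt morphotype
  for (i in seq_len(nrow(gn$diagnostic_records))) {
    d <- gn$diagnostic_records[i, ]
    for (g in gn$genotypes$genotype_id[gn$genotypes$morphotype == d$alt_morphotype]) {
      alleles <- gn$haplotypes[[g]][[d$amplicon]][[d$subgenome]]
      expect_true(all(substr(alleles, d$position, d$position) == d$alt))
    }
  }
})

test_that("zero variant rates leave haplotypes identical to the references", {
  cfg <- sim_config(n_amplicons = 2, n_genotypes_per_morphotype = 2,
                    snp_rate = 0, diagnostic_rate = 0, seed = 8)
  sg <- simulate_subgenomes(cfg)
  gn <- simulate_genotypes(sg, cfg)
  for (g in names(gn$haplotypes)) {
    for (amp in names(gn$haplotypes[[g]])) {
      for (sgn in names(gn$haplotypes[[g]][[amp]])) {
        expect_identical(unique(gn$haplotypes[[g]][[amp]][[sgn]]),
                         sg$references[[amp]][[sgn]])
      }
    }
  }
})

test_that("error-free reads are exact haplotype substrings with their barcode", {
  cfg <- sim_config(n_amplicons = 2, n_genotypes_per_morphotype = 2,
                    depth = 4, sub_error = 0, homopolymer_indel_rate = 0,
                    snp_rate = 2, diagnostic_rate = 0, seed = 13)
  sg <- simulate_subgenomes(cfg)
  gn <- simulate_genotypes(sg, cfg)
  rs <- simulate_reads(gn, cfg)
  for (i in seq_len(nrow(rs$reads))) {
    tr <- rs$truth[rs$truth$read_id == rs$reads$read_id[i], ]
    bc <- rs$barcode_table$barcode[rs$barcode_table$genotype_id == tr$genotype_id]
    expect_identical(substr(rs$reads$sequence[i], 1, 8), bc)
    hap <- gn$haplotypes[[tr$genotype_id]][[tr$amplicon]][[tr$subgenome]][tr$allele]
    body <- substring(rs$reads$sequence[i], 9)
    expect_identical(body,
                     substr(hap, tr$offset + 1, tr$offset + nchar(body)))
  }
})

test_that("read truth is a conservation map and exact-count depth multiplies out", {
  ## depth 25, 6 genotypes (3 per morphotype x 2), 10 amplicons -> 1500 reads
  cfg <- sim_config(n_amplicons = 10, n_genotypes_per_morphotype = 3,
                    n_morphotypes = 2, depth = 25, snp_rate = 0,
                    diagnostic_rate = 0, seed = 2)
  rs <- simulate_reads(simulate_genotypes(simulate_subgenomes(cfg), cfg), cfg)
  expect_identical(nrow(rs$reads), 25L * 6L * 10L)
  expect_identical(sort(rs$truth$read_id), sort(rs$reads$read_id))
  expect_false(anyDuplicated(rs$truth$read_id) > 0)
})

test_that("homopolymer indels are confined to runs of length >= 3", {
  set.seed(31)
  base <- strsplit("ACAAAGTCTTTTGACGCGCA", "")[[1]]
  ## candidate zone: inside or adjacent to AAA (pos 2:7) and TTTT (pos 8:13)
  allowed <- sort(unique(c(2:7, 8:13)))
  for (rep in 1:200) {
    out <- polysnp:::apply_homopolymer_indels(base, 0.3)
    if (length(out) == length(base)) next
    ## locate the first difference; it must fall in the candidate zone
    d <- which(out[seq_len(min(length(out), length(base)))] !=
               base[seq_len(min(length(out), length(base)))])
    first <- if (length(d)) d[1] else min(length(out), length(base)) + 1L
    expect_true(first %in% c(allowed, allowed + 1L))
  }
})

test_that("observed substitution error rate converges to sub_error", {
  cfg <- sim_config(n_amplicons = 3, n_genotypes_per_morphotype = 2,
                    depth = 25, snp_rate = 0, diagnostic_rate = 0,
                    sub_error = 0.01, homopolymer_indel_rate = 0, seed = 17)
  sg <- simulate_subgenomes(cfg)
  gn <- simulate_genotypes(sg, cfg)
  rs <- simulate_reads(gn, cfg)
  mism <- 0L; tot <- 0L
  for (i in seq_len(nrow(rs$reads))) {
    tr <- rs$truth[rs$truth$read_id == rs$reads$read_id[i], ]
    hap <- gn$haplotypes[[tr$genotype_id]][[tr$amplicon]][[tr$subgenome]][tr$allele]
    body <- substring(rs$reads$sequence[i], 9)
    truthseq <- substr(hap, tr$offset + 1, tr$offset + nchar(body))
    mism <- mism + sum(strsplit(body, "")[[1]] != strsplit(truthseq, "")[[1]])
    tot <- tot + nchar(body)
  }
  se <- sqrt(0.01 * 0.99 / tot)
  expect_lt(abs(mism / tot - 0.01), 3 * se)
})

test_that("theta follows the B-copy ratio of each scenario", {
  d <- data.frame(sample_id = c("s1", "s2", "s3"), locus_id = "l1",
                  b_copies = c(2L, 1L, 0L))
  th1 <- simulate_intensity(d, "single_subgenome", noise_sd = 0)
  expect_equal(th1$theta, c(1, 0.5, 0))
  th2 <- simulate_intensity(d, "all_one_poly", noise_sd = 0)
  expect_equal(th2$theta, c(2 / 6, 1 / 6, 0))
  expect_error(simulate_intensity(d, "no_such_scenario"), "scenario")
  expect_error(simulate_intensity(d, "single_subgenome", noise_sd = -1),
               "noise_sd")
})

test_that("barcodes keep a minimum pairwise Hamming distance", {
  set.seed(6)
  bcs <- make_barcodes(12, 8, min_dist = 3)
  expect_length(unique(bcs), 12L)
  for (i in 1:11) for (j in (i + 1):12) {
    expect_gte(sum(strsplit(bcs[i], "")[[1]] != strsplit(bcs[j], "")[[1]]), 3)
  }
})
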