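## a one-contig reference plus reads mapped onto it
make_mapped <- function(contig_seq, read_seqs, contig_id = "c1") {
  contig <- fake_contig(contig_id, contig_seq)
  mapped <- map_reads_to_contigs(reads_df(read_seqs), list(contig),
                                 mapping_params())
  list(contig = contig, mapped = mapped)
}

test_that("variant tabulation records supported alleles with depth", {
  ref <- rand_dna(200, seed = 1)
  alt <- sub_at(ref, 100)
  x <- make_mapped(ref, rep(alt, 10))
  obs <- tabulate_variants(x$mapped, list(x$contig), "g1")
  expect_identical(nrow(obs), 1L)
  expect_identical(obs$position, 100L)
  expect_identical(obs$type, "SUB")
  expect_identical(obs$site_depth, 10L)
  expect_identical(obs$alt_support, 10L)
  expect_identical(obs$alt, substr(alt, 100, 100))
  ## coverage attribute covers the whole contig
  expect_identical(attr(obs, "coverage")$c1, rep(10L, 200))
})

test_that("alleles below the support thresholds are not observed but stay in raw counts", {
  ref <- rand_dna(200, seed = 2)
  alt <- sub_at(ref, 100)
  x <- make_mapped(ref, c(rep(ref, 19), alt))
  obs <- tabulate_variants(x$mapped, list(x$contig), "g1")
  expect_identical(nrow(obs), 0L)
  raw <- attr(obs, "raw_alleles")
  expect_identical(raw$position, 100L)
  expect_identical(raw$count, 1L)
})

test_that("deletions and insertions are tabulated as indel observations", {
  ref <- rand_dna(200, seed = 3)
  del <- paste0(substr(ref, 1, 99), substr(ref, 101, 200))
  x <- make_mapped(ref, c(rep(ref, 6), rep(del, 6)))
  obs <- tabulate_variants(x$mapped, list(x$contig), "g1")
  d <- obs[obs$type == "DEL", ]
  expect_identical(nrow(d), 1L)
  ## gap placement within a repeated context is ambiguous by one position
  expect_true(d$position %in% c(100L, 101L))
  expect_identical(d$alt_support, 6L)
  ins <- paste0(substr(ref, 1, 100), "T", substr(ref, 101, 200))
  y <- make_mapped(ref, c(rep(ref, 6), rep(ins, 6)))
  obs2 <- tabulate_variants(y$mapped, list(y$contig), "g1")
  i <- obs2[obs2$type == "INS", ]
  expect_identical(nrow(i), 1L)
  expect_identical(i$alt, "+T")
  ## absent reference contig is a consistency error
  bad <- x$mapped; bad$contig_id <- "ghost"
  expect_error(tabulate_variants(bad, list(x$contig), "g1"), "ghost")
})

test_that("HSV detection compares co-attributed contigs and projects columns", {
  base <- rand_dna(300, seed = 4)
  other <- sub_at(base, 42)
  contigs <- list(fake_contig("c1", base, genotype_id = "g1"),
                  fake_contig("c2", other, genotype_id = "g1"))
  hs <- detect_hsvs(contigs)
  expect_identical(hs$n_events, 1L)
  expect_setequal(hs$hsv$position, 42L)
  expect_identical(hs$aligned_bp, 300L)
  ## identical contigs -> no HSVs, but compared
  hs2 <- detect_hsvs(list(fake_contig("c1", base, genotype_id = "g1"),
                          fake_contig("c2", base, genotype_id = "g1")))
  expect_identical(hs2$n_events, 0L)
  expect_identical(hs2$aligned_bp, 300L)
  ## contigs overlapping by fewer than 10 bp are not compared
  short <- substr(base, 1, 9)
  hs3 <- detect_hsvs(list(fake_contig("c1", base, genotype_id = "g1"),
                          fake_contig("c2", short, genotype_id = "g1")))
  expect_identical(hs3$aligned_bp, 0L)
  ## contigs of different genotypes are not compared by the within detector
  hs4 <- detect_hsvs(list(fake_contig("c1", base, genotype_id = "g1"),
                          fake_contig("c2", other, genotype_id = "g2")))
  expect_identical(hs4$n_events, 0L)
})

test_that("between-reference HSV detection skips mutual best pairs", {
  base <- rand_dna(300, seed = 5)
  subg2 <- sub_at(base, c(50, 150, 250))
  ## reference A decomposed both sub-genomes; reference B only has one
  ca <- list(fake_contig("a1", base, genotype_id = "ga"),
             fake_contig("a2", subg2, genotype_id = "ga"))
  cb <- list(fake_contig("b1", base, genotype_id = "gb"))
  btw <- detect_hsvs_between(ca, cb)
  ## b1's mutual best is a1 (identical): excluded; a2 vs b1 yields the
  ## 3 homoeologous columns on both contigs
  expect_identical(btw$n_events, 3L)
  expect_setequal(btw$hsv$contig_id, c("a2", "b1"))
  expect_setequal(btw$hsv$position[btw$hsv$contig_id == "a2"],
                  c(50L, 150L, 250L))
})

panel <- sprintf("g%d", 1:6)

test_that("qualification implements the carrier, indel and HSV rules exactly", {
  contig <- fake_contig("c1", rand_dna(200, seed = 6))
  hsv <- data.frame(contig_id = "c1", position = 120L,
                    stringsAsFactors = FALSE)
  obs <- rbind(
    do.call(rbind, lapply(panel[1:2], obs_row, pos = 50L)),       # SNP
    do.call(rbind, lapply(panel, obs_row, pos = 60L, alt = "T")), # all 6
    do.call(rbind, lapply(panel[1:3], obs_row, pos = 70L, alt = "-",
                          type = "DEL")),                         # indel
    do.call(rbind, lapply(panel[1:3], obs_row, pos = 120L)),      # at HSV
    obs_row(panel[1], pos = 80L),                                 # singleton
    do.call(rbind, lapply(panel[1:2], obs_row, pos = 5L)))        # terminal
  cl <- qualify_snps(obs, hsv, panel, list(contig))
  got <- setNames(cl$class, cl$position)
  expect_identical(got[["50"]], "SNP")
  expect_identical(got[["60"]], "REJECT_UBIQUITOUS")
  expect_identical(got[["70"]], "REJECT_INDEL")
  expect_identical(got[["120"]], "REJECT_HSV_COLOCATED")
  expect_identical(got[["80"]], "REJECT_SINGLETON")
  expect_identical(got[["5"]], "REJECT_TERMINAL")
  expect_identical(sort(cl$carriers[cl$position == 50]), "g1;g2")
  ## degenerate panel
  expect_error(qualify_snps(obs, hsv, panel[1:2], list(contig)),
               "degenerate")
})

test_that("segregation overrides the HSV rejection only with confirmed reference genotypes", {
  contig <- fake_contig("c1", rand_dna(200, seed = 7))
  hsv <- data.frame(contig_id = "c1", position = 120L,
                    stringsAsFactors = FALSE)
  obs <- do.call(rbind, lapply(panel[1:3], obs_row, pos = 120L))
  cov <- setNames(lapply(panel, function(g) list(c1 = rep(10L, 200))), panel)
  ## no raw support anywhere else: g4..g6 are confirmed reference -> SNP
  raw0 <- data.frame(genotype_id = character(), contig_id = character(),
                     position = integer(), alt = character(),
                     count = integer(), stringsAsFactors = FALSE)
  cl <- qualify_snps(obs, hsv, panel, list(contig), coverage = cov,
                     raw_support = raw0)
  expect_identical(cl$class, "SNP")
  ## every non-carrier holds at least one read of the allele -> still HSV
  raw <- do.call(rbind, lapply(panel[4:6], function(g) {
    data.frame(genotype_id = g, contig_id = "c1", position = 120L,
               alt = "G", count = 1L, stringsAsFactors = FALSE)
  }))
  cl2 <- qualify_snps(obs, hsv, panel, list(contig), coverage = cov,
                      raw_support = raw)
  expect_identical(cl2$class, "REJECT_HSV_COLOCATED")
  ## a hard-masked column can never be overridden
  hsv_hard <- cbind(hsv, hard = TRUE)
  cl3 <- qualify_snps(obs, hsv_hard, panel, list(contig), coverage = cov,
                      raw_support = raw0)
  expect_identical(cl3$class, "REJECT_HSV_COLOCATED")
})

test_that("removing a panel genotype reclassifies monotonically", {
  contig <- fake_contig("c1", rand_dna(300, seed = 8))
  no_hsv <- data.frame(contig_id = character(), position = integer(),
                       stringsAsFactors = FALSE)
  classify_k <- function(carriers, pnl) {
    obs <- do.call(rbind, lapply(carriers, obs_row, pos = 150L))
    qualify_snps(obs, no_hsv, pnl, list(contig))$class
  }
  ## 2 carriers: dropping one carrier demotes SNP -> singleton
  expect_identical(classify_k(panel[1:2], panel), "SNP")
  expect_identical(classify_k(panel[1], setdiff(panel, panel[2])),
                   "REJECT_SINGLETON")
  ## all carriers: dropping a carrier turns ubiquitous into a 5-of-5
  ## ubiquitous call, never a SNP
  expect_identical(classify_k(panel, panel), "REJECT_UBIQUITOUS")
  expect_identical(classify_k(panel[-1], panel[-1]), "REJECT_UBIQUITOUS")
  ## dropping a NON-carrier can turn a 5-of-6 SNP ubiquitous (fixed in the
  ## remaining panel) — the reverse never happens
  expect_identical(classify_k(panel[1:5], panel), "SNP")
  expect_identical(classify_k(panel[1:5], panel[1:5]), "REJECT_UBIQUITOUS")
})

test_that("diagnostic classification requires fixed, covered, differing sites", {
  base <- rand_dna(300, seed = 9)
  diffb <- sub_at(base, 142)
  ca <- list(fake_contig("a1", base, genotype_id = "ga"))
  cb <- list(fake_contig("b1", diffb, genotype_id = "gb"))
  full_cov <- function(genos, cid) {
    setNames(lapply(genos, function(g) setNames(list(rep(10L, 300)), cid)),
             genos)
  }
  no_obs <- empty_df <- data.frame(contig_id = character(),
                                   position = integer(), stringsAsFactors = FALSE)
  d <- classify_diagnostic(ca, cb, no_obs, no_obs,
                           full_cov(c("ga", "ga2"), "a1"),
                           full_cov(c("gb", "gb2"), "b1"))
  expect_identical(nrow(d), 1L)
  expect_identical(d$position_a, 142L)
  expect_identical(d$class, "DIAGNOSTIC")
  ## polymorphism inside group A at the site disqualifies it
  obs_a <- data.frame(contig_id = "a1", position = 142L,
                      stringsAsFactors = FALSE)
  d2 <- classify_diagnostic(ca, cb, obs_a, no_obs,
                            full_cov(c("ga", "ga2"), "a1"),
                            full_cov(c("gb", "gb2"), "b1"))
  expect_identical(nrow(d2), 0L)
  ## insufficient observed genotypes in group B withholds the call
  d3 <- classify_diagnostic(ca, cb, no_obs, no_obs,
                            full_cov(c("ga", "ga2"), "a1"),
                            full_cov("gb", "b1"), min_observed = 2L)
  expect_identical(nrow(d3), 0L)
  ## no shared amplicons warns and returns empty
  cb_other <- list(fake_contig("b9", rand_dna(300), genotype_id = "gb",
                               amplicon_id = "amp999"))
  expect_warning(d4 <- classify_diagnostic(ca, cb_other, no_obs, no_obs,
                                           full_cov("ga", "a1"),
                                           full_cov("gb", "b9")),
                 "shared")
  expect_identical(nrow(d4), 0L)
})

test_that("SNP summary divides counts by amplicons and contigs", {
  cl <- data.frame(class = c(rep("SNP", 30), rep("REJECT_INDEL", 5)),
                   stringsAsFactors = FALSE)
  s <- snp_summary(cl, n_amplicons = 2, n_contigs = 10)
  expect_equal(s$snps_per_amplicon, 15.0)
  expect_equal(s$snps_per_contig, 3.0)
  expect_identical(s$n_indels, 5L)
  s0 <- snp_summary(cl[0, , drop = FALSE], 2, 4)
  expect_equal(s0$n_snps, 0L)
  expect_equal(s0$snps_per_amplicon, 0)
})
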