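test_that("common-span trimming keeps only columns covered by every taxon", {
  aligned <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  blk <- trim_to_common_span(aligned)
  expect_identical(unname(blk$seqs), unname(aligned))
  expect_identical(blk$n_col, 10L)
  ## overlap on columns 11-90 of a 100-column frame -> 80 columns
  f <- rand_dna(100, seed = 1)
  two <- c(x = paste0(substr(f, 1, 90), strrep("-", 10)),
           y = paste0(strrep("-", 10), substr(f, 11, 100)))
  blk2 <- trim_to_common_span(two)
  expect_identical(blk2$n_col, 80L)
  expect_identical(blk2$span, c(11L, 90L))
  ## disjoint spans are an error
  disj <- c(x = paste0(substr(f, 1, 40), strrep("-", 60)),
            y = paste0(strrep("-", 60), substr(f, 61, 100)))
  expect_error(trim_to_common_span(disj), "common span")
})

test_that("nucleotide distances match their closed forms", {
  a <- rand_dna(100, seed = 2)
  same <- c(t1 = a, t2 = a)
  for (m in c("p", "JC69", "K2P")) {
    expect_equal(distance_matrix(same, m)[1, 2], 0)
  }
  two <- c(t1 = a, t2 = sub_at(a, c(30, 60)))
  expect_equal(distance_matrix(two, "p")[1, 2], 0.02)
  expect_equal(distance_matrix(two, "JC69")[1, 2],
               -0.75 * log(1 - 4 * 0.02 / 3), tolerance = 1e-12)
  ## p >= 3/4 has no JC69 distance
  ch <- strsplit(a, "")[[1]]
  far <- paste(c(ch[1:20], chartr("ACGT", "CATG", ch[21:100])),
               collapse = "")
  expect_error(distance_matrix(c(t1 = a, t2 = far), "JC69"), "undefined")
})

test_that("distances agree with ape's dist.dna on a random alignment", {
  set.seed(3)
  seqs <- c(t1 = rand_dna(200), t2 = NA, t3 = NA)
  seqs["t2"] <- sub_at(seqs[["t1"]], sample(200, 12))
  seqs["t3"] <- sub_at(seqs[["t1"]], sample(200, 25))
  bin <- ape::as.DNAbin(t(sapply(seqs, function(s) strsplit(tolower(s), "")[[1]])))
  for (pair in list(c("p", "raw"), c("JC69", "JC69"), c("K2P", "K80"))) {
    ours <- distance_matrix(seqs, pair[1])
    theirs <- as.matrix(ape::dist.dna(bin, model = pair[2]))
    expect_equal(unname(ours), unname(theirs), tolerance = 1e-9,
                 label = pair[1])
  }
})

test_that("JC69 distance increases monotonically in p", {
  base <- rand_dna(400, seed = 4)
  d <- vapply(seq(4, 280, by = 20), function(k) {
    distance_matrix(c(a = base, b = sub_at(base, seq_len(k))), "JC69")[1, 2]
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("neighbour joining reproduces small trees exactly", {
  ## 2 taxa: a single split of the input distance
  t2 <- nj_tree(matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("a", "b"),
                                                             c("a", "b"))))
  expect_equal(ape::cophenetic.phylo(t2)["a", "b"], 0.3)
  ## 3 taxa: branch lengths solve the pairwise equations
  D <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  D["a", "b"] <- D["b", "a"] <- 0.4
  D["a", "c"] <- D["c", "a"] <- 0.6
  D["b", "c"] <- D["c", "b"] <- 0.8
  t3 <- nj_tree(D)
  pd <- ape::cophenetic.phylo(t3)
  expect_equal(pd[rownames(D), colnames(D)], D, tolerance = 1e-12)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("NJ recovers additive matrices and their topology", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    D <- ape::cophenetic.phylo(ref)
    est <- nj_tree(D)
    pd <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_lt(max(abs(pd - D)), 1e-9)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref), ape::unroot(est))), 0)
    ## cross-check against ape's own NJ topology
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ape::nj(D)),
                                           ape::unroot(est))), 0)
  }
})

test_that("the four-point topology ((A,B),(C,D)) is recovered", {
  tr <- ape::read.tree(text = "((A:1,B:2):3,(C:1.5,D:2.5):0.5);")
  est <- nj_tree(ape::cophenetic.phylo(tr))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(est))), 0)
})

test_that("sub-genome assignment follows the nearest-progenitor margin rule", {
  tree <- ape::read.tree(
    text = "((query:0.01,meadow:0.01):0.1,(g1:0.02,g2:0.03):0.02);")
  labs <- list(P = "meadow", G = c("g1", "g2"))
  a <- assign_subgenome(tree, "query", labs)
  expect_identical(a$assignment, "P")
  expect_lt(a$d_P, a$d_G)
  ## equidistant within the margin -> ambiguous
  eq <- ape::read.tree(text = "((query:0.05,meadow:0.05):0.0,g1:0.05);")
  expect_identical(assign_subgenome(eq, "query", labs)$assignment,
                   "AMBIGUOUS")
  ## only one progenitor class present: sister leaf required
  p_only_sister <- ape::read.tree(
    text = "((query:0.01,meadow:0.01):0.1,(x1:0.02,x2:0.03):0.02);")
  expect_identical(assign_subgenome(p_only_sister, "query", labs)$assignment,
                   "P")
  p_only_far <- ape::read.tree(
    text = "((x1:0.01,meadow:0.01):0.1,(query:0.02,x2:0.03):0.02);")
  expect_identical(assign_subgenome(p_only_far, "query", labs)$assignment,
                   "AMBIGUOUS")
  expect_error(assign_subgenome(tree, "ghost", labs), "ghost")
})

test_that("simulated sub-genome haplotypes attribute to their progenitor", {
  cfg <- sim_config(n_amplicons = 20, snp_rate = 0, diagnostic_rate = 0,
                    seed = 21)
  sg <- simulate_subgenomes(cfg)
  pr <- simulate_progenitors(sg, cfg)
  correct <- 0L; called <- 0L
  for (amp in names(sg$references)) {
    orth <- unlist(pr$progenitors[[amp]])
    res <- attribute_haplotypes(
      c(qP = sg$references[[amp]]$P, qG1 = sg$references[[amp]]$G1),
      orth, p_labels = "P_ortholog",
      g_labels = c("G1_ortholog", "G2_ortholog"))
    for (k in seq_len(nrow(res$assignments))) {
      a <- res$assignments[k, ]
      if (a$assignment == "AMBIGUOUS") next
      called <- called + 1L
      truth <- if (a$haplotype == "qP") "P" else "G"
      if (a$assignment == truth) correct <- correct + 1L
    }
  }
  expect_gt(called, 20L)
  expect_gte(correct / called, 0.95)
})
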