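#' Configuration for the synthetic allohexaploid amplicon simulator
#'
#' Builds and validates the parameter set that drives every simulation stage.
#' The generator emulates an outbreeding allohexaploid (three sub-genomes,
#' here labelled `P`, `G1` and `G2`, each carried in two allelic copies per
#' genotype) resequenced over a panel of PCR amplicons with pyrosequencing-like
#' errors and 8 bp barcode multiplexing.
#'
#' @param n_amplicons number of amplicon loci to simulate.
#' @param amplicon_length amplicon length in bp (default 500, the target
#'   product size of the emulated assay).
#' @param hsv_rate expected density of homoeologous sequence variants (HSVs)
#'   per bp between any two sub-genomes (default 1/109, the density observed
#'   in Continental tall fescue reference assemblies).
#' @param snp_rate expected number of qualifying allelic SNPs planted per
#'   amplicon per morphotype panel (Poisson mean).
#' @param diagnostic_rate expected number of morphotype-diagnostic variants
#'   planted per amplicon (Poisson mean; fixed within each morphotype,
#'   different between them).
#' @param n_genotypes_per_morphotype genotypes sequenced per morphotype panel.
#' @param n_morphotypes number of morphotype panels (diagnostic variants
#'   require exactly 2).
#' @param depth reads per genotype per amplicon.
#' @param depth_mode `"exact"` emits exactly `depth` reads (deterministic
#'   totals); `"poisson"` draws per-genotype-per-amplicon depths from a
#'   Poisson with mean `depth`.
#' @param read_length read length in bp (default 400, a Titanium-era
#'   pyrosequencing read).
#' @param read_start `"ends"` (default) anchors each read at one of the two
#'   amplicon ends, emulating an amplicon library sequenced from its ligated
#'   adapters; `"uniform"` draws the start uniformly over valid offsets
#'   (shearing-like, with thin ramping coverage at the amplicon edges).
#' @param sub_error per-base substitution error rate.
#' @param homopolymer_indel_rate per-base indel rate at positions inside or
#'   adjacent to homopolymer runs of length >= 3 (the characteristic
#'   pyrosequencing error mode).
#' @param barcode_length barcode tag length in bp (default 8).
#' @param primer_length width of the primer landing site at each amplicon
#'   end (default 20 bp). Primer sites are conserved across sub-genomes
#'   (one primer pair amplifies all of them) and their template sequence is
#'   overwritten by the primer during PCR, so no variation — homoeologous
#'   or allelic — is planted there.
#' @param carrier_freq allele frequency parameter used when drawing SNP
#'   carrier genotypes (each allele copy carries the alternative base with
#'   this probability; panels are resampled until the carrier count lies in
#'   `[2, n - 1]` so every planted SNP can qualify).
#' @param progenitor_divergence per-bp substitution divergence between each
#'   simulated sub-genome and the emitted progenitor ortholog sequence
#'   (contemporary progenitors have drifted since the polyploidisation).
#' @param strand `"forward"` emits all reads on the template strand;
#'   `"both"` flips a fair coin per read.
#' @param allow_collisions allow planted SNPs/diagnostics to land on HSV
#'   positions (off by default; the planted classes are then disjoint).
#' @param seed integer RNG seed; identical configurations produce
#'   byte-identical outputs.
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_amplicons = 20L,
                       amplicon_length = 500L,
                       hsv_rate = 1 / 109,
                       snp_rate = 10,
                       diagnostic_rate = 1,
                       n_genotypes_per_morphotype = 6L,
                       n_morphotypes = 2L,
                       depth = 25L,
                       depth_mode = c("exact", "poisson"),
                       read_length = 400L,
                       read_start = c("ends", "uniform"),
                       sub_error = 0.005,
                       homopolymer_indel_rate = 0.005,
                       barcode_length = 8L,
                       primer_length = 20L,
                       carrier_freq = 0.5,
                       progenitor_divergence = 0.003,
                       strand = c("forward", "both"),
                       allow_collisions = FALSE,
                       seed = 1L) {
  depth_mode <- match.arg(depth_mode)
  read_start <- match.arg(read_start)
  strand <- match.arg(strand)
  cfg <- list(
    n_amplicons = as.integer(n_amplicons),
    amplicon_length = as.integer(amplicon_length),
    hsv_rate = hsv_rate, snp_rate = snp_rate,
    diagnostic_rate = diagnostic_rate,
    n_genotypes_per_morphotype = as.integer(n_genotypes_per_morphotype),
    n_morphotypes = as.integer(n_morphotypes),
    depth = as.integer(depth), depth_mode = depth_mode,
    read_length = as.integer(read_length), read_start = read_start,
    sub_error = sub_error,
    homopolymer_indel_rate = homopolymer_indel_rate,
    barcode_length = as.integer(barcode_length),
    primer_length = as.integer(primer_length),
    carrier_freq = carrier_freq,
    progenitor_divergence = progenitor_divergence,
    strand = strand,
    allow_collisions = isTRUE(allow_collisions),
    seed = as.integer(seed))
  rates <- c(hsv_rate = cfg$hsv_rate, sub_error = cfg$sub_error,
             homopolymer_indel_rate = cfg$homopolymer_indel_rate,
             carrier_freq = cfg$carrier_freq,
             progenitor_divergence = cfg$progenitor_divergence)
  bad <- rates < 0 | rates > 1
  if (any(bad)) {
    stop_invalid("rates must lie in [0, 1]; offending: %s",
                 paste(names(rates)[bad], collapse = ", "))
  }
  if (cfg$n_amplicons < 1L) stop_invalid("n_amplicons must be >= 1")
  if (cfg$amplicon_length < 1L) stop_invalid("amplicon_length must be >= 1")
  if (2L * cfg$primer_length >= cfg$amplicon_length) {
    stop_invalid("primer sites leave no interior sequence")
  }
  if (cfg$read_length > cfg$amplicon_length) {
    stop_invalid("read_length (%d) must not exceed amplicon_length (%d)",
                 cfg$read_length, cfg$amplicon_length)
  }
  if (cfg$depth < 1L) stop_invalid("depth must be >= 1")
  if (cfg$snp_rate > 0 && cfg$n_genotypes_per_morphotype < 2L) {
    stop_invalid(paste0("n_genotypes_per_morphotype must be >= 2 when ",
                        "snp_rate > 0 (SNP qualification is impossible ",
                        "otherwise)"))
  }
  class(cfg) <- "sim_config"
  cfg
}

amplicon_id <- function(i) sprintf("amp%03d", i)
morphotype_id <- function(m) sprintf("M%d", m)
genotype_id <- function(m, g) sprintf("M%d_g%02d", m, g)
SUBGENOMES <- c("P", "G1", "G2")

#' Simulate sub-genome reference sequences and HSV truth
#'
#' Draws one ancestral sequence per amplicon and derives the three sub-genome
#' references (`P`, `G1`, `G2`) by independently placed substitutions, so the
#' expected pairwise difference density between any two sub-genomes equals
#' `hsv_rate`. Every column at which at least two sub-genomes differ is an HSV
#' and is recorded in the returned truth table.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements
#'   `references` (per-amplicon named list of the three sub-genome strings),
#'   `ancestral` (per-amplicon ancestral strings) and
#'   `hsv` (data.frame: `amplicon`, `position` (1-based), `allele_P`,
#'   `allele_G1`, `allele_G2`).
#' @export
simulate_subgenomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$amplicon_length < 1L) stop_invalid("zero-length amplicon")
  set.seed(stage_seed(config$seed, "subgenomes"))
  ## per-lineage substitution probability r chosen so that the pairwise
  ## differing-column probability 2r(1-r) + (2/3)r^2 equals hsv_rate
  r <- if (config$hsv_rate == 0) 0 else {
    a <- 2 / 3 - 2; b <- 2; cc <- -config$hsv_rate
    (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  }
  L <- config$amplicon_length
  refs <- vector("list", config$n_amplicons)
  anc <- character(config$n_amplicons)
  hsv <- vector("list", config$n_amplicons)
  for (i in seq_len(config$n_amplicons)) {
    anc_chars <- sample(DNA_BASES, L, replace = TRUE)
    interior <- seq_len(L) > config$primer_length &
                seq_len(L) <= L - config$primer_length
    subs <- lapply(SUBGENOMES, function(sg) {
      chars <- anc_chars
      hit <- which(runif(L) < r & interior)
      mutate_bases(chars, hit)
    })
    names(subs) <- SUBGENOMES
    mat <- do.call(rbind, subs)
    diffcol <- which(apply(mat, 2, function(col) length(unique(col)) > 1L))
    anc[i] <- paste(anc_chars, collapse = "")
    refs[[i]] <- lapply(subs, paste, collapse = "")
    hsv[[i]] <- if (length(diffcol)) {
      data.frame(amplicon = amplicon_id(i), position = diffcol,
                 allele_P = mat["P", diffcol],
                 allele_G1 = mat["G1", diffcol],
                 allele_G2 = mat["G2", diffcol],
                 stringsAsFactors = FALSE)
    } else NULL
  }
  names(refs) <- amplicon_id(seq_len(config$n_amplicons))
  names(anc) <- names(refs)
  hsv <- if (length(hsv)) do.call(rbind, hsv) else NULL
  if (is.null(hsv)) {
    hsv <- data.frame(amplicon = character(), position = integer(),
                      allele_P = character(), allele_G1 = character(),
                      allele_G2 = character(), stringsAsFactors = FALSE)
  }
  rownames(hsv) <- NULL
  list(references = refs, ancestral = anc, hsv = hsv)
}

## draw a carrier/dosage configuration for one SNP: each of the 2 allele
## copies of each genotype carries the alt with probability f, resampled until
## the carrier count lies in [2, n-1] (truncated binomial on carriers)
draw_carriers <- function(n, f, max_tries = 10000L) {
  hi <- max(2L, n - 1L)  # n = 2: both genotypes carry
  for (k in seq_len(max_tries)) {
    copies <- matrix(rbinom(2L * n, 1L, f), nrow = n)
    dosage <- rowSums(copies)
    nc <- sum(dosage > 0L)
    if (nc >= 2L && nc <= hi) return(list(dosage = dosage, copies = copies))
  }
  stop_invalid("could not draw a qualifying carrier configuration")
}

#' Simulate genotype haplotypes with planted SNPs and diagnostic variants
#'
#' Each genotype carries six haplotypes (two allelic copies of each of the
#' three sub-genomes). Qualifying allelic SNPs are planted per morphotype
#' panel at positions free of HSVs (unless `allow_collisions`), carried by at
#' least 2 and at most n-1 genotypes of the panel; diagnostic variants are
#' fixed (dosage 2 in every genotype) within one morphotype and absent from
#' the other.
#'
#' @param subgenomes result of [simulate_subgenomes()].
#' @param config a [sim_config()] object.
#' @return a list with elements `haplotypes` (named list
#'   `[[genotype]][[amplicon]][[subgenome]]` -> character(2) allele
#'   sequences), `genotypes` (data.frame: `genotype_id`, `morphotype`),
#'   `snp_records`, `snp_dosages` and `diagnostic_records` truth tables.
#' @export
simulate_genotypes <- function(subgenomes, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genotypes_per_morphotype
  if (config$snp_rate > 0 && n < 2L) {
    stop_invalid("n_genotypes_per_morphotype < 2 with snp_rate > 0")
  }
  set.seed(stage_seed(config$seed, "genotypes"))
  nm <- config$n_morphotypes
  L <- config$amplicon_length
  genotypes <- do.call(rbind, lapply(seq_len(nm), function(m) {
    data.frame(genotype_id = genotype_id(m, seq_len(n)),
               morphotype = morphotype_id(m), stringsAsFactors = FALSE)
  }))

  ## per (amplicon, subgenome, genotype): list of (position, alt, copies)
  ## accumulate planted edits, then apply to the reference strings
  edits <- list()
  add_edit <- function(gid, amp, sg, pos, alt, copy_mask) {
    key <- paste(gid, amp, sg, sep = "|")
    edits[[key]] <<- c(edits[[key]],
                       list(list(pos = pos, alt = alt, copies = copy_mask)))
  }

  snp_rows <- list(); dos_rows <- list(); diag_rows <- list()
  used <- lapply(seq_len(config$n_amplicons), function(i) {
    u <- rep(FALSE, L)
    ## primer landing sites carry no plantable variation
    if (config$primer_length > 0L) {
      u[seq_len(config$primer_length)] <- TRUE
      u[(L - config$primer_length + 1L):L] <- TRUE
    }
    if (!config$allow_collisions) {
      h <- subgenomes$hsv
      u[h$position[h$amplicon == amplicon_id(i)]] <- TRUE
    }
    u
  })
  snp_ct <- 0L; diag_ct <- 0L
  for (i in seq_len(config$n_amplicons)) {
    amp <- amplicon_id(i)
    ## diagnostic variants: one sub-genome, alt fixed in one random morphotype
    if (nm >= 2L && config$diagnostic_rate > 0) {
      nd <- rpois(1L, config$diagnostic_rate)
      for (d in seq_len(nd)) {
        free <- which(!used[[i]])
        if (!length(free)) break
        pos <- if (length(free) == 1L) free else sample(free, 1L)
        used[[i]][pos] <- TRUE
        sg <- sample(SUBGENOMES, 1L)
        ref <- substr(subgenomes$references[[amp]][[sg]], pos, pos)
        alt <- sample(setdiff(DNA_BASES, ref), 1L)
        alt_m <- sample(seq_len(nm), 1L)
        for (g in seq_len(n)) {
          add_edit(genotype_id(alt_m, g), amp, sg, pos, alt, c(TRUE, TRUE))
        }
        diag_ct <- diag_ct + 1L
        diag_rows[[diag_ct]] <- data.frame(
          diag_id = sprintf("diag%04d", diag_ct), amplicon = amp,
          subgenome = sg, position = pos, ref = ref, alt = alt,
          alt_morphotype = morphotype_id(alt_m), stringsAsFactors = FALSE)
      }
    }
    ## allelic SNPs, planted independently per morphotype panel
    if (config$snp_rate > 0) {
      for (m in seq_len(nm)) {
        ns <- rpois(1L, config$snp_rate)
        for (s in seq_len(ns)) {
          free <- which(!used[[i]])
          if (!length(free)) break
          pos <- if (length(free) == 1L) free else sample(free, 1L)
          used[[i]][pos] <- TRUE
          sg <- sample(SUBGENOMES, 1L)
          ref <- substr(subgenomes$references[[amp]][[sg]], pos, pos)
          alt <- sample(setdiff(DNA_BASES, ref), 1L)
          dc <- draw_carriers(n, config$carrier_freq)
          snp_ct <- snp_ct + 1L
          sid <- sprintf("snp%05d", snp_ct)
          for (g in seq_len(n)) {
            if (dc$dosage[g] > 0L) {
              add_edit(genotype_id(m, g), amp, sg, pos, alt,
                       dc$copies[g, ] == 1L)
            }
          }
          snp_rows[[snp_ct]] <- data.frame(
            snp_id = sid, amplicon = amp, morphotype = morphotype_id(m),
            subgenome = sg, position = pos, ref = ref, alt = alt,
            n_carriers = sum(dc$dosage > 0L), stringsAsFactors = FALSE)
          dos_rows[[snp_ct]] <- data.frame(
            snp_id = sid, genotype_id = genotype_id(m, seq_len(n)),
            dosage = dc$dosage, stringsAsFactors = FALSE)
        }
      }
    }
  }

  ## apply edits to build the six haplotypes of every genotype
  haplotypes <- list()
  for (gi in seq_len(nrow(genotypes))) {
    gid <- genotypes$genotype_id[gi]
    per_amp <- list()
    for (i in seq_len(config$n_amplicons)) {
      amp <- amplicon_id(i)
      per_sg <- list()
      for (sg in SUBGENOMES) {
        ref <- subgenomes$references[[amp]][[sg]]
        alle <- c(ref, ref)
        key <- paste(gid, amp, sg, sep = "|")
        for (e in edits[[key]] %||% list()) {
          for (cp in 1:2) {
            if (e$copies[cp]) {
              substr(alle[cp], e$pos, e$pos) <- e$alt
            }
          }
        }
        per_sg[[sg]] <- alle
      }
      per_amp[[amp]] <- per_sg
    }
    haplotypes[[gid]] <- per_amp
  }

  empty_snp <- data.frame(snp_id = character(), amplicon = character(),
                          morphotype = character(), subgenome = character(),
                          position = integer(), ref = character(),
                          alt = character(), n_carriers = integer(),
                          stringsAsFactors = FALSE)
  empty_dos <- data.frame(snp_id = character(), genotype_id = character(),
                          dosage = integer(), stringsAsFactors = FALSE)
  empty_diag <- data.frame(diag_id = character(), amplicon = character(),
                           subgenome = character(), position = integer(),
                           ref = character(), alt = character(),
                           alt_morphotype = character(),
                           stringsAsFactors = FALSE)
  list(haplotypes = haplotypes, genotypes = genotypes,
       snp_records = if (length(snp_rows)) do.call(rbind, snp_rows) else empty_snp,
       snp_dosages = if (length(dos_rows)) do.call(rbind, dos_rows) else empty_dos,
       diagnostic_records = if (length(diag_rows)) do.call(rbind, diag_rows) else empty_diag)
}

#' Generate barcode tags with a minimum pairwise Hamming distance
#'
#' Barcodes are drawn at random and accepted greedily when at least
#' `min_dist` substitutions away from every accepted barcode, so exact-match
#' demultiplexing is unambiguous even under a one-mismatch policy.
#'
#' @param n number of barcodes.
#' @param length barcode length in bp.
#' @param min_dist minimum pairwise Hamming distance (default 3).
#' @return character vector of `n` barcodes.
#' @export
make_barcodes <- function(n, length = 8L, min_dist = 3L) {
  out <- character(0)
  tries <- 0L
  while (base::length(out) < n) {
    cand <- random_dna(length)
    if (all(vapply(out, function(b) hamming(b, cand) >= min_dist, logical(1)))) {
      out <- c(out, cand)
    }
    tries <- tries + 1L
    if (tries > 100000L) stop_invalid("barcode space exhausted")
  }
  out
}

## apply homopolymer-adjacent indels to a read string: candidate positions are
## inside or immediately adjacent to runs of length >= 3 of one base
apply_homopolymer_indels <- function(chars, rate) {
  if (rate <= 0 || length(chars) < 3L) return(chars)
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- logical(length(chars))
  for (j in which(r$lengths >= 3L)) {
    lo <- max(1L, starts[j] - 1L)
    hi <- min(length(chars), ends[j] + 1L)
    cand[lo:hi] <- TRUE
  }
  idx <- which(cand & runif(length(chars)) < rate)
  if (!length(idx)) return(chars)
  ## apply right-to-left so earlier positions stay valid
  for (p in rev(idx)) {
    if (runif(1) < 0.5) {
      chars <- append(chars, chars[p], after = p)  # duplicate (insertion)
    } else {
      chars <- chars[-p]                           # deletion
    }
  }
  chars
}

apply_substitutions <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- which(runif(length(chars)) < rate)
  mutate_bases(chars, hit)
}

#' Simulate barcode-tagged amplicon reads with pyrosequencing-like errors
#'
#' Reads are substrings of the genotype haplotypes drawn at uniform offsets,
#' perturbed first by homopolymer-adjacent indels and then by uniform
#' substitutions, and finally prefixed with the genotype's barcode. Per-read
#' ground truth (source genotype, sub-genome, allele copy, amplicon, offset,
#' strand) is returned alongside.
#'
#' @param genosim result of [simulate_genotypes()].
#' @param config a [sim_config()] object.
#' @param barcodes optional character vector of barcodes, one per genotype
#'   (generated with [make_barcodes()] when omitted).
#' @return a list with elements `reads` (data.frame: `read_id`, `sequence`
#'   (barcode-prefixed), `quality`), `truth` (data.frame keyed by `read_id`)
#'   and `barcode_table` (data.frame: `barcode`, `genotype_id`, `morphotype`).
#' @export
simulate_reads <- function(genosim, config, barcodes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth < 1L) stop_invalid("depth must be >= 1")
  if (config$read_length > config$amplicon_length) {
    stop_invalid("read_length exceeds amplicon_length")
  }
  set.seed(stage_seed(config$seed, "barcodes"))
  gmeta <- genosim$genotypes
  if (is.null(barcodes)) {
    barcodes <- make_barcodes(nrow(gmeta), config$barcode_length)
  }
  if (length(barcodes) != nrow(gmeta)) {
    stop_invalid("need one barcode per genotype")
  }
  barcode_table <- data.frame(barcode = barcodes,
                              genotype_id = gmeta$genotype_id,
                              morphotype = gmeta$morphotype,
                              stringsAsFactors = FALSE)
  set.seed(stage_seed(config$seed, "reads"))
  L <- config$amplicon_length
  rl <- config$read_length
  ids <- character(0); seqs <- character(0); quals <- character(0)
  truth <- list(); ti <- 0L
  for (gi in seq_len(nrow(gmeta))) {
    gid <- gmeta$genotype_id[gi]
    bc <- barcodes[gi]
    for (i in seq_len(config$n_amplicons)) {
      amp <- amplicon_id(i)
      D <- if (config$depth_mode == "exact") config$depth else rpois(1L, config$depth)
      if (D < 1L) next
      for (k in seq_len(D)) {
        sg <- sample(SUBGENOMES, 1L)
        allele <- sample(1:2, 1L)
        hap <- genosim$haplotypes[[gid]][[amp]][[sg]][allele]
        off <- if (config$read_start == "ends") {
          if (runif(1) < 0.5) 0L else L - rl
        } else sample.int(L - rl + 1L, 1L) - 1L
        chars <- seq_chars(substr(hap, off + 1L, off + rl))
        chars <- apply_homopolymer_indels(chars, config$homopolymer_indel_rate)
        chars <- apply_substitutions(chars, config$sub_error)
        strand <- "+"
        if (config$strand == "both" && runif(1) < 0.5) {
          strand <- "-"
          chars <- rev(seq_chars(chartr("ACGT", "TGCA", paste(chars, collapse = ""))))
        }
        body <- paste(chars, collapse = "")
        rid <- sprintf("%s_%s_r%04d", gid, amp, k)
        ti <- ti + 1L
        ids <- c(ids, rid)
        seqs <- c(seqs, paste0(bc, body))
        quals <- c(quals, strrep("I", nchar(body) + nchar(bc)))
        truth[[ti]] <- data.frame(read_id = rid, genotype_id = gid,
                                  morphotype = gmeta$morphotype[gi],
                                  amplicon = amp, subgenome = sg,
                                  allele = allele, offset = off,
                                  strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  list(reads = data.frame(read_id = ids, sequence = seqs, quality = quals,
                          stringsAsFactors = FALSE),
       truth = do.call(rbind, truth),
       barcode_table = barcode_table)
}

#' Simulate progenitor ortholog sequences
#'
#' Emits, per amplicon, one ortholog of the `P` sub-genome (emulating the
#' diploid progenitor) and one of each `G` sub-genome (emulating the
#' tetraploid progenitor haplotypes), each diverged from its sub-genome by
#' `progenitor_divergence` substitutions per bp. The ancestral sequence is
#' also returned as a surrogate EST template for fallback attribution.
#'
#' @param subgenomes result of [simulate_subgenomes()].
#' @param config a [sim_config()] object.
#' @return list with `progenitors` (named list per amplicon:
#'   `P_ortholog`, `G1_ortholog`, `G2_ortholog`) and `templates`
#'   (named character vector of per-amplicon template sequences).
#' @export
simulate_progenitors <- function(subgenomes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "intensity") + 7L)
  d <- config$progenitor_divergence
  progenitors <- lapply(names(subgenomes$references), function(amp) {
    out <- lapply(SUBGENOMES, function(sg) {
      chars <- seq_chars(subgenomes$references[[amp]][[sg]])
      hit <- which(runif(length(chars)) < d)
      paste(mutate_bases(chars, hit), collapse = "")
    })
    names(out) <- paste0(SUBGENOMES, "_ortholog")
    out
  })
  names(progenitors) <- names(subgenomes$references)
  templates <- subgenomes$ancestral
  list(progenitors = progenitors, templates = templates)
}

#' Admissible dosage classes per intensity scenario
#'
#' @param scenario one of `"single_subgenome"` (only the SNP-bearing
#'   sub-genome amplifies; effective-diploid classes AA/AB/BB),
#'   `"all_one_poly"` (all three sub-genomes amplify, one polymorphic) or
#'   `"all_two_poly"` (all amplify, two polymorphic; five classes).
#' @return data.frame with `class` (dosage string), `b_copies` and
#'   `total_copies`.
#' @export
scenario_classes <- function(scenario) {
  switch(scenario,
    single_subgenome = data.frame(
      class = c("AA", "AB", "BB"), b_copies = 0:2, total_copies = 2L,
      stringsAsFactors = FALSE),
    all_one_poly = data.frame(
      class = c("AAAAAA", "ABAAAA", "BBAAAA"), b_copies = 0:2,
      total_copies = 6L, stringsAsFactors = FALSE),
    all_two_poly = data.frame(
      class = c("AAAAAA", "AAABAA", "AABBAA", "ABBBAA", "BBBBAA"),
      b_copies = 0:4, total_copies = 6L, stringsAsFactors = FALSE),
    stop_invalid("unknown scenario '%s'", scenario))
}

#' Simulate two-channel intensity ratios from allele dosages
#'
#' The two-channel signal is parameterised as theta, the B-allele fraction of
#' the amplified allele copies: theta = B / (A + B) plus Gaussian noise,
#' clipped to `[0, 1]`. With a single amplified sub-genome the homozygote
#' ratios sit at 0 and 1 (the diploid-like 1:0 / 0:1 pattern); with all
#' sub-genomes amplified one B copy of six sits at 1/6.
#'
#' @param dosage data.frame with columns `sample_id`, `locus_id`, `b_copies`.
#' @param scenario see [scenario_classes()].
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return data.frame `sample_id`, `locus_id`, `theta`.
#' @export
simulate_intensity <- function(dosage, scenario, noise_sd = 0.03, seed = 1L) {
  cls <- scenario_classes(scenario)
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (!all(c("sample_id", "locus_id", "b_copies") %in% names(dosage))) {
    stop_invalid("dosage needs sample_id, locus_id, b_copies columns")
  }
  if (any(dosage$b_copies < 0 | dosage$b_copies > max(cls$b_copies))) {
    stop_invalid("b_copies outside the admissible range for scenario '%s'",
                 scenario)
  }
  set.seed(stage_seed(seed, "intensity"))
  theta <- dosage$b_copies / cls$total_copies[1]
  if (noise_sd > 0) theta <- theta + rnorm(nrow(dosage), 0, noise_sd)
  theta <- pmin(1, pmax(0, theta))
  data.frame(sample_id = dosage$sample_id, locus_id = dosage$locus_id,
             theta = theta, stringsAsFactors = FALSE)
}

#' Run every simulation stage and collect the full truth set
#'
#' Convenience wrapper: sub-genomes, genotype haplotypes, progenitor
#' orthologs, barcodes and reads, all under the configuration's seed.
#'
#' @param config a [sim_config()] object.
#' @return list with all stage outputs (`config`, `subgenomes`, `genosim`,
#'   `progenitors`, `readsim`).
#' @export
simulate_population <- function(config) {
  subg <- simulate_subgenomes(config)
  geno <- simulate_genotypes(subg, config)
  prog <- simulate_progenitors(subg, config)
  reads <- simulate_reads(geno, config)
  list(config = config, subgenomes = subg, genosim = geno,
       progenitors = prog, readsim = reads)
}
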