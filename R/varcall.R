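#' Variant support thresholds
#'
#' An alternative allele at a site is recorded only when carried by at least
#' `min_reads` reads making up at least `min_frac` of the site depth. The
#' defaults (2 reads, 20%) suppress isolated sequencing errors at typical
#' per-haplotype depths while retaining heterozygous alleles.
#'
#' @param min_reads minimum supporting reads.
#' @param min_frac minimum supporting fraction of site depth.
#' @return list of class `support_params`.
#' @export
support_params <- function(min_reads = 2L, min_frac = 0.20) {
  structure(list(min_reads = as.integer(min_reads), min_frac = min_frac),
            class = "support_params")
}

#' Map one genotype's reads to reference contigs
#'
#' Reads are aligned locally to every candidate contig (those attributed to
#' the read's assigned amplicon when an `amplicon` column is present,
#' otherwise all) and placed on the best-scoring contig passing the
#' overlap/identity thresholds (default 50 bp / 80%), ties broken by higher
#' identity.
#'
#' @param reads data.frame with `read_id`, `sequence`, optionally `amplicon`
#'   (template assignment) and `strand` (reads on `-` are
#'   reverse-complemented before alignment).
#' @param contigs attributed contig list (each with `contig_id`,
#'   `amplicon_id`, `consensus`).
#' @param params a [mapping_params()] object.
#' @return data.frame: `read_id`, `contig_id`, `score`, `identity`,
#'   `overlap`, `target_start`, `aligned_query`, `aligned_target`; unmapped
#'   reads are omitted.
#' @export
map_reads_to_contigs <- function(reads, contigs, params = mapping_params()) {
  if (!nrow(reads) || !length(contigs)) {
    return(data.frame(read_id = character(), contig_id = character(),
                      score = numeric(), identity = numeric(),
                      overlap = integer(), target_start = integer(),
                      aligned_query = character(), aligned_target = character(),
                      stringsAsFactors = FALSE))
  }
  ctab <- contig_table(contigs)
  seqs <- reads$sequence
  if (!is.null(reads$strand)) {
    flip <- reads$strand == "-"
    seqs[flip] <- revcomp(seqs[flip])
  }
  n <- nrow(reads)
  best <- data.frame(read_id = reads$read_id, contig_id = NA_character_,
                     score = -Inf, identity = -1, overlap = NA_integer_,
                     target_start = NA_integer_,
                     aligned_query = NA_character_,
                     aligned_target = NA_character_, stringsAsFactors = FALSE)
  for (ci in order(ctab$contig_id)) {
    cand <- if (!is.null(reads$amplicon))
      which(!is.na(reads$amplicon) & reads$amplicon == ctab$amplicon_id[ci])
    else seq_len(n)
    if (!length(cand)) next
    hits <- batch_align(seqs[cand], ctab$consensus[ci], params$scoring,
                        "local")
    ok <- passes_thresholds(hits$overlap, hits$identity, params)
    for (jj in which(ok)) {
      i <- cand[jj]
      better <- hits$score[jj] > best$score[i] ||
        (hits$score[jj] == best$score[i] && hits$identity[jj] > best$identity[i])
      if (better) {
        best[i, c("contig_id", "score", "identity", "overlap",
                  "target_start", "aligned_query", "aligned_target")] <-
          list(ctab$contig_id[ci], hits$score[jj], hits$identity[jj],
               hits$overlap[jj], hits$target_start[jj],
               hits$aligned_query[jj], hits$aligned_target[jj])
      }
    }
  }
  out <- best[!is.na(best$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_observations <- function() {
  data.frame(genotype_id = character(), amplicon_id = character(),
             contig_id = character(), position = integer(), ref = character(),
             alt = character(), type = character(), site_depth = integer(),
             alt_support = integer(), stringsAsFactors = FALSE)
}

#' Tabulate nucleotide variants of one genotype against reference contigs
#'
#' Builds a pileup per contig from the read placements and records one
#' observation per (contig, position, alternative allele) passing the
#' support thresholds. Substitutions (`SUB`), deletions (`DEL`, alt `-`,
#' one row per deleted reference position) and insertions (`INS`, alt
#' `+SEQ`, anchored after the reference position) are all recorded; indels
#' are retained so that the qualification stage can reject them explicitly.
#'
#' @param mapped read placements from [map_reads_to_contigs()].
#' @param contigs reference contig list.
#' @param genotype_id genotype label for the emitted rows.
#' @param support a [support_params()] object.
#' @return data.frame of VariantObservation rows; per-contig coverage
#'   vectors are attached as the `"coverage"` attribute (a named list), and
#'   every substitution allele seen in at least one read (including those
#'   below the support thresholds) as the `"raw_alleles"` attribute — the
#'   latter lets the qualification stage distinguish a genotype that truly
#'   lacks an allele from one whose support merely missed the threshold.
#' @export
tabulate_variants <- function(mapped, contigs, genotype_id,
                              support = support_params()) {
  ctab <- contig_table(contigs)
  obs <- list()
  coverage <- list()
  raw <- list()
  for (cid in unique(mapped$contig_id)) {
    crow <- which(ctab$contig_id == cid)
    if (!length(crow)) stop_invalid("reference contig '%s' absent", cid)
    ref <- ctab$consensus[crow]
    L <- nchar(ref)
    refc <- seq_chars(ref)
    mm <- mapped[mapped$contig_id == cid, , drop = FALSE]
    counts <- matrix(0L, nrow = 5L, ncol = L,
                     dimnames = list(c(DNA_BASES, "-"), NULL))
    ins_all <- list()
    for (i in seq_len(nrow(mm))) {
      w <- walk_alignment(mm$aligned_query[i], mm$aligned_target[i],
                          mm$target_start[i])
      keep <- w$pile$base %in% rownames(counts)
      idx <- cbind(match(w$pile$base[keep], rownames(counts)),
                   w$pile$pos[keep])
      counts[idx] <- counts[idx] + 1L
      if (!is.null(w$insertions)) ins_all[[length(ins_all) + 1L]] <- w$insertions
    }
    depth <- colSums(counts)
    coverage[[cid]] <- as.integer(depth)
    amp <- ctab$amplicon_id[crow]
    ## raw substitution alleles with any read support at all
    for (b in DNA_BASES) {
      at <- which(counts[b, ] > 0L & refc != b)
      if (length(at)) {
        raw[[length(raw) + 1L]] <- data.frame(
          genotype_id = genotype_id, contig_id = cid, position = at,
          alt = b, count = counts[b, at], stringsAsFactors = FALSE)
      }
    }
    for (j in which(depth > 0)) {
      for (b in DNA_BASES) {
        if (b == refc[j]) next
        supp <- counts[b, j]
        if (supp >= support$min_reads && supp >= support$min_frac * depth[j]) {
          obs[[length(obs) + 1L]] <- data.frame(
            genotype_id = genotype_id, amplicon_id = amp, contig_id = cid,
            position = j, ref = refc[j], alt = b, type = "SUB",
            site_depth = as.integer(depth[j]), alt_support = supp,
            stringsAsFactors = FALSE)
        }
      }
      supp <- counts["-", j]
      if (supp >= support$min_reads && supp >= support$min_frac * depth[j]) {
        obs[[length(obs) + 1L]] <- data.frame(
          genotype_id = genotype_id, amplicon_id = amp, contig_id = cid,
          position = j, ref = refc[j], alt = "-", type = "DEL",
          site_depth = as.integer(depth[j]), alt_support = supp,
          stringsAsFactors = FALSE)
      }
    }
    if (length(ins_all)) {
      it <- do.call(rbind, ins_all)
      key <- paste(it$pos, it$seq)
      for (k in unique(key)) {
        rows <- it[key == k, , drop = FALSE]
        pos <- rows$pos[1]
        if (pos < 1L || pos > L) next
        supp <- nrow(rows)
        if (supp >= support$min_reads && supp >= support$min_frac * depth[pos]) {
          obs[[length(obs) + 1L]] <- data.frame(
            genotype_id = genotype_id, amplicon_id = amp, contig_id = cid,
            position = pos, ref = refc[pos], alt = paste0("+", rows$seq[1]),
            type = "INS", site_depth = as.integer(depth[pos]), alt_support = supp,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(obs)) do.call(rbind, obs) else empty_observations()
  attr(out, "coverage") <- coverage
  attr(out, "raw_alleles") <- if (length(raw)) do.call(rbind, raw) else
    data.frame(genotype_id = character(), contig_id = character(),
               position = integer(), alt = character(), count = integer(),
               stringsAsFactors = FALSE)
  out
}

#' Detect homoeologous sequence variants between co-attributed contigs
#'
#' Within each genotype, the consensuses of contigs attributed to the same
#' amplicon are pairwise aligned (ends-free; compared only when they share at
#' least `min_overlap` aligned columns at `min_identity`). Every differing
#' substitution column of the aligned span is an HSV, projected onto each
#' contig's own coordinates; gap columns are recorded as indel HSV spans that
#' mask the flanking position of the ungapped contig.
#'
#' @param contigs attributed contig list (with `contig_id`, `genotype_id`,
#'   `amplicon_id`, `consensus`).
#' @param params a [mapping_params()] object (default 0.80 / 10 bp).
#' @return list with `hsv` (data.frame: `contig_id`, `position`, `allele`,
#'   `partner_contig`, `type`), `n_events` (number of differing aligned
#'   columns) and `aligned_bp` (total aligned columns compared).
#' @export
empty_hsv <- function() {
  data.frame(contig_id = character(), position = integer(),
             allele = character(), partner_contig = character(),
             partner_position = integer(), type = character(),
             stringsAsFactors = FALSE)
}

## compare two co-attributed contig consensuses; returns the differing
## columns projected onto each contig's coordinates (or NULL when the pair
## does not meet the comparison thresholds)
hsv_from_pair <- function(id_a, cons_a, id_b, cons_b, params) {
  hit <- batch_align(cons_a, cons_b, params$scoring, "overlap")
  if (!passes_thresholds(hit$overlap[1], hit$identity[1], params)) return(NULL)
  qc <- seq_chars(hit$aligned_query[1])
  tc <- seq_chars(hit$aligned_target[1])
  qpos <- hit$query_start[1] - 1L + cumsum(qc != "-")
  tpos <- hit$target_start[1] - 1L + cumsum(tc != "-")
  d <- which(qc != tc)
  rows <- if (length(d)) {
    data.frame(
      contig_id = rep(c(id_a, id_b), each = length(d)),
      ## indel columns mask the flanking position on the gapped contig
      position = c(pmax(1L, qpos[d]), pmax(1L, tpos[d])),
      allele = c(qc[d], tc[d]),
      partner_contig = rep(c(id_b, id_a), each = length(d)),
      partner_position = c(pmax(1L, tpos[d]), pmax(1L, qpos[d])),
      type = rep(ifelse(qc[d] != "-" & tc[d] != "-", "SUB", "INDEL"), 2L),
      stringsAsFactors = FALSE)
  } else NULL
  list(rows = rows, n_events = length(d), aligned_bp = hit$overlap[1],
       score = hit$score[1])
}

## greedy one-to-one matching of two contig sets by descending alignment
## score (ties by lexicographic ids); returns a logical matrix marking the
## matched (same sub-genome) pairs
greedy_pairing <- function(S, ids_a, ids_b) {
  matched <- matrix(FALSE, nrow(S), ncol(S))
  cand <- which(is.finite(S), arr.ind = TRUE)
  if (nrow(cand)) {
    ord <- order(-S[cand], ids_a[cand[, 1]], ids_b[cand[, 2]])
    cand <- cand[ord, , drop = FALSE]
  }
  used_a <- logical(nrow(S)); used_b <- logical(ncol(S))
  for (p in seq_len(nrow(cand))) {
    i <- cand[p, 1]; j <- cand[p, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    matched[i, j] <- TRUE
  }
  matched
}

detect_hsvs <- function(contigs,
                        params = mapping_params(min_overlap = 10L,
                                                min_identity = 0.80)) {
  tab <- contig_table(contigs)
  rows <- list(); n_events <- 0L; aligned_bp <- 0L
  grp <- tab[tab$amplicon_id != "UNATTRIBUTED", , drop = FALSE]
  keys <- unique(grp[c("genotype_id", "amplicon_id")])
  for (ki in seq_len(nrow(keys))) {
    sub <- grp[grp$genotype_id == keys$genotype_id[ki] &
               grp$amplicon_id == keys$amplicon_id[ki], , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (a in seq_len(nrow(sub) - 1L)) {
      for (b in (a + 1L):nrow(sub)) {
        pr <- hsv_from_pair(sub$contig_id[a], sub$consensus[a],
                            sub$contig_id[b], sub$consensus[b], params)
        if (is.null(pr)) next
        aligned_bp <- aligned_bp + pr$aligned_bp
        n_events <- n_events + pr$n_events
        if (!is.null(pr$rows)) rows[[length(rows) + 1L]] <- pr$rows
      }
    }
  }
  hsv <- if (length(rows)) do.call(rbind, rows) else empty_hsv()
  rownames(hsv) <- NULL
  list(hsv = hsv, n_events = n_events, aligned_bp = aligned_bp)
}

#' Detect HSVs between two reference contig assemblies
#'
#' Complements [detect_hsvs()]: contigs of the two reference genotypes that
#' are attributed to the same amplicon are compared pairwise, *excluding*
#' each mutual-best pair — those represent the same sub-genome in the two
#' references, and their differences are diagnostic candidates handled by
#' [classify_diagnostic()]. The remaining cross pairs compare different
#' sub-genomes, so their differing columns are homoeologous variation. This
#' recovers HSV positions internal to a contig whose sub-genomes
#' co-assembled in one reference but were decomposed in the other.
#'
#' @param contigs_a,contigs_b attributed contig lists of the two reference
#'   genotypes.
#' @param params a [mapping_params()] object (default 0.80 / 10 bp).
#' @return as [detect_hsvs()].
#' @export
detect_hsvs_between <- function(contigs_a, contigs_b,
                                params = mapping_params(min_overlap = 10L,
                                                        min_identity = 0.80)) {
  ta <- contig_table(contigs_a); tb <- contig_table(contigs_b)
  ta <- ta[ta$amplicon_id != "UNATTRIBUTED", , drop = FALSE]
  tb <- tb[tb$amplicon_id != "UNATTRIBUTED", , drop = FALSE]
  rows <- list(); n_events <- 0L; aligned_bp <- 0L
  for (amp in intersect(ta$amplicon_id, tb$amplicon_id)) {
    sa <- ta[ta$amplicon_id == amp, , drop = FALSE]
    sb <- tb[tb$amplicon_id == amp, , drop = FALSE]
    S <- matrix(-Inf, nrow(sa), nrow(sb))
    prs <- vector("list", nrow(sa))
    for (i in seq_len(nrow(sa))) {
      prs[[i]] <- vector("list", nrow(sb))
      for (j in seq_len(nrow(sb))) {
        pr <- hsv_from_pair(sa$contig_id[i], sa$consensus[i],
                            sb$contig_id[j], sb$consensus[j], params)
        if (!is.null(pr)) { S[i, j] <- pr$score; prs[[i]][[j]] <- pr }
      }
    }
    matched <- greedy_pairing(S, sa$contig_id, sb$contig_id)
    for (i in seq_len(nrow(sa))) {
      for (j in seq_len(nrow(sb))) {
        if (!is.finite(S[i, j])) next
        if (matched[i, j]) next  # same-sub-genome pair: diagnostic territory
        pr <- prs[[i]][[j]]
        aligned_bp <- aligned_bp + pr$aligned_bp
        n_events <- n_events + pr$n_events
        if (!is.null(pr$rows)) rows[[length(rows) + 1L]] <- pr$rows
      }
    }
  }
  hsv <- if (length(rows)) do.call(rbind, rows) else empty_hsv()
  rownames(hsv) <- NULL
  list(hsv = hsv, n_events = n_events, aligned_bp = aligned_bp)
}

REJECT_CLASSES <- c("REJECT_INDEL", "REJECT_SINGLETON", "REJECT_UBIQUITOUS",
                    "REJECT_HSV_COLOCATED", "REJECT_TERMINAL")

#' Qualify variant observations into SNPs and reject classes
#'
#' Variants are grouped per (contig, position, alternative allele) across the
#' genotype panel and classified: indels are rejected outright; variants
#' carried by every panel genotype are rejected as ubiquitous (a fixed
#' difference, not a segregating marker); variants at HSV positions are
#' rejected as co-located; variants within the terminal `terminal_exclude`
#' bp of a contig are rejected (alignment artefacts concentrate at contig
#' termini); variants in a single genotype are rejected as singletons.
#' Survivors — substitutions carried by at least 2 but not all panel
#' genotypes away from HSV positions — are qualified SNPs.
#'
#' The HSV co-location rejection is segregation-aware when per-genotype
#' `coverage` is supplied: a column flagged by contig comparison is only a
#' fixed homoeologous difference if the alternative allele is present in
#' essentially every genotype, so the rejection is overridden when at least
#' one genotype with site depth `>= min_confirm_depth` shows no support for
#' the allele (confirmed reference — the site segregates). Without this
#' override an allelic variant carried by the reference genotype itself
#' (and hence baked into one sub-genome consensus) would be discarded as an
#' HSV.
#'
#' @param observations combined [tabulate_variants()] rows for the panel.
#' @param hsv_set data.frame with `contig_id`, `position` (from
#'   [detect_hsvs()]'s `hsv` element); may have zero rows.
#' @param panel_genotypes character vector of all genotype ids in the panel.
#' @param contigs reference contig list (for contig lengths).
#' @param terminal_exclude width of the excluded contig termini (bp).
#' @param coverage optional named list `genotype -> contig -> depth vector`
#'   (the per-genotype `"coverage"` attributes of [tabulate_variants()]).
#' @param raw_support optional combined `"raw_alleles"` attributes of
#'   [tabulate_variants()]; a genotype with any read of the allele (even
#'   below the support thresholds) is not confirmed reference.
#' @param min_confirm_depth site depth required for a genotype without the
#'   allele to count as confirmed reference.
#' @return ClassifiedVariant data.frame: `amplicon_id`, `contig_id`,
#'   `position`, `ref`, `alt`, `type`, `class`, `n_carriers`, `carriers`
#'   (`;`-joined genotype ids).
#' @export
qualify_snps <- function(observations, hsv_set, panel_genotypes, contigs,
                         terminal_exclude = 10L, coverage = NULL,
                         raw_support = NULL, min_confirm_depth = 3L) {
  panel_size <- length(unique(panel_genotypes))
  if (panel_size < 3L) {
    stop_invalid("panel_size < 3: SNP qualification is degenerate")
  }
  ctab <- contig_table(contigs)
  clen <- stats::setNames(ctab$length, ctab$contig_id)
  if (!nrow(observations)) {
    return(data.frame(amplicon_id = character(), contig_id = character(),
                      position = integer(), ref = character(),
                      alt = character(), type = character(),
                      class = character(), n_carriers = integer(),
                      carriers = character(), stringsAsFactors = FALSE))
  }
  hsv_key <- if (nrow(hsv_set)) paste(hsv_set$contig_id, hsv_set$position)
             else character(0)
  ## hard-masked positions: corroborated homoeologous columns for which the
  ## segregation override must not apply
  hard_key <- if (nrow(hsv_set) && !is.null(hsv_set$hard)) {
    paste(hsv_set$contig_id, hsv_set$position)[hsv_set$hard]
  } else character(0)
  key <- paste(observations$contig_id, observations$position,
               observations$alt, observations$type)
  ## a genotype confirms the reference at (contig, pos, alt) when it has
  ## adequate depth there and not a single read of that allele
  raw_key <- if (!is.null(raw_support) && nrow(raw_support)) {
    paste(raw_support$genotype_id, raw_support$contig_id,
          raw_support$position, raw_support$alt)
  } else character(0)
  confirmed_ref_exists <- function(cid, pos, alt, carriers) {
    if (is.null(coverage)) return(FALSE)
    for (g in setdiff(panel_genotypes, carriers)) {
      d <- coverage[[g]][[cid]]
      if (!is.null(d) && length(d) >= pos && d[pos] >= min_confirm_depth &&
          !(paste(g, cid, pos, alt) %in% raw_key)) {
        return(TRUE)
      }
    }
    FALSE
  }
  rows <- lapply(unique(key), function(k) {
    o <- observations[key == k, , drop = FALSE]
    carriers <- sort(unique(o$genotype_id))
    nc <- length(carriers)
    pos <- o$position[1]; cid <- o$contig_id[1]
    at_hsv <- (paste(cid, pos) %in% hard_key) ||
      (paste(cid, pos) %in% hsv_key &&
       !confirmed_ref_exists(cid, pos, o$alt[1], carriers))
    cl <- if (o$type[1] != "SUB") "REJECT_INDEL"
      else if (nc >= panel_size) "REJECT_UBIQUITOUS"
      else if (at_hsv) "REJECT_HSV_COLOCATED"
      else if (pos <= terminal_exclude ||
               pos > (clen[[cid]] %||% Inf) - terminal_exclude) "REJECT_TERMINAL"
      else if (nc < 2L) "REJECT_SINGLETON"
      else "SNP"
    data.frame(amplicon_id = o$amplicon_id[1], contig_id = cid,
               position = pos, ref = o$ref[1], alt = o$alt[1],
               type = o$type[1], class = cl, n_carriers = nc,
               carriers = paste(carriers, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify diagnostic variants between two morphotype panels
#'
#' Contigs of the two groups attributed to shared amplicons are paired by
#' mutual best alignment (so homoeologous contigs of the *same* sub-genome
#' are compared across groups). Differing substitution columns whose
#' position is monomorphic across every sequenced genotype within each group
#' — no variant observation, and at least `min_observed` genotypes with
#' coverage `>= min_depth` per group — are classified `DIAGNOSTIC`.
#'
#' @param contigs_a,contigs_b attributed contig lists of the two groups.
#' @param obs_a,obs_b combined variant observations of each group's panel.
#' @param coverage_a,coverage_b named lists `genotype -> contig -> depth
#'   vector` (per-genotype `"coverage"` attributes of
#'   [tabulate_variants()]).
#' @param params a [mapping_params()] object (default 0.80 / 10 bp).
#' @param min_observed minimum genotypes with coverage per group.
#' @param min_depth minimum per-genotype site depth to count as observed.
#' @return data.frame: `amplicon_id`, `contig_a`, `position_a`, `allele_a`,
#'   `contig_b`, `position_b`, `allele_b`, `class` (`DIAGNOSTIC`). A warning
#'   is raised (and an empty table returned) when no amplicons are shared.
#' @export
classify_diagnostic <- function(contigs_a, contigs_b, obs_a, obs_b,
                                coverage_a, coverage_b,
                                params = mapping_params(min_overlap = 10L,
                                                        min_identity = 0.80),
                                min_observed = 2L, min_depth = 2L) {
  ta <- contig_table(contigs_a); tb <- contig_table(contigs_b)
  ta <- ta[ta$amplicon_id != "UNATTRIBUTED", , drop = FALSE]
  tb <- tb[tb$amplicon_id != "UNATTRIBUTED", , drop = FALSE]
  shared <- intersect(ta$amplicon_id, tb$amplicon_id)
  empty <- data.frame(amplicon_id = character(), contig_a = character(),
                      position_a = integer(), allele_a = character(),
                      contig_b = character(), position_b = integer(),
                      allele_b = character(), class = character(),
                      stringsAsFactors = FALSE)
  if (!length(shared)) {
    warning("no shared amplicons between the two groups")
    return(empty)
  }
  obs_key_a <- paste(obs_a$contig_id, obs_a$position)
  obs_key_b <- paste(obs_b$contig_id, obs_b$position)
  n_covered <- function(coverage, cid, pos) {
    sum(vapply(coverage, function(per_geno) {
      d <- per_geno[[cid]]
      !is.null(d) && length(d) >= pos && d[pos] >= min_depth
    }, logical(1)))
  }
  rows <- list()
  for (amp in shared) {
    sa <- ta[ta$amplicon_id == amp, , drop = FALSE]
    sb <- tb[tb$amplicon_id == amp, , drop = FALSE]
    ## score matrix for mutual best pairing
    S <- matrix(-Inf, nrow(sa), nrow(sb))
    alns <- vector("list", nrow(sa))
    for (i in seq_len(nrow(sa))) {
      alns[[i]] <- vector("list", nrow(sb))
      for (j in seq_len(nrow(sb))) {
        hit <- batch_align(sa$consensus[i], sb$consensus[j], params$scoring,
                           "overlap")
        if (passes_thresholds(hit$overlap[1], hit$identity[1], params)) {
          S[i, j] <- hit$score[1]
          alns[[i]][[j]] <- hit
        }
      }
    }
    ## greedy one-to-one pairing by descending score so each contig is
    ## compared with its same-sub-genome counterpart
    matched <- greedy_pairing(S, sa$contig_id, sb$contig_id)
    pairs <- which(matched, arr.ind = TRUE)
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      hit <- alns[[i]][[j]]
      qc <- seq_chars(hit$aligned_query[1]); tc <- seq_chars(hit$aligned_target[1])
      qpos <- hit$query_start[1] - 1L + cumsum(qc != "-")
      tpos <- hit$target_start[1] - 1L + cumsum(tc != "-")
      for (col in which(qc != tc & qc %in% DNA_BASES & tc %in% DNA_BASES)) {
        pa <- qpos[col]; pb <- tpos[col]
        if (paste(sa$contig_id[i], pa) %in% obs_key_a) next
        if (paste(sb$contig_id[j], pb) %in% obs_key_b) next
        if (n_covered(coverage_a, sa$contig_id[i], pa) < min_observed) next
        if (n_covered(coverage_b, sb$contig_id[j], pb) < min_observed) next
        rows[[length(rows) + 1L]] <- data.frame(
          amplicon_id = amp, contig_a = sa$contig_id[i], position_a = pa,
          allele_a = qc[col], contig_b = sb$contig_id[j], position_b = pb,
          allele_b = tc[col], class = "DIAGNOSTIC", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty
}

#' Summary of classified variants
#'
#' @param classified ClassifiedVariant data.frame from [qualify_snps()].
#' @param n_amplicons number of amplicons sequenced.
#' @param n_contigs number of reference contigs.
#' @return one-row data.frame: totals by class, mean qualified SNPs per
#'   amplicon and per contig.
#' @export
snp_summary <- function(classified, n_amplicons, n_contigs) {
  n_snp <- sum(classified$class == "SNP")
  data.frame(
    n_variants = nrow(classified),
    n_snps = n_snp,
    n_indels = sum(classified$class == "REJECT_INDEL"),
    n_singleton = sum(classified$class == "REJECT_SINGLETON"),
    n_ubiquitous = sum(classified$class == "REJECT_UBIQUITOUS"),
    n_hsv_colocated = sum(classified$class == "REJECT_HSV_COLOCATED"),
    n_terminal = sum(classified$class == "REJECT_TERMINAL"),
    snps_per_amplicon = if (n_amplicons) n_snp / n_amplicons else 0,
    snps_per_contig = if (n_contigs) n_snp / n_contigs else 0,
    stringsAsFactors = FALSE)
}
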