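#' Stringent assembly parameter set
#'
#' Defaults mirror the sub-genome-decomposing assembly stage: 97% identity
#' over at least 100 overlapping bp, a minimum of 5 reads per contig, and
#' singletons saved. `split_conflicts` enables the repeat-resolution pass
#' that separates co-assembled haplotypes at confirmed internal conflict
#' columns (see [cluster_reads()]).
#'
#' @param min_identity minimum identity for a read to join a cluster.
#' @param min_overlap minimum aligned columns for a read to join a cluster.
#' @param min_reads_per_contig clusters below this size are dissolved.
#' @param keep_singletons retain unassembled reads in downstream outputs.
#' @param split_conflicts split clusters at confirmed conflicting columns.
#' @param min_conflict_support reads required on each allele of a column for
#'   it to count as a confirmed conflict.
#' @param final_iupac encode ties in the final contig consensus as IUPAC
#'   codes; off by default so reference contigs stay strictly A/C/G/T (a
#'   tied heterozygous column falls to the lexicographically smallest base
#'   and the alternative allele surfaces at read mapping).
#' @param scoring an [align_scoring()] object.
#' @return list of class `assembly_params`.
#' @export
assembly_params <- function(min_identity = 0.97, min_overlap = 100L,
                            min_reads_per_contig = 5L, keep_singletons = TRUE,
                            split_conflicts = TRUE, min_conflict_support = 3L,
                            final_iupac = FALSE,
                            scoring = align_scoring()) {
  structure(list(min_identity = min_identity,
                 min_overlap = as.integer(min_overlap),
                 min_reads_per_contig = as.integer(min_reads_per_contig),
                 keep_singletons = isTRUE(keep_singletons),
                 split_conflicts = isTRUE(split_conflicts),
                 min_conflict_support = as.integer(min_conflict_support),
                 final_iupac = isTRUE(final_iupac),
                 scoring = scoring),
            class = "assembly_params")
}

## walk one gapped alignment (query vs target) and return the query base seen
## at every target position of the aligned span ("-" for deletions), plus
## insertions anchored after a target position
walk_alignment <- function(aligned_query, aligned_target, target_start) {
  qc <- seq_chars(aligned_query)
  tc <- seq_chars(aligned_target)
  tgap <- tc == "-"
  tpos <- target_start - 1L + cumsum(!tgap)
  pile <- data.frame(pos = tpos[!tgap], base = qc[!tgap],
                     stringsAsFactors = FALSE)
  ins <- NULL
  if (any(tgap)) {
    runs <- rle(tgap)
    endidx <- cumsum(runs$lengths)
    startidx <- endidx - runs$lengths + 1L
    w <- which(runs$values)
    ins <- data.frame(
      pos = tpos[startidx[w]],  # anchored after this target position
      seq = vapply(w, function(j) paste(qc[startidx[j]:endidx[j]],
                                        collapse = ""), character(1)),
      stringsAsFactors = FALSE)
  }
  list(pile = pile, insertions = ins)
}

## pileup of member sequences against a frame sequence; returns the base
## matrix (members x frame positions, NA outside each member's span),
## insertion records and the per-position coverage
member_pileup <- function(seqs, frame, scoring) {
  L <- nchar(frame)
  alns <- batch_align(seqs, frame, scoring, "overlap")
  M <- matrix(NA_character_, nrow = length(seqs), ncol = L)
  ins <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    w <- walk_alignment(alns$aligned_query[i], alns$aligned_target[i],
                        alns$target_start[i])
    M[i, w$pile$pos] <- w$pile$base
    ins[[i]] <- w$insertions
  }
  list(M = M, insertions = ins, alns = alns)
}

## column-wise consensus over a pileup matrix
## ties between bases: IUPAC code when allow_iupac, else lexicographically
## smallest base; a strict gap majority deletes the column; insertions seen
## identically in a majority of covering members are applied
pileup_consensus <- function(pp, allow_iupac = TRUE) {
  M <- pp$M
  L <- ncol(M)
  out <- character(0)
  depth_out <- integer(0)
  cov <- colSums(!is.na(M))
  ins_tab <- do.call(rbind, pp$insertions)
  for (j in seq_len(L)) {
    col <- M[, j]
    col <- col[!is.na(col)]
    if (length(col)) {
      tab <- table(col)
      gaps <- if ("-" %in% names(tab)) tab[["-"]] else 0L
      btab <- tab[names(tab) %in% DNA_BASES]
      if (length(btab) == 0L || gaps > sum(btab)) {
        ## strict gap majority: column deleted
      } else {
        mx <- max(btab)
        winners <- names(btab)[btab == mx]
        base <- if (length(winners) == 1L) winners else if (allow_iupac)
          iupac_code(winners) else sort(winners)[1]
        out <- c(out, base)
        depth_out <- c(depth_out, length(col))
      }
    }
    ## majority insertion anchored after position j
    if (!is.null(ins_tab) && nrow(ins_tab)) {
      here <- ins_tab[ins_tab$pos == j, , drop = FALSE]
      if (nrow(here)) {
        tt <- sort(table(here$seq), decreasing = TRUE)
        if (tt[1] > cov[j] / 2) {
          s <- names(tt)[1]
          out <- c(out, seq_chars(s))
          depth_out <- c(depth_out, rep(tt[[1]], nchar(s)))
        }
      }
    }
  }
  list(consensus = paste(out, collapse = ""), depth = depth_out)
}

## trim consensus termini where depth < 2
trim_termini <- function(cons) {
  d <- cons$depth
  keep <- which(d >= 2L)
  if (!length(keep)) return(cons)
  lo <- min(keep); hi <- max(keep)
  list(consensus = substr(cons$consensus, lo, hi), depth = d[lo:hi])
}

#' Consensus of a read cluster
#'
#' Members are aligned to the cluster frame (the running consensus, or the
#' first member); each column is called by majority over the observed bases,
#' with ties encoded as IUPAC ambiguity codes. Columns with a strict gap
#' majority are deleted, insertions shared by a majority of covering members
#' are incorporated, and terminal columns with depth < 2 are trimmed.
#'
#' @param cluster list with element `seqs` (character vector of member
#'   sequences) and optionally `consensus` (frame; defaults to the first
#'   member).
#' @param scoring an [align_scoring()] object.
#' @param allow_iupac encode ties as IUPAC codes (default) rather than the
#'   lexicographically smallest base.
#' @return list with `consensus` (string) and `depth` (integer per-position
#'   coverage).
#' @export
consensus <- function(cluster, scoring = align_scoring(),
                      allow_iupac = TRUE) {
  seqs <- cluster$seqs
  if (!length(seqs)) stop_invalid("empty cluster")
  frame <- cluster$consensus %||% seqs[1]
  pp <- member_pileup(seqs, frame, scoring)
  trim_termini(pileup_consensus(pp, allow_iupac = allow_iupac))
}

## find candidate conflict columns in a pileup matrix: columns whose two most
## frequent bases are each supported by >= min_support reads
conflict_columns <- function(M, min_support) {
  cand <- list()
  for (j in seq_len(ncol(M))) {
    col <- M[, j]
    col <- col[!is.na(col) & col %in% DNA_BASES]
    if (length(col) < 2L * min_support) next
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) >= 2L && tab[[2]] >= min_support) {
      cand[[length(cand) + 1L]] <- list(col = j, minor = tab[[2]],
                                        b1 = names(tab)[1], b2 = names(tab)[2])
    }
  }
  if (!length(cand)) return(NULL)
  cand[order(-vapply(cand, `[[`, numeric(1), "minor"),
             vapply(cand, `[[`, numeric(1), "col"))]
}

## recursively split a set of member indices at confirmed conflict columns.
## A split is accepted when both sides keep >= min_support members, the
## larger side can still form a contig (>= min_reads), and the two groups
## are phase-separated: their majority patterns disagree at >= 2 candidate
## columns, or at one column on which both sides have >= min_reads members.
## The multi-column requirement keeps an isolated heterozygous substitution
## (one allelic site within a sub-genome) from shattering the group, while
## co-assembled sub-genomes — which disagree at several correlated columns —
## are separated.
split_by_conflicts <- function(M, idx, min_support, min_reads) {
  sub <- M[idx, , drop = FALSE]
  cand <- conflict_columns(sub, min_support)
  if (is.null(cand)) return(list(idx))
  cols <- vapply(cand, `[[`, numeric(1), "col")
  for (cc in cand) {
    a_seed <- idx[!is.na(sub[, cc$col]) & sub[, cc$col] == cc$b1]
    b_seed <- idx[!is.na(sub[, cc$col]) & sub[, cc$col] == cc$b2]
    if (length(a_seed) < min_support || length(b_seed) < min_support) next
    ## haplotype pattern of each seed group over all candidate columns
    pat <- function(members) {
      apply(M[members, cols, drop = FALSE], 2, function(col) {
        col <- col[!is.na(col) & col %in% DNA_BASES]
        if (!length(col)) NA_character_ else
          names(sort(table(col), decreasing = TRUE))[1]
      })
    }
    pa <- pat(a_seed); pb <- pat(b_seed)
    assign_grp <- function(i) {
      v <- M[i, cols]
      sa <- sum(v == pa, na.rm = TRUE); sb <- sum(v == pb, na.rm = TRUE)
      if (sa >= sb) "a" else "b"
    }
    grp <- vapply(idx, assign_grp, character(1))
    a <- idx[grp == "a"]; b <- idx[grp == "b"]
    if (length(a) < min_support || length(b) < min_support) next
    if (max(length(a), length(b)) < min_reads) next
    phase_cols <- sum(pa != pb, na.rm = TRUE)
    if (phase_cols < 2L &&
        !(length(a) >= min_reads && length(b) >= min_reads)) next
    return(c(split_by_conflicts(M, a, min_support, min_reads),
             split_by_conflicts(M, b, min_support, min_reads)))
  }
  list(idx)
}

#' Greedy stringent clustering of one genotype's reads
#'
#' Reads are processed longest-first. A read joins the existing cluster with
#' which its ends-free alignment to the running consensus has the highest
#' identity, provided the overlap is at least `min_overlap` columns and the
#' identity at least `min_identity`; otherwise it seeds a new cluster. The
#' running consensus is extended by read overhangs and recomputed whenever a
#' cluster grows by 25% membership. When `split_conflicts` is enabled,
#' finished clusters are re-examined for confirmed internal conflict columns
#' (two alleles each carried by several reads — the signature of co-assembled
#' homoeologous haplotypes whose divergence lies above the identity
#' threshold) and split while both sides retain `min_reads_per_contig`
#' members. Finally, clusters below `min_reads_per_contig` members are
#' dissolved into the unassembled (singleton) set.
#'
#' @param reads data.frame with `read_id` and `sequence` (barcode-trimmed,
#'   same genotype).
#' @param params an [assembly_params()] object.
#' @return list with `clusters` (each: `member_read_ids`, `seqs`,
#'   `consensus`, `depth`) and `unassembled` (read ids).
#' @export
cluster_reads <- function(reads, params = assembly_params()) {
  if (!nrow(reads)) return(list(clusters = list(), unassembled = character()))
  ord <- order(-nchar(reads$sequence), seq_len(nrow(reads)))
  reads <- reads[ord, , drop = FALSE]
  clusters <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    best <- NULL
    for (ci in seq_along(clusters)) {
      hit <- batch_align(s, clusters[[ci]]$consensus, params$scoring,
                         "overlap")
      if (!passes_thresholds(hit$overlap[1], hit$identity[1],
                             list(min_overlap = params$min_overlap,
                                  min_identity = params$min_identity,
                                  strict_gt = FALSE))) next
      best <- list(ci = ci, identity = hit$identity[1], hit = hit)
      break  # first-passing cluster wins (clusters in creation order)
    }
    if (is.null(best)) {
      clusters[[length(clusters) + 1L]] <- list(
        member_read_ids = reads$read_id[i], seqs = s, consensus = s,
        last_recompute = 1L)
      next
    }
    ci <- best$ci
    cl <- clusters[[ci]]
    cl$member_read_ids <- c(cl$member_read_ids, reads$read_id[i])
    cl$seqs <- c(cl$seqs, s)
    ## extend the frame with read overhangs beyond the consensus ends
    hit <- best$hit
    if (hit$target_start[1] == 1L && hit$query_start[1] > 1L) {
      cl$consensus <- paste0(substr(s, 1L, hit$query_start[1] - 1L),
                             cl$consensus)
    }
    if (hit$target_end[1] == nchar(cl$consensus) &&
        hit$query_end[1] < nchar(s)) {
      cl$consensus <- paste0(cl$consensus,
                             substr(s, hit$query_end[1] + 1L, nchar(s)))
    }
    if (length(cl$seqs) >= 1.25 * cl$last_recompute) {
      pp <- member_pileup(cl$seqs, cl$consensus, params$scoring)
      cl$consensus <- pileup_consensus(pp, allow_iupac = FALSE)$consensus
      cl$last_recompute <- length(cl$seqs)
    }
    clusters[[ci]] <- cl
  }
  ## final consensus + optional conflict splitting
  out <- list()
  for (cl in clusters) {
    pp <- member_pileup(cl$seqs, cl$consensus, params$scoring)
    groups <- list(seq_along(cl$seqs))
    if (params$split_conflicts &&
        length(cl$seqs) >= params$min_reads_per_contig +
                           params$min_conflict_support) {
      groups <- split_by_conflicts(pp$M, seq_along(cl$seqs),
                                   params$min_conflict_support,
                                   params$min_reads_per_contig)
    }
    ## reunite split subgroups that are one haplotype divided by read span:
    ## their member-supported (unfilled) consensuses agree perfectly over
    ## the overlap, whereas genuinely distinct haplotypes disagree at the
    ## conflict columns that separated them
    if (length(groups) > 1L) {
      raw_cons <- vapply(groups, function(g) {
        pileup_consensus(list(M = pp$M[g, , drop = FALSE],
                              insertions = pp$insertions[g]),
                         allow_iupac = FALSE)$consensus
      }, character(1))
      repeat {
        merged_any <- FALSE
        for (a in seq_along(groups)) {
          for (b in seq_along(groups)) {
            if (a >= b) next
            hit <- batch_align(raw_cons[a], raw_cons[b], params$scoring,
                               "overlap")
            zero_mm <- hit$identity[1] == 1 &&
              hit$overlap[1] >= min(params$min_overlap,
                                    nchar(raw_cons[a]), nchar(raw_cons[b]))
            if (zero_mm) {
              groups[[a]] <- c(groups[[a]], groups[[b]])
              groups[[b]] <- NULL
              raw_cons[a] <- pileup_consensus(
                list(M = pp$M[groups[[a]], , drop = FALSE],
                     insertions = pp$insertions[groups[[a]]]),
                allow_iupac = FALSE)$consensus
              raw_cons <- raw_cons[-b]
              merged_any <- TRUE
              break
            }
          }
          if (merged_any) break
        }
        if (!merged_any) break
      }
    }
    for (g in groups) {
      subM <- pp$M[g, , drop = FALSE]
      sub_ins <- pp$insertions[g]
      ## fill thin termini of a split subgroup from the parent cluster:
      ## homoeologous haplotypes of one amplicon share their flanks, and a
      ## truncated contig would bleed its reads onto full-length siblings
      ## at the mapping stage
      if (length(g) < length(cl$seqs)) {
        cov <- colSums(!is.na(subM))
        solid <- which(cov >= 2L)
        if (length(solid)) {
          fill <- c(seq_len(min(solid) - 1L),
                    if (max(solid) < ncol(subM))
                      (max(solid) + 1L):ncol(subM) else integer(0))
          if (length(fill)) {
            rest <- setdiff(seq_along(cl$seqs), g)
            restM <- pp$M[rest, , drop = FALSE]
            restM[, -fill] <- NA_character_
            subM <- rbind(subM, restM)
          }
        }
      }
      sub_pp <- list(M = subM, insertions = sub_ins)
      cons <- trim_termini(pileup_consensus(sub_pp,
                                            allow_iupac = params$final_iupac))
      out[[length(out) + 1L]] <- list(
        member_read_ids = cl$member_read_ids[g], seqs = cl$seqs[g],
        consensus = cons$consensus, depth = cons$depth)
    }
  }
  ## groups that resolved to the same consensus are one haplotype that the
  ## greedy recursion happened to divide (e.g. by read span); reunite them
  if (length(out) > 1L) {
    cons_key <- vapply(out, `[[`, character(1), "consensus")
    merged <- list()
    for (k in unique(cons_key)) {
      same <- out[cons_key == k]
      if (length(same) == 1L) {
        merged[[length(merged) + 1L]] <- same[[1]]
      } else {
        m <- same[[1]]
        for (other in same[-1]) {
          m$member_read_ids <- c(m$member_read_ids, other$member_read_ids)
          m$seqs <- c(m$seqs, other$seqs)
          m$depth <- m$depth + other$depth
        }
        merged[[length(merged) + 1L]] <- m
      }
    }
    out <- merged
  }
  keep <- vapply(out, function(cl)
    length(cl$member_read_ids) >= params$min_reads_per_contig, logical(1))
  unassembled <- unlist(lapply(out[!keep], `[[`, "member_read_ids"))
  list(clusters = out[keep],
       unassembled = as.character(unassembled %||% character(0)))
}

#' Polish heterozygous consensus columns using sibling contigs
#'
#' A reference contig built from a heterozygous genotype may carry either
#' allele at an allelic site (the member reads split ~50/50 and the majority
#' is a coin flip). At such *confirmed heterozygous* columns — two bases
#' each supported by `min_support`+ member reads — the consensus is set to
#' the allele shared with the co-attributed sibling contigs (the other
#' sub-genomes of the same amplicon), which is the ancestral, reference
#' state of the sub-genome. Columns where no sibling carries either allele
#' are left at their majority base.
#'
#' @param contigs attributed contig list (with member `seqs` retained).
#' @param params an [assembly_params()] object (scoring).
#' @param min_support member reads required on each allele for a column to
#'   count as heterozygous; 2 suffices because sequencing errors almost
#'   never produce two concordant reads at one column.
#' @return the contig list with polished `consensus` strings.
#' @export
polish_het_columns <- function(contigs, params = assembly_params(),
                               min_support = 2L) {
  tab <- contig_table(contigs)
  keys <- unique(tab[tab$amplicon_id != "UNATTRIBUTED",
                     c("genotype_id", "amplicon_id")])
  for (ki in seq_len(nrow(keys))) {
    idx <- which(tab$genotype_id == keys$genotype_id[ki] &
                 tab$amplicon_id == keys$amplicon_id[ki])
    if (length(idx) < 2L) next
    ## confirmed het columns per contig of this amplicon
    hets <- lapply(idx, function(i) {
      pp <- member_pileup(contigs[[i]]$seqs, contigs[[i]]$consensus,
                          params$scoring)
      conflict_columns(pp$M, min_support)
    })
    for (a in seq_along(idx)) {
      if (is.null(hets[[a]])) next
      i <- idx[a]
      cons <- contigs[[i]]$consensus
      for (b in seq_along(idx)[-a]) {
        j <- idx[b]
        hit <- batch_align(cons, contigs[[j]]$consensus, params$scoring,
                           "overlap")
        qc <- seq_chars(hit$aligned_query[1])
        tc <- seq_chars(hit$aligned_target[1])
        qpos <- hit$query_start[1] - 1L + cumsum(qc != "-")
        keep <- qc != "-" & tc %in% DNA_BASES
        sib_base <- rep(NA_character_, nchar(cons))
        sib_base[qpos[keep]] <- tc[keep]
        for (cc in hets[[a]]) {
          sb <- sib_base[cc$col]
          if (!is.na(sb) && sb %in% c(cc$b1, cc$b2) &&
              substr(cons, cc$col, cc$col) != sb) {
            substr(cons, cc$col, cc$col) <- sb
          }
        }
      }
      contigs[[i]]$consensus <- cons
    }
  }
  contigs
}

#' Attribute contigs to amplicons via progenitor references
#'
#' Each contig consensus is aligned against the progenitor reference
#' sequences (80% identity over at least 10 bp by default) and attributed to
#' the amplicon of its best passing reference; contigs with no passing
#' progenitor match are tried against the fallback template set; contigs
#' failing both remain `UNATTRIBUTED`.
#'
#' @param contigs list of contigs (from [cluster_reads()]), each gaining an
#'   `amplicon_id` field.
#' @param progenitor_refs data.frame with `ref_id`, `amplicon`, `sequence`.
#' @param fallback_templates optional data.frame with the same columns.
#' @param params a [mapping_params()] object (default 0.80 / 10 bp).
#' @return the contig list with `amplicon_id` (and `attributed_via`) set.
#' @export
attribute_contigs <- function(contigs, progenitor_refs,
                              fallback_templates = NULL,
                              params = mapping_params(min_overlap = 10L,
                                                      min_identity = 0.80)) {
  if (!length(contigs)) return(contigs)
  seqs <- vapply(contigs, `[[`, character(1), "consensus")
  best_amp <- rep(NA_character_, length(contigs))
  best_via <- rep(NA_character_, length(contigs))
  try_refs <- function(refset, via, unresolved) {
    if (is.null(refset) || !nrow(refset) || !length(unresolved)) return()
    score <- rep(-Inf, length(contigs)); ident <- rep(-1, length(contigs))
    refid <- rep(NA_character_, length(contigs))
    for (ri in order(refset$ref_id)) {
      hits <- batch_align(seqs[unresolved], refset$sequence[ri],
                          params$scoring, "local")
      ok <- passes_thresholds(hits$overlap, hits$identity, params)
      for (jj in which(ok)) {
        i <- unresolved[jj]
        better <- hits$score[jj] > score[i] ||
          (hits$score[jj] == score[i] && hits$identity[jj] > ident[i])
        if (better) {
          score[i] <- hits$score[jj]; ident[i] <- hits$identity[jj]
          refid[i] <- refset$ref_id[ri]
          best_amp[i] <<- refset$amplicon[ri]
          best_via[i] <<- via
        }
      }
    }
  }
  try_refs(progenitor_refs, "progenitor", seq_along(contigs))
  unresolved <- which(is.na(best_amp))
  try_refs(fallback_templates, "fallback", unresolved)
  for (i in seq_along(contigs)) {
    contigs[[i]]$amplicon_id <- if (is.na(best_amp[i])) "UNATTRIBUTED" else best_amp[i]
    contigs[[i]]$attributed_via <- best_via[i]
  }
  contigs
}

#' Flatten a contig list to a data frame
#'
#' @param contigs list of contigs.
#' @return data.frame: `contig_id`, `genotype_id`, `amplicon_id`, `length`,
#'   `n_reads`, `consensus`.
#' @export
contig_table <- function(contigs) {
  if (!length(contigs)) {
    return(data.frame(contig_id = character(), genotype_id = character(),
                      amplicon_id = character(), length = integer(),
                      n_reads = integer(), consensus = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(contigs, function(cl) {
    data.frame(contig_id = cl$contig_id %||% NA_character_,
               genotype_id = cl$genotype_id %||% NA_character_,
               amplicon_id = cl$amplicon_id %||% "UNATTRIBUTED",
               length = nchar(cl$consensus),
               n_reads = length(cl$member_read_ids),
               consensus = cl$consensus, stringsAsFactors = FALSE)
  }))
}

#' Reference-assembly summary statistics
#'
#' Mirrors the headline descriptors of a stringent reference assembly:
#' contig count, mean length, mean reads per contig, mean contigs per
#' attributed amplicon, mean HSVs per amplicon, and the HSV frequency
#' expressed as "1 HSV every N bp" with `N = floor(aligned bp / HSV count)`.
#'
#' @param contigs attributed contig list.
#' @param hsv result of [detect_hsvs()] (or `NULL` when not yet computed).
#' @return one-row data.frame of summary statistics (plus the formatted
#'   `hsv_frequency` string, `"none"` when no HSVs were found).
#' @export
assembly_summary <- function(contigs, hsv = NULL) {
  tab <- contig_table(contigs)
  attributed <- tab[tab$amplicon_id != "UNATTRIBUTED", , drop = FALSE]
  n_amp <- length(unique(attributed$amplicon_id))
  n_hsv <- if (is.null(hsv)) 0L else hsv$n_events
  aligned_bp <- if (is.null(hsv)) 0L else hsv$aligned_bp
  data.frame(
    n_contigs = nrow(tab),
    mean_contig_length = if (nrow(tab)) mean(tab$length) else 0,
    mean_reads_per_contig = if (nrow(tab)) mean(tab$n_reads) else 0,
    contigs_per_amplicon = if (n_amp) nrow(attributed) / n_amp else 0,
    hsvs_per_amplicon = if (n_amp) n_hsv / n_amp else 0,
    hsv_every_bp = if (n_hsv > 0) floor(aligned_bp / n_hsv) else NA_integer_,
    hsv_frequency = if (n_hsv > 0)
      sprintf("1 HSV every %d bp", floor(aligned_bp / n_hsv)) else "none",
    stringsAsFactors = FALSE)
}
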