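#' Alignment scoring scheme
#'
#' BLASTN-like defaults; all values configurable. Gap penalties are given as
#' positive costs.
#'
#' @param match match score (default +2).
#' @param mismatch mismatch score (default -3).
#' @param gap_open gap opening cost (default 5).
#' @param gap_extend gap extension cost (default 2).
#' @return list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5,
                          gap_extend = 2) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_scoring")
}

#' Read-mapping parameter set
#'
#' Defaults mirror the genotype-mapping stage of the discovery pipeline:
#' at least 50 bp overlap at 80% identity. `strict_gt` switches the overlap
#' and identity comparisons from inclusive (>=) to strict (>), covering the
#' boundary reading of "greater than 50 bp overlap".
#'
#' @param min_overlap minimum aligned columns.
#' @param min_identity minimum identity (matches / aligned columns, gaps
#'   counted as columns), in (0, 1].
#' @param strict_gt use strict inequalities at the thresholds.
#' @param scoring an [align_scoring()] object.
#' @return list of class `mapping_params`.
#' @export
mapping_params <- function(min_overlap = 50L, min_identity = 0.80,
                           strict_gt = FALSE, scoring = align_scoring()) {
  if (min_overlap < 1L) stop_invalid("min_overlap must be >= 1")
  if (min_identity <= 0 || min_identity > 1) {
    stop_invalid("min_identity must be in (0, 1]")
  }
  structure(list(min_overlap = as.integer(min_overlap),
                 min_identity = min_identity, strict_gt = isTRUE(strict_gt),
                 scoring = scoring), class = "mapping_params")
}

subst_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = FALSE)
}

## Vectorised alignment of many queries against one target.
## type: "local" or "overlap" (ends-free global).
## Returns a data.frame with score/identity/overlap/spans plus the gapped
## aligned strings (the edit path).
batch_align <- function(queries, target, scoring = align_scoring(),
                        type = "local") {
  if (!length(queries)) {
    return(data.frame(score = numeric(), identity = numeric(),
                      overlap = integer(), query_start = integer(),
                      query_end = integer(), target_start = integer(),
                      target_end = integer(), aligned_query = character(),
                      aligned_target = character(), stringsAsFactors = FALSE))
  }
  pat <- Biostrings::DNAStringSet(queries)
  aln <- Biostrings::pairwiseAlignment(
    pat, Biostrings::DNAString(target), type = type,
    substitutionMatrix = subst_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  ap <- as.character(p)
  at <- as.character(s)
  nm <- Biostrings::nmatch(aln)
  cols <- nchar(ap)
  data.frame(score = Biostrings::score(aln),
             identity = ifelse(cols > 0, nm / cols, 0),
             overlap = cols,
             query_start = BiocGenerics::start(p),
             query_end = BiocGenerics::end(p),
             target_start = BiocGenerics::start(s),
             target_end = BiocGenerics::end(s),
             aligned_query = unname(ap), aligned_target = unname(at),
             stringsAsFactors = FALSE)
}

#' Optimal pairwise local alignment under affine-gap scoring
#'
#' Smith-Waterman alignment via [Biostrings::pairwiseAlignment()]. Identity
#' is defined as matches divided by aligned columns (gap columns included);
#' overlap is the number of aligned columns. When `both_strands` is set the
#' reverse complement of `a` is also tried and the better placement is
#' reported with its strand.
#'
#' @param a,b non-empty DNA strings (query and target).
#' @param scoring an [align_scoring()] object.
#' @param both_strands also consider the reverse complement of `a`.
#' @return a list of class `alignment_result` with fields `score`,
#'   `identity`, `overlap`, `strand`, `query_span`/`target_span` (1-based
#'   inclusive), `aligned_query`/`aligned_target`, or `NULL` when no
#'   positive-scoring local alignment exists.
#' @export
local_align <- function(a, b, scoring = align_scoring(),
                        both_strands = FALSE) {
  if (!nzchar(a) || !nzchar(b)) stop_invalid("empty sequence")
  fwd <- batch_align(a, b, scoring, "local")
  best <- cbind(fwd, strand = "+", stringsAsFactors = FALSE)
  if (both_strands) {
    rev <- cbind(batch_align(revcomp(a), b, scoring, "local"),
                 strand = "-", stringsAsFactors = FALSE)
    if (rev$score[1] > best$score[1]) best <- rev
  }
  if (best$score[1] <= 0) return(NULL)
  structure(list(score = best$score[1], identity = best$identity[1],
                 overlap = best$overlap[1], strand = best$strand[1],
                 query_span = c(best$query_start[1], best$query_end[1]),
                 target_span = c(best$target_start[1], best$target_end[1]),
                 aligned_query = best$aligned_query[1],
                 aligned_target = best$aligned_target[1]),
            class = "alignment_result")
}

passes_thresholds <- function(overlap, identity, params) {
  if (params$strict_gt) {
    overlap > params$min_overlap & identity > params$min_identity
  } else {
    overlap >= params$min_overlap & identity >= params$min_identity
  }
}

#' Map a read against a set of reference sequences
#'
#' The read is aligned locally against every reference (both strands when
#' requested); placements failing the overlap/identity thresholds are
#' discarded and the highest-scoring survivor is returned. Ties are broken by
#' higher identity, then by lexicographically smaller reference id, so the
#' result does not depend on reference order.
#'
#' @param read a DNA string.
#' @param references named character vector of reference sequences.
#' @param params a [mapping_params()] object (defaults: 50 bp / 0.80).
#' @param both_strands also try the reverse complement of the read.
#' @return list with `reference`, `strand`, `score`, `identity`, `overlap`,
#'   `target_span`, `aligned_query`, `aligned_target`, or `NULL` when
#'   unmapped.
#' @export
map_read <- function(read, references, params = mapping_params(),
                     both_strands = FALSE) {
  if (!length(references)) stop_invalid("references must be non-empty")
  ids <- names(references) %||% as.character(seq_along(references))
  cand <- NULL
  for (ref_i in order(ids)) {
    strands <- if (both_strands) c("+", "-") else "+"
    for (st in strands) {
      q <- if (st == "+") read else revcomp(read)
      hit <- batch_align(q, references[[ref_i]], params$scoring, "local")
      if (!passes_thresholds(hit$overlap[1], hit$identity[1], params)) next
      better <- is.null(cand) ||
        hit$score[1] > cand$score ||
        (hit$score[1] == cand$score && hit$identity[1] > cand$identity)
      if (better) {
        cand <- list(reference = ids[ref_i], strand = st,
                     score = hit$score[1], identity = hit$identity[1],
                     overlap = hit$overlap[1],
                     target_span = c(hit$target_start[1], hit$target_end[1]),
                     aligned_query = hit$aligned_query[1],
                     aligned_target = hit$aligned_target[1])
      }
    }
  }
  cand
}

#' Karlin-Altschul constants for the approximate e-value
#'
#' The amplicon-assignment step scores reads against template sequences and
#' converts the best local score to an approximate expectation value
#' `E = K * m * n * exp(-lambda * S)` (m: total template length, n: query
#' length). The constants are configuration, calibrated for the default
#' +2/-3 scoring so that genuine amplicon matches fall far below the 0.001
#' threshold and chance similarities far above it.
#'
#' @param lambda scale parameter.
#' @param K search-space constant.
#' @return list of class `evalue_params`.
#' @export
evalue_params <- function(lambda = 0.5, K = 0.3) {
  structure(list(lambda = lambda, K = K), class = "evalue_params")
}

approx_evalue <- function(score, m, n, ev = evalue_params()) {
  ev$K * m * n * exp(-ev$lambda * score)
}

## build a k-mer index over templates (both strands); used as a seeding
## prescreen so that only plausible templates are verified by alignment
kmer_index <- function(templates, k = 12L) {
  ids <- names(templates)
  km <- list(); tid <- list(); strand <- list()
  for (i in seq_along(templates)) {
    for (st in c("+", "-")) {
      s <- if (st == "+") templates[[i]] else revcomp(templates[[i]])
      n <- nchar(s)
      if (n < k) next
      kk <- substring(s, 1:(n - k + 1L), k:n)
      km[[length(km) + 1L]] <- kk
      tid[[length(tid) + 1L]] <- rep(i, length(kk))
      strand[[length(strand) + 1L]] <- rep(st, length(kk))
    }
  }
  df <- data.frame(kmer = unlist(km), template = unlist(tid),
                   strand = unlist(strand), stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("kmer", "template", "strand")]), ]
  list(k = k, table = df, ids = ids)
}

## most plausible (template, strand) for one read by shared k-mer count;
## returns NULL when nothing is shared
kmer_candidates <- function(read, index) {
  n <- nchar(read)
  k <- index$k
  if (n < k) return(NULL)
  kk <- unique(substring(read, 1:(n - k + 1L), k:n))
  hits <- index$table[index$table$kmer %in% kk, ]
  if (!nrow(hits)) return(NULL)
  agg <- stats::aggregate(kmer ~ template + strand, data = hits, FUN = length)
  agg[order(-agg$kmer, index$ids[agg$template], agg$strand), ][1, , drop = FALSE]
}

#' Assign a read to its amplicon template
#'
#' The read is aligned against every template and assigned to the
#' best-scoring one whose approximate e-value is at or below `max_evalue`.
#' Score ties go to the lexicographically smaller template id.
#'
#' @param read a DNA string.
#' @param templates named character vector of template sequences.
#' @param max_evalue expectation-value threshold (default 0.001).
#' @param scoring an [align_scoring()] object.
#' @param ev an [evalue_params()] object.
#' @param both_strands also try the reverse complement of the read.
#' @return list with `template`, `strand`, `score`, `evalue`, or `NULL` when
#'   unassigned.
#' @export
assign_to_template <- function(read, templates, max_evalue = 0.001,
                               scoring = align_scoring(),
                               ev = evalue_params(), both_strands = FALSE) {
  if (!length(templates)) stop_invalid("template set must be non-empty")
  ids <- names(templates) %||% as.character(seq_along(templates))
  m <- sum(nchar(templates))
  best <- NULL
  for (i in order(ids)) {
    strands <- if (both_strands) c("+", "-") else "+"
    for (st in strands) {
      q <- if (st == "+") read else revcomp(read)
      hit <- batch_align(q, templates[[i]], scoring, "local")
      if (is.null(best) || hit$score[1] > best$score) {
        best <- list(template = ids[i], strand = st, score = hit$score[1])
      }
    }
  }
  e <- approx_evalue(best$score, m, nchar(read), ev)
  if (e > max_evalue) return(NULL)
  c(best, list(evalue = e))
}

## fast batch template assignment: k-mer prescreen, then one vectorised
## alignment per (template, strand) group to verify and compute e-values
assign_templates_batch <- function(reads, templates, max_evalue = 0.001,
                                   scoring = align_scoring(),
                                   ev = evalue_params(), k = 12L) {
  ids <- names(templates)
  index <- kmer_index(templates, k)
  n <- length(reads)
  cand_t <- integer(n); cand_s <- character(n)
  for (i in seq_len(n)) {
    cc <- kmer_candidates(reads[i], index)
    if (is.null(cc)) { cand_t[i] <- NA_integer_; cand_s[i] <- NA_character_ }
    else { cand_t[i] <- cc$template; cand_s[i] <- cc$strand }
  }
  m <- sum(nchar(templates))
  out <- data.frame(template = rep(NA_character_, n),
                    strand = rep(NA_character_, n),
                    score = rep(NA_real_, n), evalue = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  for (ti in unique(cand_t[!is.na(cand_t)])) {
    for (st in c("+", "-")) {
      w <- which(!is.na(cand_t) & cand_t == ti & cand_s == st)
      if (!length(w)) next
      q <- if (st == "+") reads[w] else revcomp(reads[w])
      hits <- batch_align(q, templates[[ti]], scoring, "local")
      e <- approx_evalue(hits$score, m, nchar(reads[w]), ev)
      keep <- e <= max_evalue
      out$template[w[keep]] <- ids[ti]
      out$strand[w[keep]] <- st
      out$score[w[keep]] <- hits$score[keep]
      out$evalue[w[keep]] <- e[keep]
    }
  }
  out
}

#' Per-genotype amplicon coverage summary
#'
#' Reports, for each genotype, how many (and what percentage of) templates
#' received at least one assigned read, and the mean number of assigned reads
#' per covered template. Genotypes with no assigned reads are reported with
#' zero coverage and flagged.
#'
#' @param assignments data.frame with `genotype_id` and `template` (NA for
#'   unassigned reads).
#' @param templates named character vector (or character vector of ids) of
#'   all templates.
#' @param genotypes character vector of genotype ids to report (defaults to
#'   those present in `assignments`).
#' @return data.frame: `genotype_id`, `templates_covered`, `pct_covered`,
#'   `mean_reads_per_template`, `no_reads` flag.
#' @export
coverage_summary <- function(assignments, templates,
                             genotypes = unique(assignments$genotype_id)) {
  tot <- length(templates)
  ids <- names(templates) %||% as.character(templates)
  rows <- lapply(sort(genotypes), function(g) {
    a <- assignments[assignments$genotype_id == g & !is.na(assignments$template), ]
    cov <- unique(a$template)
    nc <- length(cov)
    data.frame(genotype_id = g, templates_covered = nc,
               pct_covered = 100 * nc / tot,
               mean_reads_per_template = if (nc) nrow(a) / nc else 0,
               no_reads = nc == 0L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
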