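#' Stack sequences onto a common reference frame
#'
#' Each sequence is aligned (ends-free) to the reference and projected onto
#' the reference's coordinates: deletions become `-`, insertions relative to
#' the reference are dropped, positions outside the aligned span are padded
#' with `-`. The result is a set of equal-length rows suitable for
#' [trim_to_common_span()] and [distance_matrix()].
#'
#' @param seqs named character vector of sequences.
#' @param reference frame sequence.
#' @param scoring an [align_scoring()] object.
#' @return named character vector of gapped sequences, all of
#'   `nchar(reference)` columns.
#' @export
stack_on_reference <- function(seqs, reference, scoring = align_scoring()) {
  L <- nchar(reference)
  out <- vapply(seqs, function(s) {
    hit <- batch_align(s, reference, scoring, "overlap")
    w <- walk_alignment(hit$aligned_query[1], hit$aligned_target[1],
                        hit$target_start[1])
    chars <- rep("-", L)
    chars[w$pile$pos] <- w$pile$base
    paste(chars, collapse = "")
  }, character(1))
  names(out) <- names(seqs)
  out
}

#' Trim aligned sequences to their common covered span
#'
#' Returns only the columns covered by every taxon, i.e. columns between
#' each taxon's first and last non-gap position — the "make each read equal
#' length" trimming applied before tree construction. Leading and trailing
#' overhangs are removed; internal gap columns are retained.
#'
#' @param aligned named character vector of equal-length gapped sequences
#'   (>= 2 taxa).
#' @return list of class `aligned_block` with `taxa`, `seqs` (trimmed,
#'   equal length), `n_col` and `span` (the retained column window of the
#'   input frame).
#' @export
trim_to_common_span <- function(aligned) {
  if (length(aligned) < 2L) stop_invalid("need >= 2 taxa")
  lens <- unique(nchar(aligned))
  if (length(lens) != 1L) stop_invalid("sequences must be pre-aligned to equal length")
  spans <- vapply(aligned, function(s) {
    ch <- seq_chars(s)
    w <- which(ch != "-")
    if (!length(w)) c(NA_integer_, NA_integer_) else range(w)
  }, integer(2))
  if (anyNA(spans)) stop_invalid("a taxon has no aligned positions")
  lo <- max(spans[1, ]); hi <- min(spans[2, ])
  if (lo > hi) stop_invalid("empty common span")
  structure(list(taxa = names(aligned),
                 seqs = substr(aligned, lo, hi),
                 n_col = hi - lo + 1L, span = c(lo, hi)),
            class = "aligned_block")
}

#' Pairwise nucleotide distance matrix
#'
#' Distances are computed over pairwise comparable sites (both bases in
#' A/C/G/T; gap and ambiguous columns are excluded per pair). Models:
#' `p` (raw proportion of differing sites), `JC69`
#' (`-(3/4) ln(1 - 4p/3)`), and `K2P` (Kimura two-parameter from transition
#' and transversion proportions).
#'
#' @param block an `aligned_block` from [trim_to_common_span()], or a named
#'   character vector of equal-length sequences.
#' @param model one of `"p"`, `"JC69"`, `"K2P"`.
#' @return symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
distance_matrix <- function(block, model = c("p", "JC69", "K2P")) {
  model <- match.arg(model)
  if (inherits(block, "aligned_block")) {
    seqs <- block$seqs; taxa <- block$taxa
  } else {
    seqs <- block; taxa <- names(block)
  }
  n <- length(seqs)
  chars <- lapply(seqs, seq_chars)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- chars[[i]]; b <- chars[[j]]
      ok <- a %in% DNA_BASES & b %in% DNA_BASES
      m <- sum(ok)
      if (m < 1L) stop_invalid("no comparable sites between %s and %s",
                               taxa[i], taxa[j])
      diff <- ok & a != b
      p <- sum(diff) / m
      d <- switch(model,
        p = p,
        JC69 = {
          if (p >= 0.75) stop_invalid("JC69 undefined for p >= 3/4 (p = %.3f)", p)
          -0.75 * log(1 - 4 * p / 3)
        },
        K2P = {
          ts <- sum(diff & purine[a] == purine[b]) / m  # transitions
          tv <- p - ts                                  # transversions
          arg1 <- 1 - 2 * ts - tv; arg2 <- 1 - 2 * tv
          if (arg1 <= 0 || arg2 <= 0) {
            stop_invalid("K2P undefined for these proportions")
          }
          -0.5 * log(arg1) - 0.25 * log(arg2)
        })
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration under the standard Q-criterion, with ties broken
#' by the lowest index pair. Negative branch-length estimates are clamped to
#' zero; whether any were clamped is recorded in the returned tree's
#' `negative_branches` attribute. For two taxa a single edge of the input
#' distance is returned (split evenly across the internal node).
#'
#' @param D symmetric numeric distance matrix with zero diagonal (taxa in
#'   dimnames).
#' @return an unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(D) {
  if (!isSymmetric(unname(as.matrix(D)))) stop_invalid("matrix must be symmetric")
  if (any(!is.finite(D))) stop_invalid("distance matrix has non-finite entries")
  D <- as.matrix(D)
  taxa <- rownames(D)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 2L) stop_invalid("need >= 2 taxa")
  clamped <- FALSE
  bl <- function(x) { if (x < 0) clamped <<- TRUE; format(max(0, x), digits = 12) }
  lab <- taxa
  if (n == 2L) {
    txt <- sprintf("(%s:%s,%s:%s);", lab[1], bl(D[1, 2] / 2),
                   lab[2], bl(D[1, 2] / 2))
  } else {
    while (n > 3L) {
      r <- rowSums(D)
      Q <- (n - 2) * D - outer(r, r, `+`)
      diag(Q) <- Inf
      ## lowest-index pair among Q minima (row-major, i < j)
      idx <- which(Q == min(Q), arr.ind = TRUE)
      idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      i <- idx[1, 1]; j <- idx[1, 2]
      li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
      lj <- D[i, j] - li
      newlab <- sprintf("(%s:%s,%s:%s)", lab[i], bl(li), lab[j], bl(lj))
      dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
      keep <- setdiff(seq_len(n), c(i, j))
      D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                  c(dnew[keep], 0))
      lab <- c(lab[keep], newlab)
      dimnames(D2) <- NULL
      D <- D2
      n <- n - 1L
    }
    v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    txt <- sprintf("(%s:%s,%s:%s,%s:%s);", lab[1], bl(v1), lab[2], bl(v2),
                   lab[3], bl(v3))
  }
  tree <- ape::read.tree(text = txt)
  attr(tree, "negative_branches") <- clamped
  tree
}

## is tip `a` a sister leaf of tip `b` (they form a cherry)?
is_sister_leaf <- function(tree, a, b) {
  ta <- match(a, tree$tip.label); tb <- match(b, tree$tip.label)
  pa <- tree$edge[tree$edge[, 2] == ta, 1]
  pb <- tree$edge[tree$edge[, 2] == tb, 1]
  length(pa) == 1L && length(pb) == 1L && pa == pb
}

#' Attribute a haplotype to a progenitor sub-genome from an NJ tree
#'
#' The patristic distance from the query leaf to the nearest progenitor leaf
#' of each class (`P`: the diploid progenitor; `G`: the tetraploid
#' progenitor haplotypes) is computed; the closer class is assigned when its
#' distance undercuts the other by the relative `margin` (default 10%),
#' otherwise the call is `AMBIGUOUS`. When only one progenitor class is in
#' the tree, it is assigned only if the query is its direct sister leaf.
#'
#' @param tree a `phylo` tree containing the query and progenitor leaves.
#' @param query query leaf label.
#' @param progenitor_labels list with character vectors `P` and `G` of leaf
#'   labels (either may be empty, not both).
#' @param margin relative margin in `[0, 1)`.
#' @param abs_margin minimum absolute distance separation (substitutions per
#'   site) below which no attribution is attempted; amplicons whose
#'   sub-genomes have barely diverged carry no attribution signal, and a
#'   relative margin alone cannot guard against them.
#' @return list of class `subgenome_assignment`: `haplotype`, `assignment`
#'   (`"P"`, `"G"` or `"AMBIGUOUS"`), `d_P`, `d_G`, `margin`.
#' @export
assign_subgenome <- function(tree, query, progenitor_labels, margin = 0.10,
                             abs_margin = 0.005) {
  if (!(query %in% tree$tip.label)) stop_invalid("query '%s' not in tree", query)
  if (margin < 0) stop_invalid("margin must be >= 0")
  pd <- ape::cophenetic.phylo(tree)
  pl <- intersect(progenitor_labels$P %||% character(0), tree$tip.label)
  gl <- intersect(progenitor_labels$G %||% character(0), tree$tip.label)
  if (!length(pl) && !length(gl)) stop_invalid("no progenitor leaf in tree")
  d_P <- if (length(pl)) min(pd[query, pl]) else NA_real_
  d_G <- if (length(gl)) min(pd[query, gl]) else NA_real_
  assignment <- "AMBIGUOUS"
  if (length(pl) && length(gl)) {
    if (abs(d_P - d_G) > abs_margin) {
      if (d_P <= (1 - margin) * d_G) assignment <- "P"
      else if (d_G <= (1 - margin) * d_P) assignment <- "G"
    }
  } else if (length(pl)) {
    nearest <- pl[which.min(pd[query, pl])]
    if (is_sister_leaf(tree, query, nearest)) assignment <- "P"
  } else {
    nearest <- gl[which.min(pd[query, gl])]
    if (is_sister_leaf(tree, query, nearest)) assignment <- "G"
  }
  structure(list(haplotype = query, assignment = assignment,
                 d_P = d_P, d_G = d_G, margin = margin),
            class = "subgenome_assignment")
}

#' Sub-genome attribution of haplotype consensuses for one amplicon
#'
#' Builds the NJ tree of the query haplotype consensuses together with the
#' progenitor ortholog sequences (all stacked on a common reference frame
#' and trimmed to the common span) and assigns each query to `P`, `G` or
#' `AMBIGUOUS`.
#'
#' @param haplotypes named character vector of query consensus sequences.
#' @param progenitors named character vector of progenitor ortholog
#'   sequences.
#' @param p_labels,g_labels names in `progenitors` belonging to each class.
#' @param reference frame sequence for stacking (defaults to the first
#'   progenitor).
#' @param model distance model (see [distance_matrix()]).
#' @param margin relative margin for [assign_subgenome()].
#' @return list with `tree` (phylo) and `assignments` (data.frame:
#'   `haplotype`, `assignment`, `d_P`, `d_G`).
#' @export
attribute_haplotypes <- function(haplotypes, progenitors, p_labels, g_labels,
                                 reference = NULL, model = "JC69",
                                 margin = 0.10) {
  seqs <- c(haplotypes, progenitors)
  reference <- reference %||% progenitors[[1]]
  stacked <- stack_on_reference(seqs, reference)
  block <- trim_to_common_span(stacked)
  D <- distance_matrix(block, model)
  tree <- nj_tree(D)
  rows <- lapply(names(haplotypes), function(h) {
    a <- assign_subgenome(tree, h, list(P = p_labels, G = g_labels), margin)
    data.frame(haplotype = h, assignment = a$assignment,
               d_P = a$d_P, d_G = a$d_G, stringsAsFactors = FALSE)
  })
  list(tree = tree, assignments = do.call(rbind, rows))
}
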