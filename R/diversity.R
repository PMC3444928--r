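#' Binary allele-presence encoding of genotype calls
#'
#' Each SNP locus contributes one column per allele observed anywhere in the
#' panel; a genotype scores 1 where its call contains the allele, 0 where it
#' does not, and NA throughout the locus where its call is missing.
#'
#' @param calls data.frame with `sample_id` (or `genotype_id`), `locus_id`,
#'   `class` (allele/dosage string such as `"AB"` or `"ABAAAA"`; NA =
#'   missing).
#' @return numeric matrix (genotypes x allele columns, entries 0/1/NA),
#'   columns named `<locus>.<allele>`.
#' @export
binary_encode <- function(calls) {
  id_col <- if ("sample_id" %in% names(calls)) "sample_id" else "genotype_id"
  samples <- sort(unique(calls[[id_col]]))
  loci <- sort(unique(calls$locus_id))
  cols <- list()
  for (l in loci) {
    sub <- calls[calls$locus_id == l, , drop = FALSE]
    alleles <- sort(unique(unlist(strsplit(sub$class[!is.na(sub$class)], ""))))
    for (a in alleles) {
      v <- rep(NA_real_, length(samples))
      names(v) <- samples
      for (i in seq_len(nrow(sub))) {
        s <- sub[[id_col]][i]
        if (!is.na(sub$class[i])) {
          v[s] <- as.numeric(grepl(a, sub$class[i], fixed = TRUE))
        }
      }
      cols[[paste(l, a, sep = ".")]] <- v
    }
  }
  do.call(cbind, cols)
}

#' Dice similarity matrix over binary allele scores
#'
#' For each pair of genotypes, `D = 2a / (2a + b + c)` over the columns
#' scored in both (pairwise deletion of missing data), where `a` counts
#' shared presences and `b`, `c` the presences unique to each genotype.
#' Pairs with no mutually scored column are set to NA and flagged.
#'
#' @param mat binary matrix from [binary_encode()].
#' @return symmetric similarity matrix in `[0, 1]`, unit diagonal; the
#'   `"undefined_pairs"` attribute lists pairs without comparable columns.
#' @export
dice_matrix <- function(mat) {
  n <- nrow(mat)
  if (n < 2L) stop_invalid("need >= 2 genotypes")
  ids <- rownames(mat) %||% as.character(seq_len(n))
  S <- matrix(1, n, n, dimnames = list(ids, ids))
  undef <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      if (!any(ok)) {
        S[i, j] <- S[j, i] <- NA_real_
        undef[[length(undef) + 1L]] <- c(ids[i], ids[j])
        next
      }
      a <- sum(mat[i, ok] == 1 & mat[j, ok] == 1)
      b <- sum(mat[i, ok] == 1 & mat[j, ok] == 0)
      cc <- sum(mat[i, ok] == 0 & mat[j, ok] == 1)
      S[i, j] <- S[j, i] <- if (2 * a + b + cc == 0) 0 else
        2 * a / (2 * a + b + cc)
    }
  }
  attr(S, "undefined_pairs") <- undef
  S
}

#' UPGMA phenogram from a dissimilarity matrix
#'
#' Unweighted pair-group agglomeration with arithmetic averaging: the
#' closest pair of clusters is merged at height `d/2` (so leaf-to-root path
#' lengths are equal — the tree is ultrametric) and inter-cluster distances
#' are updated as size-weighted averages. Ties are broken by the
#' lexicographically smallest cluster pair.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal (typically
#'   `1 - dice_matrix(...)`).
#' @return a rooted ultrametric `phylo` tree with merge heights recorded in
#'   the `"merge_heights"` attribute.
#' @export
upgma <- function(D) {
  D <- as.matrix(D)
  if (any(is.na(D))) stop_invalid("dissimilarity matrix has NA entries")
  n <- nrow(D)
  ids <- rownames(D) %||% paste0("t", seq_len(n))
  if (n < 2L) stop_invalid("need >= 2 taxa")
  ## active clusters: newick label, size, height, lexicographic key
  lab <- ids; size <- rep(1L, n); height <- rep(0, n); keys <- ids
  heights_out <- numeric(0)
  while (n > 1L) {
    dmin <- Inf; pick <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        key <- sort(c(keys[i], keys[j]))
        if (D[i, j] < dmin ||
            (D[i, j] == dmin &&
             (key[1] < pick$key[1] ||
              (key[1] == pick$key[1] && key[2] < pick$key[2])))) {
          dmin <- D[i, j]
          pick <- list(i = i, j = j, key = key)
        }
      }
    }
    i <- pick$i; j <- pick$j
    h <- dmin / 2
    heights_out <- c(heights_out, h)
    newlab <- sprintf("(%s:%s,%s:%s)", lab[i], format(h - height[i], digits = 12),
                      lab[j], format(h - height[j], digits = 12))
    dnew <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    dimnames(D) <- NULL
    lab <- c(lab[keep], newlab)
    size <- c(size[keep], size[pick$i] + size[pick$j])
    height <- c(height[keep], h)
    keys <- c(keys[keep], pick$key[1])
    n <- n - 1L
  }
  tree <- ape::read.tree(text = paste0(lab[1], ";"))
  attr(tree, "merge_heights") <- heights_out
  tree
}
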