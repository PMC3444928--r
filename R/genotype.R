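#' Dosage-based co-dominant genotype calling for one locus
#'
#' Samples are assigned to the nearest expected theta centre of the
#' scenario. With a single amplified sub-genome the centres are
#' `{0, 1/2, 1}` (the diploid-like 1:0 / 0:1 homozygote ratios); with all
#' three sub-genomes amplified and one polymorphic they are `{0, 1/6, 2/6}`
#' (skewed ratios: each B copy contributes one sixth of the signal); with
#' two polymorphic sub-genomes, `{0, 1/6, 2/6, 3/6, 4/6}`. Centres carry
#' dosage meaning, so they are fixed a priori rather than fit freely;
#' optionally one refinement round replaces each occupied centre by its
#' cluster mean before the final assignment (absorbing per-locus channel
#' bias).
#'
#' @param thetas data.frame with `sample_id` and `theta` (B-allele signal
#'   fraction in `[0, 1]`), or a named numeric vector.
#' @param scenario see [scenario_classes()].
#' @param refit run one round of per-cluster mean refitting.
#' @return data.frame: `sample_id`, `class` (dosage string), `b_copies`,
#'   `cluster` (centre index), `residual`; fitted centres in the
#'   `"centres"` attribute.
#' @export
call_dosage <- function(thetas, scenario, refit = FALSE) {
  if (is.numeric(thetas)) {
    thetas <- data.frame(sample_id = names(thetas) %||%
                           as.character(seq_along(thetas)),
                         theta = unname(thetas), stringsAsFactors = FALSE)
  }
  if (!nrow(thetas)) stop_invalid("empty locus")
  cls <- scenario_classes(scenario)
  centres <- cls$b_copies / cls$total_copies[1]
  assign_idx <- function(x, ctr) {
    vapply(x, function(t) which.min(abs(t - ctr)), integer(1))
  }
  idx <- assign_idx(thetas$theta, centres)
  if (refit) {
    fitted <- centres
    for (k in seq_along(centres)) {
      w <- idx == k
      if (any(w)) fitted[k] <- mean(thetas$theta[w])
    }
    idx <- assign_idx(thetas$theta, fitted)
    centres <- fitted
  }
  data.frame(sample_id = thetas$sample_id, class = cls$class[idx],
             b_copies = cls$b_copies[idx], cluster = idx,
             residual = abs(thetas$theta - centres[idx]),
             stringsAsFactors = FALSE) -> out
  attr(out, "centres") <- centres
  out
}

LOCUS_CATEGORIES <- c("THREE_CLUSTER_SINGLE_SUBGENOME",
                      "THREE_CLUSTER_ALL_SUBGENOMES", "TWO_CLUSTER",
                      "FIVE_CLUSTER", "DISPERSED", "MONOMORPHIC", "FAILED")

## mean silhouette-like separation of thetas under a centre set
separation_score <- function(theta, centres, idx) {
  if (length(centres) < 2L) return(0)
  s <- vapply(seq_along(theta), function(i) {
    d <- abs(theta[i] - centres)
    d1 <- d[idx[i]]
    d2 <- min(d[-idx[i]])
    if (max(d1, d2) == 0) 1 else (d2 - d1) / max(d1, d2)
  }, numeric(1))
  mean(s)
}

#' Classify the clustering behaviour of one genotyped locus
#'
#' Each candidate scenario is scored by how cleanly the panel's thetas
#' separate around its expected centres (a silhouette-like score). The locus
#' is `FAILED` when too much intensity data is missing, `MONOMORPHIC` when
#' only one centre is occupied, `DISPERSED` when even the best scenario
#' separates poorly (a broad spectrum of intensity ratios), and otherwise
#' categorised by the winning scenario and its number of occupied centres.
#'
#' @param thetas numeric vector of theta values (NA = missing) for the
#'   panel at one locus.
#' @param min_samples minimum non-missing samples.
#' @param min_cluster_size members needed for a centre to count as occupied.
#' @param dispersed_threshold separation score below which the locus is
#'   classed dispersed.
#' @param max_missing maximum tolerated missing fraction before `FAILED`.
#' @return list of class `locus_pattern`: `category`, `scenario`,
#'   `occupied`, `separation`.
#' @export
classify_locus_pattern <- function(thetas, min_samples = 4L,
                                   min_cluster_size = 2L,
                                   dispersed_threshold = 0.70,
                                   max_missing = 0.5) {
  n <- length(thetas)
  miss <- mean(is.na(thetas))
  x <- thetas[!is.na(thetas)]
  if (miss > max_missing || length(x) < min_samples) {
    return(structure(list(category = "FAILED", scenario = NA_character_,
                          occupied = NA_integer_, separation = NA_real_),
                     class = "locus_pattern"))
  }
  scens <- c("single_subgenome", "all_one_poly", "all_two_poly")
  best <- NULL
  for (sc in scens) {
    cls <- scenario_classes(sc)
    centres <- cls$b_copies / cls$total_copies[1]
    idx <- vapply(x, function(t) which.min(abs(t - centres)), integer(1))
    occ <- sum(tabulate(idx, length(centres)) >= min_cluster_size)
    sep <- separation_score(x, centres, idx)
    if (is.null(best) || sep > best$sep) {
      best <- list(scenario = sc, occ = occ, sep = sep)
    }
  }
  category <- if (best$occ <= 1L) "MONOMORPHIC"
    else if (best$sep < dispersed_threshold) "DISPERSED"
    else if (best$occ == 2L) "TWO_CLUSTER"
    else if (best$scenario == "single_subgenome") "THREE_CLUSTER_SINGLE_SUBGENOME"
    else if (best$scenario == "all_one_poly") "THREE_CLUSTER_ALL_SUBGENOMES"
    else if (best$occ >= 5L) "FIVE_CLUSTER"
    else "THREE_CLUSTER_ALL_SUBGENOMES"
  structure(list(category = category, scenario = best$scenario,
                 occupied = best$occ, separation = best$sep),
            class = "locus_pattern")
}

## dosage class string -> set of alleles present
allele_set <- function(class) {
  lapply(strsplit(class, "", fixed = TRUE), function(ch) sort(unique(ch)))
}

#' Cross-assay concordance of allele calls
#'
#' Calls are compared on allele presence: each co-dominant dosage class is
#' collapsed to the set of alleles it detects (so `ABAAAA` and `AB` agree),
#' accommodating the differing co-dominant capacities of the two assay
#' chemistries. Pairs where either side is missing are excluded from both
#' numerator and denominator.
#'
#' @param calls_a,calls_b data.frames with `sample_id`, `locus_id`, `class`
#'   (NA = missing call).
#' @return list with `overall` (percent concordant across all comparable
#'   pairs; NA with `undefined = TRUE` when there are none) and `per_locus`
#'   (data.frame: `locus_id`, `n_compared`, `pct_concordant`).
#' @export
concordance <- function(calls_a, calls_b) {
  m <- merge(calls_a, calls_b, by = c("sample_id", "locus_id"),
             suffixes = c("_a", "_b"))
  ok <- !is.na(m$class_a) & !is.na(m$class_b)
  m <- m[ok, , drop = FALSE]
  if (!nrow(m)) {
    return(list(overall = NA_real_, undefined = TRUE,
                per_locus = data.frame(locus_id = character(),
                                       n_compared = integer(),
                                       pct_concordant = numeric(),
                                       stringsAsFactors = FALSE)))
  }
  agree <- mapply(function(a, b) identical(a, b),
                  allele_set(m$class_a), allele_set(m$class_b))
  per <- do.call(rbind, lapply(sort(unique(m$locus_id)), function(l) {
    w <- m$locus_id == l
    data.frame(locus_id = l, n_compared = sum(w),
               pct_concordant = 100 * mean(agree[w]), stringsAsFactors = FALSE)
  }))
  list(overall = 100 * mean(agree), undefined = FALSE, per_locus = per)
}
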