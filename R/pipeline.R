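#' Default run configuration
#'
#' All stage parameters with the pipeline's defaults: stringent assembly at
#' 97% identity / 100 bp overlap / 5 reads per contig; contig attribution
#' and HSV detection at 80% identity / 10 bp; genotype read mapping at 50 bp
#' / 80%; template assignment at e-value 0.001; variant support 2 reads and
#' 20% of depth; 10 bp contig termini excluded from qualification; JC69
#' distances with a 10% attribution margin.
#'
#' @param simulate list of [sim_config()] arguments (simulate mode), or
#'   `NULL` when `inputs` is given.
#' @param inputs list of input paths (`reads` FASTQ, `barcode_table` TSV
#'   with barcode/genotype_id/morphotype columns, `templates` FASTA with
#'   amplicon ids as record names, `progenitor_refs` FASTA with record
#'   names `<amplicon>|<label>`).
#' @param out_dir output directory.
#' @param seed integer seed for the run.
#' @param ... overrides for individual parameter blocks (`assembly`,
#'   `genotype_mapping`, `attribution`, `hsv`, `support`, `evalue`,
#'   `max_evalue`, `terminal_exclude`, `phylo`, `diagnostics`,
#'   `attribution_trees`, `log_level`).
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL, out_dir = tempfile("polysnp_run_"),
                       seed = 1L, ...) {
  if (is.null(simulate) == is.null(inputs)) {
    stop_invalid("exactly one of 'simulate' or 'inputs' must be given")
  }
  cfg <- list(
    simulate = simulate, inputs = inputs, out_dir = out_dir,
    seed = as.integer(seed),
    assembly = list(min_identity = 0.97, min_overlap = 100L,
                    min_reads_per_contig = 5L, keep_singletons = TRUE,
                    split_conflicts = TRUE),
    genotype_mapping = list(min_overlap = 50L, min_identity = 0.80),
    attribution = list(min_overlap = 10L, min_identity = 0.80),
    hsv = list(min_overlap = 10L, min_identity = 0.80),
    support = list(min_reads = 2L, min_frac = 0.20),
    max_evalue = 0.001,
    terminal_exclude = 10L,
    phylo = list(model = "JC69", margin = 0.10),
    diagnostics = list(min_observed = 2L, min_depth = 2L),
    attribution_trees = TRUE,
    log_level = "info")
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      utils::modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [run_config()]'s arguments.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

log_msg <- function(state, level, fmt, ...) {
  msg <- sprintf("[%s] %s", level, sprintf(fmt, ...))
  if (state$log_level != "quiet") message(msg)
  if (!is.null(state$log_file)) cat(msg, "\n", file = state$log_file,
                                    append = TRUE, sep = "")
}

## stringent reference assembly + attribution for one morphotype panel
assemble_morphotype <- function(morph, reads_by_geno, cfg, prog_refs,
                                fallback, state) {
  genos <- sort(names(reads_by_geno))
  refgeno <- genos[1]
  ap <- assembly_params(min_identity = cfg$assembly$min_identity,
                        min_overlap = cfg$assembly$min_overlap,
                        min_reads_per_contig = cfg$assembly$min_reads_per_contig,
                        keep_singletons = cfg$assembly$keep_singletons,
                        split_conflicts = cfg$assembly$split_conflicts)
  rr <- reads_by_geno[[refgeno]]
  contigs <- list(); unassembled <- character(0)
  for (amp in sort(unique(rr$amplicon[!is.na(rr$amplicon)]))) {
    bin <- rr[!is.na(rr$amplicon) & rr$amplicon == amp, , drop = FALSE]
    seqs <- bin$sequence
    flip <- !is.na(bin$strand) & bin$strand == "-"
    seqs[flip] <- revcomp(seqs[flip])
    res <- cluster_reads(data.frame(read_id = bin$read_id, sequence = seqs,
                                    stringsAsFactors = FALSE), ap)
    for (k in seq_along(res$clusters)) {
      cl <- res$clusters[[k]]
      cl$contig_id <- sprintf("%s_%s_c%02d", refgeno, amp, k)
      cl$genotype_id <- refgeno
      contigs[[length(contigs) + 1L]] <- cl
    }
    unassembled <- c(unassembled, res$unassembled)
  }
  log_msg(state, "info", "%s: reference %s assembled %d contigs (%d reads unassembled)",
          morph, refgeno, length(contigs), length(unassembled))
  att <- mapping_params(min_overlap = cfg$attribution$min_overlap,
                        min_identity = cfg$attribution$min_identity)
  contigs <- attribute_contigs(contigs, prog_refs, fallback, att)
  contigs <- polish_het_columns(contigs, ap)
  list(morphotype = morph, reference_genotype = refgeno, genotypes = genos,
       contigs = contigs, unassembled = unassembled)
}

## per-genotype mapping, variant tabulation and SNP qualification for one
## morphotype panel, given the (within + between) HSV position set
call_morphotype <- function(r, reads_by_geno, hsv_positions, cfg, state) {
  mp <- mapping_params(min_overlap = cfg$genotype_mapping$min_overlap,
                       min_identity = cfg$genotype_mapping$min_identity)
  sp <- support_params(cfg$support$min_reads, cfg$support$min_frac)
  obs_list <- list(); coverage <- list(); raw_list <- list()
  for (g in r$genotypes) {
    mapped <- map_reads_to_contigs(reads_by_geno[[g]], r$contigs, mp)
    ob <- tabulate_variants(mapped, r$contigs, g, sp)
    coverage[[g]] <- attr(ob, "coverage")
    raw_list[[g]] <- attr(ob, "raw_alleles")
    obs_list[[g]] <- ob
  }
  obs <- do.call(rbind, c(obs_list, list(make.row.names = FALSE)))
  raw <- do.call(rbind, c(raw_list, list(make.row.names = FALSE)))
  classified <- qualify_snps(obs, hsv_positions, r$genotypes, r$contigs,
                             cfg$terminal_exclude, coverage = coverage,
                             raw_support = raw)
  log_msg(state, "info", "%s: %d variant groups, %d qualified SNPs",
          r$morphotype, nrow(classified), sum(classified$class == "SNP"))
  c(r, list(observations = obs, coverage = coverage, classified = classified))
}

## contig -> amplicon coordinate maps via alignment against the true
## sub-genome references (simulate mode only)
contig_position_maps <- function(contigs, subg_refs) {
  maps <- list()
  tab <- contig_table(contigs)
  for (i in seq_len(nrow(tab))) {
    amp <- tab$amplicon_id[i]
    if (amp == "UNATTRIBUTED" || is.null(subg_refs[[amp]])) next
    best <- NULL
    for (sg in names(subg_refs[[amp]])) {
      hit <- batch_align(tab$consensus[i], subg_refs[[amp]][[sg]],
                         align_scoring(), "overlap")
      if (is.null(best) || hit$score[1] > best$hit$score[1]) {
        best <- list(sg = sg, hit = hit)
      }
    }
    qc <- seq_chars(best$hit$aligned_query[1])
    tc <- seq_chars(best$hit$aligned_target[1])
    qpos <- best$hit$query_start[1] - 1L + cumsum(qc != "-")
    tpos <- best$hit$target_start[1] - 1L + cumsum(tc != "-")
    keep <- qc != "-" & tc != "-"
    m <- rep(NA_integer_, nchar(tab$consensus[i]))
    m[qpos[keep]] <- tpos[keep]
    maps[[tab$contig_id[i]]] <- list(amplicon = amp, subgenome = best$sg,
                                     map = m)
  }
  maps
}

## compare qualified SNP calls and diagnostics against the planted truth
truth_comparison <- function(results, diag, sim, maps) {
  truth_snps <- sim$genosim$snp_records
  truth_hsv <- sim$subgenomes$hsv
  hsv_key <- paste(truth_hsv$amplicon, truth_hsv$position)
  calls <- do.call(rbind, lapply(results, function(r) {
    cl <- r$classified
    cl[cl$class == "SNP", , drop = FALSE]
  }))
  tp <- 0L; fp <- 0L; at_hsv <- 0L
  hit_ids <- character(0)
  if (!is.null(calls) && nrow(calls)) {
    for (i in seq_len(nrow(calls))) {
      m <- maps[[calls$contig_id[i]]]
      pos <- if (!is.null(m) && calls$position[i] <= length(m$map))
        m$map[calls$position[i]] else NA_integer_
      amp <- if (!is.null(m)) m$amplicon else NA_character_
      if (!is.na(pos) && paste(amp, pos) %in% hsv_key) at_hsv <- at_hsv + 1L
      ## allele-set match: the contig consensus may itself carry the planted
      ## allele (reference-genotype carrier), flipping ref and alt
      w <- which(!is.na(pos) & truth_snps$amplicon == amp &
                 truth_snps$position == pos &
                 (truth_snps$alt == calls$alt[i] |
                  (truth_snps$alt == calls$ref[i] &
                   truth_snps$ref == calls$alt[i])))
      if (length(w)) {
        tp <- tp + 1L
        hit_ids <- c(hit_ids, truth_snps$snp_id[w])
      } else fp <- fp + 1L
    }
  }
  n_planted <- nrow(truth_snps)
  n_calls <- tp + fp
  ## diagnostics: project group-A contig positions and compare to truth
  truth_diag <- sim$genosim$diagnostic_records
  diag_hits <- character(0); diag_fp <- 0L
  if (!is.null(diag) && nrow(diag)) {
    for (i in seq_len(nrow(diag))) {
      m <- maps[[diag$contig_a[i]]]
      pos <- if (!is.null(m) && diag$position_a[i] <= length(m$map))
        m$map[diag$position_a[i]] else NA_integer_
      w <- which(!is.na(pos) & truth_diag$amplicon == diag$amplicon_id[i] &
                 truth_diag$position == pos)
      if (length(w)) diag_hits <- c(diag_hits, truth_diag$diag_id[w])
      else diag_fp <- diag_fp + 1L
    }
  }
  data.frame(
    class = c("SNP", "DIAGNOSTIC"),
    n_planted = c(n_planted, nrow(truth_diag)),
    n_called = c(n_calls, (if (is.null(diag)) 0L else nrow(diag))),
    n_recovered = c(length(unique(hit_ids)), length(unique(diag_hits))),
    sensitivity = c(
      if (n_planted) length(unique(hit_ids)) / n_planted else NA_real_,
      if (nrow(truth_diag)) length(unique(diag_hits)) / nrow(truth_diag) else NA_real_),
    precision = c(
      if (n_calls) tp / n_calls else NA_real_,
      if (!is.null(diag) && nrow(diag)) 1 - diag_fp / nrow(diag) else NA_real_),
    pct_at_hsv = c(if (n_calls) 100 * at_hsv / n_calls else 0, NA_real_),
    stringsAsFactors = FALSE)
}

#' Run the full sub-genome-aware SNP discovery pipeline
#'
#' Orchestrates demultiplexing, template assignment and coverage estimation,
#' stringent reference assembly per morphotype, contig attribution, HSV
#' detection, per-genotype read mapping and variant tabulation, SNP
#' qualification, diagnostic classification across morphotypes, and
#' (optionally) NJ sub-genome attribution of SNP-bearing contigs. All stage
#' outputs are written under `config$out_dir`; in simulate mode a
#' truth-comparison report (sensitivity/precision per variant class) is
#' additionally produced. The returned manifest records a configuration
#' hash, per-stage record counts and the output inventory, and is identical
#' across re-runs with the same configuration.
#'
#' @param config a [run_config()] object (or a YAML path understood by
#'   [read_run_config()]).
#' @return list with `manifest`, per-morphotype `results`, `diagnostics`,
#'   `truth_comparison` (simulate mode) and `attribution` (when enabled).
#' @export
run_discovery <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  state <- list(log_level = config$log_level,
                log_file = file.path(out_dir, "run.log"))
  cat("", file = state$log_file)

  ## resolved configuration: audit record + config hash
  cfg_path <- file.path(out_dir, "config.yaml")
  cfg_for_yaml <- unclass(config)
  cfg_for_yaml$out_dir <- NULL
  yaml::write_yaml(cfg_for_yaml, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  log_msg(state, "info", "config hash %s", config_hash)

  sim <- NULL
  if (!is.null(config$simulate)) {
    simargs <- config$simulate
    if (is.null(simargs$seed)) simargs$seed <- config$seed
    scfg <- do.call(sim_config, simargs)
    sim <- simulate_population(scfg)
    reads <- sim$readsim$reads
    barcode_table <- sim$readsim$barcode_table
    templates <- sim$progenitors$templates
    prog_refs <- do.call(rbind, lapply(names(sim$progenitors$progenitors),
      function(amp) {
        p <- sim$progenitors$progenitors[[amp]]
        data.frame(ref_id = paste0(amp, "|", names(p)), amplicon = amp,
                   sequence = unlist(p), stringsAsFactors = FALSE)
      }))
    write_fastq(reads, file.path(out_dir, "reads.fastq"))
    write_reports(list(barcode_table = barcode_table), out_dir)
    write_fasta(stats::setNames(templates, names(templates)),
                file.path(out_dir, "templates.fasta"))
    write_fasta(stats::setNames(prog_refs$sequence, prog_refs$ref_id),
                file.path(out_dir, "progenitor_refs.fasta"))
    truth_tables <- list(
      truth_hsv = sim$subgenomes$hsv,
      truth_snps = sim$genosim$snp_records,
      truth_diagnostic = sim$genosim$diagnostic_records)
    write_reports(truth_tables, out_dir)
  } else {
    reads <- read_fastq(config$inputs$reads)
    barcode_table <- read_report(config$inputs$barcode_table)
    tdf <- read_fasta(config$inputs$templates)
    templates <- stats::setNames(tdf$sequence, tdf$read_id)
    pdf <- read_fasta(config$inputs$progenitor_refs)
    prog_refs <- data.frame(
      ref_id = pdf$read_id,
      amplicon = sub("\\|.*$", "", pdf$read_id),
      sequence = pdf$sequence, stringsAsFactors = FALSE)
  }
  if (!nrow(reads)) stop_invalid("stage demultiplex: empty read set")
  fallback <- data.frame(ref_id = names(templates), amplicon = names(templates),
                         sequence = unname(templates), stringsAsFactors = FALSE)

  ## stage: demultiplex
  dmx <- demultiplex(reads, barcode_table)
  log_msg(state, "info", "demultiplex: %d assigned, %d unassigned",
          nrow(dmx$assigned), nrow(dmx$unassigned))
  if (!nrow(dmx$assigned)) stop_invalid("stage demultiplex: no read assigned")

  ## stage: template assignment + coverage
  asg <- assign_templates_batch(dmx$assigned$sequence, templates,
                                max_evalue = config$max_evalue)
  assigned <- cbind(dmx$assigned, amplicon = asg$template,
                    strand = asg$strand, stringsAsFactors = FALSE)
  coverage_rep <- coverage_summary(
    data.frame(genotype_id = assigned$genotype_id, template = assigned$amplicon,
               stringsAsFactors = FALSE),
    templates)
  write_reports(list(coverage = coverage_rep), out_dir)
  log_msg(state, "info", "coverage: %d/%d reads template-assigned",
          sum(!is.na(assigned$amplicon)), nrow(assigned))

  ## per-morphotype stringent assembly + attribution
  morphs <- sort(unique(barcode_table$morphotype))
  results <- list(); reads_by_geno_all <- list()
  for (mo in morphs) {
    genos <- barcode_table$genotype_id[barcode_table$morphotype == mo]
    rbg <- split(assigned[assigned$genotype_id %in% genos, , drop = FALSE],
                 assigned$genotype_id[assigned$genotype_id %in% genos])
    reads_by_geno_all[[mo]] <- rbg
    results[[mo]] <- assemble_morphotype(mo, rbg, config, prog_refs,
                                         fallback, state)
  }

  ## HSV detection: within each reference assembly, plus between reference
  ## assemblies (cross-sub-genome pairs only; mutual-best pairs are the
  ## diagnostic comparisons)
  hsv_params <- mapping_params(min_overlap = config$hsv$min_overlap,
                               min_identity = config$hsv$min_identity)
  for (mo in morphs) {
    results[[mo]]$hsv <- detect_hsvs(results[[mo]]$contigs, hsv_params)
  }
  between_rows <- empty_hsv()
  if (length(morphs) >= 2L) {
    for (i in seq_len(length(morphs) - 1L)) {
      for (j in (i + 1L):length(morphs)) {
        btw <- detect_hsvs_between(results[[morphs[i]]]$contigs,
                                   results[[morphs[j]]]$contigs, hsv_params)
        between_rows <- rbind(between_rows, btw$hsv)
      }
    }
  }
  ## a between-reference HSV flag is hard (not segregation-overridable) when
  ## the partner reference's own within-genotype comparison corroborates the
  ## column as homoeologous
  within_key <- unlist(lapply(results, function(r)
    paste(r$hsv$hsv$contig_id, r$hsv$hsv$position)), use.names = FALSE)
  for (mo in morphs) {
    r <- results[[mo]]
    own <- contig_table(r$contigs)$contig_id
    within <- r$hsv$hsv
    if (nrow(within)) within$hard <- FALSE
    btw <- between_rows[between_rows$contig_id %in% own, , drop = FALSE]
    if (nrow(btw)) {
      btw$hard <- paste(btw$partner_contig, btw$partner_position) %in% within_key
    }
    mask <- rbind(
      if (nrow(within)) within else cbind(empty_hsv(), hard = logical(0)),
      if (nrow(btw)) btw else NULL)
    log_msg(state, "info", "%s: %d HSV events over %d aligned bp (+%d cross-reference positions, %d hard)",
            mo, r$hsv$n_events, r$hsv$aligned_bp, nrow(btw),
            sum(mask$hard %||% FALSE))
    results[[mo]] <- call_morphotype(r, reads_by_geno_all[[mo]], mask,
                                     config, state)
  }

  ## reports per morphotype
  for (mo in morphs) {
    r <- results[[mo]]
    tab <- contig_table(r$contigs)
    write_fasta(stats::setNames(tab$consensus,
                                paste(tab$contig_id, tab$amplicon_id, sep = "|")),
                file.path(out_dir, sprintf("contigs_%s.fasta", mo)))
    write_reports(stats::setNames(
      list(tab[, c("contig_id", "genotype_id", "amplicon_id", "length", "n_reads")],
           r$hsv$hsv, r$observations, r$classified,
           assembly_summary(r$contigs, r$hsv),
           snp_summary(r$classified, length(unique(tab$amplicon_id)),
                       nrow(tab))),
      paste0(c("contigs_", "hsv_", "variants_", "classified_",
               "assembly_summary_", "snp_summary_"), mo)), out_dir)
    write_variant_vcf(r$classified,
                      file.path(out_dir, sprintf("variants_%s.vcf", mo)))
  }

  ## diagnostics across the first two morphotype panels
  diag <- NULL
  if (length(morphs) >= 2L) {
    a <- results[[morphs[1]]]; b <- results[[morphs[2]]]
    diag <- classify_diagnostic(
      a$contigs, b$contigs, a$observations, b$observations,
      a$coverage, b$coverage,
      mapping_params(min_overlap = config$hsv$min_overlap,
                     min_identity = config$hsv$min_identity),
      min_observed = config$diagnostics$min_observed,
      min_depth = config$diagnostics$min_depth)
    write_reports(list(diagnostic = diag), out_dir)
    log_msg(state, "info", "diagnostics: %d variants", nrow(diag))
  }

  ## NJ sub-genome attribution of SNP-bearing contigs (first morphotype)
  attribution <- NULL
  if (isTRUE(config$attribution_trees) && length(results)) {
    r <- results[[1]]
    tab <- contig_table(r$contigs)
    snp_contigs <- unique(r$classified$contig_id[r$classified$class == "SNP"])
    rows <- list(); trees <- character(0)
    for (amp in sort(unique(tab$amplicon_id[tab$contig_id %in% snp_contigs]))) {
      if (amp == "UNATTRIBUTED") next
      pr <- prog_refs[prog_refs$amplicon == amp, , drop = FALSE]
      if (!nrow(pr)) next
      queries <- tab[tab$amplicon_id == amp & tab$contig_id %in% snp_contigs, ]
      labels <- pr$ref_id
      p_lab <- labels[grepl("P_ortholog", labels)]
      g_lab <- labels[grepl("G[0-9]*_ortholog", labels)]
      res <- try(attribute_haplotypes(
        stats::setNames(queries$consensus, queries$contig_id),
        stats::setNames(pr$sequence, pr$ref_id),
        p_lab, g_lab, model = config$phylo$model,
        margin = config$phylo$margin), silent = TRUE)
      if (inherits(res, "try-error")) next
      rows[[length(rows) + 1L]] <- res$assignments
      trees <- c(trees, ape::write.tree(res$tree))
    }
    attribution <- if (length(rows)) do.call(rbind, rows) else
      data.frame(haplotype = character(), assignment = character(),
                 d_P = numeric(), d_G = numeric(), stringsAsFactors = FALSE)
    write_reports(list(subgenome_attribution = attribution), out_dir)
    writeLines(trees, file.path(out_dir, "attribution_trees.nwk"))
    log_msg(state, "info", "attribution: %d haplotypes over %d trees",
            nrow(attribution), length(trees))
  }

  ## truth comparison (simulate mode)
  truth_cmp <- NULL
  if (!is.null(sim)) {
    maps <- list()
    for (r in results) {
      maps <- c(maps, contig_position_maps(r$contigs, sim$subgenomes$references))
    }
    truth_cmp <- truth_comparison(results, diag, sim, maps)
    write_reports(list(truth_comparison = truth_cmp), out_dir)
  }

  ## manifest
  counts <- list(
    reads_in = nrow(reads), reads_assigned = nrow(dmx$assigned),
    reads_template_assigned = sum(!is.na(assigned$amplicon)))
  for (mo in morphs) {
    r <- results[[mo]]
    counts[[paste0("contigs_", mo)]] <- length(r$contigs)
    counts[[paste0("hsv_events_", mo)]] <- r$hsv$n_events
    counts[[paste0("variant_groups_", mo)]] <- nrow(r$classified)
    counts[[paste0("snps_", mo)]] <- sum(r$classified$class == "SNP")
  }
  if (!is.null(diag)) counts$diagnostics <- nrow(diag)
  if (!is.null(attribution)) counts$attributed_haplotypes <- nrow(attribution)
  files <- sort(list.files(out_dir))
  files <- setdiff(files, c("run.log", "manifest.json"))
  inventory <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("polysnp")),
                   config_hash = config_hash, counts = counts,
                   inventory = inventory)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, results = results, diagnostics = diag,
                 truth_comparison = truth_cmp, attribution = attribution,
                 out_dir = out_dir))
}
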