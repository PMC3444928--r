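#' Read a FASTA file into a data frame of records
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()].
#'
#' @param path input FASTA path.
#' @return data.frame with columns `read_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  data.frame(read_id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with `read_id` and `sequence` columns, or a
#'   named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(read_id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- records$read_id
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

## structural validation of a 4-line FASTQ file; reports 1-based line numbers
validate_fastq_lines <- function(lines, path) {
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop_invalid("%s: truncated FASTQ record starting at line %d",
                 path, (n %/% 4L) * 4L + 1L)
  }
  for (i in seq_len(n %/% 4L)) {
    b <- (i - 1L) * 4L
    if (!startsWith(lines[b + 1L], "@")) {
      stop_invalid("%s: expected '@' header at line %d", path, b + 1L)
    }
    if (!startsWith(lines[b + 3L], "+")) {
      stop_invalid("%s: expected '+' separator at line %d", path, b + 3L)
    }
    if (nchar(lines[b + 2L]) != nchar(lines[b + 4L])) {
      stop_invalid("%s: sequence/quality length mismatch at line %d",
                   path, b + 2L)
    }
  }
  invisible(TRUE)
}

#' Read a FASTQ file into a data frame of records
#'
#' The file is structurally validated first (malformed records are reported
#' with their line number), then parsed with
#' [Biostrings::readDNAStringSet()]. Only 4-line-per-record FASTQ is
#' supported, which is what the package itself emits.
#'
#' @param path input FASTQ path.
#' @return data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  validate_fastq_lines(lines, path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = names(x), sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequence records to FASTQ (Sanger-scaled qualities)
#'
#' @param records data.frame with `read_id`, `sequence` and optionally
#'   `quality` (defaults to constant high quality).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(records, path) {
  qual <- records$quality
  if (is.null(qual)) qual <- strrep("I", nchar(records$sequence))
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- records$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Demultiplex barcode-tagged reads into per-genotype sets
#'
#' Reads are sorted by their 5' barcode tag and the barcode (plus any
#' configured adaptor) is trimmed from assigned reads. Every input read ends
#' up in exactly one output set. Under the one-mismatch policy a read prefix
#' within Hamming distance 1 of two different barcodes is left unassigned.
#'
#' @param reads data.frame with `read_id`, `sequence` and optionally
#'   `quality`.
#' @param barcode_table data.frame with `barcode`, `genotype_id` and
#'   optionally `morphotype`; barcodes must be unique and of equal length.
#' @param policy `"exact"` (default) or `"max1mm"`.
#' @param adaptor additional 5' adaptor sequence trimmed after the barcode
#'   (length only is used; default none).
#' @return list with `assigned` (read_id, genotype_id, morphotype, barcode,
#'   sequence, quality; barcode+adaptor trimmed) and `unassigned`
#'   (untouched input rows).
#' @export
demultiplex <- function(reads, barcode_table, policy = c("exact", "max1mm"),
                        adaptor = "") {
  policy <- match.arg(policy)
  bcs <- barcode_table$barcode
  if (anyDuplicated(bcs)) stop_invalid("duplicate barcodes in barcode table")
  bl <- unique(nchar(bcs))
  if (length(bl) != 1L) stop_invalid("barcodes must all have equal length")
  trim_len <- bl + nchar(adaptor)
  prefix <- substr(reads$sequence, 1L, bl)
  hit <- match(prefix, bcs)
  if (policy == "max1mm") {
    todo <- which(is.na(hit) & nchar(reads$sequence) >= bl)
    if (length(todo)) {
      bc_mat <- do.call(rbind, strsplit(bcs, "", fixed = TRUE))
      for (i in todo) {
        pc <- seq_chars(prefix[i])
        d <- rowSums(bc_mat != matrix(pc, nrow = length(bcs), ncol = bl,
                                      byrow = TRUE))
        w <- which(d <= 1L)
        if (length(w) == 1L) hit[i] <- w
      }
    }
  }
  ok <- !is.na(hit)
  qual <- reads$quality %||% strrep("I", nchar(reads$sequence))
  morph <- barcode_table$morphotype %||% rep(NA_character_, length(bcs))
  assigned <- data.frame(
    read_id = reads$read_id[ok],
    genotype_id = barcode_table$genotype_id[hit[ok]],
    morphotype = morph[hit[ok]],
    barcode = bcs[hit[ok]],
    sequence = substring(reads$sequence[ok], trim_len + 1L),
    quality = substring(qual[ok], trim_len + 1L),
    stringsAsFactors = FALSE)
  unassigned <- reads[!ok, , drop = FALSE]
  rownames(unassigned) <- NULL
  list(assigned = assigned, unassigned = unassigned)
}

## canonical row sort: lexicographic over columns left to right
sort_table <- function(df) {
  if (!nrow(df)) return(df)
  ord <- do.call(order, lapply(df, function(col) {
    if (is.numeric(col)) col else as.character(col)
  }))
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write report tables as deterministic TSV files
#'
#' Each table is written as `<name>.tsv` under `out_dir` with a fixed column
#' order and rows sorted lexicographically, so identical tables always
#' produce byte-identical files. All emitted coordinates are 1-based.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_reports <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    df <- sort_table(as.data.frame(tables[[nm]]))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a TSV report written by [write_reports()]
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "")
}

#' Write classified variants as a minimal VCF
#'
#' One record per classified (contig, position, alt); the contig consensus is
#' the reference. Class and carrier genotypes are stored in INFO. The file is
#' plain uncompressed VCF 4.2 readable by standard tooling.
#'
#' @param classified data.frame from [qualify_snps()] /
#'   [classify_diagnostic()] with columns `contig_id`, `position`, `ref`,
#'   `alt`, `class`, `carriers`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variant_vcf <- function(classified, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant classification\">",
           "##INFO=<ID=CARRIERS,Number=.,Type=String,Description=\"Carrier genotypes\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(classified)) {
    cl <- sort_table(classified)
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tCLASS=%s;CARRIERS=%s",
                    cl$contig_id, cl$position, cl$ref,
                    ifelse(cl$class %in% c("REJECT_INDEL"), "<INDEL>", cl$alt),
                    cl$class, gsub(";", ",", cl$carriers))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
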