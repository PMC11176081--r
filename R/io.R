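#' Read a gene x sample count matrix with gene lengths
#'
#' Expects a TSV whose first column is `gene_id` and remaining columns are
#' samples (integer counts), plus a two-column gene-length TSV
#' (`gene_id`, `length_bp`). Validation failures raise conditions of class
#' `stoichsi_validation_error` with a named reason.
#'
#' @param counts_path path to the count TSV.
#' @param lengths_path path to the gene-length TSV; may be `NULL` if lengths
#'   are supplied later.
#' @return object of class `si_counts`: list with `counts` (integer matrix),
#'   `gene_lengths` (named integer or NULL) and `library_size` (column sums).
#' @export
read_counts <- function(counts_path, lengths_path = NULL) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") {
    stop_validation("count file must have 'gene_id' as its first column")
  }
  gene_ids <- df$gene_id
  if (anyDuplicated(gene_ids)) stop_validation("duplicate gene ids in counts")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) {
    stop_validation("duplicate sample ids in counts")
  }
  if (any(is.na(m)) || any(m < 0)) {
    stop_validation("counts must be non-negative and complete")
  }
  if (any(m != round(m))) stop_validation("counts must be integers")
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  lengths <- NULL
  if (!is.null(lengths_path)) {
    ld <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "length_bp") %in% names(ld))) {
      stop_validation("gene-length file needs columns gene_id, length_bp")
    }
    lengths <- as.integer(ld$length_bp)
    names(lengths) <- ld$gene_id
    lengths <- match_gene_lengths(lengths, gene_ids)
  }
  new_si_counts(m, lengths)
}

match_gene_lengths <- function(lengths, gene_ids) {
  if (!all(gene_ids %in% names(lengths))) {
    stop_validation("gene-length table is missing genes present in counts")
  }
  out <- lengths[gene_ids]
  if (any(is.na(out)) || any(out <= 0)) {
    stop_validation("gene lengths must be positive")
  }
  out
}

new_si_counts <- function(counts, gene_lengths = NULL) {
  structure(list(counts = counts,
                 gene_lengths = gene_lengths,
                 library_size = colSums(counts)),
            class = "si_counts")
}

#' Build an `si_counts` object from in-memory pieces
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param gene_lengths named positive integer vector covering all genes.
#' @return `si_counts` object.
#' @export
as_si_counts <- function(counts, gene_lengths = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_validation("counts need gene and sample dimnames")
  }
  if (!is.null(gene_lengths)) {
    gene_lengths <- match_gene_lengths(gene_lengths, rownames(counts))
  }
  new_si_counts(counts, gene_lengths)
}

#' @export
print.si_counts <- function(x, ...) {
  cat("Count dataset:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples; median library size",
      format(stats::median(x$library_size), big.mark = ","), "\n")
  invisible(x)
}

#' Read and validate a sample metadata table
#'
#' TSV with columns sample_id, diagnosis (BD/HC), age, sex (M/F), ethnicity,
#' RIN, PMI. Samples younger than 18 are not dropped here but flagged in the
#' logical column `excluded` (the case group contains no children, so
#' retaining them would confound diagnosis with age-related development).
#'
#' @param path TSV path.
#' @param counts optional `si_counts`; if given, sample sets must match.
#' @return validated data.frame with an additional `excluded` column.
#' @export
read_samples <- function(path, counts = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_samples(df, counts)
}

#' @rdname read_samples
#' @param samples a data.frame to validate in memory.
#' @export
validate_samples <- function(samples, counts = NULL) {
  need <- c("sample_id", "diagnosis", "age", "sex", "ethnicity", "RIN", "PMI")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop_validation(paste("metadata is missing columns:",
                          paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop_validation("duplicate sample ids in metadata")
  }
  if (!all(samples$diagnosis %in% c("BD", "HC"))) {
    stop_validation("diagnosis must be BD or HC")
  }
  if (!all(samples$sex %in% c("M", "F"))) {
    stop_validation("sex must be M or F")
  }
  num <- c("age", "RIN", "PMI")
  for (v in num) {
    if (!is.numeric(samples[[v]]) || any(is.na(samples[[v]]))) {
      stop_validation(paste("covariate", v, "must be numeric and complete"))
    }
  }
  if (any(samples$RIN < 0 | samples$RIN > 10)) {
    stop_validation("RIN must lie in [0, 10]")
  }
  if (!is.null(counts)) {
    cs <- colnames(counts$counts)
    if (!setequal(cs, samples$sample_id)) {
      stop_validation("sample ids in counts and metadata do not match")
    }
    samples <- samples[match(cs, samples$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
  }
  samples$excluded <- samples$age < 18
  samples
}

#' Read a locus-to-gene candidate table
#'
#' TSV with columns locus_id, gene_id, protein_coding (0/1), l2g (in [0,1]),
#' distance_bp (to the GWAS index SNP, non-negative).
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_locus_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_locus_table(df)
}

#' @rdname read_locus_table
#' @param table data.frame to validate in memory.
#' @export
validate_locus_table <- function(table) {
  need <- c("locus_id", "gene_id", "protein_coding", "l2g", "distance_bp")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop_validation(paste("locus table is missing columns:",
                          paste(miss, collapse = ", ")))
  }
  if (any(table$l2g < 0 | table$l2g > 1, na.rm = TRUE)) {
    stop_validation("L2G scores must lie in [0, 1]")
  }
  if (any(table$distance_bp < 0)) {
    stop_validation("distances to the index SNP must be non-negative")
  }
  if (!all(table$protein_coding %in% c(0L, 1L))) {
    stop_validation("protein_coding must be 0/1")
  }
  table
}

#' Gene lengths from a GTF annotation
#'
#' Per gene, the length is the width of the exon union of its canonical
#' transcript when one is tagged (default tag `Ensembl_canonical`), otherwise
#' the median of per-transcript exon-union lengths (midpoint of the two
#' middle transcripts for an even count). Coordinates are 1-based inclusive;
#' overlapping exons within a transcript are unioned, not summed.
#'
#' @param gtf_path path to a GTF file with exon features carrying `gene_id`
#'   and `transcript_id` attributes.
#' @param canonical_tag attribute tag marking the canonical transcript.
#' @return named integer vector of lengths (bp).
#' @export
gene_lengths_from_gtf <- function(gtf_path, canonical_tag = "Ensembl_canonical") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for GTF parsing")
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stop_validation("GTF contains no exon features")
  tags <- if ("tag" %in% names(S4Vectors::mcols(ex))) ex$tag else
    rep(NA_character_, length(ex))
  # Exon union per transcript.
  by_tx <- split(ex, ex$transcript_id)
  tx_len <- vapply(by_tx, function(g) {
    sum(GenomicRanges::width(GenomicRanges::reduce(g)))
  }, numeric(1))
  tx_gene <- vapply(by_tx, function(g) g$gene_id[1], character(1))
  tx_canon <- vapply(by_tx, function(g) {
    tg <- if ("tag" %in% names(S4Vectors::mcols(g))) g$tag else NULL
    any(!is.na(tg) & tg == canonical_tag)
  }, logical(1))
  genes <- unique(tx_gene)
  out <- vapply(genes, function(gid) {
    sel <- tx_gene == gid
    if (!any(sel)) stop_validation(paste("gene", gid, "has no transcripts"))
    if (any(tx_canon[sel])) {
      tx_len[sel & tx_canon][1]
    } else {
      stats::median(tx_len[sel])
    }
  }, numeric(1))
  round(out)
}
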