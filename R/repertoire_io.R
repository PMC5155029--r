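#' Sample metadata for a repertoire
#'
#' Describes one sequencing sample: identifiers, time point (days from
#' diagnosis), tissue, template nucleic acid, and an optional external MRD
#' measurement (e.g. a fusion-gene qPCR T/C ratio or % blasts) used only for
#' correlation with sequencing-based MRD.
#'
#' @param sample_id Unique sample identifier.
#' @param patient_id Patient identifier shared by all of a patient's samples.
#' @param day Integer day from diagnosis (>= 0).
#' @param tissue One of `"BM"`, `"PB"`, `"CSF"`, `"synthetic"`.
#' @param template One of `"RNA"`, `"DNA"`.
#' @param external_mrd Optional numeric external MRD covariate (`NA` if absent).
#' @return An object of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, patient_id, day = 0L,
                        tissue = c("BM", "PB", "CSF", "synthetic"),
                        template = c("RNA", "DNA"),
                        external_mrd = NA_real_) {
  tissue <- match.arg(tissue)
  template <- match.arg(template)
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id),
            is.character(patient_id), length(patient_id) == 1L, nzchar(patient_id))
  day <- as.integer(day)
  if (is.na(day) || day < 0L) {
    bcrmrd_error("`day` must be a non-negative integer (days from diagnosis)",
                 "bcrmrd_invalid_meta")
  }
  structure(list(sample_id = sample_id, patient_id = patient_id, day = day,
                 tissue = tissue, template = template,
                 external_mrd = as.numeric(external_mrd)),
            class = "sample_meta")
}

#' Construct a repertoire of unique sequences
#'
#' A repertoire is a collapsed multiset of unique nucleotide sequences with
#' read counts plus sample metadata — the universal currency of the pipeline.
#' Sequences are canonicalized to uppercase with U mapped to T.
#'
#' @param seqs Character vector of nucleotide sequences over `{A,C,G,T,N}`.
#' @param counts Positive integer read counts, one per sequence.
#' @param meta A [sample_meta()] object.
#' @return An object of class `repertoire` with elements `meta` and
#'   `sequences` (a data frame with columns `seq`, `count`).
#' @export
repertoire <- function(seqs, counts, meta) {
  stopifnot(inherits(meta, "sample_meta"), length(seqs) == length(counts))
  if (length(seqs) == 0L) {
    bcrmrd_error("repertoire has no sequences", "bcrmrd_empty_repertoire")
  }
  seqs <- canonical_seq(as.character(seqs))
  assert_nucleotides(seqs)
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 1L)) {
    bcrmrd_error("all counts must be integers >= 1", "bcrmrd_invalid_count")
  }
  if (any(!nzchar(seqs))) bcrmrd_error("empty sequence string", "bcrmrd_invalid_seq")
  if (anyDuplicated(seqs)) {
    bcrmrd_error("duplicate sequences; collapse before construction",
                 "bcrmrd_duplicate_seq")
  }
  structure(list(meta = meta,
                 sequences = data.frame(seq = seqs, count = counts,
                                        stringsAsFactors = FALSE)),
            class = "repertoire")
}

#' Total reads in a repertoire
#' @param rep A `repertoire`.
#' @return Integer sum of read counts.
#' @export
total_reads <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  sum(rep$sequences$count)
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> sample %s (patient %s, day %d, %s/%s): %d unique sequences, %d reads\n",
              x$meta$sample_id, x$meta$patient_id, x$meta$day, x$meta$tissue,
              x$meta$template, nrow(x$sequences), total_reads(x)))
  invisible(x)
}

# Collapse raw reads (with possible duplicates) into a repertoire.
collapse_reads <- function(reads, meta) {
  if (length(reads) == 0L) {
    bcrmrd_error("no reads survived filtering", "bcrmrd_empty_repertoire")
  }
  tab <- table(reads)
  repertoire(names(tab), as.integer(tab), meta)
}

#' Read and filter raw reads into a repertoire
#'
#' Reads FASTA or FASTQ (gzip-transparent), applies a minimal length and
#' ambiguity filter, and collapses identical surviving reads. This filter is a
#' simple substitute for upstream read QC and is deliberately conservative:
#' full-length FR1 amplicons comfortably exceed the default length floor.
#'
#' @param path Path to a FASTA/FASTQ file (optionally gzipped).
#' @param meta A [sample_meta()].
#' @param min_length Reads shorter than this are dropped (default 100).
#' @param max_n_fraction Reads with a higher fraction of N bases are dropped
#'   (default 0: no ambiguous bases tolerated).
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return A [repertoire()].
#' @export
read_reads <- function(path, meta, min_length = 100L, max_n_fraction = 0,
                       format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(min_length >= 1L, max_n_fraction >= 0, max_n_fraction <= 1)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  reads <- tryCatch(
    as.character(Biostrings::readBStringSet(path, format = format)),
    error = function(e) {
      bcrmrd_error(sprintf("cannot parse %s as %s: %s", path, format,
                           conditionMessage(e)), "bcrmrd_format_error")
    })
  reads <- canonical_seq(unname(reads))
  assert_nucleotides(reads, what = sprintf("read in %s", path))
  keep <- nchar(reads) >= min_length
  n_frac <- vapply(strsplit(reads, ""), function(x) mean(x == "N"), 0)
  n_frac[nchar(reads) == 0L] <- 1
  keep <- keep & n_frac <= max_n_fraction
  collapse_reads(reads[keep], meta)
}

# tabular serialization -----------------------------------------------------

#' Write a repertoire to a tab-separated table
#'
#' Columns: `sequence`, `count`, then the metadata columns (`sample_id`,
#' `patient_id`, `day`, `tissue`, `template`, `external_mrd`), following the
#' community rearrangement-table convention of one row per unique sequence.
#'
#' @param rep A [repertoire()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path) {
  stopifnot(inherits(rep, "repertoire"))
  m <- rep$meta
  df <- data.frame(sequence = rep$sequences$seq, count = rep$sequences$count,
                   sample_id = m$sample_id, patient_id = m$patient_id,
                   day = m$day, tissue = m$tissue, template = m$template,
                   external_mrd = m$external_mrd, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a repertoire table written by [write_repertoire()]
#'
#' @param path Path to a tab-separated repertoire table.
#' @return A [repertoire()]. Duplicate sequence rows are merged (with a
#'   warning); a non-positive count is a validation error.
#' @export
read_repertoire <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = list(sequence = "character"))
  mandatory <- c("sequence", "count")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0L) {
    bcrmrd_error(sprintf("repertoire table %s lacks mandatory column(s): %s",
                         path, paste(missing_cols, collapse = ", ")),
                 "bcrmrd_schema_error")
  }
  if (nrow(df) == 0L) bcrmrd_error("empty repertoire table", "bcrmrd_empty_repertoire")
  if (any(is.na(df$count)) || any(df$count < 1)) {
    bcrmrd_error("counts must be >= 1", "bcrmrd_invalid_count")
  }
  if (anyDuplicated(df$sequence)) {
    warning("duplicate sequence rows merged (counts summed)")
    agg <- tapply(df$count, df$sequence, sum)
    first <- df[!duplicated(df$sequence), , drop = FALSE]
    first$count <- as.integer(agg[first$sequence])
    df <- first
  }
  meta_cols <- c("sample_id", "patient_id", "day", "tissue", "template")
  if (!all(meta_cols %in% names(df))) {
    bcrmrd_error("repertoire table lacks metadata columns", "bcrmrd_schema_error")
  }
  meta <- sample_meta(as.character(df$sample_id[1L]), as.character(df$patient_id[1L]),
                      df$day[1L], df$tissue[1L], df$template[1L],
                      if ("external_mrd" %in% names(df)) df$external_mrd[1L] else NA_real_)
  repertoire(df$sequence, df$count, meta)
}

# germline reference --------------------------------------------------------

#' Load a germline V/D/J gene reference from FASTA
#'
#' Record headers carry gene names (first whitespace-delimited token); the
#' segment class is inferred from the IMGT-style name prefix (`IGHV`, `IGHD`,
#' `IGHJ`) unless an explicit classifier is supplied.
#'
#' @param path Germline FASTA path.
#' @param classify Optional function mapping a gene name to `"V"`, `"D"`,
#'   `"J"` or `NA` (unclassifiable).
#' @return A `germline_db`: list with named character vectors `V`, `D`, `J`
#'   and (when present in the input ordering) a `v_order` vector giving the
#'   5'-to-3' locus order of V genes.
#' @export
load_germline <- function(path, classify = NULL) {
  recs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(recs) == 0L) bcrmrd_error("empty germline FASTA", "bcrmrd_format_error")
  full_names <- names(recs)
  gene <- vapply(strsplit(full_names, "[ \t|]"), `[[`, "", 1L)
  if (is.null(classify)) {
    classify <- function(nm) {
      if (grepl("^IGHV", nm, ignore.case = TRUE)) "V"
      else if (grepl("^IGHD", nm, ignore.case = TRUE)) "D"
      else if (grepl("^IGHJ", nm, ignore.case = TRUE)) "J"
      else NA_character_
    }
  }
  cls <- vapply(gene, classify, "")
  if (anyNA(cls)) {
    bcrmrd_error(sprintf("unclassifiable germline header(s): %s",
                         paste(full_names[is.na(cls)], collapse = ", ")),
                 "bcrmrd_unclassifiable_gene")
  }
  if (anyDuplicated(gene)) {
    bcrmrd_error(sprintf("duplicate gene name(s): %s",
                         paste(unique(gene[duplicated(gene)]), collapse = ", ")),
                 "bcrmrd_duplicate_gene")
  }
  seqs <- canonical_seq(as.character(recs))
  if (any(!nzchar(seqs))) bcrmrd_error("empty germline sequence", "bcrmrd_invalid_seq")
  db <- list(V = setNames(seqs[cls == "V"], gene[cls == "V"]),
             D = setNames(seqs[cls == "D"], gene[cls == "D"]),
             J = setNames(seqs[cls == "J"], gene[cls == "J"]))
  db$v_order <- setNames(seq_along(db$V), names(db$V))
  structure(db, class = "germline_db")
}

#' Write a germline reference to FASTA
#' @param db A `germline_db`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_germline <- function(db, path) {
  stopifnot(inherits(db, "germline_db"))
  all_seqs <- c(db$V, db$D, db$J)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(all_seqs), path)
  invisible(path)
}

#' @export
print.germline_db <- function(x, ...) {
  cat(sprintf("<germline_db> %d V, %d D, %d J genes\n",
              length(x$V), length(x$D), length(x$J)))
  invisible(x)
}
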