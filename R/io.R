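# Shared format I/O: FASTA (via Biostrings), annotation / intensity /
# metadata TSV. TSV is the single tabular dialect (tab separator, decimal
# point). Sequence coordinates are 0-based half-open internally.

#' Read a FASTA file into a sequence-record data frame
#'
#' Sequences are upcased on ingest (mixed-case input is normalized) and
#' validated against the A/C/G/T alphabet.
#'
#' @param path FASTA file.
#' @param alphabet_check Error on non-ACGT characters (default TRUE).
#' @return Data frame with `seq_id` (first word of the header) and
#'   `sequence`; zero rows for an empty file.
#' @export
read_fasta <- function(path, alphabet_check = TRUE) {
  if (file.info(path)$size == 0) {
    return(data.frame(seq_id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path,
                                           ": ", conditionMessage(e)))
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  if (alphabet_check) {
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad)) {
      stop("invalid sequence character(s) in record(s): ",
           paste(utils::head(ids[bad], 5L), collapse = ", "))
    }
  }
  data.frame(seq_id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA
#'
#' @param records Data frame with `seq_id` and `sequence`.
#' @param path Output file.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::DNAStringSet(stats::setNames(records$sequence,
                                                  records$seq_id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a taxonomy/annotation TSV
#'
#' @param path TSV with header `seq_id, organism, genus, family, phylum,
#'   gene_type, functional_category`.
#' @return Annotation data frame.
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("seq_id", "organism", "genus", "family", "phylum", "gene_type",
            "functional_category")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation lacks column(s): ",
                         paste(miss, collapse = ", "))
  ann
}

#' Join FASTA sequences with their annotation into sequence records
#'
#' Validates the record contract: every sequence annotated, non-empty
#' taxonomy for CDS records, `gene_type` in CDS/rRNA.
#'
#' @param fasta_path FASTA file of sequences.
#' @param annot_path Annotation TSV (see [read_annotation_tsv()]).
#' @return Sequence-record data frame.
#' @export
read_sequence_records <- function(fasta_path, annot_path) {
  fa <- read_fasta(fasta_path)
  ann <- read_annotation_tsv(annot_path)
  miss <- setdiff(fa$seq_id, ann$seq_id)
  if (length(miss)) stop("unannotated sequence(s): ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  rec <- merge(fa, ann, by = "seq_id", sort = FALSE)
  if (!all(rec$gene_type %in% c("CDS", "rRNA"))) {
    stop("gene_type must be CDS or rRNA")
  }
  cds <- rec$gene_type == "CDS"
  tax_ok <- nzchar(rec$genus) & nzchar(rec$family) & nzchar(rec$phylum)
  if (any(cds & !tax_ok)) {
    stop("CDS record(s) with empty taxonomy: ",
         paste(utils::head(rec$seq_id[cds & !tax_ok], 5L), collapse = ", "))
  }
  rec
}

#' Write a data frame as TSV
#'
#' @param x Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-by-sample intensity matrix TSV
#'
#' First column = probe ids, header row = sample ids, numeric cells.
#'
#' @param path TSV file.
#' @param state Intensity state tag attached to the matrix (`"raw"` or
#'   `"normalized"`).
#' @param kind `"intensity"` (non-negative, no missing values enforced) or
#'   `"ratio"` (signed values allowed, e.g. log2 ratio matrices).
#' @return Numeric matrix; intensities carry an attribute `state`.
#' @export
read_matrix_tsv <- function(path, state = "raw",
                            kind = c("intensity", "ratio")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1L]]
  vals <- df[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, TRUE)
  if (any(bad)) stop("non-numeric intensity column(s): ",
                     paste(names(vals)[bad], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (kind == "ratio") {
    if (anyNA(m)) stop("ratio matrix contains missing values")
    return(m)
  }
  attr(m, "state") <- state
  .as_intensity(m)
}

#' Write an intensity (or ratio) matrix as TSV
#'
#' @param m Matrix with probe rownames and sample colnames.
#' @param path Output file.
#' @param id_col Name of the leading id column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write_tsv(df, path)
}

#' Read and validate sample metadata TSV
#'
#' @param path TSV with columns `sample_id, season, habitat, salinity_psu,
#'   depth_class, location_code, is_baseline`.
#' @return Validated metadata data frame (`is_baseline` as logical).
#' @export
read_meta_tsv <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(meta$is_baseline)) meta$is_baseline <- as.logical(meta$is_baseline)
  validate_sample_meta(meta)
  meta
}
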