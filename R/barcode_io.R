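# Reading, validation and QC of aligned COI barcode libraries.

IUPAC_CHARS <- c("A", "C", "G", "T", "N", "-",
                 "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

META_COLUMNS <- c("sample_id", "morphospecies", "genus", "tribe",
                  "country", "province", "source")

# Stop codons under the invertebrate mitochondrial genetic code
# (TGA encodes Trp and AGA/AGG encode Ser, so only TAA/TAG terminate).
MITO_STOPS <- c("TAA", "TAG")

#' Construct a barcode dataset
#'
#' Joins an aligned set of barcode sequences to a specimen metadata table
#' into the single container consumed by every downstream stage. Sequences
#' are uppercased and validated against the IUPAC nucleotide alphabet
#' (plus `N` and the gap character `-`); all sequences must share one
#' alignment length.
#'
#' @param sequences Named character vector of aligned sequences (names are
#'   sample ids), or a character matrix with one row per sequence and
#'   rownames as sample ids.
#' @param metadata Data frame with columns `sample_id`, `morphospecies`,
#'   `genus`, `tribe`, `country`, `province`, `source`.
#' @param frame_offset Integer in `0:2`; number of bases preceding the
#'   first complete codon. The 658-bp Folmer COI fragment conventionally
#'   begins mid-codon, hence the default `1`.
#' @param max_missing_frac Sequences whose fraction of gap/`N` characters
#'   is at least this value are rejected (guards truncated records).
#' @return An object of class `barcode_dataset`: a list with elements
#'   `seq` (character matrix, one row per specimen, one column per
#'   alignment site), `meta` (data frame in FASTA order) and
#'   `frame_offset`.
#' @export
barcode_dataset <- function(sequences, metadata, frame_offset = 1L,
                            max_missing_frac = 0.5) {
  if (!frame_offset %in% 0:2)
    stop("frame_offset must be 0, 1 or 2", call. = FALSE)
  if (is.matrix(sequences)) {
    mat <- toupper(sequences)
  } else {
    if (length(sequences) == 0L)
      stop("no sequences supplied: empty alignment", call. = FALSE)
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
      stop("sequences must be named by sample_id", call. = FALSE)
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("alignment error: sequences differ in length (",
           paste(unique(lens), collapse = ", "), ")", call. = FALSE)
    mat <- do.call(rbind, strsplit(toupper(sequences), ""))
    rownames(mat) <- names(sequences)
  }
  if (nrow(mat) == 0L)
    stop("no sequences supplied: empty alignment", call. = FALSE)

  bad <- !(mat %in% IUPAC_CHARS)
  if (any(bad)) {
    offend <- unique(rownames(mat)[row(mat)[bad]])
    stop("invalid characters (not IUPAC/N/-) in: ",
         paste(utils::head(offend, 5L), collapse = ", "), call. = FALSE)
  }

  ids <- rownames(mat)
  if (anyDuplicated(ids))
    stop("duplicate sample_id in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)

  missing_frac <- rowMeans(mat == "-" | mat == "N")
  if (any(missing_frac >= max_missing_frac))
    stop("sequences with >= ", round(100 * max_missing_frac),
         "% gap/N rejected: ",
         paste(ids[missing_frac >= max_missing_frac], collapse = ", "),
         call. = FALSE)

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  missing_cols <- setdiff(META_COLUMNS, names(metadata))
  if (length(missing_cols))
    stop("metadata missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
               collapse = ", "), call. = FALSE)

  only_fasta <- setdiff(ids, metadata$sample_id)
  only_meta  <- setdiff(metadata$sample_id, ids)
  if (length(only_fasta) || length(only_meta))
    stop("join error between alignment and metadata.",
         if (length(only_fasta))
           paste0(" Missing from metadata: ",
                  paste(only_fasta, collapse = ", "), "."),
         if (length(only_meta))
           paste0(" Missing from alignment: ",
                  paste(only_meta, collapse = ", "), "."),
         call. = FALSE)

  for (col in c("morphospecies", "genus", "tribe"))
    if (any(is.na(metadata[[col]]) | !nzchar(metadata[[col]])))
      stop("metadata column '", col, "' has empty values", call. = FALSE)

  meta <- metadata[match(ids, metadata$sample_id), META_COLUMNS,
                   drop = FALSE]
  rownames(meta) <- NULL
  structure(list(seq = mat, meta = meta,
                 frame_offset = as.integer(frame_offset)),
            class = "barcode_dataset")
}

#' Read an aligned barcode FASTA plus specimen metadata
#'
#' @param fasta_path Path to an aligned nucleotide FASTA (fixed length).
#' @param metadata_path Path to a tab-separated metadata table with header
#'   columns `sample_id`, `morphospecies`, `genus`, `tribe`, `country`,
#'   `province`, `source`.
#' @inheritParams barcode_dataset
#' @return A validated [barcode_dataset()], rows in FASTA order.
#' @export
read_dataset <- function(fasta_path, metadata_path, frame_offset = 1L,
                         max_missing_frac = 0.5) {
  dna <- tryCatch(suppressWarnings(ape::read.FASTA(fasta_path)),
                  error = function(e) NULL)
  if (is.null(dna) || length(dna) == 0L)
    stop("empty or unreadable FASTA: ", fasta_path, call. = FALSE)
  seqs <- vapply(as.character(dna),
                 function(x) paste(toupper(x), collapse = ""), "")
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  barcode_dataset(seqs, meta, frame_offset = frame_offset,
                  max_missing_frac = max_missing_frac)
}

#' Write a barcode dataset back to FASTA + metadata
#'
#' Inverse of [read_dataset()]; re-reading the two files yields an
#' identical dataset.
#'
#' @param ds A `barcode_dataset`.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, `ds`.
#' @export
write_dataset <- function(ds, fasta_path, metadata_path) {
  stopifnot(inherits(ds, "barcode_dataset"))
  seqs <- apply(ds$seq, 1L, paste, collapse = "")
  lines <- as.vector(rbind(paste0(">", names(seqs)), seqs))
  writeLines(lines, fasta_path)
  utils::write.table(ds$meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat("barcode_dataset:", nrow(x$seq), "sequences x", ncol(x$seq),
      "aligned sites\n")
  cat("  morphospecies:", length(unique(x$meta$morphospecies)),
      " genera:", length(unique(x$meta$genus)),
      " tribes:", length(unique(x$meta$tribe)), "\n")
  invisible(x)
}

in_frame_codons <- function(chars, frame_offset) {
  nt <- chars[chars != "-"]
  if (frame_offset > 0L) nt <- nt[-seq_len(frame_offset)]
  k <- length(nt) %/% 3L
  matrix(nt[seq_len(3L * k)], nrow = 3L)
}

#' Screen for pseudogenes (Numts) by reading-frame integrity
#'
#' Flags sequences whose in-frame conceptual translation under the
#' invertebrate mitochondrial code contains an internal stop codon
#' (TAA/TAG), and sequences whose non-gap length is incongruent with an
#' intact reading frame (indel not a multiple of 3 relative to the modal
#' sequence length in the alignment). Codons containing `N` or ambiguity
#' codes are skipped. Nuclear mitochondrial paralogues (Numts) typically
#' betray themselves by exactly these signatures.
#'
#' @param ds A `barcode_dataset`.
#' @param frame_offset Frame offset to use; defaults to the dataset's.
#' @return Data frame with columns `sample_id` and `reason`; zero rows for
#'   a clean dataset.
#' @export
screen_pseudogenes <- function(ds, frame_offset = ds$frame_offset) {
  stopifnot(inherits(ds, "barcode_dataset"))
  if (!frame_offset %in% 0:2)
    stop("frame_offset must be 0, 1 or 2", call. = FALSE)
  nongap <- rowSums(ds$seq != "-")
  if (any(nongap - frame_offset < 3L))
    stop("sequences too short to translate at frame_offset ", frame_offset,
         call. = FALSE)
  modal_len <- as.integer(names(which.max(table(nongap))))

  out_id <- character(0); out_reason <- character(0)
  for (i in seq_len(nrow(ds$seq))) {
    id <- rownames(ds$seq)[i]
    if ((nongap[i] - modal_len) %% 3L != 0L) {
      out_id <- c(out_id, id)
      out_reason <- c(out_reason, "frame-shifting indel")
      next
    }
    cod <- in_frame_codons(ds$seq[i, ], frame_offset)
    complete <- colSums(matrix(cod %in% c("A", "C", "G", "T"), nrow = 3L)) == 3L
    codons <- apply(cod[, complete, drop = FALSE], 2L, paste, collapse = "")
    # terminal codon may legitimately be a stop; only internal stops flag
    internal <- codons[-length(codons)]
    if (any(internal %in% MITO_STOPS)) {
      out_id <- c(out_id, id)
      out_reason <- c(out_reason, "internal stop")
    }
  }
  data.frame(sample_id = out_id, reason = out_reason,
             stringsAsFactors = FALSE)
}

#' Partition morphospecies by sampling depth
#'
#' @param ds A `barcode_dataset`.
#' @return Named integer vector `c(n_singleton_species, n_multi_species)`;
#'   the two entries always sum to the number of distinct morphospecies.
#' @export
count_by_sampling <- function(ds) {
  stopifnot(inherits(ds, "barcode_dataset"))
  n <- table(ds$meta$morphospecies)
  c(n_singleton_species = sum(n == 1L), n_multi_species = sum(n > 1L))
}
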