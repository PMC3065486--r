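IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Construct a barcode dataset
#'
#' Bundles aligned barcode sequences with their specimen metadata into a
#' validated `barcode_dataset`, the input container for every analysis in
#' the package. All sequences must share one alignment length; COI
#' barcodes in Lepidoptera are effectively indel-free, so inputs are
#' expected pre-aligned.
#'
#' @param specimen_id character vector of unique voucher identifiers.
#' @param genus,species character vectors: genus name and specific epithet
#'   (both non-empty). The working species label is `paste(genus, species)`.
#' @param region character vector of locality tags (province/state); may be
#'   empty strings.
#' @param sequence character vector of aligned IUPAC nucleotide strings.
#'   Case-insensitive; `U` is mapped to `T`; `-` marks alignment gaps and is
#'   treated like an ambiguous site downstream (pairwise deletion).
#' @return An object of class `barcode_dataset`: a list with elements
#'   `records` (a data frame with one row per specimen and columns
#'   `specimen_id`, `genus`, `species`, `region`, `sequence`,
#'   `seq_length_unambiguous`) and `alignment_length`.
#' @examples
#' d <- barcode_dataset(c("s1", "s2"), c("Macaria", "Macaria"),
#'                      c("signaria", "oweni"), c("BC", "BC"),
#'                      c("ACGTACGTAC", "ACGTACGTAT"))
#' d$alignment_length
#' @seealso [read_dataset()], [qc_flags()], [distance_matrix()]
#' @export
barcode_dataset <- function(specimen_id, genus, species, region, sequence) {
  n <- length(specimen_id)
  stopifnot(length(genus) == n, length(species) == n,
            length(region) == n, length(sequence) == n)
  if (n == 0L) stop("a barcode_dataset needs at least one record")
  specimen_id <- as.character(specimen_id)
  dup <- specimen_id[duplicated(specimen_id)]
  if (length(dup))
    stop("duplicate specimen IDs: ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(genus)) || any(!nzchar(species)))
    stop("genus and species must be non-empty for every record")
  sequence <- toupper(as.character(sequence))
  sequence <- gsub("U", "T", sequence, fixed = TRUE)
  lens <- nchar(sequence)
  if (length(unique(lens)) != 1L)
    stop("alignment error: sequences differ in length (",
         paste(sort(unique(lens)), collapse = ", "),
         "); inputs must be pre-aligned to equal length")
  bad <- grepl(paste0("[^", paste(IUPAC_CHARS, collapse = ""), "]"), sequence)
  if (any(bad))
    stop("invalid sequence characters in: ",
         paste(specimen_id[bad], collapse = ", "))
  unamb <- vapply(strsplit(sequence, ""), function(s)
    sum(s %in% c("A", "C", "G", "T")), integer(1))
  records <- data.frame(
    specimen_id = specimen_id,
    genus = as.character(genus),
    species = as.character(species),
    region = as.character(region),
    sequence = sequence,
    seq_length_unambiguous = unamb,
    stringsAsFactors = FALSE
  )
  structure(list(records = records, alignment_length = lens[1]),
            class = "barcode_dataset")
}

#' Read an aligned FASTA file plus specimen metadata
#'
#' Joins a FASTA alignment to a tab-separated metadata table by specimen
#' ID. The metadata file must be strict TSV with a header row containing
#' the case-sensitive columns `specimen_id`, `genus`, `species`, `region`
#' (extra columns are ignored). Records are returned in metadata row
#' order.
#'
#' @param fasta_path path to a FASTA file (wrapped or single-line).
#' @param metadata_path path to the TSV metadata file.
#' @return A [barcode_dataset].
#' @export
read_dataset <- function(fasta_path, metadata_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  aln <- ape::read.FASTA(fasta_path)
  if (length(aln) == 0L) stop("FASTA file contains no sequences")
  seqs <- vapply(as.character(aln), function(s)
    paste(toupper(s), collapse = ""), character(1))
  ids <- names(aln)
  if (anyDuplicated(ids))
    stop("duplicate FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  meta <- read.delim(metadata_path, sep = "\t", header = TRUE,
                     colClasses = "character", check.names = FALSE,
                     quote = "", comment.char = "")
  need <- c("specimen_id", "genus", "species", "region")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$specimen_id))
    stop("duplicate specimen IDs in metadata: ",
         paste(unique(meta$specimen_id[duplicated(meta$specimen_id)]),
               collapse = ", "))
  only_fa <- setdiff(ids, meta$specimen_id)
  only_md <- setdiff(meta$specimen_id, ids)
  if (length(only_fa) || length(only_md))
    stop("join error: ",
         if (length(only_fa))
           paste0("FASTA IDs missing from metadata: ",
                  paste(only_fa, collapse = ", "), ". ") else "",
         if (length(only_md))
           paste0("metadata IDs missing from FASTA: ",
                  paste(only_md, collapse = ", "), ".") else "")
  seqs <- seqs[match(meta$specimen_id, ids)]
  barcode_dataset(meta$specimen_id, meta$genus, meta$species,
                  meta$region, unname(seqs))
}

#' Write a barcode dataset back to FASTA + TSV
#'
#' Inverse of [read_dataset()]: re-reading the two files yields an
#' identical dataset.
#'
#' @param d a [barcode_dataset].
#' @param fasta_path,metadata_path output paths.
#' @return Invisibly, `d`.
#' @export
write_dataset <- function(d, fasta_path, metadata_path) {
  stopifnot(inherits(d, "barcode_dataset"))
  rec <- d$records
  lines <- character(2L * nrow(rec))
  lines[c(TRUE, FALSE)] <- paste0(">", rec$specimen_id)
  lines[c(FALSE, TRUE)] <- rec$sequence
  writeLines(lines, fasta_path)
  write.table(rec[, c("specimen_id", "genus", "species", "region")],
              metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}

#' Quality flags against a minimum-length standard
#'
#' Community barcode quality standards require a minimum number of
#' resolved nucleotides (conventionally more than 500 bp of the ~658 bp
#' COI barcode). This flags each record without removing any: short
#' mini-barcodes are retained in all analyses, the flag is advisory.
#'
#' @param d a [barcode_dataset].
#' @param min_len minimum count of unambiguous A/C/G/T positions; the
#'   comparison is inclusive (`>=`).
#' @return A data frame with columns `specimen_id`,
#'   `seq_length_unambiguous` and `meets_standard`; one row per record.
#' @export
qc_flags <- function(d, min_len = 500) {
  stopifnot(inherits(d, "barcode_dataset"))
  rec <- d$records
  data.frame(specimen_id = rec$specimen_id,
             seq_length_unambiguous = rec$seq_length_unambiguous,
             meets_standard = rec$seq_length_unambiguous >= min_len,
             stringsAsFactors = FALSE)
}

#' @export
print.barcode_dataset <- function(x, ...) {
  rec <- x$records
  cat("Barcode dataset: ", nrow(rec), " specimens, ",
      length(unique(paste(rec$genus, rec$species))), " species, ",
      length(unique(rec$genus)), " genera; alignment length ",
      x$alignment_length, " bp\n", sep = "")
  invisible(x)
}

# integer coding used by the distance kernel: 0=A,1=C,2=G,3=T, -1 otherwise
.encode_sequences <- function(d) {
  rec <- d$records
  chars <- strsplit(rec$sequence, "")
  m <- matrix(-1L, nrow = nrow(rec), ncol = d$alignment_length)
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  for (i in seq_along(chars)) {
    v <- code[chars[[i]]]
    v[is.na(v)] <- -1L
    m[i, ] <- v
  }
  rownames(m) <- rec$specimen_id
  m
}
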