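# FASTA input/output and sequence validation.
#
# Sequences travel through the package as tibbles with columns `id`, `seq`
# and (optionally) `description`; Biostrings does the file handling.

#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble, validating every sequence against the
#' 20-letter canonical alphabet. Lowercase input is uppercased; any other
#' non-canonical character (X, B, Z, U, gaps, ...) is an error, because the
#' downstream metrics require a closed alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header), `description` (remainder of the header, `NA` if absent)
#'   and `seq` (uppercase residue string).
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    abort(paste0("no sequences found in FASTA file: ", path))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), NA_character_)
  seqs <- as.character(set)
  tibble(
    id = ids,
    description = desc,
    seq = vapply(seq_along(seqs), function(i) {
      check_residues(seqs[[i]], what = paste0("sequence '", ids[[i]], "'"))
    }, character(1))
  )
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences A data frame with columns `id` and `seq`, and optionally
#'   `description` (appended to the header after a space when non-missing).
#' @param path Output path.
#' @param width Line-wrap width for residues (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(is.data.frame(sequences), all(c("id", "seq") %in% names(sequences)))
  headers <- sequences$id
  if ("description" %in% names(sequences)) {
    has_desc <- !is.na(sequences$description) & nzchar(sequences$description)
    headers[has_desc] <- paste(headers[has_desc], sequences$description[has_desc])
  }
  set <- Biostrings::AAStringSet(setNames(sequences$seq, headers))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

# Internal: split a residue string into a character vector.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]
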