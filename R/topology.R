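# Transmembrane topology: ordered, non-overlapping 1-based inclusive spans.

#' Build and validate a transmembrane topology
#'
#' A topology is a tibble with columns `start` and `end` (1-based, inclusive,
#' UniProt convention) and optionally `sequence_id`. Spans are sorted by
#' `start` and must be pairwise non-overlapping with `start <= end`.
#'
#' @param spans A data frame with numeric columns `start` and `end`, or a
#'   two-column matrix. Zero rows describe a protein with no annotated
#'   transmembrane helix.
#' @param sequence_id Optional identifier of the annotated sequence.
#' @param seq_length Optional sequence length; when given, spans must not
#'   extend past it.
#' @return A tibble with columns `sequence_id`, `start`, `end`, sorted by
#'   `start`.
#' @examples
#' tm_topology(data.frame(start = c(10, 40), end = c(30, 60)))
#' @export
tm_topology <- function(spans, sequence_id = NA_character_, seq_length = NULL) {
  if (is.matrix(spans)) {
    spans <- as.data.frame(spans)
    names(spans) <- c("start", "end")
  }
  stopifnot(is.data.frame(spans))
  if (nrow(spans) == 0L) {
    return(tibble(sequence_id = character(), start = integer(), end = integer()))
  }
  if (!all(c("start", "end") %in% names(spans))) {
    abort("topology needs columns 'start' and 'end'")
  }
  start <- as.integer(spans$start)
  end <- as.integer(spans$end)
  if (anyNA(start) || anyNA(end)) abort("non-numeric span bounds")
  if (any(start < 1L)) abort("span starts must be >= 1 (1-based coordinates)")
  if (any(start > end)) abort("span with start > end")
  ord <- order(start)
  start <- start[ord]
  end <- end[ord]
  if (nrow(spans) > 1L && any(start[-1L] <= end[-length(end)])) {
    abort("overlapping transmembrane spans")
  }
  if (!is.null(seq_length) && any(end > seq_length)) {
    abort(paste0("span exceeds sequence length (", seq_length, ")"))
  }
  sid <- if ("sequence_id" %in% names(spans)) as.character(spans$sequence_id)[ord] else
    rep(as.character(sequence_id), length(start))
  tibble(sequence_id = sid, start = start, end = end)
}

#' Read a transmembrane topology file
#'
#' Two dialects are supported: `"uniprot"`, flat-file style lines containing
#' `TRANSMEM a..b` (the `FT` key and qualifiers are tolerated and ignored);
#' and `"tsv"`, a headerless two-column table of `start<TAB>end`. Both yield
#' 1-based inclusive spans validated by [tm_topology()].
#'
#' @param path Path to the annotation file.
#' @param dialect `"uniprot"` or `"tsv"`.
#' @param sequence_id Optional id recorded on the returned spans.
#' @return A topology tibble (see [tm_topology()]).
#' @export
read_topology <- function(path, dialect = c("uniprot", "tsv"), sequence_id = NA_character_) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "uniprot") {
    hits <- str_match(lines, "TRANSMEM\\s+(\\d+)\\.\\.(\\d+)")
    hits <- hits[!is.na(hits[, 1L]), , drop = FALSE]
    if (nrow(hits) == 0L) abort(paste0("no TRANSMEM lines found in ", path))
    spans <- data.frame(
      start = as.integer(hits[, 2L]),
      end = as.integer(hits[, 3L])
    )
  } else {
    fields <- str_split(lines, "\\t")
    if (any(vapply(fields, length, integer(1)) < 2L)) {
      abort("tsv topology rows need two tab-separated fields: start<TAB>end")
    }
    start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 1L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
    if (anyNA(start) || anyNA(end)) abort("non-numeric field in tsv topology")
    spans <- data.frame(start = start, end = end)
  }
  tm_topology(spans, sequence_id = sequence_id)
}

#' Write a topology as two-column TSV
#'
#' @param topo A topology tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path) {
  utils::write.table(topo[, c("start", "end")], path,
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

# Internal: logical membership mask of positions 1..n inside any span.
span_mask <- function(topo, n) {
  mask <- logical(n)
  if (nrow(topo) > 0L) {
    if (any(topo$end > n)) abort("topology span exceeds sequence length")
    for (i in seq_len(nrow(topo))) mask[topo$start[i]:topo$end[i]] <- TRUE
  }
  mask
}
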