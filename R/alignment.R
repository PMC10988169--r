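# Text rendering of native-vs-variant alignments, in the style of the
# classic pairwise dot plots: native line, marker line, variant line, and a
# helix-annotation line marking transmembrane columns.

#' Render a native/variant alignment as text
#'
#' Produces wrapped alignment blocks for one QTY record. Each block has
#' four lines: a helix-annotation line (`H` under transmembrane columns,
#' spaces elsewhere), the native sequence, a marker line (`|` where the
#' two sequences are identical, `*` where they differ), and the variant
#' sequence. Blocks are `width` columns wide (last block possibly
#' shorter). The native and variant sequences are recoverable by
#' concatenating their lines.
#'
#' @param record A one-row tibble from [qty_transform()] (or any list with
#'   `native` and `variant` strings of equal length).
#' @param topo A topology tibble for the native sequence.
#' @param width Block width in columns, at least 10 (default 60).
#' @return A single string (lines separated by newlines), of class
#'   `qty_alignment` so that printing shows it verbatim.
#' @export
render_alignment <- function(record, topo, width = 60L) {
  if (width < 10L) abort("alignment width must be at least 10 columns")
  native <- record$native[[1L]]
  variant <- record$variant[[1L]]
  a <- seq_chars(native)
  b <- seq_chars(variant)
  if (length(a) != length(b)) abort("native and variant lengths differ")
  n <- length(a)
  marker <- ifelse(a == b, "|", "*")
  helix <- ifelse(span_mask(topo, n), "H", " ")

  starts <- seq(1L, n, by = width)
  blocks <- vapply(starts, function(s) {
    e <- min(s + width - 1L, n)
    paste(
      paste(helix[s:e], collapse = ""),
      paste(a[s:e], collapse = ""),
      paste(marker[s:e], collapse = ""),
      paste(b[s:e], collapse = ""),
      sep = "\n"
    )
  }, character(1))
  out <- paste(blocks, collapse = "\n\n")
  class(out) <- c("qty_alignment", "character")
  out
}

#' @export
print.qty_alignment <- function(x, ...) {
  cat(x, "\n", sep = "")
  invisible(x)
}
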