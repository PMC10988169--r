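# The QTY substitution code: L->Q, I->T, V->T, F->Y inside annotated
# transmembrane spans. This is the central operation of the package; every
# other module characterises its consequences.

#' Apply the QTY code to protein sequences
#'
#' Replaces, inside each annotated transmembrane span, every leucine with
#' glutamine, isoleucine and valine with threonine, and phenylalanine with
#' tyrosine. All positions outside the spans - including L/I/V/F residues -
#' are left untouched, so the transform is local to the membrane-embedded
#' helices and idempotent (a variant transforms to itself).
#'
#' @param sequences A tibble of sequences as returned by [read_fasta()]
#'   (columns `id`, `seq`), or a single residue string.
#' @param topology A topology tibble (see [tm_topology()]). With several
#'   input sequences the `sequence_id` column is used to match spans to
#'   sequences; every sequence must have a topology entry (possibly with
#'   zero spans only when `allow_missing` is `TRUE`).
#' @param allow_missing If `TRUE`, sequences without topology rows get an
#'   `error` message in the output instead of aborting the whole call
#'   (used by the batch pipeline for per-entry error isolation).
#' @return A tibble with one row per sequence: `id`, `native`, `variant`,
#'   `n_substitutions`, `substitutions` (list column of tibbles with
#'   `position`, `from`, `to` in ascending position order), the sequence
#'   metrics `total_variation_pct`, `tm_variation_pct`, `pi_native`,
#'   `pi_variant`, `mw_native`, `mw_variant`, `gravy_native`,
#'   `gravy_variant` (percentages, pI and MW rounded to 2 decimals, the
#'   printed precision of the field's reports), and `error` (`NA` on
#'   success).
#' @examples
#' qty_transform("MLIVFA", tm_topology(data.frame(start = 2, end = 6)))
#' @export
qty_transform <- function(sequences, topology, allow_missing = FALSE) {
  if (is.character(sequences) && length(sequences) == 1L && !is.data.frame(sequences)) {
    topo_id <- unique(topology$sequence_id)
    id <- if (length(topo_id) == 1L && !is.na(topo_id)) topo_id else "seq1"
    sequences <- tibble(id = id, seq = check_residues(sequences))
  }
  stopifnot(is.data.frame(sequences), all(c("id", "seq") %in% names(sequences)))
  topo_ids <- unique(topology$sequence_id)
  single_topo <- nrow(sequences) == 1L &&
    (nrow(topology) == 0L || all(is.na(topo_ids)) || identical(topo_ids, sequences$id))

  rows <- map(seq_len(nrow(sequences)), function(i) {
    id <- sequences$id[[i]]
    seq <- sequences$seq[[i]]
    topo_i <- if (single_topo) topology else filter(topology, .data$sequence_id == id)
    if (!single_topo && nrow(topo_i) == 0L && !(id %in% topo_ids)) {
      if (allow_missing) {
        return(qty_error_row(id, seq, paste0("no topology entry for '", id, "'")))
      }
      abort(paste0("no topology entry for sequence '", id, "'"))
    }
    res <- try(qty_record(id, seq, topo_i), silent = TRUE)
    if (inherits(res, "try-error")) {
      if (allow_missing) {
        return(qty_error_row(id, seq, conditionMessage(attr(res, "condition"))))
      }
      stop(attr(res, "condition"))
    }
    res
  })
  bind_rows(rows)
}

# One fully-populated record row; errors propagate.
qty_record <- function(id, seq, topo) {
  seq <- check_residues(seq, what = paste0("sequence '", id, "'"))
  chars <- seq_chars(seq)
  n <- length(chars)
  mask <- span_mask(topo, n)

  hit <- mask & chars %in% names(QTY_MAPPING)
  variant_chars <- chars
  variant_chars[hit] <- unname(QTY_MAPPING[chars[hit]])
  variant <- paste(variant_chars, collapse = "")

  subs <- tibble(
    position = which(hit),
    from = chars[hit],
    to = variant_chars[hit]
  )

  vp <- variation_percentages(seq, variant, topo)
  pka <- bjellqvist_pka()
  tibble(
    id = id,
    native = seq,
    variant = variant,
    n_substitutions = nrow(subs),
    substitutions = list(subs),
    total_variation_pct = vp[["total_pct"]],
    tm_variation_pct = vp[["tm_pct"]],
    pi_native = round(isoelectric_point(seq, pka), 2),
    pi_variant = round(isoelectric_point(variant, pka), 2),
    mw_native = round(molecular_weight(seq), 2),
    mw_variant = round(molecular_weight(variant), 2),
    gravy_native = round(gravy(seq), 4),
    gravy_variant = round(gravy(variant), 4),
    error = NA_character_
  )
}

qty_error_row <- function(id, seq, msg) {
  tibble(
    id = id, native = seq, variant = NA_character_,
    n_substitutions = NA_integer_, substitutions = list(tibble()),
    total_variation_pct = NA_real_, tm_variation_pct = NA_real_,
    pi_native = NA_real_, pi_variant = NA_real_,
    mw_native = NA_real_, mw_variant = NA_real_,
    gravy_native = NA_real_, gravy_variant = NA_real_,
    error = msg
  )
}

#' Sequence variation percentages
#'
#' Compares two equal-length sequences position by position and reports the
#' percentage of positions that differ, overall and restricted to the
#' transmembrane spans. The TM denominator is the number of residues inside
#' the spans of the (native) annotation. Both values are rounded to 2
#' decimals; with an empty topology the TM percentage is 0 by convention.
#'
#' @param native,variant Equal-length residue strings.
#' @param topo A topology tibble for the native sequence.
#' @return Named numeric vector `c(total_pct, tm_pct)`.
#' @examples
#' variation_percentages("LLLLAAAA", "QQQQAAAA",
#'   tm_topology(data.frame(start = 1, end = 4)))
#' @export
variation_percentages <- function(native, variant, topo) {
  a <- seq_chars(native)
  b <- seq_chars(variant)
  if (length(a) != length(b)) {
    abort("native and variant sequences have different lengths")
  }
  diff <- a != b
  mask <- span_mask(topo, length(a))
  total_pct <- 100 * sum(diff) / length(a)
  n_tm <- sum(mask)
  tm_pct <- if (n_tm == 0L) {
    if (any(diff & mask)) abort("impossible: differences inside empty spans")
    0
  } else {
    100 * sum(diff & mask) / n_tm
  }
  c(total_pct = round(total_pct, 2), tm_pct = round(tm_pct, 2))
}
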