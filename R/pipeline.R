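# Batch orchestration: apply the QTY code across a study manifest and
# emit one characterisation row per protein, with per-entry error
# isolation (one bad structure must not abort a six-protein batch).

REPORT_COLS <- c(
  "id", "pi_native", "pi_qty", "mw_native", "mw_qty",
  "total_variation_pct", "tm_variation_pct",
  "rmsd_all", "rmsd_refined", "n_pairs_used",
  "tm_rmsd_all", "tm_rmsd_refined", "tm_n_pairs_used",
  "error"
)

#' Read a study manifest
#'
#' A manifest lists the proteins of a study, one entry per row/element,
#' with fields `id`, `fasta`, `topology` (paths) and optionally
#' `native_structure`, `variant_structure`, `chain_native`,
#' `chain_variant`. Accepted formats: TSV with a header row, or JSON (an
#' array of objects). Ids must be unique.
#'
#' @param path Manifest file path.
#' @return A tibble of manifest entries.
#' @export
read_manifest <- function(path) {
  m <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  }
  if (!all(c("id", "fasta", "topology") %in% names(m))) {
    abort("manifest needs at least columns id, fasta, topology")
  }
  if (anyDuplicated(m$id)) abort("duplicate ids in manifest")
  as_tibble(m)
}

#' Run the characterisation report over a study manifest
#'
#' For every manifest entry: read the sequence and transmembrane
#' topology, apply the QTY code, compute the sequence metrics, and - when
#' native and variant structure paths are present - superpose the variant
#' onto the native structure (whole chain and transmembrane-domain-only)
#' and report the RMSDs. Entries that fail are reported with their error
#' message in the `error` column; the remaining entries are unaffected.
#'
#' @param manifest A tibble as returned by [read_manifest()] (paths may
#'   also be filled in programmatically).
#' @param cycles,reject_factor Refinement settings for the superpositions.
#' @param mode Residue pairing mode (see [build_correspondence()]).
#' @return A tibble with one row per entry and the fixed column set
#'   `id`, `pi_native`, `pi_qty`, `mw_native`, `mw_qty`,
#'   `total_variation_pct`, `tm_variation_pct`, `rmsd_all`,
#'   `rmsd_refined`, `n_pairs_used`, `tm_rmsd_all`, `tm_rmsd_refined`,
#'   `tm_n_pairs_used`, `error`; rows follow manifest order.
#' @export
run_report <- function(manifest, cycles = 5L, reject_factor = 2.0,
                       mode = "by_resnum") {
  stopifnot(is.data.frame(manifest), nrow(manifest) > 0L)
  rows <- map(seq_len(nrow(manifest)), function(i) {
    entry <- manifest[i, ]
    res <- try(report_entry(entry, cycles, reject_factor, mode), silent = TRUE)
    if (inherits(res, "try-error")) {
      msg <- conditionMessage(attr(res, "condition"))
      res <- empty_report_row(entry$id)
      res$error <- msg
    }
    res
  })
  out <- bind_rows(rows)
  if (all(!is.na(out$error))) abort("all manifest entries failed")
  out[, REPORT_COLS]
}

report_entry <- function(entry, cycles, reject_factor, mode) {
  seqs <- read_fasta(entry$fasta)
  seqs <- if (entry$id %in% seqs$id) seqs[seqs$id == entry$id, ] else seqs[1L, ]
  topo <- read_topology_any(entry$topology, sequence_id = entry$id)
  rec <- qty_transform(seqs, topo)

  row <- empty_report_row(entry$id)
  row$pi_native <- rec$pi_native
  row$pi_qty <- rec$pi_variant
  row$mw_native <- rec$mw_native
  row$mw_qty <- rec$mw_variant
  row$total_variation_pct <- rec$total_variation_pct
  row$tm_variation_pct <- rec$tm_variation_pct

  has_structs <- all(c("native_structure", "variant_structure") %in% names(entry)) &&
    !is.na(entry$native_structure) && !is.na(entry$variant_structure) &&
    nzchar(entry$native_structure) && nzchar(entry$variant_structure)
  if (has_structs) {
    a <- read_structure(entry$native_structure)
    b <- read_structure(entry$variant_structure)
    chain_a <- entry_chain(entry, "chain_native")
    chain_b <- entry_chain(entry, "chain_variant")
    sup <- superpose_structures(a, b, chain_a, chain_b, mode = mode,
                                cycles = cycles, reject_factor = reject_factor)
    row$rmsd_all <- sup$rmsd_all
    row$rmsd_refined <- sup$rmsd_refined
    row$n_pairs_used <- sup$n_used_pairs
    sup_tm <- superpose_structures(a, b, chain_a, chain_b, mode = mode,
                                   tm_only = TRUE, topology = topo,
                                   cycles = cycles, reject_factor = reject_factor)
    row$tm_rmsd_all <- sup_tm$rmsd_all
    row$tm_rmsd_refined <- sup_tm$rmsd_refined
    row$tm_n_pairs_used <- sup_tm$n_used_pairs
  }
  row
}

entry_chain <- function(entry, field) {
  if (field %in% names(entry) && !is.na(entry[[field]]) && nzchar(entry[[field]])) {
    entry[[field]]
  } else {
    NULL
  }
}

empty_report_row <- function(id) {
  tibble(
    id = id, pi_native = NA_real_, pi_qty = NA_real_,
    mw_native = NA_real_, mw_qty = NA_real_,
    total_variation_pct = NA_real_, tm_variation_pct = NA_real_,
    rmsd_all = NA_real_, rmsd_refined = NA_real_, n_pairs_used = NA_integer_,
    tm_rmsd_all = NA_real_, tm_rmsd_refined = NA_real_,
    tm_n_pairs_used = NA_integer_, error = NA_character_
  )
}

# Read a topology file whichever dialect it is in: UniProt-style lines if
# any line matches TRANSMEM, otherwise 2-column (start, end) or 3-column
# (sequence_id, start, end) TSV.
read_topology_any <- function(path, sequence_id = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("TRANSMEM", lines))) {
    return(read_topology(path, "uniprot", sequence_id = sequence_id))
  }
  lines <- lines[nzchar(trimws(lines))]
  fields <- str_split(lines, "\\t")
  nf <- vapply(fields, length, integer(1))
  if (all(nf >= 3L)) {
    df <- data.frame(
      sequence_id = vapply(fields, `[[`, character(1), 1L),
      start = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L))),
      end = suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
    )
    if (anyNA(df$start) || anyNA(df$end)) abort("non-numeric field in topology")
    if (!is.na(sequence_id)) df <- df[df$sequence_id == sequence_id, , drop = FALSE]
    if (nrow(df) == 0L) abort(paste0("no topology rows for '", sequence_id, "'"))
    return(tm_topology(df))
  }
  read_topology(path, "tsv", sequence_id = sequence_id)
}

#' Apply the QTY code to a FASTA file
#'
#' Batch counterpart of [qty_transform()] working on files: reads a
#' (possibly multi-record) FASTA and a topology file, writes the variant
#' sequences (ids suffixed `_QTY`) as FASTA and the substitution list as
#' TSV (`id`, `position`, `from`, `to`). Records whose topology is
#' missing or invalid are skipped with their error recorded; the others
#' are still written.
#'
#' @param fasta Input FASTA path.
#' @param topology Topology path (UniProt-style, 2-column TSV for a
#'   single-record FASTA, or 3-column `id<TAB>start<TAB>end` TSV).
#' @param out_prefix Output prefix; writes `<prefix>_qty.fasta` and
#'   `<prefix>_substitutions.tsv`.
#' @return Invisibly, a list with `records` (the [qty_transform()] tibble
#'   including any `error` rows), `fasta` and `tsv` (output paths) and
#'   `ok` (`TRUE` when every record succeeded).
#' @export
run_transform <- function(fasta, topology, out_prefix) {
  seqs <- read_fasta(fasta)
  lines <- readLines(topology, warn = FALSE)
  multi <- !any(grepl("TRANSMEM", lines)) &&
    all(vapply(str_split(lines[nzchar(trimws(lines))], "\\t"), length, integer(1)) >= 3L)
  topo <- if (multi) {
    read_topology_any(topology)
  } else {
    if (nrow(seqs) > 1L) {
      abort("multi-record FASTA requires a 3-column (id, start, end) topology")
    }
    read_topology_any(topology, sequence_id = seqs$id[[1L]])
  }
  rec <- qty_transform(seqs, topo, allow_missing = TRUE)

  ok <- is.na(rec$error)
  if (!any(ok)) abort("every record failed to transform")
  out_fasta <- paste0(out_prefix, "_qty.fasta")
  out_tsv <- paste0(out_prefix, "_substitutions.tsv")
  write_fasta(
    tibble(id = paste0(rec$id[ok], "_QTY"), seq = rec$variant[ok]),
    out_fasta
  )
  subs <- bind_rows(map(which(ok), function(i) {
    mutate(rec$substitutions[[i]], id = rec$id[[i]], .before = 1L)
  }))
  utils::write.table(subs, out_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(records = rec, fasta = out_fasta, tsv = out_tsv, ok = all(ok)))
}

#' Write a report table as TSV or JSON
#'
#' @param report A report tibble from [run_report()].
#' @param path Output path; format picked by extension (`.json` vs TSV).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.table(report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
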