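# Rigid-body superposition: closed-form Kabsch fit (SVD with reflection
# correction) plus PyMOL-style iterative outlier rejection, and the
# residue-correspondence and transmembrane-extraction steps that feed it.

#' Pair residues between two structures
#'
#' Builds the ordered one-to-one residue correspondence used for
#' superposition, restricted to residues that possess a C-alpha atom in
#' both models. `by_resnum` pairs residues sharing the same residue number
#' and insertion code - with real structures this reproduces the usual
#' loop trimming, since residues unresolved in either model simply drop
#' out. `by_position` pairs the i-th C-alpha with the i-th C-alpha up to
#' the shorter chain length.
#'
#' @param a,b Atom tibbles (see [read_structure()]).
#' @param mode `"by_resnum"` or `"by_position"`.
#' @param chain_a,chain_b Chain identifiers; `NULL` means the first chain
#'   in file order.
#' @return A tibble with one row per pair: `res_seq_a`, `icode_a`,
#'   `res_seq_b`, `icode_b` and the paired coordinates `xa`,`ya`,`za`,
#'   `xb`,`yb`,`zb`, sorted by position in chain a.
#' @export
build_correspondence <- function(a, b, mode = c("by_resnum", "by_position"),
                                 chain_a = NULL, chain_b = NULL) {
  mode <- match.arg(mode)
  ca_a <- ca_table(a, chain_a)
  ca_b <- ca_table(b, chain_b)
  if (mode == "by_resnum") {
    pairs <- inner_join(
      ca_a |> select(res_seq_a = "res_seq", icode_a = "icode",
                     xa = "x", ya = "y", za = "z"),
      ca_b |> select(res_seq_b = "res_seq", icode_b = "icode",
                     xb = "x", yb = "y", zb = "z"),
      by = c(res_seq_a = "res_seq_b", icode_a = "icode_b"),
      keep = TRUE
    ) |>
      arrange(.data$res_seq_a, .data$icode_a)
  } else {
    k <- min(nrow(ca_a), nrow(ca_b))
    pairs <- tibble(
      res_seq_a = ca_a$res_seq[seq_len(k)], icode_a = ca_a$icode[seq_len(k)],
      res_seq_b = ca_b$res_seq[seq_len(k)], icode_b = ca_b$icode[seq_len(k)],
      xa = ca_a$x[seq_len(k)], ya = ca_a$y[seq_len(k)], za = ca_a$z[seq_len(k)],
      xb = ca_b$x[seq_len(k)], yb = ca_b$y[seq_len(k)], zb = ca_b$z[seq_len(k)]
    )
  }
  if (nrow(pairs) == 0L) abort("empty residue correspondence")
  pairs
}

#' Optimal rigid superposition of paired coordinates (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' \eqn{\sum_i \|p_i - (R q_i + t)\|^2} by the closed-form SVD solution:
#' centre both sets, decompose the covariance, and correct a reflection by
#' flipping the sign of the smallest singular vector so that
#' \eqn{\det(R) = +1} always.
#'
#' @param p,q Numeric n-by-3 matrices of paired coordinates (q is fitted
#'   onto p); n must be at least 3 and the points not all collinear.
#' @return A `qty_superposition` object; see [refine_superpose()] for the
#'   fields. For a plain Kabsch fit `rmsd_refined` equals `rmsd_all`.
#' @export
kabsch_superpose <- function(p, q) {
  fit <- kabsch_fit(p, q)
  new_superposition(
    rotation = fit$rotation, translation = fit$translation,
    n_input_pairs = nrow(p), n_used_pairs = nrow(p),
    rmsd_all = fit$rmsd, rmsd_refined = fit$rmsd,
    cycle_log = tibble(cycle = 0L, n_pairs = nrow(p), rmsd = fit$rmsd),
    used = rep(TRUE, nrow(p))
  )
}

# Core closed-form fit; returns rotation, translation, rmsd.
kabsch_fit <- function(p, q) {
  p <- as.matrix(p)
  q <- as.matrix(q)
  if (!all(dim(p) == dim(q))) abort("coordinate sets differ in size")
  n <- nrow(p)
  if (n < 3L) abort("need at least 3 point pairs for a rigid fit")
  pc <- colMeans(p)
  qc <- colMeans(q)
  pp <- sweep(p, 2L, pc)
  qq <- sweep(q, 2L, qc)
  h <- crossprod(qq, pp) # 3x3 covariance, maps q-frame to p-frame
  if (svd_rank_deficient(h)) abort("degenerate (collinear) configuration")
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- pc - as.numeric(rot %*% qc)
  moved <- qq %*% t(rot)
  rmsd <- sqrt(sum((pp - moved)^2) / n)
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

svd_rank_deficient <- function(h) {
  d <- svd(h, nu = 0, nv = 0)$d
  d[2L] <= max(d[1L], 1) * 1e-12
}

#' Superposition with iterative outlier rejection
#'
#' Emulates refinement as done by interactive alignment tools: fit all
#' pairs (cycle 0, reported as `rmsd_all`), then repeatedly discard pairs
#' whose post-fit distance exceeds `reject_factor` times the current RMSD
#' and refit on the survivors. Iteration stops after `cycles` rounds, when
#' a round discards nothing, or when fewer than 3 pairs would remain. The
#' RMSD over retained pairs is non-increasing across cycles.
#'
#' @inheritParams kabsch_superpose
#' @param cycles Maximum refinement rounds (default 5); 0 disables
#'   rejection.
#' @param reject_factor Distance cutoff in multiples of the current RMSD
#'   (default 2.0).
#' @return A `qty_superposition` object with fields `rotation` (3x3 proper
#'   orthogonal), `translation` (length-3, Angstrom), `n_input_pairs`,
#'   `n_used_pairs`, `rmsd_all` (cycle-0 RMSD over all pairs),
#'   `rmsd_refined` (final RMSD over retained pairs), `cycle_log`
#'   (tibble: cycle, n_pairs, rmsd) and `used` (logical retention mask
#'   over the input pairs).
#' @export
refine_superpose <- function(p, q, cycles = 5L, reject_factor = 2.0) {
  p <- as.matrix(p)
  q <- as.matrix(q)
  fit <- kabsch_fit(p, q)
  n <- nrow(p)
  used <- rep(TRUE, n)
  log <- tibble(cycle = 0L, n_pairs = n, rmsd = fit$rmsd)
  rmsd_all <- fit$rmsd
  current <- fit
  if (cycles > 0L) {
    for (cyc in seq_len(cycles)) {
      moved <- sweep(q %*% t(current$rotation), 2L, current$translation, "+")
      dist <- sqrt(rowSums((p - moved)^2))
      cutoff <- reject_factor * current$rmsd
      drop <- used & dist > cutoff
      if (!any(drop)) break
      if (sum(used & !drop) < 3L) break
      used <- used & !drop
      current <- kabsch_fit(p[used, , drop = FALSE], q[used, , drop = FALSE])
      log <- bind_rows(log, tibble(cycle = cyc, n_pairs = sum(used),
                                   rmsd = current$rmsd))
    }
  }
  new_superposition(
    rotation = current$rotation, translation = current$translation,
    n_input_pairs = n, n_used_pairs = sum(used),
    rmsd_all = rmsd_all, rmsd_refined = current$rmsd,
    cycle_log = log, used = used
  )
}

new_superposition <- function(rotation, translation, n_input_pairs,
                              n_used_pairs, rmsd_all, rmsd_refined,
                              cycle_log, used, transformed = NULL) {
  structure(
    list(
      rotation = rotation, translation = as.numeric(translation),
      n_input_pairs = n_input_pairs, n_used_pairs = n_used_pairs,
      rmsd_all = rmsd_all, rmsd_refined = rmsd_refined,
      cycle_log = cycle_log, used = used, transformed = transformed
    ),
    class = "qty_superposition"
  )
}

#' Apply a rigid transform to an atom tibble
#'
#' @param model An atom tibble.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation vector (Angstrom).
#' @return The model with transformed coordinates.
#' @export
apply_transform <- function(model, rotation, translation) {
  xyz <- as.matrix(model[, c("x", "y", "z")])
  moved <- sweep(xyz %*% t(rotation), 2L, as.numeric(translation), "+")
  model$x <- moved[, 1L]
  model$y <- moved[, 2L]
  model$z <- moved[, 3L]
  model
}

#' Extract the transmembrane domain of a structure
#'
#' Keeps exactly the atoms of residues whose residue number falls inside
#' some transmembrane span of the topology (one chain at a time), the
#' structural counterpart of restricting the sequence analysis to the TM
#' helices. Spans reaching past the resolved residues intersect silently
#' down to what is present (with a warning).
#'
#' @param model An atom tibble.
#' @param topo A topology tibble with at least one span.
#' @param chain Chain id; `NULL` means the first chain in file order.
#' @return The filtered atom tibble.
#' @export
extract_tm_domain <- function(model, topo, chain = NULL) {
  if (nrow(topo) == 0L) abort("empty topology: no transmembrane span to extract")
  if (is.null(chain)) chain <- model$chain[[1L]]
  if (!chain %in% model$chain) abort(paste0("chain '", chain, "' not present"))
  sub <- filter(model, .data$chain == !!chain)
  in_span <- rep(FALSE, nrow(sub))
  for (i in seq_len(nrow(topo))) {
    in_span <- in_span | (sub$res_seq >= topo$start[i] & sub$res_seq <= topo$end[i])
  }
  covered <- unique(sub$res_seq[in_span])
  wanted <- sum(topo$end - topo$start + 1L)
  if (length(covered) < wanted) {
    warning(sprintf("only %d of %d transmembrane residues are resolved in the model",
                    length(covered), wanted), call. = FALSE)
  }
  out <- sub[in_span, , drop = FALSE]
  if (nrow(out) == 0L) abort("no transmembrane residue resolved in the model")
  out
}

#' Superpose two structures
#'
#' End-to-end superposition of chain `chain_b` of model `b` onto chain
#' `chain_a` of model `a`: monomer selection, optional restriction to the
#' transmembrane domain, residue correspondence over shared C-alpha atoms,
#' and Kabsch fitting with iterative outlier rejection. The returned
#' object carries the transformed copy of `b` (all atoms of the selected
#' chain) for inspection or writing.
#'
#' @param a,b Atom tibbles (the fit moves `b` onto `a`).
#' @param chain_a,chain_b Chain ids (`NULL`: first chain in file order).
#' @param mode Residue pairing mode, see [build_correspondence()].
#' @param tm_only If `TRUE`, restrict the fit to transmembrane residues.
#' @param topology Topology tibble; required when `tm_only = TRUE`.
#' @param cycles,reject_factor Refinement settings, see
#'   [refine_superpose()].
#' @return A `qty_superposition` object (see [refine_superpose()]), with
#'   `transformed` set to the moved copy of `b`.
#' @export
superpose_structures <- function(a, b, chain_a = NULL, chain_b = NULL,
                                 mode = c("by_resnum", "by_position"),
                                 tm_only = FALSE, topology = NULL,
                                 cycles = 5L, reject_factor = 2.0) {
  mode <- match.arg(mode)
  if (is.null(chain_a)) chain_a <- a$chain[[1L]]
  if (is.null(chain_b)) chain_b <- b$chain[[1L]]
  sel_a <- filter(a, .data$chain == !!chain_a)
  sel_b <- filter(b, .data$chain == !!chain_b)
  if (nrow(sel_a) == 0L) abort(paste0("chain '", chain_a, "' not present in a"))
  if (nrow(sel_b) == 0L) abort(paste0("chain '", chain_b, "' not present in b"))
  if (tm_only) {
    if (is.null(topology)) abort("tm_only = TRUE requires a topology")
    sel_a <- extract_tm_domain(sel_a, topology, chain_a)
    sel_b <- extract_tm_domain(sel_b, topology, chain_b)
  }
  pairs <- build_correspondence(sel_a, sel_b, mode, chain_a, chain_b)
  res <- refine_superpose(
    as.matrix(pairs[, c("xa", "ya", "za")]),
    as.matrix(pairs[, c("xb", "yb", "zb")]),
    cycles = cycles, reject_factor = reject_factor
  )
  res$transformed <- apply_transform(filter(b, .data$chain == !!chain_b),
                                     res$rotation, res$translation)
  res
}

#' @export
print.qty_superposition <- function(x, ...) {
  cat("Rigid superposition (Kabsch + outlier rejection)\n")
  cat(sprintf("  pairs: %d input, %d used\n", x$n_input_pairs, x$n_used_pairs))
  cat(sprintf("  RMSD:  %.3f A (all pairs), %.3f A (refined)\n",
              x$rmsd_all, x$rmsd_refined))
  cat(sprintf("  cycles run: %d\n", max(x$cycle_log$cycle)))
  invisible(x)
}

#' @describeIn refine_superpose `tidy()` returns the per-cycle log
#'   (`cycle`, `n_pairs`, `rmsd`).
#' @param x A `qty_superposition` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qty_superposition <- function(x, ...) x$cycle_log

#' @describeIn refine_superpose `glance()` returns a one-row summary
#'   (`n_input_pairs`, `n_used_pairs`, `rmsd_all`, `rmsd_refined`,
#'   `n_cycles`, `det_rotation`).
#' @exportS3Method generics::glance
glance.qty_superposition <- function(x, ...) {
  tibble(
    n_input_pairs = x$n_input_pairs, n_used_pairs = x$n_used_pairs,
    rmsd_all = x$rmsd_all, rmsd_refined = x$rmsd_refined,
    n_cycles = max(x$cycle_log$cycle), det_rotation = det(x$rotation)
  )
}

#' @describeIn refine_superpose `autoplot()` shows RMSD and retained pair
#'   count across refinement cycles.
#' @param object A `qty_superposition` object.
#' @exportS3Method ggplot2::autoplot
autoplot.qty_superposition <- function(object, ...) {
  ggplot(object$cycle_log, aes(x = .data$cycle, y = .data$rmsd)) +
    geom_line(colour = "grey40") +
    geom_point(aes(size = .data$n_pairs), colour = "#2166ac") +
    labs(
      x = "refinement cycle", y = "RMSD over retained pairs (Å)",
      size = "pairs",
      title = "Superposition refinement"
    ) +
    theme_minimal()
}
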