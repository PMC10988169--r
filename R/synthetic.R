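# Synthetic multi-pass membrane proteins: hydrophobic-helix/polar-loop
# sequences with matching transmembrane annotations and consistent
# alpha-helical bundle coordinates. Stands in for database downloads so
# the whole pipeline is testable offline.

#' Specification of a synthetic membrane protein
#'
#' Defaults emulate a mid-sized multi-pass transporter domain: 6
#' transmembrane helices of 22 residues (the span of a lipid bilayer at
#' 1.5 A rise per residue) joined by 6-residue loops, with helices drawn
#' from a hydrophobic-enriched composition (L/I/V/F/A/G-heavy) and loops
#' from a polar-enriched one. Real transporters carry 5-11 membrane
#' helices per transmembrane domain; `n_helices` accepts 2-12.
#'
#' @param n_helices Number of transmembrane helices (2-12, default 6).
#' @param helix_len Residues per helix (default 22).
#' @param loop_len Residues per loop; loops flank every helix, so there
#'   are `n_helices + 1` of them (default 6).
#' @param tm_composition,loop_composition Named probability vectors over
#'   the canonical alphabet; each must sum to 1.
#' @param seed Integer seed making the generated protein reproducible.
#' @return A `bundle_spec` list.
#' @export
bundle_spec <- function(n_helices = 6L, helix_len = 22L, loop_len = 6L,
                        tm_composition = NULL, loop_composition = NULL,
                        seed = 1L) {
  if (n_helices < 2L || n_helices > 12L) abort("n_helices must be in 2..12")
  if (helix_len < 1L || loop_len < 1L) abort("helix_len and loop_len must be >= 1")
  if (is.null(tm_composition)) {
    tm_composition <- c(
      L = 0.22, I = 0.13, V = 0.13, F = 0.10, A = 0.14, G = 0.08,
      S = 0.05, T = 0.05, M = 0.04, W = 0.03, Y = 0.03
    )
  }
  if (is.null(loop_composition)) {
    loop_composition <- c(
      S = 0.12, T = 0.10, N = 0.10, Q = 0.10, D = 0.09, E = 0.09,
      K = 0.09, R = 0.08, G = 0.08, P = 0.07, H = 0.04, A = 0.04
    )
  }
  check_composition(tm_composition, "tm_composition")
  check_composition(loop_composition, "loop_composition")
  structure(
    list(
      n_helices = as.integer(n_helices), helix_len = as.integer(helix_len),
      loop_len = as.integer(loop_len), tm_composition = tm_composition,
      loop_composition = loop_composition, seed = as.integer(seed)
    ),
    class = "bundle_spec"
  )
}

check_composition <- function(comp, what) {
  if (is.null(names(comp)) || !all(names(comp) %in% AA_ALPHABET)) {
    abort(paste0(what, " must be named with canonical one-letter codes"))
  }
  if (any(comp < 0) || abs(sum(comp) - 1) > 1e-9) {
    abort(paste0(what, " probabilities must be non-negative and sum to 1"))
  }
}

#' Ideal alpha-helix geometry constants
#'
#' @param rise Rise per residue along the helix axis, Angstrom
#'   (default 1.5).
#' @param twist Rotation per residue about the axis, degrees
#'   (default 100).
#' @param ca_radius Distance of the C-alpha trace from the axis, Angstrom
#'   (default 2.3).
#' @return A `helix_geometry` list.
#' @export
helix_geometry <- function(rise = 1.5, twist = 100, ca_radius = 2.3) {
  if (rise <= 0 || twist <= 0 || ca_radius <= 0) abort("geometry constants must be positive")
  structure(list(rise = rise, twist = twist, ca_radius = ca_radius),
            class = "helix_geometry")
}

# Run code with a private, restored RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic membrane-protein sequence and topology
#'
#' Draws a loop-helix-...-helix-loop sequence: helices from the
#' hydrophobic transmembrane composition, loops from the polar loop
#' composition. The returned topology spans exactly cover the helix
#' segments. Deterministic given `spec$seed`.
#'
#' @param spec A [bundle_spec()].
#' @param id Sequence identifier (default `"synthetic"`).
#' @return A list with `sequence` (tibble: `id`, `description`, `seq`) and
#'   `topology` (tibble, see [tm_topology()]).
#' @export
generate_membrane_protein <- function(spec, id = "synthetic") {
  stopifnot(inherits(spec, "bundle_spec"))
  n <- spec$n_helices
  h <- spec$helix_len
  l <- spec$loop_len
  with_seed(spec$seed, {
    draw <- function(k, comp) {
      paste(sample(names(comp), k, replace = TRUE, prob = comp), collapse = "")
    }
    parts <- character(2L * n + 1L)
    parts[1L] <- draw(l, spec$loop_composition)
    for (k in seq_len(n)) {
      parts[2L * k] <- draw(h, spec$tm_composition)
      parts[2L * k + 1L] <- draw(l, spec$loop_composition)
    }
    seq <- paste(parts, collapse = "")
  })
  starts <- l + (seq_len(n) - 1L) * (h + l) + 1L
  topo <- tm_topology(data.frame(start = starts, end = starts + h - 1L),
                      sequence_id = id, seq_length = nchar(seq))
  list(
    sequence = tibble(id = id,
                      description = sprintf("synthetic %d-helix bundle", n),
                      seq = seq),
    topology = topo
  )
}

#' Generate bundle coordinates for a synthetic membrane protein
#'
#' Builds a C-alpha-only model consistent with the sequence and topology
#' of [generate_membrane_protein()]: each transmembrane helix is an ideal
#' alpha helix with its axis on a circle (10 A spacing between adjacent
#' axes) and alternating up/down orientation, as in an antiparallel
#' helical bundle. Loop residues are deliberately omitted - unresolved,
#' like the unstructured loops of real cryo-EM models - so residue-number
#' correspondence against a full-length annotation exercises the same
#' trimming logic real comparisons need.
#'
#' @param spec A [bundle_spec()].
#' @param geom A [helix_geometry()].
#' @param chain Chain identifier (default `"A"`).
#' @return An atom tibble (see [read_structure()]) with one CA per
#'   transmembrane residue.
#' @export
generate_bundle_structure <- function(spec, geom = helix_geometry(),
                                      chain = "A") {
  stopifnot(inherits(spec, "bundle_spec"))
  gp <- generate_membrane_protein(spec)
  chars <- seq_chars(gp$sequence$seq[[1L]])
  topo <- gp$topology
  n <- spec$n_helices
  h <- spec$helix_len
  axis_r <- if (n == 2L) 5 else 10 / (2 * sin(pi / n))
  twist_rad <- geom$twist * pi / 180

  rows <- map(seq_len(n), function(k) {
    res_seq <- topo$start[k]:topo$end[k]
    j <- seq_len(h)
    up <- k %% 2L == 1L
    zpos <- if (up) (j - 1) * geom$rise else (h - j) * geom$rise
    ang <- j * twist_rad
    cx <- axis_r * cos(2 * pi * (k - 1) / n)
    cy <- axis_r * sin(2 * pi * (k - 1) / n)
    tibble(
      chain = chain, res_seq = res_seq, icode = "",
      res_name = unname(AA_ONE_TO_THREE[chars[res_seq]]),
      atom_name = "CA", element = "C",
      x = cx + geom$ca_radius * cos(ang),
      y = cy + geom$ca_radius * sin(ang),
      z = zpos,
      occupancy = 1, altloc = "", b = 0
    )
  })
  bind_rows(rows)
}

#' Perturb a structure with noise and a rigid motion
#'
#' Adds i.i.d. Gaussian displacement (`sigma` per coordinate, Angstrom)
#' to every atom and then applies a rigid motion, producing matched pairs
#' with known ground truth for superposition benchmarks. Deterministic
#' given `seed`.
#'
#' @param model An atom tibble.
#' @param sigma Noise standard deviation per coordinate (>= 0).
#' @param angles Length-3 rotation angles in radians (applied as
#'   Rz(a3) Ry(a2) Rx(a1)).
#' @param translation Length-3 translation, Angstrom.
#' @param seed Integer seed for the noise.
#' @return The perturbed atom tibble (identical atom identities).
#' @export
perturb_structure <- function(model, sigma = 0, angles = c(0, 0, 0),
                              translation = c(0, 0, 0), seed = 1L) {
  if (sigma < 0) abort("sigma must be non-negative")
  n <- nrow(model)
  noise <- if (sigma > 0) {
    with_seed(seed, matrix(rnorm(3L * n, sd = sigma), ncol = 3L))
  } else {
    matrix(0, nrow = n, ncol = 3L)
  }
  xyz <- as.matrix(model[, c("x", "y", "z")]) + noise
  rot <- euler_rotation(angles)
  moved <- sweep(xyz %*% t(rot), 2L, as.numeric(translation), "+")
  model$x <- moved[, 1L]
  model$y <- moved[, 2L]
  model$z <- moved[, 3L]
  model
}

#' Rotation matrix from Euler angles
#'
#' @param angles Length-3 numeric vector (radians); the rotation is
#'   Rz(angles[3]) Ry(angles[2]) Rx(angles[1]).
#' @return A 3x3 proper rotation matrix.
#' @export
euler_rotation <- function(angles) {
  a <- angles[1L]; b <- angles[2L]; c <- angles[3L]
  rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L)
  ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3L)
  rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3L)
  rz %*% ry %*% rx
}

#' Relabel a structure's residues by the QTY code
#'
#' In-place residue renaming for the relabel-only surrogate used in
#' surface comparisons: coordinates stay fixed (the premise that QTY
#' variants keep the native fold) while LEU/ILE/VAL/PHE residues inside
#' the transmembrane spans become GLN/THR/THR/TYR.
#'
#' @param model An atom tibble.
#' @param topo A topology tibble.
#' @return The relabelled atom tibble.
#' @export
qty_relabel <- function(model, topo) {
  mapping3 <- c(LEU = "GLN", ILE = "THR", VAL = "THR", PHE = "TYR")
  in_span <- rep(FALSE, nrow(model))
  for (i in seq_len(nrow(topo))) {
    in_span <- in_span | (model$res_seq >= topo$start[i] & model$res_seq <= topo$end[i])
  }
  hit <- in_span & model$res_name %in% names(mapping3)
  model$res_name[hit] <- unname(mapping3[model$res_name[hit]])
  model
}
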