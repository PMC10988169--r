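# Solvent-accessible surface area by the Shrake-Rupley method, with a
# deterministic golden-spiral point sphere, and the hydrophobic-surface
# fraction statistic built on it.

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Estimates per-atom SASA by placing `n_points` quasi-uniform test points
#' on each atom's probe-expanded sphere (radius \eqn{r_i + probe}) and
#' counting the points that fall inside no other expanded sphere; the
#' accessible fraction times \eqn{4\pi(r_i+probe)^2} is the atom's area.
#' The point distribution is a deterministic golden spiral, so results are
#' seed-free and exactly reproducible. The neighbour search is
#' cutoff-limited (atoms further apart than the sum of expanded radii
#' cannot occlude one another), which bounds the cost without changing the
#' result. Hydrogens are ignored.
#'
#' @param model An atom tibble (see [read_structure()]).
#' @param probe Probe (solvent) radius in Angstrom, default 1.4.
#' @param n_points Test points per atom, at least 100 (default 960).
#' @param radii Element radius table, see [vdw_radii()].
#' @return A `qty_sasa` object: list with `atoms` (the input atoms plus an
#'   `area` column, in square Angstrom), `residues` (per-residue areas),
#'   `total` (total area) and `parameters`.
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960L,
                               radii = vdw_radii()) {
  if (nrow(model) == 0L) abort("empty model")
  if (probe <= 0) abort("probe radius must be positive")
  if (n_points < 100L) abort("n_points must be at least 100")
  model <- filter(model, .data$element != "H")
  n <- nrow(model)
  r <- unname(radii[model$element])
  r[is.na(r)] <- radii[["default"]]
  re <- r + probe # expanded radii
  xyz <- as.matrix(model[, c("x", "y", "z")])
  sphere <- golden_spiral_points(n_points)

  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    cutoff2 <- (re[i] + re)^2
    nb <- which(d2 < cutoff2 & d2 > 0)
    pts <- sweep(sphere * re[i], 2L, xyz[i, ], "+")
    if (length(nb) == 0L) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        dj2 <- rowSums(sweep(pts, 2L, xyz[j, ])^2)
        buried <- buried | dj2 < re[j]^2
      }
      acc <- sum(!buried)
    }
    area[i] <- 4 * pi * re[i]^2 * acc / n_points
  }

  atoms <- mutate(model, radius = r, area = area)
  residues <- atoms |>
    group_by(.data$chain, .data$res_seq, .data$icode, .data$res_name) |>
    summarise(area = sum(.data$area), .groups = "drop") |>
    arrange(.data$chain, .data$res_seq, .data$icode)
  structure(
    list(
      atoms = atoms, residues = residues, total = sum(area),
      parameters = list(probe = probe, n_points = n_points)
    ),
    class = "qty_sasa"
  )
}

#' Hydrophobic fraction of the solvent-accessible surface
#'
#' The fraction of total SASA contributed by residues of hydrophobic type.
#' This is the package's numeric operationalisation of the visual
#' "hydrophobic surface patch" comparison: relabelling transmembrane
#' L/I/V/F residues to Q/T/Y moves their (unchanged) surface area out of
#' the hydrophobic class, so the fraction strictly decreases whenever a
#' substituted residue is solvent-exposed.
#'
#' @param sasa A `qty_sasa` object.
#' @param hydrophobic_set One-letter codes treated as hydrophobic
#'   (default [HYDROPHOBIC_SET]).
#' @return A fraction in `[0, 1]`.
#' @export
hydrophobic_surface_fraction <- function(sasa, hydrophobic_set = HYDROPHOBIC_SET) {
  stopifnot(inherits(sasa, "qty_sasa"))
  if (sasa$total <= 0) abort("total SASA is zero")
  res <- sasa$residues
  one <- AA_THREE_TO_ONE[res$res_name]
  one[is.na(one)] <- res$res_name[is.na(one)] # tolerate one-letter labels
  sum(res$area[one %in% hydrophobic_set]) / sasa$total
}

#' @export
print.qty_sasa <- function(x, ...) {
  cat("Shrake-Rupley SASA\n")
  cat(sprintf("  atoms: %d, residues: %d\n", nrow(x$atoms), nrow(x$residues)))
  cat(sprintf("  total area: %.1f A^2 (probe %.2f A, %d points/atom)\n",
              x$total, x$parameters$probe, x$parameters$n_points))
  invisible(x)
}

#' @describeIn shrake_rupley_sasa `tidy()` returns the per-residue table
#'   (`chain`, `res_seq`, `icode`, `res_name`, `area`, `hydrophobic`).
#' @param x A `qty_sasa` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qty_sasa <- function(x, ...) {
  res <- x$residues
  one <- AA_THREE_TO_ONE[res$res_name]
  one[is.na(one)] <- res$res_name[is.na(one)]
  mutate(res, hydrophobic = one %in% HYDROPHOBIC_SET)
}

#' @describeIn shrake_rupley_sasa `glance()` returns a one-row summary
#'   (`total_area`, `hydrophobic_fraction`, `n_atoms`, `probe`,
#'   `n_points`).
#' @exportS3Method generics::glance
glance.qty_sasa <- function(x, ...) {
  tibble(
    total_area = x$total,
    hydrophobic_fraction = hydrophobic_surface_fraction(x),
    n_atoms = nrow(x$atoms),
    probe = x$parameters$probe,
    n_points = x$parameters$n_points
  )
}

#' @describeIn shrake_rupley_sasa `autoplot()` shows per-residue area
#'   coloured by hydrophobic class.
#' @param object A `qty_sasa` object.
#' @exportS3Method ggplot2::autoplot
autoplot.qty_sasa <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = .data$res_seq, y = .data$area, fill = .data$hydrophobic)) +
    geom_col(width = 1) +
    labs(x = "residue", y = expression("SASA (" * ring(A)^2 * ")"),
         fill = "hydrophobic",
         title = "Per-residue solvent-accessible surface area") +
    theme_minimal()
}
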