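# Shared fixtures and independent oracles. Everything here is built in
# code at test time; the oracles deliberately avoid the code paths they
# check.

random_sequence <- function(n, alphabet = qtykit::AA_ALPHABET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Minimal atom tibble for toy structures.
toy_model <- function(xyz, res_name = "ALA", chain = "A",
                      res_seq = seq_len(nrow(xyz)), atom_name = "CA",
                      element = "C") {
  tibble::tibble(
    chain = chain, res_seq = as.integer(res_seq), icode = "",
    res_name = rep_len(res_name, nrow(xyz)),
    atom_name = rep_len(atom_name, nrow(xyz)),
    element = rep_len(element, nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, altloc = "", b = 0
  )
}

# Fixed-column PDB ATOM/HETATM line (v3.3 layout).
pdb_line <- function(serial, name, alt, resn, chain, resno, icode,
                     x, y, z, occ = 1, b = 0, elem = "C", type = "ATOM") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, sprintf(" %-3s", name), alt, resn, chain, resno,
          icode, x, y, z, occ, b, elem)
}

# --- pI oracle: dense grid scan of the net-charge curve -------------------
# Re-derives the Bjellqvist charge model from the published constants and
# scans Z(pH): coarse bracket at step 0.01, then a 1e-4-step scan across
# the bracketing interval (valid because Z is strictly decreasing).
grid_scan_pi <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  nt_table <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                V = 7.44, E = 7.70, G = 7.50)
  nt <- if (chars[1] %in% names(nt_table)) nt_table[[chars[1]]] else 7.5
  basic <- c(nt, rep(5.98, sum(chars == "H")), rep(10.0, sum(chars == "K")),
             rep(12.0, sum(chars == "R")))
  acidic <- c(3.55, rep(4.05, sum(chars == "D")), rep(4.45, sum(chars == "E")),
              rep(9.0, sum(chars == "C")), rep(10.0, sum(chars == "Y")))
  z_at <- function(ph) {
    colSums(1 / (1 + 10^(outer(basic, ph, function(a, p) p - a)))) -
      colSums(1 / (1 + 10^(outer(acidic, ph, function(a, p) a - p))))
  }
  coarse <- seq(0, 14, by = 0.01)
  zc <- z_at(coarse)
  i <- max(which(zc > 0))
  fine <- seq(coarse[i], coarse[min(i + 1, length(coarse))], by = 1e-4)
  zf <- z_at(fine)
  j <- max(which(zf > 0))
  (fine[j] + fine[min(j + 1, length(fine))]) / 2
}

# --- molecular weight oracle: atomic composition mass sum -----------------
# Residue atomic compositions (C,H,N,O,S counts of the residue within a
# chain) times IUPAC average atomic masses.
composition_mass <- function(seq) {
  comp <- list(
    A = c(3, 5, 1, 1, 0),  R = c(6, 12, 4, 1, 0), N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),  C = c(3, 5, 1, 1, 1),  E = c(5, 7, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),  G = c(2, 3, 1, 1, 0),  H = c(6, 7, 3, 1, 0),
    I = c(6, 11, 1, 1, 0), L = c(6, 11, 1, 1, 0), K = c(6, 12, 2, 1, 0),
    M = c(5, 9, 1, 1, 1),  F = c(9, 9, 1, 1, 0),  P = c(5, 7, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),  T = c(4, 7, 1, 2, 0),  W = c(11, 10, 2, 1, 0),
    Y = c(9, 9, 1, 2, 0),  V = c(5, 9, 1, 1, 0)
  )
  masses <- c(12.011, 1.008, 14.007, 15.999, 32.06)
  chars <- strsplit(seq, "")[[1]]
  tot <- Reduce(`+`, comp[chars])
  sum(tot * masses) + sum(c(0, 2, 0, 1, 0) * masses) # plus one H2O
}

# --- rigid-fit oracle: direct numerical optimisation ----------------------
# Minimises RMSD over Euler angles (translation eliminated by centring),
# from several starts; independent of the SVD route.
optimizer_rmsd <- function(p, q, n_starts = 8) {
  pc <- colMeans(p); qc <- colMeans(q)
  pp <- sweep(p, 2, pc); qq <- sweep(q, 2, qc)
  obj <- function(ang) {
    r <- qtykit::euler_rotation(ang)
    sqrt(sum((pp - qq %*% t(r))^2) / nrow(p))
  }
  starts <- rbind(c(0, 0, 0),
                  matrix(runif(3 * (n_starts - 1), -pi, pi), ncol = 3))
  best <- Inf
  for (k in seq_len(nrow(starts))) {
    fit <- optim(starts[k, ], obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-15))
    best <- min(best, fit$value)
  }
  best
}

# --- SASA oracle: latitude-longitude quadrature ---------------------------
# Numerically integrates the accessible surface with an equal-angle grid
# and exact per-cell solid angles; independent of the golden-spiral
# point set.
quadrature_sasa <- function(model, probe = 1.4, n_theta = 60, n_phi = 120,
                            radii = qtykit::vdw_radii()) {
  r <- unname(radii[model$element])
  r[is.na(r)] <- radii[["default"]]
  re <- r + probe
  xyz <- as.matrix(model[, c("x", "y", "z")])
  theta_edges <- seq(0, pi, length.out = n_theta + 1)
  theta_mid <- (theta_edges[-1] + theta_edges[-(n_theta + 1)]) / 2
  # solid angle of each latitude band cell
  band_sa <- (cos(theta_edges[-(n_theta + 1)]) - cos(theta_edges[-1])) *
    (2 * pi / n_phi)
  phi_mid <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  grid <- cbind(
    sin(rep(theta_mid, each = n_phi)) * cos(rep(phi_mid, times = n_theta)),
    sin(rep(theta_mid, each = n_phi)) * sin(rep(phi_mid, times = n_theta)),
    cos(rep(theta_mid, each = n_phi))
  )
  w <- rep(band_sa, each = n_phi)
  total <- 0
  for (i in seq_len(nrow(xyz))) {
    pts <- sweep(grid * re[i], 2, xyz[i, ], "+")
    accessible <- rep(TRUE, nrow(pts))
    for (j in seq_len(nrow(xyz))[-i]) {
      dj2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      accessible <- accessible & dj2 >= re[j]^2
    }
    total <- total + re[i]^2 * sum(w[accessible])
  }
  total
}

# Analytic accessible area of two intersecting equal spheres of expanded
# radius R at centre distance d (< 2R): each sphere loses a cap of height
# h = R - d/2.
two_sphere_area <- function(R, d) {
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}
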