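test_that("Kabsch recovers exact rigid motions", {
  set.seed(1)
  p <- matrix(rnorm(30, sd = 5), ncol = 3)
  # identity case
  s0 <- kabsch_superpose(p, p)
  expect_lt(s0$rmsd_all, 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(s0$translation, c(0, 0, 0), tolerance = 1e-10)

  # 90 degrees about z plus a translation: RMSD 0, inverse recovered
  rot90 <- euler_rotation(c(0, 0, pi / 2))
  q <- sweep(p %*% t(rot90), 2, c(1, 2, 3), "+")
  s1 <- kabsch_superpose(p, q)
  expect_lt(s1$rmsd_all, 1e-10)
  expect_equal(s1$rotation %*% rot90, diag(3), tolerance = 1e-8)
})

test_that("rotations are proper and orthonormal, including reflection-prone cases", {
  set.seed(23)
  for (i in 1:30) {
    n <- sample(3:12, 1)
    p <- matrix(rnorm(3 * n, sd = 3), ncol = 3)
    # near-planar clouds invite reflection solutions
    if (i %% 3 == 0) p[, 3] <- p[, 3] * 1e-4
    q <- matrix(rnorm(3 * n, sd = 3), ncol = 3)
    if (i %% 2 == 0) q <- p %*% diag(c(-1, 1, 1)) # mirrored copy
    s <- kabsch_superpose(p, q)
    expect_equal(det(s$rotation), 1, tolerance = 1e-8)
    expect_equal(t(s$rotation) %*% s$rotation, diag(3), tolerance = 1e-8)
  }
})

test_that("Kabsch RMSD matches a direct numerical optimizer", {
  set.seed(31)
  for (i in 1:12) {
    n <- sample(4:12, 1)
    p <- matrix(rnorm(3 * n, sd = 4), ncol = 3)
    q <- p + matrix(rnorm(3 * n, sd = 0.5), ncol = 3)
    s <- kabsch_superpose(p, q)
    expect_equal(s$rmsd_all, optimizer_rmsd(p, q), tolerance = 1e-6)
  }
})

test_that("plain Kabsch RMSD is symmetric in its arguments", {
  set.seed(37)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    p <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    q <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    expect_equal(kabsch_superpose(p, q)$rmsd_all,
                 kabsch_superpose(q, p)$rmsd_all, tolerance = 1e-9)
  }
})

test_that("degenerate and undersized inputs are rejected", {
  line <- cbind(1:5, 1:5, 1:5) * 1.0
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
  p <- matrix(rnorm(6), ncol = 3)
  expect_error(kabsch_superpose(p, p), "at least 3")
  expect_error(kabsch_superpose(matrix(rnorm(12), 4), matrix(rnorm(9), 3)),
               "differ in size")
})

test_that("refinement rejects a planted outlier and logs monotone RMSD", {
  set.seed(43)
  p <- matrix(runif(150, -20, 20), ncol = 3)
  q <- p + matrix(rnorm(150, sd = 0.2), ncol = 3)
  q[7, ] <- q[7, ] + c(20, 0, 0)
  s <- refine_superpose(p, q)
  expect_gt(s$rmsd_all, 1)
  expect_lt(s$rmsd_refined, 0.5)
  expect_false(s$used[7])
  expect_lte(s$n_used_pairs, s$n_input_pairs - 1L)
  # RMSD over retained pairs never increases across cycles
  expect_true(all(diff(s$cycle_log$rmsd) <= 1e-12))
  expect_lte(s$rmsd_refined, s$rmsd_all)
})

test_that("refinement with cycles = 0 or clean data equals plain Kabsch", {
  set.seed(47)
  p <- matrix(rnorm(60, sd = 5), ncol = 3)
  q <- p + matrix(rnorm(60, sd = 0.1), ncol = 3)
  s0 <- refine_superpose(p, q, cycles = 0)
  expect_equal(s0$rmsd_refined, s0$rmsd_all)
  expect_equal(s0$n_used_pairs, nrow(p))

  rot <- euler_rotation(c(0.2, 0.4, -0.1))
  q2 <- sweep(p %*% t(rot), 2, c(3, -2, 1), "+")
  s1 <- refine_superpose(p, q2)
  expect_equal(s1$n_used_pairs, s1$n_input_pairs)
  expect_equal(s1$rmsd_refined, kabsch_superpose(p, q2)$rmsd_all, tolerance = 1e-12)
})

test_that("fit agrees with an established reference implementation", {
  set.seed(53)
  p <- matrix(rnorm(90, sd = 6), ncol = 3)
  q <- p + matrix(rnorm(90, sd = 0.8), ncol = 3)
  ref <- bio3d::fit.xyz(as.numeric(t(p)), as.numeric(t(q)),
                        fixed.inds = 1:90, mobile.inds = 1:90)
  ref_rmsd <- sqrt(mean(colSums(matrix((as.numeric(t(p)) - ref)^2, nrow = 3))))
  expect_equal(kabsch_superpose(p, q)$rmsd_all, ref_rmsd, tolerance = 1e-6)
})

test_that("residue correspondence trims to shared numbering and CA presence", {
  xyz <- cbind(seq(0, 27, 3), 0, 0) + matrix(rnorm(30, sd = 0.2), ncol = 3)
  a <- toy_model(xyz, res_seq = 1:10)
  b <- toy_model(xyz, res_seq = 3:12)
  pairs <- build_correspondence(a, b, "by_resnum")
  expect_equal(nrow(pairs), 8L)
  expect_equal(pairs$res_seq_a, 3:10)

  # identical chains: everything pairs
  expect_equal(nrow(build_correspondence(a, a, "by_resnum")), 10L)

  # a residue lacking CA in b drops out
  b2 <- b
  b2$atom_name[b2$res_seq == 5] <- "CB"
  expect_equal(nrow(build_correspondence(a, b2, "by_resnum")), 7L)

  # by_position pairs i-th with i-th up to the shorter chain
  pairs_pos <- build_correspondence(a, b[1:6, ], "by_position")
  expect_equal(nrow(pairs_pos), 6L)
  expect_equal(pairs_pos$res_seq_b, 3:8)

  expect_error(build_correspondence(a, toy_model(xyz, res_seq = 101:110), "by_resnum"),
               "empty")
})

test_that("transmembrane extraction keeps exactly the span residues", {
  xyz <- matrix(rnorm(150), ncol = 3)
  m <- toy_model(xyz, res_seq = 1:50)
  topo <- tm_topology(data.frame(start = c(10, 30), end = c(20, 40)))
  sub <- extract_tm_domain(m, topo)
  expect_equal(sort(sub$res_seq), c(10:20, 30:40))
  expect_equal(nrow(sub), 22L)

  # span past the resolved residues intersects with a warning
  topo2 <- tm_topology(data.frame(start = 45, end = 60))
  expect_warning(sub2 <- extract_tm_domain(m, topo2), "resolved")
  expect_equal(sort(sub2$res_seq), 45:50)

  expect_error(
    extract_tm_domain(m, tm_topology(data.frame(start = integer(), end = integer()))),
    "empty topology"
  )
})

test_that("whole-structure superposition recovers rigid motions and emits the moved copy", {
  sp <- bundle_spec(seed = 61)
  m <- generate_bundle_structure(sp)
  moved <- perturb_structure(m, sigma = 0, angles = c(0.5, -0.3, 1.2),
                             translation = c(10, -5, 3))
  s <- superpose_structures(m, moved)
  expect_lt(s$rmsd_refined, 1e-6)
  # the transformed copy of b lands back on a
  expect_equal(s$transformed$x, m$x, tolerance = 1e-6)
  expect_equal(s$transformed$z, m$z, tolerance = 1e-6)
  # recovered rotation differs from the inverse truth by < 1e-6 rad
  truth <- euler_rotation(c(0.5, -0.3, 1.2))
  resid <- s$rotation %*% truth
  angle <- acos(pmin(1, (sum(diag(resid)) - 1) / 2))
  expect_lt(angle, 1e-6)
})

test_that("tidy, glance and autoplot expose the refinement result", {
  set.seed(67)
  p <- matrix(rnorm(60, sd = 5), ncol = 3)
  q <- p + matrix(rnorm(60, sd = 0.3), ncol = 3)
  s <- refine_superpose(p, q)
  td <- generics::tidy(s)
  expect_named(td, c("cycle", "n_pairs", "rmsd"))
  gl <- generics::glance(s)
  expect_equal(gl$det_rotation, 1, tolerance = 1e-8)
  expect_equal(gl$rmsd_all, s$rmsd_all)
  expect_s3_class(ggplot2::autoplot(s), "ggplot")
})
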