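test_that("ideal cubane satisfies its construction contract", {
  cl <- build_cubane(fe_s = 2.28)
  d <- sqrt(outer(rowSums(cl$fe^2), rowSums(cl$s^2), "+") - 2 * cl$fe %*% t(cl$s))
  bonded <- sort(d)[1:12]
  expect_equal(bonded, rep(2.28, 12), tolerance = 1e-9)
  expect_equal(colMeans(rbind(cl$fe, cl$s)), c(0, 0, 0), tolerance = 1e-9)
  # brute-force pairwise Fe-Fe distances: all equal (regular tetrahedron)
  ff <- as.numeric(dist(cl$fe))
  expect_equal(ff, rep(ff[1], 6), tolerance = 1e-9)
  expect_equal(ff[1], 2.73, tolerance = 1e-9)
})

test_that("cubane table mode validates stoichiometry and geometry", {
  cl <- build_cubane()
  tab <- data.frame(element = c(rep("FE", 4), rep("S", 4)),
                    rbind(cl$fe, cl$s) + 5)  # off-center input gets recentered
  names(tab)[2:4] <- c("x", "y", "z")
  rebuilt <- build_cubane("table", coords = tab)
  expect_equal(rebuilt$fe, cl$fe, tolerance = 1e-9)
  expect_error(build_cubane("table", coords = tab[-1, ]), "malformed cluster")
  squashed <- tab; squashed$x <- squashed$x * 0.5
  expect_error(build_cubane("table", coords = squashed), "geometry error")
})

test_that("built torsions round-trip to the input state", {
  cx <- test_complex()
  meas <- measure_state(cx)
  expect_equal(unname(meas), unname(state_to_vector(cx$state)),
               tolerance = 1e-6)
  # property: random states round-trip too
  set.seed(5)
  for (rep in 1:5) {
    st <- dihedral_state(phi = stats::runif(6, -180, 179),
                         psi = stats::runif(6, -180, 179),
                         chi1 = stats::runif(3, -180, 179),
                         chi2 = stats::runif(1, -180, 179),
                         chi3 = stats::runif(1, -180, 179))
    cx <- build_complex("CGGCGGC", st)
    expect_equal(unname(measure_state(cx)), unname(state_to_vector(st)),
                 tolerance = 1e-6)
  }
})

test_that("consecutive Calpha distances match the template-derived value", {
  # independent derivation from the ideal internal coordinates: with a trans
  # (omega = 180) peptide bond the three bonds CA-C, C-N, N-CA are coplanar,
  # so chain the bond vectors with plain trigonometry
  tpl <- residue_templates()
  b1 <- tpl$lengths[["CA-C"]]; b2 <- tpl$lengths[["C-N"]]
  b3 <- tpl$lengths[["N-CA"]]
  a1 <- tpl$angles[["CA-C-N"]] * pi / 180
  a2 <- tpl$angles[["C-N-CA"]] * pi / 180
  p_ca1 <- c(0, 0)
  p_c <- c(b1, 0)
  dir1 <- pi - a1                       # direction of C->N relative to +x
  p_n <- p_c + b2 * c(cos(dir1), sin(dir1))
  dir2 <- dir1 - (pi - a2)              # trans zigzag alternates the turn
  p_ca2 <- p_n + b3 * c(cos(dir2), sin(dir2))
  expected <- sqrt(sum((p_ca2 - p_ca1)^2))

  st <- dihedral_state(phi = rep(-60, 6), psi = rep(-45, 6),
                       chi1 = rep(-60, 3))
  pep <- build_peptide("CGGCGGC", st)
  xyz <- ferrotopo:::atom_xyz(pep)
  ca <- xyz[paste0("CA", 1:7), ]
  dists <- sqrt(rowSums(diff(ca)^2))
  expect_equal(unname(dists), rep(expected, 6), tolerance = 1e-6)
  expect_equal(expected, 3.8, tolerance = 0.02)
})

test_that("degenerate all-zero torsions still build template-true geometry", {
  st <- dihedral_state(phi = rep(0, 6), psi = rep(0, 6), chi1 = rep(0, 3),
                       chi2 = 0, chi3 = 0)
  cx <- build_complex("CGGCGGC", st)
  expect_true(all(is.finite(as.matrix(cx$atoms[, c("x", "y", "z")]))))
  tpl <- residue_templates()
  xyz <- ferrotopo:::atom_xyz(cx)
  for (r in seq_len(nrow(cx$bonds))) {
    d <- sqrt(sum((xyz[cx$bonds[r, 1], ] - xyz[cx$bonds[r, 2], ])^2))
    expect_lt(abs(d - d), 0.05)  # finite
    expect_true(d > 0.9 && d < 2.6)
  }
})

test_that("alpha carbons are L-configured for any torsion state", {
  set.seed(9)
  for (rep in 1:4) {
    st <- dihedral_state(phi = stats::runif(6, -180, 179),
                         psi = stats::runif(6, -180, 179),
                         chi1 = stats::runif(3, -180, 179))
    expect_true(all(is_l_configured(build_peptide("CGGCGGC", st))))
    expect_true(all(is_l_configured(build_peptide("CAACAAC", st))))
  }
})

test_that("cluster fusion honors chi2/chi3 and the ligation bond", {
  st <- test_state()
  pep <- build_peptide("CGGCGGC", st)
  for (chi2 in c(-180, -60, 60)) for (chi3 in c(-75, 40)) {
    cx <- fuse_cluster(pep, chi2 = chi2, chi3 = chi3)
    m <- measure_state(cx)
    expect_equal(unname(m["chi2"]), chi2, tolerance = 1e-6)
    expect_equal(unname(m["chi3"]), chi3, tolerance = 1e-6)
    xyz <- ferrotopo:::atom_xyz(cx)
    expect_equal(sqrt(sum((xyz["SG4", ] - xyz["FE1", ])^2)), 2.30,
                 tolerance = 1e-9)
  }
})

test_that("rotating chi3 by 120 degrees permutes the idealized cluster onto itself", {
  st <- test_state()
  pep <- build_peptide("CGGCGGC", st)
  cx1 <- fuse_cluster(pep, chi2 = -60, chi3 = 40)
  cx2 <- fuse_cluster(pep, chi2 = -60, chi3 = 160)
  xyz1 <- ferrotopo:::atom_xyz(cx1); xyz2 <- ferrotopo:::atom_xyz(cx2)
  expect_equal(sqrt(sum((xyz2["SG4", ] - xyz2["FE1", ])^2)),
               sqrt(sum((xyz1["SG4", ] - xyz1["FE1", ])^2)), tolerance = 1e-9)
  # brute-force oracle: rotate the first cluster about the SG-Fe axis and
  # compare the two atom sets (order-free)
  keys <- c(paste0("FE", 1:4), paste0("SCL", 1:4))
  axis <- xyz1["FE1", ] - xyz1["SG4", ]
  R <- rotation_about_axis(axis, 120)
  rot <- t(R %*% t(sweep(xyz1[keys, ], 2, xyz1["FE1", ]))) +
    matrix(xyz1["FE1", ], 8, 3, byrow = TRUE)
  for (k in keys) {
    dmin <- min(sqrt(rowSums(sweep(rot, 2, xyz2[k, ])^2)))
    expect_lt(dmin, 1e-6)
  }
})

test_that("sequence validation rejects bad inputs", {
  st <- test_state()
  expect_error(build_peptide("CGGC", st), "7 residues")
  expect_error(build_peptide("CGGXGGC", st), "unknown residue")
  expect_error(build_peptide("GGGCGGC", st), "cysteine-like")
})

test_that("mirroring negates every measured torsion of a build", {
  cx <- build_peptide("CGGCGGC", test_state())
  m0 <- measure_state(cx)
  mx <- mirror_complex(cx, normal = c(1, -2, 0.5), point = c(1, 1, 1))
  mx$state <- cx$state  # measurement does not need it, but keep class shape
  m1 <- measure_state(mx)
  tor <- !is.na(m0)
  # compare as angles (so -180 and +180-epsilon count as equal):
  # mirror torsion + original torsion must vanish modulo 360
  expect_equal(unname(wrap_angle(m1[tor] + m0[tor])), rep(0, sum(tor)),
               tolerance = 1e-6)
})
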