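toy_pair_complex <- function(r, q_keys = c("CA1", "CA2")) {
  atoms <- data.frame(resno = c(1L, 2L), resid = "GLY", elety = "CA",
                      key = q_keys, elem = "C",
                      x = c(0, r), y = 0, z = 0)
  structure(list(atoms = atoms, bonds = matrix(character(0), 0, 2)),
            class = "conformation")
}

test_that("the Coulomb sum reproduces its closed form", {
  # two unit charges of opposite sign at 3.32 A in vacuum: q1 q2 k / r
  tf <- tempfile(fileext = ".txt")
  writeLines(c("*.CA 1.0", "GLY.CB -1.0"), tf)
  cs <- charge_set(tf)
  atoms <- data.frame(resno = 1L, resid = "GLY", elety = c("CA", "CB"),
                      key = c("CA1", "CB1"), elem = "C",
                      x = c(0, 3.32), y = 0, z = 0)
  cx <- structure(list(atoms = atoms, bonds = matrix(character(0), 0, 2)),
                  class = "conformation")
  expect_equal(electrostatic_energy(cx, cs, dielectric = "constant", eps = 1),
               -332.06 / 3.32, tolerance = 1e-9)
  expect_equal(-332.06 / 3.32, -100.018, tolerance = 1e-3)
  # 1/r scaling: doubling the distance halves the energy
  cx2 <- cx; cx2$atoms$x <- cx$atoms$x * 2
  expect_equal(electrostatic_energy(cx2, cs, dielectric = "constant", eps = 1),
               electrostatic_energy(cx, cs, dielectric = "constant", eps = 1) / 2,
               tolerance = 1e-9)
  # screened model falls off as 1/r^2
  expect_equal(electrostatic_energy(cx2, cs),
               electrostatic_energy(cx, cs) / 4, tolerance = 1e-9)
})

test_that("null charges give exactly zero energy", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c("*.N 0", "*.NT 0", "*.H 0", "*.CA 0", "*.C 0", "*.O 0",
               "*.SG 0", "CYS.CB 0", "CLU.CB 0", "SF4.FE 0", "SF4.S 0"), tf)
  expect_equal(electrostatic_energy(test_complex(), charge_set(tf)), 0)
})

test_that("the shipped charge set reproduces the declared net charge", {
  cs <- charge_set()
  expect_equal(cs$q_fe, 0.6518)
  expect_equal(cs$q_s_cluster, -0.5552)
  expect_equal(cs$q_sg, -0.6042)
  q <- ferrotopo:::atom_charges(test_complex()$atoms, cs)
  expect_equal(sum(q), -1, tolerance = 1e-3)
})

test_that("stabilization is the charged-versus-uncharged difference", {
  cx <- test_complex()
  rep <- cluster_stabilization(cx)
  expect_equal(rep$delta_stabilization,
               rep$e_total_charged - rep$e_total_uncharged_s, tolerance = 1e-9)
  expect_equal(unname(sum(rep$components)), rep$e_total_charged,
               tolerance = 1e-6)
  # brute-force per-pair oracle with sulfide and SG charges zeroed
  cs <- charge_set()
  e_fun <- electrostatic_energy(cx, cs, zero_cluster_s = TRUE, zero_sg = TRUE)
  q <- ferrotopo:::atom_charges(cx$atoms, cs)
  q[cx$atoms$resid == "SF4" & cx$atoms$elem == "S"] <- 0
  q[cx$atoms$elety == "SG"] <- 0
  pr <- ferrotopo:::coulomb_pairs(cx$atoms, cx$bonds, cs)
  xyz <- ferrotopo:::atom_xyz(cx)
  e_ref <- 0
  for (r in seq_len(nrow(pr))) {
    d <- sqrt(sum((xyz[pr$i[r], ] - xyz[pr$j[r], ])^2))
    e_ref <- e_ref + 332.06 * q[pr$i[r]] * q[pr$j[r]] * pr$w[r] / (4 * d^2)
  }
  expect_equal(e_fun, e_ref, tolerance = 1e-9)
})

test_that("stabilization vanishes without backbone charges", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c("*.N 0", "*.NT 0", "*.H 0", "*.CA 0", "*.C 0", "*.O 0",
               "CYS.CB 0", "CLU.CB 0",
               "*.SG -0.6042", "SF4.FE 0.6518", "SF4.S -0.5552"), tf)
  cs0 <- charge_set(tf)
  cx <- test_complex()
  rep <- cluster_stabilization(cx, cs0)
  # only cluster-internal and SG terms remain; they are rigid within the
  # cluster, and the difference retains no peptide-dipole contribution
  cx_far <- cx
  keep <- cx$atoms$resid == "SF4" | cx$atoms$elety == "SG"
  cx_far$atoms$x[!keep] <- cx_far$atoms$x[!keep] + 500
  rep_far <- cluster_stabilization(cx_far, cs0)
  expect_equal(rep$delta_stabilization, rep_far$delta_stabilization,
               tolerance = 1e-6)
})

test_that("a peptide far from the cluster contributes no stabilization", {
  # the difference retains a constant intra-cluster term; the peptide's
  # contribution must fall to the long-range tail once it is far away
  cx <- test_complex()
  shift <- function(d) {
    out <- cx
    pep <- out$atoms$resid != "SF4"
    out$atoms$x[pep] <- out$atoms$x[pep] + d
    cluster_stabilization(out)$delta_stabilization
  }
  expect_equal(shift(5000), shift(10000), tolerance = 1e-5)
  expect_false(isTRUE(all.equal(shift(0), shift(5000), tolerance = 1e-4)))
})

test_that("relaxation is a fixed point at a minimum and descends otherwise", {
  # quadratic toy: two bonded atoms restrained to the reference length
  mk <- function(r) {
    atoms <- data.frame(resno = c(1L, 1L), resid = "GLY", elety = c("N", "CA"),
                        key = c("N1", "CA1"), elem = c("N", "C"),
                        x = c(0, r), y = 0, z = 0)
    structure(list(atoms = atoms, bonds = cbind("N1", "CA1")),
              class = "conformation")
  }
  ref <- mk(1.458)
  at_min <- relax_complex(ref, max_cycles = 500, grad_rms_tol = 1e-6)
  expect_true(at_min$converged)
  expect_equal(ferrotopo:::atom_xyz(at_min$complex), ferrotopo:::atom_xyz(ref),
               tolerance = 1e-6)
  stretched <- relax_complex(mk(2.2), max_cycles = 2000, grad_rms_tol = 1e-8,
                             reference = ref)
  expect_true(stretched$converged)
  xyz <- ferrotopo:::atom_xyz(stretched$complex)
  # converges to the analytic minimum: the reference bond length
  expect_equal(sqrt(sum((xyz[1, ] - xyz[2, ])^2)), 1.458, tolerance = 1e-5)
  expect_lt(stretched$e_final, stretched$e_initial)
})

test_that("relaxing a clashed complex lowers its energy", {
  st <- dihedral_state(phi = rep(0, 6), psi = rep(0, 6), chi1 = rep(0, 3))
  cx <- build_complex("CGGCGGC", st)
  out <- relax_complex(cx, max_cycles = 300, grad_rms_tol = 1e-2)
  expect_lt(out$e_final, out$e_initial)
})

test_that("energies are invariant under rigid motion and mirror", {
  cx <- test_complex()
  e0 <- electrostatic_energy(cx)
  l0 <- lj_energy(cx)
  xyz <- ferrotopo:::random_isometry(ferrotopo:::atom_xyz(cx), seed = 8)
  moved <- cx
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]; moved$atoms$z <- xyz[, 3]
  expect_equal(electrostatic_energy(moved), e0, tolerance = 1e-8)
  expect_equal(lj_energy(moved), l0, tolerance = 1e-8)
  mir <- mirror_complex(cx, normal = c(2, -1, 1))
  expect_equal(electrostatic_energy(mir), e0, tolerance = 1e-8)
  expect_equal(lj_energy(mir), l0, tolerance = 1e-8)
})
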