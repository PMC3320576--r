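# Shared fixtures for the test suite.  Everything is generated in code; no
# stored coordinates.

# A generic non-degenerate dihedral state used wherever any valid state
# will do.
test_state <- function() {
  dihedral_state(phi = c(-60, -60, 60, -60, 60, -60),
                 psi = c(-45, 45, -45, 45, -45, 45),
                 chi1 = c(-60, 60, -180), chi2 = -60, chi3 = 60)
}

test_complex <- function(state = test_state(), sequence = "CGGCGGC") {
  build_complex(sequence, state)
}

# Small grids for exhaustive/pruned comparisons: a named list of frozen
# values keeps the rest of the torsions fixed at chain-like angles.
small_frozen <- function(...) {
  base <- c(phi2 = -60, phi3 = -60, phi4 = -60, phi5 = -60, phi6 = -60,
            phi7 = -60, psi1 = -45, psi2 = -45, psi3 = -45, psi4 = -45,
            psi5 = -45, psi6 = -45, chi11 = -60, chi14 = -60, chi17 = -60,
            chi2 = -180, chi3 = -180)
  ov <- c(...)
  base[names(ov)] <- ov
  base
}

small_grid <- function(free, ...) {
  grid_spec(free = free, frozen = small_frozen(...))
}

# Independent torsion measurement (plain arithmetic, no package geometry
# helpers) used as the oracle against measure_dihedral / the builder.
ref_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  c1 <- cr(b1, b2); c2 <- cr(b2, b3)
  x <- sum(c1 * c2)
  y <- sum(cr(c1, c2) * b2 / sqrt(sum(b2^2)))
  d <- atan2(y, x) * 180 / pi
  if (d >= 180) d - 360 else d
}
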