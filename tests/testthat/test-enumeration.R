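test_that("grid cardinality is the exact product of state counts", {
  expect_equal(grid_cardinality(grid_spec()), 3^3 * 6^12)
  one <- small_grid("phi5")
  expect_equal(grid_cardinality(one), 6)
  # brute-force oracle: exhaustively enumerate a 2-backbone + 1-chi grid
  sp <- small_grid(c("phi3", "psi5", "chi14"))
  states <- iterate_grid(sp)
  expect_equal(nrow(unique(as.data.frame(states))), grid_cardinality(sp))
  expect_equal(grid_cardinality(sp), 6 * 6 * 3)
})

test_that("grid iteration is ordered, complete and restartable", {
  sp <- small_grid(c("psi2", "chi17"))
  full <- iterate_grid(sp)
  expect_equal(nrow(full), grid_cardinality(sp))
  expect_equal(anyDuplicated(as.data.frame(full)), 0L)
  # resume: concatenation of [0, k) and [k, end) equals the full stream
  part1 <- iterate_grid(sp, max_states = 7)
  part2 <- iterate_grid(sp, resume_token = attr(part1, "next_token"))
  expect_equal(rbind(part1[, ], part2[, ]), full[, ])
  expect_true(is.na(attr(part2, "next_token")))
  expect_error(iterate_grid(sp, resume_token = -1), "resume error")
  expect_error(iterate_grid(sp, resume_token = 1e9), "resume error")
})

test_that("the 12-6 term reproduces its closed form", {
  # two atoms at the potential minimum r = 2^(1/6) sigma score exactly -eps
  prm <- lj_params()
  sC <- prm$sigma[prm$element == "C"]; eC <- prm$epsilon[prm$element == "C"]
  r <- 2^(1 / 6) * sC
  atoms <- data.frame(resno = c(1L, 2L), resid = "GLY", elety = "CA",
                      key = c("CA1", "CA2"), elem = "C",
                      x = c(0, r), y = 0, z = 0)
  cx <- structure(list(atoms = atoms, bonds = matrix(character(0), 0, 2)),
                  class = "conformation")
  expect_equal(lj_energy(cx), -eC, tolerance = 1e-12)
  # hand-evaluated 12-6 at another separation
  r2 <- 1.3 * sC
  cx$atoms$x[2] <- r2
  expect_equal(lj_energy(cx),
               4 * eC * ((sC / r2)^12 - (sC / r2)^6), tolerance = 1e-12)
  # beyond an explicit cutoff the contribution is zero
  expect_equal(lj_energy(cx, cutoff = 1.0), 0)
  # deep clash is strongly repulsive
  cx$atoms$x[2] <- 0.4 * sC
  expect_gt(lj_energy(cx), 1e4)
})

test_that("screening separates criteria and reports reasons", {
  cx <- test_complex()
  rec <- screen_complex(cx)
  expect_s3_class(rec, "survivor_record")
  expect_equal(rec$passed, length(rec$reasons) == 0L)
  # boundary strictness: a cutoff equal to the measured distance fails
  d1 <- rec$fe_sg_distances[["res1"]]
  at_boundary <- filter_criteria(fe_sg_max = d1,
                                 cb_sg_fe_angle_range = c(0, 180),
                                 lj_max = Inf)
  expect_false(screen_complex(cx, at_boundary)$passed)
  expect_true("fe_sg_max" %in% screen_complex(cx, at_boundary)$reasons)
  just_above <- filter_criteria(fe_sg_max = max(rec$fe_sg_distances) + 1e-6,
                                cb_sg_fe_angle_range = c(0, 180), lj_max = Inf)
  expect_true(screen_complex(cx, just_above)$passed)
})

test_that("pruned search returns exactly the exhaustive survivor set", {
  loose <- filter_criteria(fe_sg_max = 9, cb_sg_fe_angle_range = c(30, 180),
                           lj_max = 30)
  specs <- list(
    small_grid(c("psi1", "phi4", "psi4", "phi7", "chi11", "chi17")),
    small_grid(c("psi2", "phi5", "chi14"), psi4 = 60),
    grid_spec(sequence = "CAACAAC",
              free = c("psi1", "psi4", "phi7", "chi14"),
              frozen = small_frozen()))
  for (sp in specs) {
    ex <- run_enumeration(sp, loose, mode = "exhaustive")
    pr <- run_enumeration(sp, loose, mode = "pruned")
    expect_equal(pr$survivors, ex$survivors)
  }
  # strict criteria as well (possibly empty survivor sets)
  strict <- filter_criteria()
  sp <- small_grid(c("psi1", "phi4", "psi4", "chi17"))
  expect_equal(run_enumeration(sp, strict, mode = "pruned")$survivors,
               run_enumeration(sp, strict, mode = "exhaustive")$survivors)
})

test_that("survivor and reject counts conserve the states visited", {
  sp <- small_grid(c("psi1", "phi4", "psi4", "phi7"))
  loose <- filter_criteria(fe_sg_max = 8, cb_sg_fe_angle_range = c(20, 180),
                           lj_max = 40)
  res <- run_enumeration(sp, loose, mode = "exhaustive")
  mf <- res$manifest
  expect_equal(mf$states_visited, grid_cardinality(sp))
  # every reject has at least one reason; survivors have none
  expect_gte(mf$reject_counts$fe_sg_max + mf$reject_counts$cb_sg_fe_angle +
               mf$reject_counts$lj_max,
             mf$states_visited - mf$n_survivors)
})

test_that("subsampling is deterministic under its seed", {
  sp <- small_grid(c("psi1", "phi4", "psi4", "phi7", "chi14"))
  loose <- filter_criteria(fe_sg_max = 9, cb_sg_fe_angle_range = c(0, 180),
                           lj_max = 50)
  a <- run_enumeration(sp, loose, mode = "subsampled", n_sample = 300, seed = 42)
  b <- run_enumeration(sp, loose, mode = "subsampled", n_sample = 300, seed = 42)
  expect_identical(a$survivors, b$survivors)
  c <- run_enumeration(sp, loose, mode = "subsampled", n_sample = 300, seed = 43)
  expect_false(identical(a$survivors, c$survivors))
})

test_that("vacuous criteria yield zero survivors", {
  sp <- small_grid(c("psi1", "phi4"))
  none <- filter_criteria(lj_max = -Inf, fe_sg_max = 9,
                          cb_sg_fe_angle_range = c(0, 180))
  expect_equal(nrow(run_enumeration(sp, none, mode = "exhaustive")$survivors), 0L)
})

test_that("relaxing any single criterion never decreases the survivor count", {
  sp <- small_grid(c("psi1", "phi4", "psi4", "phi7"))
  base <- filter_criteria(fe_sg_max = 6, cb_sg_fe_angle_range = c(60, 180),
                          lj_max = 5)
  n0 <- nrow(run_enumeration(sp, base, mode = "exhaustive")$survivors)
  relaxed <- list(filter_criteria(fe_sg_max = 8, cb_sg_fe_angle_range = c(60, 180), lj_max = 5),
                  filter_criteria(fe_sg_max = 6, cb_sg_fe_angle_range = c(30, 180), lj_max = 5),
                  filter_criteria(fe_sg_max = 6, cb_sg_fe_angle_range = c(60, 180), lj_max = 20))
  for (cr in relaxed)
    expect_gte(nrow(run_enumeration(sp, cr, mode = "exhaustive")$survivors), n0)
})

test_that("mirrored survivors keep their LJ energy and geometric pass", {
  sp <- small_grid(c("psi1", "phi4", "psi4", "phi7"))
  loose <- filter_criteria(fe_sg_max = 8, cb_sg_fe_angle_range = c(20, 180),
                           lj_max = 40)
  res <- run_enumeration(sp, loose, mode = "exhaustive")
  sv <- res$survivors
  expect_gt(nrow(sv), 0)
  for (r in seq_len(min(nrow(sv), 5))) {
    v <- as.numeric(sv[r, ferrotopo:::torsion_names()])
    cx <- build_complex("CGGCGGC", ferrotopo:::vector_to_state(v))
    mx <- mirror_complex(cx, normal = c(0.3, 1, -0.7))
    expect_equal(lj_energy(mx, heavy_only = TRUE), sv$lj[r], tolerance = 1e-8)
    # mirrored geometry still satisfies the geometric criteria even though
    # its torsions lie off the L-chiral grid
    xyz <- ferrotopo:::atom_xyz(mx)
    fe <- xyz[paste0("FE", 1:4), ]
    for (res_i in c(1, 7)) {
      dmin <- min(sqrt(rowSums(sweep(fe, 2, xyz[paste0("SG", res_i), ])^2)))
      expect_lt(dmin, loose$fe_sg_max)
    }
  }
})
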