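test_that("leader clustering handles degenerate and far inputs", {
  cx <- test_complex()
  xyz <- ferrotopo:::atom_xyz(cx)
  dup <- deduplicate_conformations(list(xyz, xyz, xyz), 0.5)
  expect_equal(length(dup$representatives), 1L)
  expect_equal(dup$assignment, c(1L, 1L, 1L))
  # superposition removes rigid shifts, so a genuinely different shape is
  # needed for a second cluster
  set.seed(31)
  far <- xyz + matrix(stats::rnorm(length(xyz), 0, 3), nrow(xyz))
  two <- deduplicate_conformations(list(xyz, far), 0.5)
  expect_equal(length(two$representatives), 2L)
  expect_error(deduplicate_conformations(list(xyz, xyz[-1, ])),
               "comparability")
})

test_that("greedy clustering matches a brute-force reimplementation", {
  # independent oracle: all-pairs Kabsch RMSD via SVD, then leader pass
  kabsch_rmsd <- function(a, b) {
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    s <- svd(t(ac) %*% bc)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    sqrt(mean(rowSums((bc - ac %*% t(R))^2)))
  }
  set.seed(13)
  base <- ferrotopo:::atom_xyz(test_complex())
  structs <- lapply(1:10, function(i) {
    x <- base + matrix(stats::rnorm(length(base), 0, sample(c(0.05, 2), 1)),
                       nrow(base))
    ferrotopo:::random_isometry(x)
  })
  thr <- 1.0
  got <- deduplicate_conformations(structs, thr)
  reps <- integer(0); assign <- integer(10)
  for (s in 1:10) {
    hit <- 0L
    for (ci in seq_along(reps)) {
      if (kabsch_rmsd(structs[[reps[ci]]], structs[[s]]) <= thr) { hit <- ci; break }
    }
    if (hit == 0L) { reps <- c(reps, s); hit <- length(reps) }
    assign[s] <- hit
  }
  expect_equal(got$representatives, reps)
  expect_equal(got$assignment, assign)
})

test_that("deduplication is idempotent on its representatives", {
  set.seed(14)
  base <- ferrotopo:::atom_xyz(test_complex())
  structs <- lapply(1:8, function(i)
    base + matrix(stats::rnorm(length(base), 0, 1), nrow(base)))
  first <- deduplicate_conformations(structs, 0.8)
  again <- deduplicate_conformations(structs[first$representatives], 0.8)
  expect_equal(length(again$representatives),
               length(first$representatives))
  expect_equal(again$assignment, seq_along(first$representatives))
})

test_that("backbone windows classify canonical conformations", {
  allR <- classify_conformation(rep(-60, 7), rep(-45, 7))
  expect_true(all(allR$labels == "alphaR"))
  expect_false(allR$is_alpha_sheet)
  alt <- classify_conformation(c(-60, 60, -60, 60, -60, 60, -60),
                               c(-45, 45, -45, 45, -45, 45, -45))
  expect_true(alt$is_alpha_sheet)
  ext <- classify_conformation(rep(-150, 7), rep(150, 7))
  expect_true(all(ext$labels == "other"))
  # termini may be missing without breaking the alternation test
  na_term <- classify_conformation(c(NA, 60, -60, 60, -60, 60, NA),
                                   c(-45, 45, -45, 45, -45, 45, NA))
  expect_true(na_term$is_alpha_sheet)
})

test_that("ensemble summaries count, bin and conserve", {
  tab <- data.frame(index = 1:4, theta = c(30, 60, 120, 150),
                    handedness = c("RIGHT", "RIGHT", "LEFT", "LEFT"),
                    delta_stab = c(-5, -12, -3, -8), n_hs = c(2, 6, 1, 3),
                    mean_hs_dist = c(3.0, 2.8, 3.2, 3.1))
  sm <- summarize_ensemble(tab)
  expect_equal(sm$n_total, 4L)
  expect_equal(sm$n_right, 2L)
  expect_equal(sm$n_left, 2L)
  expect_equal(sum(sm$theta_histogram$count), sm$n_total)
  expect_equal(unname(sm$best_energy), c(-12, -8))
  expect_equal(unname(sm$max_hbonds), c(6, 3))
  # invariant under row permutation
  sm2 <- summarize_ensemble(tab[c(3, 1, 4, 2), ])
  expect_equal(sm2$n_right, sm$n_right)
  expect_equal(sm2$theta_histogram, sm$theta_histogram)
  expect_equal(unname(sm2$best_energy), unname(sm$best_energy))
  # file outputs
  od <- tempfile("sumdir")
  summarize_ensemble(tab, out_dir = od)
  expect_true(file.exists(file.path(od, "theta_hist.tsv")))
  expect_true(file.exists(file.path(od, "energy_vs_nhb.tsv")))
  expect_true(file.exists(file.path(od, "summary.json")))
  expect_warning(summarize_ensemble(tab[0, ]), "empty")
})
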