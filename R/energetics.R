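# Peptide-cluster interaction energetics.
#
# Electrostatics: pairwise Coulomb sum with the conversion constant
# 332.06 kcal*A/(mol*e^2), screened by a distance-dependent dielectric
# eps(r) = 4r by default (a constant-dielectric mode is available).  The
# stabilization of the charged cluster is estimated as the difference of two
# single-point energies: full charges versus cluster-sulfide charges zeroed.
#
# Relaxation: distance-restrained Cartesian minimization of LJ + Coulomb +
# harmonic restraints holding every bonded (1-2) and angle-defining (1-3)
# distance at its template value; quasi-Newton steps with the printed
# stopping criteria (gradient RMS or a cycle cap).

COULOMB_K <- 332.06

coulomb_pairs <- function(meta, bonds, charges = charge_set(),
                          zero_cluster_s = FALSE, zero_sg = FALSE) {
  q <- atom_charges(meta, charges)
  if (zero_cluster_s) q[meta$resid == "SF4" & meta$elem == "S"] <- 0
  if (zero_sg) q[meta$elety == "SG"] <- 0
  n <- nrow(meta)
  A <- matrix(FALSE, n, n)
  A[bonds_as_index(meta, bonds)] <- TRUE
  A <- A | t(A)
  A2 <- (A %*% A) > 0
  A3 <- (A2 %*% A) > 0
  ut <- upper.tri(A)
  keep <- ut & !(A | A2)
  ij <- which(keep, arr.ind = TRUE)
  w <- ifelse((A3 & !(A | A2))[keep], 0.5, 1)
  qq <- q[ij[, 1L]] * q[ij[, 2L]]
  sel <- qq != 0
  data.frame(i = ij[sel, 1L], j = ij[sel, 2L], qq = qq[sel], w = w[sel])
}

bonds_as_index <- function(meta, bonds) {
  cbind(match(bonds[, 1L], meta$key), match(bonds[, 2L], meta$key))
}

#' Electrostatic energy of a structure
#'
#' Pairwise Coulomb sum over nonbonded pairs (1-2/1-3 excluded, 1-4 scaled
#' by 0.5) with conversion constant 332.06 kcal*A/(mol*e^2).  The default
#' dielectric model is distance-dependent, eps(r) = 4r; `"constant"` uses a
#' fixed `eps`.
#'
#' @param cx an `fs_complex` or `conformation`.
#' @param charges a [charge_set()].
#' @param dielectric `"r4"` or `"constant"`.
#' @param eps relative dielectric constant for the constant model.
#' @param zero_cluster_s zero the inorganic sulfide charges.
#' @param zero_sg zero the cysteine Sgamma charges.
#' @return energy in kcal/mol.
#' @export
electrostatic_energy <- function(cx, charges = charge_set(),
                                 dielectric = c("r4", "constant"), eps = 1,
                                 zero_cluster_s = FALSE, zero_sg = FALSE) {
  dielectric <- match.arg(dielectric)
  pr <- coulomb_pairs(cx$atoms, cx$bonds, charges, zero_cluster_s, zero_sg)
  if (!nrow(pr)) return(0)
  xyz <- atom_xyz(cx)
  d <- sqrt(rowSums((xyz[pr$i, , drop = FALSE] - xyz[pr$j, , drop = FALSE])^2))
  if (any(d < 1e-6)) stop("singular distance: overlapping charged atoms")
  if (dielectric == "r4") sum(COULOMB_K * pr$qq * pr$w / (4 * d^2))
  else sum(COULOMB_K * pr$qq * pr$w / (eps * d))
}

#' Electrostatic stabilization of the charged cluster
#'
#' Two single-point evaluations - full charges, then cluster-sulfide
#' charges set to zero - and their difference.  A more negative
#' `delta_stabilization` means the peptide's amide dipoles stabilize the
#' charged cluster more strongly.
#'
#' @inheritParams electrostatic_energy
#' @param params a [lj_params()] table (the LJ component is charge-
#'   independent and cancels in the difference; it is reported as a
#'   component of the totals).
#' @return object of class `energy_report`: `e_total_charged`,
#'   `e_total_uncharged_s`, `delta_stabilization`, and `components`
#'   (electrostatic and LJ of the full-charge evaluation).
#' @export
cluster_stabilization <- function(cx, charges = charge_set(),
                                  dielectric = c("r4", "constant"), eps = 1,
                                  params = lj_params()) {
  dielectric <- match.arg(dielectric)
  e_lj <- lj_energy(cx, params)
  e_full <- electrostatic_energy(cx, charges, dielectric, eps)
  e_zero <- electrostatic_energy(cx, charges, dielectric, eps,
                                 zero_cluster_s = TRUE)
  structure(list(e_total_charged = e_full + e_lj,
                 e_total_uncharged_s = e_zero + e_lj,
                 delta_stabilization = e_full - e_zero,
                 components = c(electrostatic = e_full, lj = e_lj)),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("charged: %.3f  uncharged-S: %.3f  delta: %.3f kcal/mol\n",
              x$e_total_charged, x$e_total_uncharged_s, x$delta_stabilization))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Relaxation

# Assemble the energy model: LJ pairs, Coulomb pairs, and harmonic
# restraints on 1-2 and 1-3 distances (targets = current coordinates, which
# for a freshly built model are the template values).
relax_model <- function(cx, charges, params, dielectric, eps,
                        k_bond = 300, k_angle = 100, reference = cx) {
  meta <- cx$atoms
  n <- nrow(meta)
  A <- matrix(FALSE, n, n)
  A[bonds_as_index(meta, cx$bonds)] <- TRUE
  A <- A | t(A)
  A2 <- ((A %*% A) > 0) & !A
  diag(A2) <- FALSE
  xyz <- atom_xyz(reference)
  ut <- upper.tri(A)
  ij1 <- which(A & ut, arr.ind = TRUE)
  ij2 <- which(A2 & ut, arr.ind = TRUE)
  r0 <- function(ij) sqrt(rowSums((xyz[ij[, 1L], , drop = FALSE] -
                                   xyz[ij[, 2L], , drop = FALSE])^2))
  list(lj = lj_pair_table(meta, cx$bonds, params),
       coul = coulomb_pairs(meta, cx$bonds, charges),
       dielectric = dielectric, eps = eps,
       restr = data.frame(i = c(ij1[, 1L], ij2[, 1L]),
                          j = c(ij1[, 2L], ij2[, 2L]),
                          r0 = c(r0(ij1), r0(ij2)),
                          k = c(rep(k_bond, nrow(ij1)), rep(k_angle, nrow(ij2)))),
       natoms = n)
}

relax_energy_grad <- function(x, model) {
  xyz <- matrix(x, ncol = 3L)
  G <- matrix(0, nrow(xyz), 3L)
  e <- 0
  # restraints
  rr <- model$restr
  if (nrow(rr)) {
    dv <- xyz[rr$i, , drop = FALSE] - xyz[rr$j, , drop = FALSE]
    r <- pmax(sqrt(rowSums(dv^2)), 1e-8)
    e <- e + sum(rr$k * (r - rr$r0)^2)
    s <- 2 * rr$k * (r - rr$r0) / r
    cc <- dv * s
    G <- G + grad_accum(cc, rr$i, rr$j, nrow(xyz))
  }
  lj <- model$lj
  if (nrow(lj)) {
    dv <- xyz[lj$i, , drop = FALSE] - xyz[lj$j, , drop = FALSE]
    r2 <- pmax(rowSums(dv^2), 1e-8)
    s6 <- (lj$sigma^2 / r2)^3
    e <- e + sum(4 * lj$epsilon * lj$weight * (s6^2 - s6))
    dEdr_over_r <- 4 * lj$epsilon * lj$weight * (-12 * s6^2 + 6 * s6) / r2
    G <- G + grad_accum(dv * dEdr_over_r, lj$i, lj$j, nrow(xyz))
  }
  co <- model$coul
  if (nrow(co)) {
    dv <- xyz[co$i, , drop = FALSE] - xyz[co$j, , drop = FALSE]
    r <- pmax(sqrt(rowSums(dv^2)), 1e-8)
    if (model$dielectric == "r4") {
      C <- COULOMB_K * co$qq * co$w / 4
      e <- e + sum(C / r^2)
      G <- G + grad_accum(dv * (-2 * C / r^4), co$i, co$j, nrow(xyz))
    } else {
      C <- COULOMB_K * co$qq * co$w / model$eps
      e <- e + sum(C / r)
      G <- G + grad_accum(dv * (-C / r^3), co$i, co$j, nrow(xyz))
    }
  }
  list(e = e, grad = G)
}

grad_accum <- function(contrib, i, j, n) {
  g <- rowsum(rbind(contrib, -contrib), c(i, j))
  G <- matrix(0, n, 3L)
  G[as.integer(rownames(g)), ] <- g
  G
}

#' Relax a structure by restrained minimization
#'
#' Local Cartesian minimization of LJ + screened Coulomb + harmonic
#' restraints that hold all bonded (1-2) and angle-defining (1-3) distances
#' at their built (template) values; quasi-Newton (L-BFGS) steps.
#' Terminates when the root-mean-square of the Cartesian gradient drops
#' below `grad_rms_tol` or after `max_cycles` function evaluations.
#'
#' @param cx an `fs_complex` or `conformation` with finite coordinates.
#' @param max_cycles cycle cap (default 1e5).
#' @param grad_rms_tol gradient RMS convergence threshold, kcal/mol-A
#'   (default 1e-4).
#' @param charges,params,dielectric,eps energy model parameters.
#' @param k_bond,k_angle restraint force constants (kcal/mol-A^2).
#' @param reference structure supplying the restraint target distances
#'   (default the input itself, whose freshly built geometry carries the
#'   template values).
#' @return list with `complex` (relaxed copy), `converged`, `cycles`,
#'   `e_initial`, `e_final` and `grad_rms`.
#' @export
relax_complex <- function(cx, max_cycles = 1e5, grad_rms_tol = 1e-4,
                          charges = charge_set(), params = lj_params(),
                          dielectric = c("r4", "constant"), eps = 1,
                          k_bond = 300, k_angle = 100, reference = cx) {
  dielectric <- match.arg(dielectric)
  model <- relax_model(cx, charges, params, dielectric, eps, k_bond, k_angle,
                       reference)
  run <- relax_xyz(as.numeric(atom_xyz(cx)), model, max_cycles, grad_rms_tol)
  out <- cx
  xyz <- matrix(run$x, ncol = 3L)
  out$atoms$x <- xyz[, 1L]; out$atoms$y <- xyz[, 2L]; out$atoms$z <- xyz[, 3L]
  out$state <- NULL  # torsions moved off the grid
  list(complex = out, converged = run$converged, cycles = run$cycles,
       e_initial = run$e_initial, e_final = run$e_final,
       grad_rms = run$grad_rms)
}

# Optimization core shared by relax_complex() and the ensemble annotator
# (which reuses one model across many survivors of identical topology).
relax_xyz <- function(x0, model, max_cycles, grad_rms_tol) {
  eg0 <- relax_energy_grad(x0, model)
  if (!is.finite(eg0$e)) stop("invalid structure: non-finite starting energy")
  fn <- function(x) relax_energy_grad(x, model)$e
  gr <- function(x) as.numeric(relax_energy_grad(x, model)$grad)
  x <- x0; cycles <- 0; converged <- FALSE
  grms <- sqrt(mean(eg0$grad^2))
  if (grms < grad_rms_tol) converged <- TRUE
  while (!converged && cycles < max_cycles) {
    step <- min(1000, max_cycles - cycles)
    res <- stats::optim(x, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = step, factr = 10))
    x <- res$par
    cycles <- cycles + step
    grms <- sqrt(mean(relax_energy_grad(x, model)$grad^2))
    if (grms < grad_rms_tol) converged <- TRUE
    else if (res$convergence == 0) break  # optimizer at its own precision limit
  }
  list(x = x, converged = converged, cycles = cycles, e_initial = eg0$e,
       e_final = relax_energy_grad(x, model)$e, grad_rms = grms)
}
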