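# Torsion-grid enumeration with geometric and Lennard-Jones screens.
#
# Three execution modes share one screening definition:
#  * exhaustive - visit every grid state (practical up to ~1e6 states);
#  * pruned     - a staged search that decomposes the screen into a
#                 prefix test (residues 1-4 + cluster; the Sgamma(1)
#                 criteria), a suffix test (residues 4-7; the Sgamma(7)
#                 criteria) and an admissible clash bound, and only
#                 assembles full states for candidates that can still
#                 pass.  Provably returns the identical survivor set;
#  * subsampled - evaluate a seeded uniform draw of grid states.

#' Specify a torsion grid
#'
#' @param sequence 7-residue sequence (positions 1, 4, 7 cysteine-like).
#' @param phi_psi_step step size in degrees for backbone torsions (must
#'   divide 360).
#' @param chi_values the discrete side-chain torsion set, degrees in
#'   `[-180, 180)`.
#' @param free character vector naming the free torsions (subset of
#'   [torsion_names()]); the default frees the 12 backbone torsions and the
#'   3 chi1 rotamers, with chi2/chi3 frozen.
#' @param frozen named numeric vector of values for non-free torsions
#'   (defaults to -180 for any not given).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(sequence = "CGGCGGC", phi_psi_step = 60,
                      chi_values = c(-180, -60, 60),
                      free = setdiff(torsion_names(), c("chi2", "chi3")),
                      frozen = c(chi2 = -180, chi3 = -180)) {
  if (360 %% phi_psi_step != 0) stop("360 must be divisible by phi_psi_step")
  if (!length(chi_values) || any(chi_values < -180 | chi_values >= 180))
    stop("chi_values must be nonempty, each in [-180, 180)")
  bad <- setdiff(free, torsion_names())
  if (length(bad)) stop("unknown torsion name(s): ", paste(bad, collapse = ", "))
  resnames <- check_sequence(sequence)
  bb <- wrap_angle(seq(-180, 179.999, by = phi_psi_step))
  values <- stats::setNames(vector("list", 17L), torsion_names())
  for (nm in torsion_names()) {
    if (nm %in% free) {
      values[[nm]] <- if (grepl("^(phi|psi)", nm)) bb else sort(wrap_angle(chi_values))
    } else {
      v <- if (nm %in% names(frozen)) frozen[[nm]] else -180
      values[[nm]] <- wrap_angle(v)
    }
  }
  structure(list(sequence = sequence, resnames = resnames,
                 phi_psi_step = phi_psi_step, chi_values = sort(wrap_angle(chi_values)),
                 free = free, values = values),
            class = "grid_spec")
}

#' Number of states in a torsion grid
#'
#' The exact product of per-torsion state counts (returned as a double,
#' since production grids exceed the integer range).
#'
#' @param spec a [grid_spec()].
#' @return the grid cardinality as a numeric scalar.
#' @export
grid_cardinality <- function(spec) {
  prod(vapply(spec$values, length, 1L))
}

# Mixed-radix decode: 0-based state indices -> n x 17 torsion matrix.
# Canonical lexicographic order: the first torsion in torsion_names() is the
# most significant digit.
states_from_indices <- function(spec, idx) {
  radix <- vapply(spec$values, length, 1L)
  place <- rev(cumprod(rev(c(radix[-1L], 1))))
  out <- matrix(NA_real_, length(idx), 17L, dimnames = list(NULL, torsion_names()))
  for (j in seq_len(17L)) {
    digit <- floor(idx / place[j]) %% radix[j]
    out[, j] <- spec$values[[j]][digit + 1L]
  }
  out
}

# Inverse: digits (1-based, per torsion) -> 0-based index, as a double.
index_from_digits <- function(spec, digits) {
  radix <- vapply(spec$values, length, 1L)
  place <- rev(cumprod(rev(c(radix[-1L], 1))))
  as.numeric((digits - 1) %*% place)
}

#' Stream grid states in deterministic order
#'
#' Emits grid states in lexicographic order over the canonical torsion
#' order, restartable from a resume token (the 0-based index of the next
#' state to emit).
#'
#' @param spec a [grid_spec()].
#' @param resume_token 0-based index to resume from (default 0).
#' @param max_states maximum number of states to emit in this call.
#' @return numeric matrix (states x 17 torsions) with attributes
#'   `next_token` (index of the first unemitted state, or `NA` when the
#'   grid is exhausted) and `indices` (the 0-based index of each row).
#' @export
iterate_grid <- function(spec, resume_token = 0, max_states = Inf) {
  N <- grid_cardinality(spec)
  if (length(resume_token) != 1L || is.na(resume_token) ||
      resume_token < 0 || resume_token > N || resume_token != floor(resume_token))
    stop("resume error: token must be an integer in [0, ", N, "]")
  n <- min(max_states, N - resume_token)
  idx <- if (n > 0) resume_token + seq_len(n) - 1 else numeric(0L)
  out <- states_from_indices(spec, idx)
  attr(out, "next_token") <- if (resume_token + n < N) resume_token + n else NA_real_
  attr(out, "indices") <- idx
  out
}

# ---------------------------------------------------------------------------
# Lennard-Jones machinery

# Nonbonded pair table for a fixed topology: 1-2 and 1-3 pairs excluded,
# 1-4 pairs scaled by 0.5.  meta/bonds as produced by the builder.
lj_pair_table <- function(meta, bonds, params = lj_params()) {
  n <- nrow(meta)
  A <- matrix(FALSE, n, n, dimnames = list(meta$key, meta$key))
  A[bonds] <- TRUE
  A <- A | t(A)
  A2 <- (A %*% A) > 0
  A3 <- (A2 %*% A) > 0
  ut <- upper.tri(A)
  excl <- (A | A2) & ut
  scal <- A3 & !(A | A2) & ut
  keep <- ut & !excl
  ij <- which(keep, arr.ind = TRUE)
  el <- meta$elem
  pi_ <- match(el[ij[, 1L]], params$element)
  pj_ <- match(el[ij[, 2L]], params$element)
  if (anyNA(pi_) || anyNA(pj_))
    stop("missing Lennard-Jones parameters for element(s): ",
         paste(unique(el[ij[, 1L]][is.na(pi_)]), unique(el[ij[, 2L]][is.na(pj_)])))
  data.frame(i = ij[, 1L], j = ij[, 2L],
             sigma = (params$sigma[pi_] + params$sigma[pj_]) / 2,
             epsilon = sqrt(params$epsilon[pi_] * params$epsilon[pj_]),
             weight = ifelse(scal[keep], 0.5, 1))
}

# 12-6 energy for all states; XYZ is list(X, Y, Z) of n x natoms matrices.
lj_energy_states <- function(XYZ, pairs, cutoff = Inf) {
  n <- nrow(XYZ$X)
  e <- numeric(n)
  co2 <- cutoff^2
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    r2 <- (XYZ$X[, i] - XYZ$X[, j])^2 + (XYZ$Y[, i] - XYZ$Y[, j])^2 +
          (XYZ$Z[, i] - XYZ$Z[, j])^2
    s6 <- (pairs$sigma[r]^2 / r2)^3
    term <- 4 * pairs$epsilon[r] * pairs$weight[r] * (s6^2 - s6)
    if (is.finite(cutoff)) term[r2 > co2] <- 0
    e <- e + term
  }
  e
}

#' Lennard-Jones energy of a structure
#'
#' Sum of 12-6 terms over nonbonded atom pairs (1-2 and 1-3 excluded,
#' 1-4 scaled by 0.5), with Lorentz-Berthelot combination of the
#' per-element parameters.
#'
#' @param cx a `conformation` or `fs_complex`.
#' @param params a [lj_params()] table.
#' @param cutoff optional distance cutoff in Angstrom (pairs beyond it
#'   contribute 0); default no cutoff.
#' @param heavy_only drop pairs involving hydrogen.
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(cx, params = lj_params(), cutoff = Inf,
                      heavy_only = FALSE) {
  pairs <- lj_pair_table(cx$atoms, cx$bonds, params)
  if (heavy_only) {
    el <- cx$atoms$elem
    pairs <- pairs[el[pairs$i] != "H" & el[pairs$j] != "H", , drop = FALSE]
  }
  xyz <- atom_xyz(cx)
  XYZ <- list(X = matrix(xyz[, 1L], 1L), Y = matrix(xyz[, 2L], 1L),
              Z = matrix(xyz[, 3L], 1L))
  lj_energy_states(XYZ, pairs, cutoff = cutoff)
}

#' Screening criteria for enumerated conformations
#'
#' @param fe_sg_max strict upper bound on the terminal Sgamma...Fe distance
#'   (Angstrom).
#' @param cb_sg_fe_angle_range closed CB-SG...Fe angle window, degrees.
#' @param lj_max strict upper bound on the total Lennard-Jones energy
#'   (kcal/mol).
#' @param lj_heavy_only evaluate the screening LJ energy over heavy atoms
#'   only (default `TRUE`: the enumerated models carry amide hydrogens only
#'   for the hydrogen-bond census, so the van der Waals feasibility screen
#'   is a heavy-atom criterion).
#' @return object of class `filter_criteria`.
#' @export
filter_criteria <- function(fe_sg_max = 3.0, cb_sg_fe_angle_range = c(120, 180),
                            lj_max = 0, lj_heavy_only = TRUE) {
  if (any(cb_sg_fe_angle_range < 0 | cb_sg_fe_angle_range > 180))
    stop("angle range must lie within [0, 180]")
  structure(list(fe_sg_max = fe_sg_max,
                 cb_sg_fe_angle_range = sort(cb_sg_fe_angle_range),
                 lj_max = lj_max, lj_heavy_only = isTRUE(lj_heavy_only)),
            class = "filter_criteria")
}

# Pair table restricted to the criteria's atom set.
lj_pairs_for <- function(ctx, criteria) {
  if (!isTRUE(criteria$lj_heavy_only)) return(ctx$pairs)
  keep <- ctx$meta$elem[ctx$pairs$i] != "H" & ctx$meta$elem[ctx$pairs$j] != "H"
  ctx$pairs[keep, , drop = FALSE]
}

# Terminal-cysteine geometry for all states: distance to the nearest Fe and
# the CB-SG...Fe angle at that Fe.  P holds per-atom coordinate matrices.
terminal_geometry_states <- function(P, res) {
  SG <- as_rowmat(P[[paste0("SG", res)]]); CB <- as_rowmat(P[[paste0("CB", res)]])
  n <- max(nrow(SG), nrow(CB),
           vapply(paste0("FE", 1:4), function(k) nrow(as_rowmat(P[[k]])), 1L))
  if (nrow(SG) == 1L && n > 1L) SG <- SG[rep(1L, n), , drop = FALSE]
  if (nrow(CB) == 1L && n > 1L) CB <- CB[rep(1L, n), , drop = FALSE]
  d2 <- matrix(NA_real_, n, 4L)
  for (f in 1:4) {
    FE <- as_rowmat(P[[paste0("FE", f)]])
    if (nrow(FE) == 1L && n > 1L) FE <- FE[rep(1L, n), , drop = FALSE]
    d2[, f] <- row_dot(SG - FE, SG - FE)
  }
  nearest <- max.col(-d2, ties.method = "first")
  FEn <- matrix(NA_real_, n, 3L)
  for (f in 1:4) {
    sel <- nearest == f
    if (any(sel)) FEn[sel, ] <- as_rowmat(P[[paste0("FE", f)]])[if (nrow(as_rowmat(P[[paste0("FE", f)]])) == 1L) rep(1L, sum(sel)) else sel, , drop = FALSE]
  }
  list(dist = sqrt(d2[cbind(seq_len(n), nearest)]),
       angle = measure_angle(CB, SG, FEn),
       nearest = nearest)
}

#' Screen one complex against the filter criteria
#'
#' Evaluates, for each terminal cysteine (residues 1 and 7), the
#' minimum-over-Fe Sgamma...Fe distance and the CB-SG...Fe angle to that
#' nearest Fe, plus the total Lennard-Jones energy.  Failures are recorded
#' as reasons, not errors.
#'
#' @param cx an `fs_complex`.
#' @param criteria a [filter_criteria()].
#' @param params a [lj_params()] table.
#' @return a `survivor_record`: list with `state`, `lj_energy`,
#'   `fe_sg_distances`, `cb_sg_fe_angles`, `nearest_fe`, `passed` and
#'   `reasons` (character vector, empty when passed).
#' @export
screen_complex <- function(cx, criteria = filter_criteria(), params = lj_params()) {
  P <- stats::setNames(lapply(seq_len(nrow(cx$atoms)), function(r)
    as.numeric(cx$atoms[r, c("x", "y", "z")])), cx$atoms$key)
  g1 <- terminal_geometry_states(P, 1L)
  g7 <- terminal_geometry_states(P, 7L)
  e <- lj_energy(cx, params, heavy_only = isTRUE(criteria$lj_heavy_only))
  ar <- criteria$cb_sg_fe_angle_range
  reasons <- character(0L)
  if (!(g1$dist < criteria$fe_sg_max) || !(g7$dist < criteria$fe_sg_max))
    reasons <- c(reasons, "fe_sg_max")
  if (!(g1$angle >= ar[1L] && g1$angle <= ar[2L] &&
        g7$angle >= ar[1L] && g7$angle <= ar[2L]))
    reasons <- c(reasons, "cb_sg_fe_angle")
  if (!(e < criteria$lj_max)) reasons <- c(reasons, "lj_max")
  structure(list(state = cx$state, lj_energy = e,
                 fe_sg_distances = c(res1 = g1$dist, res7 = g7$dist),
                 cb_sg_fe_angles = c(res1 = g1$angle, res7 = g7$angle),
                 nearest_fe = c(res1 = g1$nearest, res7 = g7$nearest),
                 passed = length(reasons) == 0L, reasons = reasons),
            class = "survivor_record")
}
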