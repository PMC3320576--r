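# Post-processing of survivor ensembles: structural deduplication, the
# alphaL/alphaR (alpha-sheet) backbone classification, per-class histograms
# and the hydrogen-bond / energy relationship tables.

#' Deduplicate conformations by best-fit RMSD
#'
#' Greedy leader clustering: structures are taken in input order; each joins
#' the first existing representative within `rmsd_threshold` (best-fit
#' heavy-atom RMSD after least-squares superposition), else founds a new
#' cluster.  Deterministic given input order.
#'
#' @param xyz_list list of coordinate matrices (identical atom ordering), or
#'   a list of `fs_complex` objects.
#' @param rmsd_threshold clustering radius in Angstrom.
#' @return list with `representatives` (indices into the input) and
#'   `assignment` (cluster id per structure).
#' @export
deduplicate_conformations <- function(xyz_list, rmsd_threshold = 0.5) {
  if (!length(xyz_list)) return(list(representatives = integer(0L),
                                     assignment = integer(0L)))
  xyz <- lapply(xyz_list, function(x) {
    if (inherits(x, c("fs_complex", "conformation"))) x <- atom_xyz(x)
    as.numeric(t(x))
  })
  nat <- unique(lengths(xyz))
  if (length(nat) != 1L)
    stop("comparability error: structures have different atom counts")
  reps <- integer(0L)
  assign <- integer(length(xyz))
  for (s in seq_along(xyz)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      r <- suppressWarnings(bio3d::rmsd(xyz[[reps[ci]]], xyz[[s]], fit = TRUE))
      if (r <= rmsd_threshold) { assign[s] <- ci; placed <- TRUE; break }
    }
    if (!placed) { reps <- c(reps, s); assign[s] <- length(reps) }
  }
  list(representatives = reps, assignment = assign)
}

#' Classify per-residue backbone conformation and the alpha-sheet pattern
#'
#' Labels each residue `alphaR` (phi in (-120, 0), psi in (-90, 30)),
#' `alphaL` (phi in (0, 120), psi in (-30, 90)) or `other`; the structure is
#' an alpha-sheet when the interior residues (positions 2-6 of the
#' heptapeptide) strictly alternate between alphaL and alphaR.
#'
#' @param phis,psis per-residue torsions in degrees (length 7 for the
#'   heptapeptide; termini may be `NA`).
#' @return object of class `conformation_label`: list with `labels`
#'   (character vector) and `is_alpha_sheet`.
#' @export
classify_conformation <- function(phis, psis) {
  if (length(phis) != length(psis)) stop("phi/psi lengths differ")
  lab <- rep("other", length(phis))
  aR <- !is.na(phis) & !is.na(psis) &
    phis > -120 & phis < 0 & psis > -90 & psis < 30
  aL <- !is.na(phis) & !is.na(psis) &
    phis > 0 & phis < 120 & psis > -30 & psis < 90
  lab[aR] <- "alphaR"; lab[aL] <- "alphaL"
  interior <- lab[seq(2L, length(lab) - 1L)]
  is_sheet <- all(interior %in% c("alphaL", "alphaR")) &&
    all(interior[-1L] != interior[-length(interior)])
  structure(list(labels = lab, is_alpha_sheet = is_sheet),
            class = "conformation_label")
}

#' Annotate survivors with topology, hydrogen bonds and energetics
#'
#' Rebuilds every surviving conformation from its grid torsions in one
#' vectorized pass and appends the topology angle and handedness, the
#' H-S-rule hydrogen-bond count and mean contact distance, the cluster
#' stabilization energy and the LJ energy.  With `relax = TRUE` the most
#' promising survivors per handedness class (ranked by unrelaxed
#' hydrogen-bond count, ties by stabilization energy) are additionally
#' relaxed and re-measured; `relax_top = Inf` relaxes the whole ensemble.
#'
#' @param survivors survivor data frame from [run_enumeration()].
#' @param sequence the enumerated sequence.
#' @param relax if `TRUE`, relax the selected survivors before measuring.
#' @param relax_top number of survivors per class to relax.
#' @param relax_cycles,relax_tol relaxation settings (desk-scale defaults;
#'   see [relax_complex()] for the strict ones).
#' @param criteria an [hbond_criteria()].
#' @param charges,params energy model tables.
#' @param templates a [residue_templates()] table.
#' @return the survivor data frame with columns `theta`, `handedness`,
#'   `n_hs`, `mean_hs_dist`, `delta_stab`, `e_lj` and `relaxed` appended.
#' @export
annotate_survivors <- function(survivors, sequence = "CGGCGGC", relax = TRUE,
                               relax_top = 50, relax_cycles = 400,
                               relax_tol = 1e-2,
                               criteria = hbond_criteria(),
                               charges = charge_set(), params = lj_params(),
                               templates = residue_templates()) {
  n <- nrow(survivors)
  empty_cols <- function(d) {
    d$theta <- d$n_hs <- d$mean_hs_dist <- numeric(0L)
    d$handedness <- character(0L)
    d$delta_stab <- d$e_lj <- numeric(0L); d$relaxed <- logical(0L)
    d
  }
  if (!n) return(empty_cols(survivors))
  resnames <- check_sequence(sequence)
  resnames[4L] <- "CLU"
  cluster <- default_cubane(templates)
  meta <- rbind(peptide_atom_meta(resnames), cluster_atom_meta())
  bonds <- bond_list(resnames, fused = TRUE, cluster = cluster)
  pairs <- lj_pair_table(meta, bonds, params)

  tormat <- as.matrix(survivors[, torsion_names()])
  tor <- stats::setNames(lapply(torsion_names(), function(nm) tormat[, nm]),
                         torsion_names())
  P <- build_chain_states(resnames, tor, templates, 1:7)
  P <- c(P, fuse_states(P, tor$chi2, tor$chi3, templates, cluster))
  rows <- seq_len(n)
  get <- function(k) {
    m <- as_rowmat(P[[k]])
    if (nrow(m) == 1L) m[rep(1L, n), , drop = FALSE] else m
  }

  # topology angle, vectorized
  CA1 <- get("CA1"); CA4 <- get("CA4"); CA7 <- get("CA7")
  ctr <- Reduce(`+`, lapply(c(paste0("FE", 1:4), paste0("SCL", 1:4)), get)) / 8
  nrm <- row_cross(CA7 - CA1, CA4 - CA1)
  w <- ctr - CA4
  theta <- acos(pmin(1, pmax(-1, row_dot(nrm, w) /
                               (row_norm(nrm) * row_norm(w))))) * 180 / pi
  hand <- classify_handedness(theta)

  # hydrogen bonds, vectorized (H-S rule)
  hb <- hbond_counts_states(P, rows, criteria)

  # stabilization energy: Coulomb terms touching the cluster sulfides
  # (identical to the two-single-point difference, since every other pair's
  # charge product is unchanged by zeroing the sulfides)
  q <- atom_charges(meta, charges)
  pr <- coulomb_pairs(meta, bonds, charges)
  sclS <- which(meta$resid == "SF4" & meta$elem == "S")
  prS <- pr[pr$i %in% sclS | pr$j %in% sclS, , drop = FALSE]
  XYZ <- xyz_mats(P, meta$key, rows)
  dstab <- numeric(n)
  for (r in seq_len(nrow(prS))) {
    i <- prS$i[r]; j <- prS$j[r]
    r2 <- (XYZ$X[, i] - XYZ$X[, j])^2 + (XYZ$Y[, i] - XYZ$Y[, j])^2 +
          (XYZ$Z[, i] - XYZ$Z[, j])^2
    dstab <- dstab + COULOMB_K * prS$qq[r] * prS$w[r] / (4 * r2)
  }
  elj <- lj_energy_states(XYZ, pairs)

  out <- survivors
  out$theta <- theta; out$handedness <- hand
  out$n_hs <- hb$n_hs; out$mean_hs_dist <- hb$mean_hs_dist
  out$delta_stab <- dstab; out$e_lj <- elj
  out$relaxed <- FALSE

  if (relax && n) {
    pick <- unlist(lapply(c("RIGHT", "LEFT"), function(h) {
      cand <- which(out$handedness == h)
      cand[order(-out$n_hs[cand], out$delta_stab[cand])][
        seq_len(min(relax_top, length(cand)))]
    }))
    if (length(pick)) {
      # one shared relaxation model: all survivors have identical topology
      # and template-built restraint targets
      cx0 <- build_complex(sequence, vector_to_state(as.numeric(tormat[pick[1L], ])),
                           templates = templates)
      model <- relax_model(cx0, charges, params, "r4", 1, reference = cx0)
      for (r in pick) {
        cx <- build_complex(sequence, vector_to_state(as.numeric(tormat[r, ])),
                            templates = templates)
        run <- relax_xyz(as.numeric(atom_xyz(cx)), model, relax_cycles,
                         relax_tol)
        xyz <- matrix(run$x, ncol = 3L)
        cx$atoms$x <- xyz[, 1L]; cx$atoms$y <- xyz[, 2L]; cx$atoms$z <- xyz[, 3L]
        tp <- complex_topology(cx)
        census <- find_hbonds(cx, criteria)
        out$theta[r] <- tp$theta; out$handedness[r] <- tp$handedness
        out$n_hs[r] <- census$n_hs
        out$mean_hs_dist[r] <- if (census$n_hs > 0)
          mean(census$contacts$hs_dist[census$contacts$hit_hs]) else NA_real_
        out$delta_stab[r] <-
          cluster_stabilization(cx, charges, params = params)$delta_stabilization
        out$e_lj[r] <- lj_energy(cx, params)
        out$relaxed[r] <- TRUE
      }
    }
  }
  out
}

hist_table <- function(x, width, lo = NULL, hi = NULL) {
  x <- x[is.finite(x)]
  if (!length(x)) return(data.frame(lower = numeric(0L), upper = numeric(0L),
                                    count = integer(0L)))
  if (is.null(lo)) lo <- floor(min(x) / width) * width
  if (is.null(hi)) hi <- ceiling(max(x) / width) * width
  if (hi <= lo) hi <- lo + width
  br <- seq(lo, hi, by = width)
  ct <- table(cut(x, br, include.lowest = TRUE, right = FALSE))
  data.frame(lower = br[-length(br)], upper = br[-1L],
             count = as.integer(ct))
}

#' Summarize an annotated survivor ensemble
#'
#' Class counts, topology-angle and energy histograms per handedness class,
#' per-class best energies and maximum hydrogen-bond counts, plus the
#' energy-versus-geometry scatter tables.  With `out_dir`, writes
#' `summary.json` and the per-figure TSVs (`theta_hist.tsv`,
#' `theta_hist_by_class.tsv`, `energy_hist_by_class.tsv`,
#' `energy_vs_hsdist.tsv`, `energy_vs_nhb.tsv`).
#'
#' @param tab annotated survivor data frame (needs `theta`, `handedness`,
#'   `delta_stab`, `n_hs`, `mean_hs_dist`).
#' @param theta_bin,energy_bin histogram bin widths (degrees, kcal/mol).
#' @param out_dir optional output directory.
#' @return object of class `ensemble_summary`.
#' @export
summarize_ensemble <- function(tab, theta_bin = 5, energy_bin = 5,
                               out_dir = NULL) {
  if (!nrow(tab)) warning("empty survivor table: empty summary")
  cls <- factor(tab$handedness, levels = c("RIGHT", "LEFT", "UNDEFINED"))
  counts <- table(cls)
  per_class <- function(f, col) {
    vapply(c("RIGHT", "LEFT"), function(h) {
      v <- tab[[col]][tab$handedness == h]
      if (length(v) && any(is.finite(v))) f(v[is.finite(v)]) else NA_real_
    }, numeric(1L))
  }
  out <- structure(list(
    n_total = nrow(tab),
    n_right = unname(counts["RIGHT"]), n_left = unname(counts["LEFT"]),
    n_undefined = unname(counts["UNDEFINED"]),
    theta_histogram = hist_table(tab$theta, theta_bin, 0, 180),
    theta_histogram_by_class = lapply(stats::setNames(nm = c("RIGHT", "LEFT")),
      function(h) hist_table(tab$theta[tab$handedness == h], theta_bin, 0, 180)),
    energy_histogram_by_class = lapply(stats::setNames(nm = c("RIGHT", "LEFT")),
      function(h) hist_table(tab$delta_stab[tab$handedness == h], energy_bin)),
    best_energy = per_class(min, "delta_stab"),
    max_hbonds = per_class(max, "n_hs"),
    scatter_hsdist = tab[, intersect(c("index", "handedness", "mean_hs_dist",
                                       "delta_stab"), names(tab))],
    scatter_nhb = tab[, intersect(c("index", "handedness", "n_hs",
                                    "delta_stab"), names(tab))]),
    class = "ensemble_summary")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(d, f) utils::write.table(d, file.path(out_dir, f),
                                            sep = "\t", row.names = FALSE,
                                            quote = FALSE)
    wt(out$theta_histogram, "theta_hist.tsv")
    wt(cbind(class = rep(c("RIGHT", "LEFT"),
                         vapply(out$theta_histogram_by_class, nrow, 1L)),
             do.call(rbind, out$theta_histogram_by_class)),
       "theta_hist_by_class.tsv")
    wt(cbind(class = rep(c("RIGHT", "LEFT"),
                         vapply(out$energy_histogram_by_class, nrow, 1L)),
             do.call(rbind, out$energy_histogram_by_class)),
       "energy_hist_by_class.tsv")
    wt(out$scatter_hsdist, "energy_vs_hsdist.tsv")
    wt(out$scatter_nhb, "energy_vs_nhb.tsv")
    jsonlite::write_json(list(
      n_total = out$n_total, n_right = out$n_right, n_left = out$n_left,
      n_undefined = out$n_undefined,
      best_energy = as.list(out$best_energy),
      max_hbonds = as.list(out$max_hbonds)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  out
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble: %d structures (%d right, %d left, %d undefined)\n",
              x$n_total, x$n_right, x$n_left, x$n_undefined))
  cat(sprintf("best delta_stab: RIGHT %.2f, LEFT %.2f kcal/mol\n",
              x$best_energy["RIGHT"], x$best_energy["LEFT"]))
  cat(sprintf("max H bonds: RIGHT %s, LEFT %s\n",
              x$max_hbonds["RIGHT"], x$max_hbonds["LEFT"]))
  invisible(x)
}
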