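# Execution engine behind run_enumeration(): shared vectorized state
# evaluation, the exhaustive/subsampled drivers, and the staged pruned
# search (exact: provably the same survivor set as exhaustive).

# 1-based digit grids in canonical lexicographic order (first column most
# significant, consistent with states_from_indices()).
expand_digit_grid <- function(value_list) {
  radix <- vapply(value_list, length, 1L)
  n <- prod(radix)
  digits <- matrix(1L, n, length(radix),
                   dimnames = list(NULL, names(value_list)))
  rep_inner <- 1
  for (j in rev(seq_along(radix))) {
    digits[, j] <- rep(rep(seq_len(radix[j]), each = rep_inner), length.out = n)
    rep_inner <- rep_inner * radix[j]
  }
  digits
}

# Per-atom coordinate list -> n x natoms coordinate matrices (rows = the
# selected states), broadcasting 1-row constants.
xyz_mats <- function(P, keys, rows) {
  n <- length(rows)
  X <- Y <- Z <- matrix(NA_real_, n, length(keys))
  for (a in seq_along(keys)) {
    m <- as_rowmat(P[[keys[a]]])
    r <- if (nrow(m) == 1L) rep(1L, n) else rows
    X[, a] <- m[r, 1L]; Y[, a] <- m[r, 2L]; Z[, a] <- m[r, 3L]
  }
  list(X = X, Y = Y, Z = Z)
}

# Fixed evaluation context for one sequence: atom metadata, bonds, LJ pairs.
enum_context <- function(spec, tpl, params) {
  resnames <- spec$resnames
  resnames[4L] <- "CLU"
  cluster <- default_cubane(tpl)
  meta <- rbind(peptide_atom_meta(resnames), cluster_atom_meta())
  bonds <- bond_list(resnames, fused = TRUE, cluster = cluster)
  pairs <- lj_pair_table(meta, bonds, params)
  list(resnames = resnames, cluster = cluster, meta = meta, bonds = bonds,
       pairs = pairs)
}

# Evaluate full grid states given as an n x 17 torsion matrix: terminal-Cys
# geometry for every state, LJ energy for states passing the geometric
# criteria (or all states when lj_all = TRUE).
eval_states_full <- function(tormat, ctx, criteria, tpl, lj_all = FALSE) {
  n <- nrow(tormat)
  tor <- stats::setNames(lapply(torsion_names(), function(nm) tormat[, nm]),
                         torsion_names())
  P <- build_chain_states(ctx$resnames, tor, tpl, 1:7)
  P <- c(P, fuse_states(P, tor$chi2, tor$chi3, tpl, ctx$cluster))
  g1 <- terminal_geometry_states(P, 1L)
  g7 <- terminal_geometry_states(P, 7L)
  ar <- criteria$cb_sg_fe_angle_range
  dist_ok <- g1$dist < criteria$fe_sg_max & g7$dist < criteria$fe_sg_max
  ang_ok <- g1$angle >= ar[1L] & g1$angle <= ar[2L] &
            g7$angle >= ar[1L] & g7$angle <= ar[2L]
  geom_ok <- dist_ok & ang_ok
  lj <- rep(NA_real_, n)
  sel <- if (lj_all) seq_len(n) else which(geom_ok)
  if (length(sel))
    lj[sel] <- lj_energy_states(xyz_mats(P, ctx$meta$key, sel),
                                lj_pairs_for(ctx, criteria))
  data.frame(d_sg1 = g1$dist, d_sg7 = g7$dist,
             ang_sg1 = g1$angle, ang_sg7 = g7$angle,
             fe_sg1 = g1$nearest, fe_sg7 = g7$nearest,
             lj = lj, dist_ok = dist_ok, ang_ok = ang_ok,
             passed = geom_ok & !is.na(lj) & lj < criteria$lj_max)
}

survivor_table <- function(indices, tormat, ev) {
  out <- data.frame(index = indices)
  out <- cbind(out, as.data.frame(tormat))
  cbind(out, ev[, c("d_sg1", "d_sg7", "ang_sg1", "ang_sg7",
                    "fe_sg1", "fe_sg7", "lj")])
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# ---------------------------------------------------------------------------
# Pruned (staged) search

# Admissible per-element-pair clash distances: a nonbonded pair closer than
# this contributes more repulsion than the most negative possible total of
# every other pair, so the state's LJ energy must exceed lj_max and the
# exhaustive screen would reject it too.
clash_distances <- function(pairs, params, lj_max) {
  bound <- sum(pairs$epsilon * pairs$weight) + max(lj_max, 0)
  els <- params$element
  out <- matrix(0, length(els), length(els), dimnames = list(els, els))
  for (a in seq_along(els)) for (b in seq_len(a)) {
    sig <- (params$sigma[a] + params$sigma[b]) / 2
    eps <- sqrt(params$epsilon[a] * params$epsilon[b]) * 0.5  # weakest weight
    f <- function(r) 4 * eps * ((sig / r)^12 - (sig / r)^6) - bound
    r <- tryCatch(stats::uniroot(f, c(1e-4 * sig, sig))$root, error = function(e) 0)
    out[a, b] <- out[b, a] <- r
  }
  out
}

run_pruned <- function(spec, criteria, ctx, tpl, params, verbose = FALSE,
                       chunk_size = 50000L) {
  vals <- spec$values
  pf <- c("psi1", "phi2", "psi2", "phi3", "psi3", "phi4", "chi14", "chi2", "chi3")
  sf <- c("psi4", "phi5", "psi5", "phi6", "psi6", "phi7", "chi17")
  ar <- criteria$cb_sg_fe_angle_range
  cut <- criteria$fe_sg_max

  # Sgamma(1)/CB(1) candidates: fixed in the seed frame, one per chi11 value
  k1 <- length(vals$chi11)
  P1 <- build_chain_states(spec$resnames, list(chi11 = vals$chi11), tpl, 1:1)
  SG1 <- as_rowmat(P1$SG1); CB1 <- as.numeric(P1$CB1)

  # suffix table in the canonical residue-4 frame
  sdig <- expand_digit_grid(vals[sf])
  stor <- stats::setNames(lapply(sf, function(nm) vals[[nm]][sdig[, nm]]), sf)
  resn_suffix <- ctx$resnames
  PS <- build_chain_states(resn_suffix, stor, tpl, 4:7)
  suffix_keys <- setdiff(names(PS), c("N4", "CA4", "C4"))
  SG7 <- PS$SG7; CB7 <- PS$CB7
  r7 <- row_norm(SG7)
  ord7 <- order(r7)
  r7s <- r7[ord7]

  # clash pruning tables (suffix atoms vs the 8 cluster atoms); when the LJ
  # criterion is heavy-atom-only, hydrogens cannot trigger a rejection
  lj_pairs <- lj_pairs_for(ctx, criteria)
  rcl <- clash_distances(lj_pairs, params, criteria$lj_max)
  if (isTRUE(criteria$lj_heavy_only) && "H" %in% rownames(rcl)) {
    rcl["H", ] <- 0; rcl[, "H"] <- 0
  }
  suffix_el <- atom_element(sub("[0-9]+$", "", sub("^SCL", "S", suffix_keys)))
  cl_el <- c(rep("FE", 4L), rep("S", 4L))
  # atoms bonded (or 1-3/1-4) to the cluster are excluded from clash tests:
  # only SG4 (prefix side) qualifies, so all suffix atoms are safe to test.

  # ---- stage A: prefix scan ---------------------------------------------
  pdig <- expand_digit_grid(vals[pf])
  np <- nrow(pdig)
  keep_frame <- list(); keep_fe <- list(); keep_pass1 <- list(); keep_row <- list()
  for (lo in seq(1L, np, by = chunk_size)) {
    hi <- min(lo + chunk_size - 1L, np)
    rows <- lo:hi
    tor <- stats::setNames(lapply(pf, function(nm) vals[[nm]][pdig[rows, nm]]), pf)
    P <- build_chain_states(spec$resnames, tor, tpl, 1:4)
    CL <- fuse_states(P, tor$chi2, tor$chi3, tpl, ctx$cluster)
    n <- length(rows)
    passA <- matrix(FALSE, n, k1)
    for (c1 in seq_len(k1)) {
      s1 <- SG1[c1, ]
      d2 <- matrix(NA_real_, n, 4L)
      for (f in 1:4) {
        FE <- CL[[paste0("FE", f)]]
        d2[, f] <- (FE[, 1L] - s1[1L])^2 + (FE[, 2L] - s1[2L])^2 + (FE[, 3L] - s1[3L])^2
      }
      nearest <- max.col(-d2, ties.method = "first")
      dmin <- sqrt(d2[cbind(seq_len(n), nearest)])
      ok <- dmin < cut
      if (any(ok)) {
        FEn <- matrix(NA_real_, sum(ok), 3L)
        for (f in 1:4) {
          s <- nearest[ok] == f
          if (any(s)) FEn[s, ] <- CL[[paste0("FE", f)]][which(ok)[s], , drop = FALSE]
        }
        ang <- measure_angle(matrix(CB1, sum(ok), 3L, byrow = TRUE),
                             matrix(s1, sum(ok), 3L, byrow = TRUE), FEn)
        ok[ok] <- ang >= ar[1L] & ang <= ar[2L]
      }
      passA[, c1] <- ok
    }
    anyp <- which(rowSums(passA) > 0)
    if (length(anyp)) {
      keep_row[[length(keep_row) + 1L]] <- rows[anyp]
      keep_pass1[[length(keep_pass1) + 1L]] <- passA[anyp, , drop = FALSE]
      keep_frame[[length(keep_frame) + 1L]] <-
        cbind(P$N4[anyp, , drop = FALSE], P$CA4[anyp, , drop = FALSE],
              P$C4[anyp, , drop = FALSE])
      fe <- matrix(NA_real_, length(anyp), 12L)
      for (f in 1:4) fe[, 3L * f - (2:0)] <- CL[[paste0("FE", f)]][anyp, , drop = FALSE]
      keep_fe[[length(keep_fe) + 1L]] <- fe
      # cluster sulfides + Fe for the clash stage
    }
  }
  if (!length(keep_row))
    return(list(cand = NULL, pdig = pdig, sdig = sdig, pf = pf, sf = sf))
  prow <- unlist(keep_row)
  pass1 <- do.call(rbind, keep_pass1)
  frames <- do.call(rbind, keep_frame)
  fes <- do.call(rbind, keep_fe)
  if (verbose) message(sprintf("prefix pass: %d / %d", length(prow), np))

  # cluster atoms are needed in local frame for the clash stage; rebuild the
  # sulfide coordinates for kept prefixes from the stored Fe + frame is not
  # possible, so re-derive all 8 cluster atoms from a second pass over kept
  # rows (cheap: only kept prefixes).
  tor <- stats::setNames(lapply(pf, function(nm) vals[[nm]][pdig[prow, nm]]), pf)
  Pk <- build_chain_states(spec$resnames, tor, tpl, 1:4)
  CLk <- fuse_states(Pk, tor$chi2, tor$chi3, tpl, ctx$cluster)

  # ---- stage B/C: per-prefix suffix filtering ---------------------------
  cand_p <- list(); cand_s <- list()
  nsfx <- nrow(sdig)
  for (q in seq_along(prow)) {
    N4 <- frames[q, 1:3]; CA4 <- frames[q, 4:6]; C4 <- frames[q, 7:9]
    e1 <- CA4 - N4; e1 <- e1 / sqrt(sum(e1^2))
    u <- C4 - CA4; u <- u - sum(u * e1) * e1
    e2 <- u / sqrt(sum(u^2))
    e3 <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
            e1[3L] * e2[1L] - e1[1L] * e2[3L],
            e1[1L] * e2[2L] - e1[2L] * e2[1L])
    R <- cbind(e1, e2, e3)
    feg <- matrix(fes[q, ], 4L, 3L, byrow = TRUE)
    fel <- sweep(feg, 2L, N4) %*% R
    rho <- sqrt(rowSums(fel^2))
    # radius prefilter on |SG7|
    cand <- integer(0L)
    for (f in 1:4) {
      lo <- findInterval(rho[f] - cut, r7s) + 1L
      hi <- findInterval(rho[f] + cut, r7s)
      if (hi >= lo) cand <- c(cand, ord7[lo:hi])
    }
    cand <- unique(cand)
    if (!length(cand)) next
    # exact distance + angle
    d2 <- matrix(NA_real_, length(cand), 4L)
    sg <- SG7[cand, , drop = FALSE]
    for (f in 1:4)
      d2[, f] <- (sg[, 1L] - fel[f, 1L])^2 + (sg[, 2L] - fel[f, 2L])^2 +
                 (sg[, 3L] - fel[f, 3L])^2
    nearest <- max.col(-d2, ties.method = "first")
    ok <- sqrt(d2[cbind(seq_along(cand), nearest)]) < cut
    if (any(ok)) {
      sel <- which(ok)
      ang <- measure_angle(CB7[cand[sel], , drop = FALSE], sg[sel, , drop = FALSE],
                           fel[nearest[sel], , drop = FALSE])
      ok[sel] <- ang >= ar[1L] & ang <= ar[2L]
    }
    cand <- cand[ok]
    if (!length(cand)) next
    # admissible clash rejection: suffix atoms vs the 8 cluster atoms
    clg <- rbind(CLk$FE1[q, ], CLk$FE2[q, ], CLk$FE3[q, ], CLk$FE4[q, ],
                 CLk$SCL1[q, ], CLk$SCL2[q, ], CLk$SCL3[q, ], CLk$SCL4[q, ])
    cll <- sweep(clg, 2L, N4) %*% R
    alive <- rep(TRUE, length(cand))
    for (a in seq_along(suffix_keys)) {
      if (!any(alive)) break
      m <- PS[[suffix_keys[a]]][cand, , drop = FALSE]
      for (b in 1:8) {
        rc2 <- rcl[suffix_el[a], cl_el[b]]^2
        if (rc2 <= 0) next
        d2c <- (m[, 1L] - cll[b, 1L])^2 + (m[, 2L] - cll[b, 2L])^2 +
               (m[, 3L] - cll[b, 3L])^2
        alive <- alive & d2c >= rc2
      }
    }
    cand <- cand[alive]
    if (length(cand)) {
      cand_p[[length(cand_p) + 1L]] <- rep.int(q, length(cand))
      cand_s[[length(cand_s) + 1L]] <- cand
    }
  }
  list(cand = list(p = unlist(cand_p), s = unlist(cand_s)),
       prow = prow, pass1 = pass1, pdig = pdig, sdig = sdig, pf = pf, sf = sf)
}

#' Run a grid enumeration with screening
#'
#' Generates conformations over the torsion grid, fuses the cluster, applies
#' the geometric and Lennard-Jones screens and returns the survivors.
#'
#' `"exhaustive"` visits every state (practical for small grids);
#' `"pruned"` uses a staged search with only exact or provably admissible
#' eliminations and returns the identical survivor set; `"subsampled"`
#' evaluates a seeded uniform draw of the grid.
#'
#' @param spec a [grid_spec()].
#' @param criteria a [filter_criteria()].
#' @param mode `"pruned"`, `"exhaustive"` or `"subsampled"`.
#' @param n_sample number of draws for subsampled mode.
#' @param seed RNG seed for subsampled mode (required there; recorded in the
#'   manifest).
#' @param out_dir optional directory: survivors are written to
#'   `survivors.tsv` and the manifest to `manifest.json`.
#' @param templates,params geometry templates and LJ parameters.
#' @param chunk_size states evaluated per vectorized block.
#' @param verbose print progress.
#' @return list with `survivors` (data frame: grid `index`, the 17 torsions,
#'   terminal-Cys geometry and `lj`, ordered by `index`) and `manifest`.
#' @export
run_enumeration <- function(spec, criteria = filter_criteria(),
                            mode = c("pruned", "exhaustive", "subsampled"),
                            n_sample = NULL, seed = NULL, out_dir = NULL,
                            templates = residue_templates(),
                            params = lj_params(),
                            chunk_size = 20000L, verbose = FALSE) {
  mode <- match.arg(mode)
  tpl <- templates
  ctx <- enum_context(spec, tpl, params)
  N <- grid_cardinality(spec)
  reject <- c(fe_sg_max = 0, cb_sg_fe_angle = 0, lj_max = 0)
  n_visited <- 0
  surv <- list()

  if (mode %in% c("exhaustive", "subsampled")) {
    if (mode == "exhaustive") {
      if (N > 2e6) stop("exhaustive mode is limited to 2e6 states; use pruned")
      idx_all <- seq_len(N) - 1
    } else {
      if (is.null(seed) || is.null(n_sample))
        stop("subsampled mode requires n_sample and seed")
      idx_all <- with_local_seed(seed, sort(unique(floor(stats::runif(n_sample) * N))))
    }
    for (lo in seq(1L, length(idx_all), by = chunk_size)) {
      idx <- idx_all[lo:min(lo + chunk_size - 1L, length(idx_all))]
      tormat <- states_from_indices(spec, idx)
      ev <- eval_states_full(tormat, ctx, criteria, tpl)
      n_visited <- n_visited + length(idx)
      reject["fe_sg_max"] <- reject["fe_sg_max"] + sum(!ev$dist_ok)
      reject["cb_sg_fe_angle"] <- reject["cb_sg_fe_angle"] + sum(!ev$ang_ok)
      reject["lj_max"] <- reject["lj_max"] + sum(ev$dist_ok & ev$ang_ok & !ev$passed)
      if (any(ev$passed))
        surv[[length(surv) + 1L]] <-
          survivor_table(idx[ev$passed], tormat[ev$passed, , drop = FALSE],
                         ev[ev$passed, , drop = FALSE])
      if (verbose) message(sprintf("visited %d / %d", n_visited, length(idx_all)))
    }
  } else {
    st <- run_pruned(spec, criteria, ctx, tpl, params, verbose,
                     chunk_size = max(chunk_size, 50000L))
    n_visited <- N
    reject[] <- NA_real_
    if (!is.null(st$cand) && length(st$cand$p)) {
      # expand candidate (prefix, suffix) pairs over passing chi11 values
      reps <- rowSums(st$pass1[st$cand$p, , drop = FALSE])
      qidx <- rep.int(st$cand$p, reps)
      sidx <- rep.int(st$cand$s, reps)
      c1idx <- unlist(lapply(seq_along(st$cand$p), function(k)
        which(st$pass1[st$cand$p[k], ])))
      ncand <- length(qidx)
      if (verbose) message(sprintf("full candidates: %d", ncand))
      digits <- matrix(1L, ncand, 17L, dimnames = list(NULL, torsion_names()))
      digits[, st$pf] <- st$pdig[st$prow[qidx], , drop = FALSE]
      digits[, st$sf] <- st$sdig[sidx, , drop = FALSE]
      digits[, "chi11"] <- c1idx
      idx_all <- index_from_digits(spec, digits)
      o <- order(idx_all)
      idx_all <- idx_all[o]; digits <- digits[o, , drop = FALSE]
      for (lo in seq(1L, ncand, by = chunk_size)) {
        sel <- lo:min(lo + chunk_size - 1L, ncand)
        tormat <- matrix(NA_real_, length(sel), 17L,
                         dimnames = list(NULL, torsion_names()))
        for (j in torsion_names())
          tormat[, j] <- spec$values[[j]][digits[sel, j]]
        ev <- eval_states_full(tormat, ctx, criteria, tpl)
        if (any(ev$passed))
          surv[[length(surv) + 1L]] <-
            survivor_table(idx_all[sel][ev$passed],
                           tormat[ev$passed, , drop = FALSE],
                           ev[ev$passed, , drop = FALSE])
      }
    }
  }

  survivors <- if (length(surv)) do.call(rbind, surv) else {
    cols <- c("index", torsion_names(), "d_sg1", "d_sg7", "ang_sg1",
              "ang_sg7", "fe_sg1", "fe_sg7", "lj")
    as.data.frame(stats::setNames(rep(list(numeric(0L)), length(cols)), cols))
  }
  survivors <- survivors[order(survivors$index), , drop = FALSE]
  rownames(survivors) <- NULL
  manifest <- list(mode = mode, sequence = spec$sequence,
                   phi_psi_step = spec$phi_psi_step,
                   chi_values = spec$chi_values, free = spec$free,
                   criteria = unclass(criteria),
                   grid_cardinality = N, states_visited = n_visited,
                   n_survivors = nrow(survivors),
                   reject_counts = as.list(reject),
                   seed = seed,
                   survivor_index_sum = sum(survivors$index))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(survivors, file.path(out_dir, "survivors.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(survivors = survivors, manifest = manifest)
}
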