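# Synthetic fixture generators: every input the test suite and desk-scale
# pipeline need, built from the package's own geometry (no experimental
# coordinates).  All generators are deterministic under their seed.

# Canonical grid state of a right-handed cluster-binding conformation: the
# default enumeration's survivor with the richest amide-to-cluster
# hydrogen-bond network (the natural-fold analogue).  Both terminal
# cysteines ligate within the screen cutoffs by construction.
canonical_right_state <- function() {
  dihedral_state(phi = c(-180, 120, -180, 60, -120, -60),
                 psi = c(-60, 60, 60, -60, 60, -60),
                 chi1 = c(60, 60, -60), chi2 = -180, chi3 = -180)
}

#' Generate a heptapeptide-cluster complex of known handedness
#'
#' Builds a CGGCGGC complex whose topology-angle handedness holds by
#' construction: the RIGHT fixture is a stored cluster-binding conformation
#' verified to score theta in (20, 70); the LEFT fixture is its mirror
#' image (theta_L = 180 - theta_R).  Optional Gaussian coordinate noise is
#' seeded and applied after the handedness check, scaled so it cannot flip
#' the class.
#'
#' @param handedness `"RIGHT"` or `"LEFT"`.
#' @param seed integer seed (used for the noise draw).
#' @param noise_sigma Gaussian coordinate noise, Angstrom (default 0).
#' @return an `fs_complex`.
#' @export
make_handed_complex <- function(handedness = c("RIGHT", "LEFT"), seed = 1,
                                noise_sigma = 0) {
  handedness <- match.arg(handedness)
  cx <- build_complex("CGGCGGC", canonical_right_state())
  tp <- complex_topology(cx)
  if (tp$handedness != "RIGHT" || tp$theta <= 20 || tp$theta >= 70)
    stop("generator bug: canonical state no longer scores RIGHT in (20, 70)")
  if (handedness == "LEFT") cx <- mirror_complex(cx)
  if (noise_sigma > 0) {
    xyz <- atom_xyz(cx)
    noise <- with_local_seed(seed, matrix(stats::rnorm(length(xyz), 0, noise_sigma),
                                          nrow(xyz), 3L))
    xyz <- xyz + noise
    cx$atoms$x <- xyz[, 1L]; cx$atoms$y <- xyz[, 2L]; cx$atoms$z <- xyz[, 3L]
    cx$state <- NULL
  }
  cx
}

#' Toy complexes with hand-constructed hydrogen-bond censuses
#'
#' Builds a set of cluster-plus-amide toy structures engineered by explicit
#' trigonometry to contain exactly 0, 1, 3 and 6 qualifying amide-to-sulfide
#' contacts under the default H-S rule.  Each member is re-verified
#' internally by an independent brute-force distance/angle pass before being
#' returned; a mismatch raises an error rather than silently emitting.
#'
#' @param seed integer seed (orientation jitter of the non-contacting
#'   donors).
#' @return named list of `fs_complex`-like objects (`"n0"`, `"n1"`, `"n3"`,
#'   `"n6"`), each with attribute `expected` giving its constructed count.
#' @export
make_toy_hbond_set <- function(seed = 1) {
  out <- list()
  for (k in c(0L, 1L, 3L, 6L)) {
    cx <- toy_hbond_complex(k, seed)
    census <- verify_hbond_brute(cx)
    if (census != k)
      stop("generator bug: toy complex built for ", k,
           " contacts verified at ", census)
    attr(cx, "expected") <- k
    out[[paste0("n", k)]] <- cx
  }
  out
}

# One toy complex: an ideal cubane with 6 fabricated backbone amide units
# (residues 2-7).  The first k donors aim N-H at distinct sulfur acceptors
# with H...S = 2.4 A and N-H...S = 165 deg (inside the rule); the rest point
# directly away from the cluster (H...S > 5 A from every S).
toy_hbond_complex <- function(k, seed = 1) {
  cl <- build_cubane()
  sulf <- cl$s
  # acceptor directions: outward unit vectors from the centroid through each
  # sulfide, plus two extra slots reusing sulfides 1-2 (bifurcation-free
  # geometry: distinct donors, same acceptor from a different direction)
  acc_idx <- c(1L, 2L, 3L, 4L, 1L, 2L)
  rot_ang <- c(0, 0, 0, 0, 70, 70)  # second approach rotated off-axis
  atoms <- list()
  push <- function(resno, resid, elety, p)
    atoms[[length(atoms) + 1L]] <<- data.frame(
      resno = resno, resid = resid, elety = elety,
      key = paste0(elety, resno), elem = atom_element(elety),
      x = p[1L], y = p[2L], z = p[3L], stringsAsFactors = FALSE)
  jit <- with_local_seed(seed, matrix(stats::runif(12, -0.2, 0.2), 6L, 2L))
  for (d in 1:6) {
    resno <- d + 1L
    s <- sulf[acc_idx[d], ]
    u <- s / sqrt(sum(s^2))     # outward through the acceptor
    if (rot_ang[d] > 0) {
      ax <- c(-u[2L], u[1L], 0); ax <- ax / sqrt(sum(ax^2))
      u <- as.numeric(rotation_about_axis(ax, rot_ang[d]) %*% u)
    }
    if (d <= k) {
      H <- s + 2.4 * u
      # N on the line at the 165-deg N-H...S angle, 1.01 A from H
      perp <- c(-u[2L], u[1L], 0)
      if (sum(perp^2) < 1e-8) perp <- c(1, 0, 0)
      perp <- perp / sqrt(sum(perp^2))
      nd <- rotation_about_axis(perp, 180 - 165) %*% u
      N <- H + 1.01 * as.numeric(nd)
    } else {
      # aimed far away: donor shifted radially out, H pointing outward
      H <- s + (6 + jit[d, 1L]) * u
      N <- H + 1.01 * (u + c(0, 0, jit[d, 2L])) /
        sqrt(sum((u + c(0, 0, jit[d, 2L]))^2))
    }
    push(resno, "GLY", "N", N)
    push(resno, "GLY", "H", H)
  }
  ca <- cluster_atom_meta()
  cxyz <- rbind(cl$fe, cl$s)
  for (r in seq_len(nrow(ca)))
    push(ca$resno[r], ca$resid[r], ca$elety[r], cxyz[r, ])
  at <- do.call(rbind, atoms)
  at$key <- ifelse(at$resid == "SF4",
                   ifelse(at$elem == "S", sub("^S", "SCL", at$elety), at$elety),
                   at$key)
  structure(list(atoms = at, resnames = rep("GLY", 7L), cluster = cl,
                 bonds = cbind(paste0("N", 2:7), paste0("H", 2:7))),
            class = "fs_complex")
}

# Independent brute-force census (H-S rule, default cutoffs) used to verify
# the generator's construction.
verify_hbond_brute <- function(cx) {
  a <- cx$atoms
  count <- 0L
  for (d in 2:7) {
    N <- as.numeric(a[a$key == paste0("N", d), c("x", "y", "z")])
    H <- as.numeric(a[a$key == paste0("H", d), c("x", "y", "z")])
    if (!length(N) || !length(H)) next
    for (s in which(a$resid == "SF4" & a$elem == "S")) {
      S <- as.numeric(a[s, c("x", "y", "z")])
      hs <- sqrt(sum((H - S)^2))
      v1 <- N - H; v2 <- S - H
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (hs < 3.5 && ang >= 120 && ang <= 180) count <- count + 1L
    }
  }
  count
}

#' Write synthetic survey fixture files
#'
#' Emits standards-conformant PDB files, each containing one handed
#' CGGCGGC-cluster complex (SF4 heterogroup) renumbered as motif residues
#' 10-16, plus a synthetic outlier cysteine ligating the vacant Fe site
#' (residue 25 for Type A, 2 for Type B), so the survey runs end-to-end
#' offline.
#'
#' @param n_right,n_left file counts per handedness.
#' @param seed integer seed (per-file coordinate jitter).
#' @param out_dir output directory (created if needed).
#' @param outlier_type `"A"` (outlier C-terminal to the motif) or `"B"`.
#' @return character vector of written paths.
#' @export
make_survey_files <- function(n_right = 3, n_left = 1, seed = 17,
                              out_dir = tempfile("survey"),
                              outlier_type = "A") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0L)
  hands <- c(rep("RIGHT", n_right), rep("LEFT", n_left))
  for (f in seq_along(hands)) {
    at <- survey_fixture_atoms(hands[f], seed + f, outlier_type)
    p <- file.path(out_dir, sprintf("synthetic_%s_%02d.pdb",
                                    tolower(hands[f]), f))
    write_atoms_pdb(at, p)
    paths <- c(paths, p)
  }
  paths
}

# Atom table for one survey fixture: the handed complex with author residue
# numbers 10-16, an SF4 heterogroup, and a fabricated outlier Cys whose
# Sgamma caps the vacant Fe.
survey_fixture_atoms <- function(handedness, seed, outlier_type = "A") {
  cx <- make_handed_complex(handedness, seed = seed, noise_sigma = 0.02)
  a <- cx$atoms
  pep <- a$resid != "SF4"
  a$resno[pep] <- a$resno[pep] + 9L
  a$resid[a$resid == "CLU"] <- "CYS"
  a$resid[a$resid %in% c("GLY", "CYS") & !pep] <- a$resid[!pep]
  # vacant Fe: the one with no SG within 3 A
  xyz <- atom_xyz(cx)
  fe <- xyz[paste0("FE", 1:4), , drop = FALSE]
  sg <- xyz[intersect(c("SG1", "SG4", "SG7"), rownames(xyz)), , drop = FALSE]
  dmin <- apply(fe, 1L, function(p) min(sqrt(rowSums(sweep(sg, 2L, p)^2))))
  vac <- which.max(dmin)
  ctr <- colMeans(xyz[a$resid == "SF4", , drop = FALSE])
  u <- fe[vac, ] - ctr; u <- u / sqrt(sum(u^2))
  # synthetic outlier residue: chain extended radially outward
  SGo <- fe[vac, ] + 2.30 * u
  perp <- c(-u[2L], u[1L], 0); perp <- perp / sqrt(sum(perp^2))
  CBo <- SGo + 1.81 * (0.8 * u + 0.6 * perp) / sqrt(sum((0.8 * u + 0.6 * perp)^2))
  CAo <- CBo + 1.53 * u
  No  <- CAo + 1.458 * perp
  Co  <- CAo + 1.525 * (0.5 * u - 0.87 * perp) / sqrt(sum((0.5 * u - 0.87 * perp)^2))
  Oo  <- Co + 1.231 * u
  orn <- if (outlier_type == "A") 25L else 2L
  extra <- data.frame(resno = orn, resid = "CYS",
                      elety = c("N", "CA", "C", "O", "CB", "SG"),
                      key = paste0(c("N", "CA", "C", "O", "CB", "SG"), "o"),
                      elem = c("N", "C", "C", "O", "C", "S"),
                      x = c(No[1], CAo[1], Co[1], Oo[1], CBo[1], SGo[1]),
                      y = c(No[2], CAo[2], Co[2], Oo[2], CBo[2], SGo[2]),
                      z = c(No[3], CAo[3], Co[3], Oo[3], CBo[3], SGo[3]),
                      stringsAsFactors = FALSE)
  pep_rows <- a[pep, , drop = FALSE]
  clu_rows <- a[!pep, , drop = FALSE]
  clu_rows$resno <- 101L
  if (outlier_type == "A") rbind(pep_rows, extra, clu_rows)
  else rbind(extra, pep_rows, clu_rows)
}

# Generic fixed-format PDB writer for fixture atom tables.
write_atoms_pdb <- function(atoms, file, chain = "A") {
  het <- atoms$resid == "SF4"
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = atoms$resno, resid = atoms$resid,
                   eleno = seq_len(nrow(atoms)), elety = atoms$elety,
                   chain = rep(chain, nrow(atoms)),
                   elesy = ifelse(atoms$elem == "FE", "FE", atoms$elem))
  invisible(file)
}

#' Write a fixture atom table as mmCIF
#'
#' Minimal atom_site rendering used to test dialect equivalence of the
#' structure reader.
#'
#' @param cx an `fs_complex` (or compatible atom table holder).
#' @param file output path.
#' @param chain chain identifier.
#' @return `file`, invisibly.
#' @export
write_complex_cif <- function(cx, file, chain = "A") {
  a <- if (is.data.frame(cx)) cx else cx$atoms
  het <- a$resid == "SF4"
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("data_synthetic", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
               "_atom_site.auth_seq_id", "_atom_site.Cartn_x",
               "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "_atom_site.occupancy", "_atom_site.pdbx_PDB_model_num"), con)
  writeLines(sprintf("%s %d %s %s %s %s %d %.3f %.3f %.3f 1.00 1",
                     ifelse(het, "HETATM", "ATOM"), seq_len(nrow(a)),
                     ifelse(a$elem == "FE", "FE", a$elem), a$elety, a$resid,
                     chain, a$resno, a$x, a$y, a$z), con)
  invisible(file)
}

#' Generate a fixture from a specification
#'
#' Dispatcher over the individual generators, keyed by fixture kind.
#'
#' @param kind one of `"ideal_cubane"`, `"handed_complex"`,
#'   `"mirrored_pair"`, `"noisy_copy"`, `"toy_hbond"`, `"survey_file"`.
#' @param seed integer seed.
#' @param handedness for `handed_complex`.
#' @param noise_sigma for `noisy_copy` (Angstrom, >= 0).
#' @param out_dir for `survey_file`.
#' @return the fixture object (or file paths for `survey_file`).
#' @export
make_fixture <- function(kind = c("ideal_cubane", "handed_complex",
                                  "mirrored_pair", "noisy_copy", "toy_hbond",
                                  "survey_file"),
                         seed = 1, handedness = "RIGHT", noise_sigma = 0.1,
                         out_dir = tempfile("survey")) {
  kind <- match.arg(kind)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  switch(kind,
    ideal_cubane = build_cubane(),
    handed_complex = make_handed_complex(handedness, seed),
    mirrored_pair = list(right = make_handed_complex("RIGHT", seed),
                         left = make_handed_complex("LEFT", seed)),
    noisy_copy = make_handed_complex(handedness, seed, noise_sigma),
    toy_hbond = make_toy_hbond_set(seed),
    survey_file = make_survey_files(seed = seed, out_dir = out_dir))
}
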