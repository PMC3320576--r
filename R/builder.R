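# Cartesian model construction: the Fe4S4 cubane, the heptapeptide chain
# grown from torsions by sequential internal-to-Cartesian (NeRF) placement,
# and their fusion through the hybrid Clu residue.
#
# The core builder is vectorized over conformations: every torsion argument
# may be a length-n vector and every atom is then placed for all n states in
# one call.  Single-structure interfaces wrap the n = 1 case.

#' Build an Fe4S4 cubane
#'
#' In `"ideal"` mode, constructs an idealized cubane with crystallographic
#' proportions: the four Fe form a regular tetrahedron of edge `fe_fe`, the
#' four inorganic sulfides the interpenetrating (larger) tetrahedron, scaled
#' so every Fe-S contact equals `fe_s`.  Real cubanes are compressed in this
#' way (Fe-Fe about 2.73 A, S-S about 3.6 A) rather than perfect cubes; the
#' construction keeps exact three-fold symmetry about each centroid-Fe axis.
#' In `"table"` mode, accepts 8 labeled coordinates.  The result is centered
#' on the centroid of its 8 atoms.
#'
#' @param mode `"ideal"` or `"table"`.
#' @param fe_s ideal Fe-S bond length in Angstrom.
#' @param fe_fe ideal Fe-Fe distance in Angstrom (set to `fe_s * sqrt(2)`
#'   for a perfect cube).
#' @param coords for table mode: a data frame / matrix-like with columns
#'   `element` (`"FE"` or `"S"`), `x`, `y`, `z`.
#' @return object of class `cluster_geometry`: list with `fe` and `s`
#'   (4 x 3 coordinate matrices, centroid at the origin), `fe_s` and a
#'   `bonds` matrix of Fe-S index pairs.
#' @export
build_cubane <- function(mode = c("ideal", "table"), fe_s = 2.28,
                         fe_fe = 2.73, coords = NULL) {
  mode <- match.arg(mode)
  if (mode == "ideal") {
    a <- fe_fe / (2 * sqrt(2))
    # solve 3 b^2 - 2 a b + (3 a^2 - fe_s^2 - 2 a^2)... adjacent Fe-S
    # distance for half-diagonals a (Fe) and b (S): 3a^2 - 2ab + 3b^2
    b <- (2 * a + sqrt(4 * a^2 - 12 * (3 * a^2 - fe_s^2))) / 6
    fe <- a * rbind(c( 1,  1,  1), c( 1, -1, -1), c(-1,  1, -1), c(-1, -1,  1))
    s  <- b * rbind(c( 1,  1, -1), c( 1, -1,  1), c(-1,  1,  1), c(-1, -1, -1))
  } else {
    coords <- as.data.frame(coords)
    el <- toupper(coords$element)
    if (sum(el == "FE") != 4L || sum(el == "S") != 4L)
      stop("malformed cluster: need exactly 4 Fe and 4 S atoms, got ",
           sum(el == "FE"), " Fe and ", sum(el == "S"), " S")
    fe <- as.matrix(coords[el == "FE", c("x", "y", "z")])
    s  <- as.matrix(coords[el == "S",  c("x", "y", "z")])
    dimnames(fe) <- dimnames(s) <- NULL
  }
  ctr <- colMeans(rbind(fe, s))
  fe <- sweep(fe, 2L, ctr)
  s  <- sweep(s, 2L, ctr)
  d <- sqrt(outer(rowSums(fe^2), rowSums(s^2), "+") - 2 * fe %*% t(s))
  bonded <- d < 2.6
  if (any(d[bonded] < 2.0) || !all(rowSums(bonded) == 3L) || !all(colSums(bonded) == 3L))
    stop("cluster geometry error: Fe-S contacts outside [2.0, 2.6] A or not a cubane")
  structure(list(fe = fe, s = s, fe_s = mean(d[bonded]),
                 bonds = which(bonded, arr.ind = TRUE)),
            class = "cluster_geometry")
}

# ---------------------------------------------------------------------------
# Torsion bookkeeping

#' Construct and validate a dihedral state
#'
#' The 17 torsions that define one conformation of the heptapeptide-cluster
#' model: 6 phi (residues 2-7), 6 psi (residues 1-6), 3 chi1 (the cysteine-
#' like residues 1, 4, 7), and chi2/chi3 orienting the cluster about the
#' Clu side chain.
#'
#' @param phi,psi numeric length 6, degrees.
#' @param chi1 numeric length 3, degrees.
#' @param chi2,chi3 numeric scalars, degrees.
#' @return object of class `dihedral_state` (named list of wrapped angles).
#' @export
dihedral_state <- function(phi, psi, chi1, chi2 = -180, chi3 = -180) {
  if (length(phi) != 6L || length(psi) != 6L || length(chi1) != 3L ||
      length(chi2) != 1L || length(chi3) != 1L)
    stop("dihedral state needs 6 phi, 6 psi, 3 chi1 and scalar chi2/chi3")
  st <- list(phi = wrap_angle(as.numeric(phi)), psi = wrap_angle(as.numeric(psi)),
             chi1 = wrap_angle(as.numeric(chi1)),
             chi2 = wrap_angle(as.numeric(chi2)), chi3 = wrap_angle(as.numeric(chi3)))
  structure(st, class = "dihedral_state")
}

#' Canonical torsion order
#'
#' Names of the 17 model torsions in the canonical order used by grid
#' vectors and survivor tables: phi2-phi7, psi1-psi6, chi1 of residues
#' 1/4/7, then chi2 and chi3.
#'
#' @return character vector of length 17.
#' @export
torsion_names <- function() {
  c(paste0("phi", 2:7), paste0("psi", 1:6), "chi11", "chi14", "chi17",
    "chi2", "chi3")
}

state_to_vector <- function(state) {
  stats::setNames(c(state$phi, state$psi, state$chi1, state$chi2, state$chi3),
                  torsion_names())
}

vector_to_state <- function(v) {
  dihedral_state(phi = v[1:6], psi = v[7:12], chi1 = v[13:15],
                 chi2 = v[16], chi3 = v[17])
}

# ---------------------------------------------------------------------------
# Vectorized chain construction

check_sequence <- function(sequence) {
  if (is.character(sequence) && length(sequence) == 1L)
    sequence <- strsplit(sequence, "")[[1L]]
  sequence <- toupper(sequence)
  map <- c(G = "GLY", A = "ALA", C = "CYS", GLY = "GLY", ALA = "ALA",
           CYS = "CYS", CLU = "CLU")
  if (any(is.na(map[sequence])))
    stop("unknown residue in sequence: ", paste(setdiff(sequence, names(map)), collapse = ","))
  res <- unname(map[sequence])
  if (length(res) != 7L) stop("sequence must have exactly 7 residues, got ", length(res))
  if (!all(res[c(1L, 4L, 7L)] %in% c("CYS", "CLU")))
    stop("positions 1, 4 and 7 must be cysteine-like")
  res
}

# Build peptide atoms for all n states at once.  `tor` is a named list of
# length-n numeric vectors (see torsion_names(); chi2/chi3 unused here).
# Returns a named list of n x 3 matrices keyed "N1", "CA1", "H2", "SG4", ...
# Residues outside `residues` are skipped; the first residue of the range is
# seeded in a canonical frame (N at origin, CA on +x, C in the xy plane).
build_chain_states <- function(resnames, tor, tpl = residue_templates(),
                               residues = 1:7) {
  bNCA <- tpl_len(tpl, "N-CA"); bCAC <- tpl_len(tpl, "CA-C")
  bCN <- tpl_len(tpl, "C-N");   bCO  <- tpl_len(tpl, "C-O")
  bNH <- tpl_len(tpl, "N-H");   bCACB <- tpl_len(tpl, "CA-CB")
  bCBSG <- tpl_len(tpl, "CB-SG")
  aCNCA <- tpl_ang(tpl, "C-N-CA"); aNCAC <- tpl_ang(tpl, "N-CA-C")
  aCACN <- tpl_ang(tpl, "CA-C-N"); aCACO <- tpl_ang(tpl, "CA-C-O")
  aCNH <- tpl_ang(tpl, "C-N-H");   aNCACB <- tpl_ang(tpl, "N-CA-CB")
  aCACBSG <- tpl_ang(tpl, "CA-CB-SG")
  cbt <- tpl$params[["cb_torsion"]]; omg <- tpl$params[["omega"]]
  htr <- tpl$params[["h_torsion"]]

  first <- min(residues); last <- max(residues)
  P <- list()
  # canonical seed frame for the first residue of the range
  ar <- aNCAC * pi / 180
  P[[paste0("N", first)]]  <- matrix(c(0, 0, 0), 1L)
  P[[paste0("CA", first)]] <- matrix(c(bNCA, 0, 0), 1L)
  P[[paste0("C", first)]]  <- matrix(c(bNCA - bCAC * cos(ar), bCAC * sin(ar), 0), 1L)
  chi1_of <- c("1" = "chi11", "4" = "chi14", "7" = "chi17")

  for (i in residues) {
    Ni <- paste0("N", i); CAi <- paste0("CA", i); Ci <- paste0("C", i)
    if (i > first) {
      p <- i - 1L
      psi <- tor[[paste0("psi", p)]]
      P[[paste0("O", p)]] <- place_atom(P[[paste0("N", p)]], P[[paste0("CA", p)]],
                                        P[[paste0("C", p)]], bCO, aCACO, psi + 180)
      P[[Ni]]  <- place_atom(P[[paste0("N", p)]], P[[paste0("CA", p)]],
                             P[[paste0("C", p)]], bCN, aCACN, psi)
      P[[CAi]] <- place_atom(P[[paste0("CA", p)]], P[[paste0("C", p)]], P[[Ni]],
                             bNCA, aCNCA, omg)
      P[[paste0("H", i)]] <- place_atom(P[[paste0("O", p)]], P[[paste0("C", p)]],
                                        P[[Ni]], bNH, aCNH, htr)
      P[[Ci]] <- place_atom(P[[paste0("C", p)]], P[[Ni]], P[[CAi]],
                            bCAC, aNCAC, tor[[paste0("phi", i)]])
    }
    rn <- resnames[i]
    # side chains of the seed residue belong to the upstream segment when a
    # partial range is built from residue > 1
    if (rn %in% c("ALA", "CYS", "CLU") && !(i == first && first > 1L)) {
      P[[paste0("CB", i)]] <- place_atom(P[[Ci]], P[[Ni]], P[[CAi]],
                                         bCACB, aNCACB, cbt)
      if (rn != "ALA") {
        ch <- chi1_of[[as.character(i)]]
        if (!is.null(tor[[ch]]))
          P[[paste0("SG", i)]] <- place_atom(P[[Ni]], P[[CAi]], P[[paste0("CB", i)]],
                                             bCBSG, aCACBSG, tor[[ch]])
      }
    }
    if (i == last && i == 7L) {
      # C-terminal carbonyl O: no psi7 exists; anti to N by convention
      P[[paste0("O", i)]] <- place_atom(P[[Ni]], P[[CAi]], P[[Ci]], bCO,
                                        aCACO, 180)
    }
  }
  P
}

# Minimal rotation taking unit vector a onto unit vector b, applied to point
# rows p (all n x 3; a, b rows are unit).  Rodrigues without explicit matrix.
rotate_a_to_b <- function(p, a, b) {
  v <- row_cross(a, b)
  cth <- row_dot(a, b)
  # antiparallel guard: rotate 180 about any axis perpendicular to a
  flip <- cth < -1 + 1e-12
  if (any(flip)) {
    perp <- row_unit(row_cross(a[flip, , drop = FALSE],
                               matrix(rep(c(1, 0.3, 0.2), each = sum(flip)), ncol = 3L)))
    pf <- p[flip, , drop = FALSE]
    p[flip, ] <- 2 * row_dot(pf, perp) * perp - pf
  }
  ok <- !flip
  po <- p[ok, , drop = FALSE]; vo <- v[ok, , drop = FALSE]
  co <- cth[ok]
  p[ok, ] <- po * co + row_cross(vo, po) + vo * (row_dot(vo, po) / (1 + co))
  p
}

# Rotate point rows p about per-row unit axis u through origin by ang degrees.
rotate_about_axis_rows <- function(p, u, ang) {
  th <- ang * pi / 180
  ct <- cos(th); st <- sin(th)
  p * ct + row_cross(u, p) * st + u * (row_dot(u, p) * (1 - ct))
}

# Place the 8 cluster atoms for all states.  P must contain CA4, CB4, SG4.
# Returns list of n x 3 matrices FE1..FE4, SCL1..SCL4 (cluster sulfides).
default_cubane <- function(tpl = residue_templates()) {
  ff <- tpl$params[["fe_fe"]]
  build_cubane(fe_s = tpl_len(tpl, "FE-S"),
               fe_fe = if (is.null(ff)) 2.73 else ff)
}

fuse_states <- function(P, chi2, chi3, tpl = residue_templates(),
                        cluster = default_cubane(tpl)) {
  bSGFE <- tpl_len(tpl, "SG-FE"); aCBSGFE <- tpl_ang(tpl, "CB-SG-FE")
  CA4 <- as_rowmat(P$CA4); CB4 <- as_rowmat(P$CB4); SG4 <- as_rowmat(P$SG4)
  fe1 <- place_atom(CA4, CB4, SG4, bSGFE, aCBSGFE, chi2)
  fe1 <- as_rowmat(fe1)
  n <- nrow(fe1)
  # local cubane: centroid at origin; FE1 along (1,1,1)
  loc <- rbind(cluster$fe, cluster$s)
  u_loc <- loc[1L, ] / sqrt(sum(loc[1L, ]^2))
  d_ctr <- sqrt(sum(loc[1L, ]^2))
  u_glob <- row_unit(SG4 - fe1)            # centroid -> FE1 -> SG direction
  ctr <- fe1 - d_ctr * u_glob
  a <- matrix(u_loc, n, 3L, byrow = TRUE)
  out <- vector("list", 8L)
  for (k in 1:8) {
    pk <- matrix(loc[k, ], n, 3L, byrow = TRUE)
    out[[k]] <- ctr + rotate_a_to_b(pk, a, u_glob)
  }
  names(out) <- c(paste0("FE", 1:4), paste0("SCL", 1:4))
  # chi3: torsion CB4-SG4-FE1-SCLref about the SG-FE axis; SCLref is FE1's
  # first bonded sulfide in the local table
  sref <- cluster$bonds[cluster$bonds[, "row"] == 1L, "col"][1L]
  t0 <- measure_dihedral(CB4, SG4, out$FE1, out[[4L + sref]], check = FALSE)
  dlt <- wrap_angle(chi3 - t0)
  axis <- -u_glob                          # SG -> FE direction
  for (k in 1:8) {
    out[[k]] <- fe1 + rotate_about_axis_rows(out[[k]] - fe1, axis, dlt)
  }
  out
}

# ---------------------------------------------------------------------------
# Single-structure interfaces

atom_element <- function(elety) {
  ifelse(grepl("^FE", elety), "FE", substr(elety, 1L, 1L))
}

peptide_atom_meta <- function(resnames) {
  rows <- list()
  for (i in seq_along(resnames)) {
    nm <- c("N", if (i > 1L) "H", "CA", "C", "O",
            if (resnames[i] %in% c("ALA", "CYS", "CLU")) "CB",
            if (resnames[i] %in% c("CYS", "CLU")) "SG")
    rows[[i]] <- data.frame(resno = i, resid = resnames[i], elety = nm,
                            stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, rows)
  meta$key <- paste0(meta$elety, meta$resno)
  meta$elem <- atom_element(meta$elety)
  meta
}

cluster_atom_meta <- function() {
  data.frame(resno = 8L, resid = "SF4",
             elety = c(paste0("FE", 1:4), paste0("S", 1:4)),
             key = c(paste0("FE", 1:4), paste0("SCL", 1:4)),
             elem = c(rep("FE", 4L), rep("S", 4L)),
             stringsAsFactors = FALSE)
}

# Covalent bond list (pairs of atom keys) for a peptide or fused complex.
bond_list <- function(resnames, fused = FALSE,
                      cluster = NULL) {
  b <- list()
  add <- function(a1, a2) b[[length(b) + 1L]] <<- c(a1, a2)
  for (i in seq_along(resnames)) {
    add(paste0("N", i), paste0("CA", i))
    add(paste0("CA", i), paste0("C", i))
    add(paste0("C", i), paste0("O", i))
    if (i > 1L) { add(paste0("C", i - 1L), paste0("N", i)); add(paste0("N", i), paste0("H", i)) }
    if (resnames[i] %in% c("ALA", "CYS", "CLU")) add(paste0("CA", i), paste0("CB", i))
    if (resnames[i] %in% c("CYS", "CLU")) add(paste0("CB", i), paste0("SG", i))
  }
  if (fused) {
    add("SG4", "FE1")
    for (r in seq_len(nrow(cluster$bonds)))
      add(paste0("FE", cluster$bonds[r, "row"]), paste0("SCL", cluster$bonds[r, "col"]))
  }
  do.call(rbind, b)
}

states_to_table <- function(P, meta, k = 1L) {
  xyz <- t(vapply(meta$key, function(a) {
    m <- as_rowmat(P[[a]])
    m[if (nrow(m) == 1L) 1L else k, ]
  }, numeric(3L)))
  out <- meta
  out$x <- xyz[, 1L]; out$y <- xyz[, 2L]; out$z <- xyz[, 3L]
  rownames(out) <- NULL
  out
}

#' Build a heptapeptide from torsions
#'
#' Grows the chain by sequential internal-to-Cartesian placement using the
#' ideal template geometry; peptide bonds are trans (omega = 180).  Amide
#' hydrogens are built explicitly at residues 2-7 (the N-terminus carries
#' none).
#'
#' @param sequence 7 one-letter (or three-letter) residue codes; positions
#'   1, 4 and 7 must be cysteine-like.
#' @param state a [dihedral_state()] (chi2/chi3 are ignored until fusion).
#' @param templates a [residue_templates()] table.
#' @return object of class `conformation`: list with the atom data frame
#'   (`atoms`: resno, resid, elety, elem, key, x, y, z), `sequence`,
#'   `resnames`, `state` and the covalent `bonds` (atom-key pairs).
#' @export
build_peptide <- function(sequence, state, templates = residue_templates()) {
  resnames <- check_sequence(sequence)
  if (!inherits(state, "dihedral_state")) stop("state must be a dihedral_state")
  tor <- as.list(state_to_vector(state))
  P <- build_chain_states(resnames, tor, templates)
  meta <- peptide_atom_meta(resnames)
  structure(list(atoms = states_to_table(P, meta), sequence = sequence,
                 resnames = resnames, state = state,
                 bonds = bond_list(resnames, fused = FALSE)),
            class = "conformation")
}

#' Fuse an Fe4S4 cluster onto the central cysteine
#'
#' Converts residue 4 into the hybrid Clu residue: the cluster is placed so
#' the Sgamma(4)-Fe bond has the template ligation length, with orientation
#' set by the chi2 (CA-CB-SG-Fe) and chi3 (CB-SG-Fe-S) torsions.  Residues
#' 1 and 7 remain unligated candidates for the geometric screen.
#'
#' @param peptide a [build_peptide()] result.
#' @param cluster a [build_cubane()] geometry.
#' @param chi2,chi3 torsions in degrees (default: the values in the
#'   peptide's stored state).
#' @param templates a [residue_templates()] table.
#' @return object of class `fs_complex`: like `conformation` plus cluster
#'   atoms (resno 8, resid `SF4`), the `cluster` geometry, and
#'   `ligation = c("4" = 1)` (Sgamma 4 bound to Fe 1).
#' @export
fuse_cluster <- function(peptide, cluster = NULL, chi2 = peptide$state$chi2,
                         chi3 = peptide$state$chi3,
                         templates = residue_templates()) {
  if (is.null(cluster)) cluster <- default_cubane(templates)
  P <- stats::setNames(lapply(peptide$atoms$key, function(k)
    as.numeric(peptide$atoms[peptide$atoms$key == k, c("x", "y", "z")])),
    peptide$atoms$key)
  CL <- fuse_states(P, chi2, chi3, templates, cluster)
  if (any(!is.finite(unlist(CL))))
    stop("fusion error: cluster placement produced non-finite coordinates")
  resnames <- peptide$resnames
  resnames[4L] <- "CLU"
  meta <- peptide_atom_meta(resnames)
  atoms <- states_to_table(c(P, CL), rbind(meta, cluster_atom_meta()))
  st <- peptide$state; st$chi2 <- wrap_angle(chi2); st$chi3 <- wrap_angle(chi3)
  structure(list(atoms = atoms, sequence = peptide$sequence,
                 resnames = resnames, state = st, cluster = cluster,
                 ligation = c("4" = 1L),
                 bonds = bond_list(resnames, fused = TRUE, cluster = cluster)),
            class = "fs_complex")
}

#' Build a full heptapeptide-cluster complex from a dihedral state
#'
#' Convenience wrapper: [build_peptide()] followed by [fuse_cluster()].
#'
#' @inheritParams build_peptide
#' @param cluster optional [build_cubane()] geometry (default ideal).
#' @return an `fs_complex`.
#' @export
build_complex <- function(sequence, state, cluster = NULL,
                          templates = residue_templates()) {
  fuse_cluster(build_peptide(sequence, state, templates), cluster,
               templates = templates)
}

# ---------------------------------------------------------------------------
# Accessors and measurement

atom_xyz <- function(cx, keys = NULL) {
  a <- cx$atoms
  if (!is.null(keys)) a <- a[match(keys, a$key), , drop = FALSE]
  out <- as.matrix(a[, c("x", "y", "z")])
  rownames(out) <- a$key
  out
}

#' Measure all model torsions on built coordinates
#'
#' @param cx a `conformation` or `fs_complex`.
#' @return named numeric vector over [torsion_names()] (chi2/chi3 are `NA`
#'   for an unfused peptide).
#' @export
measure_state <- function(cx) {
  g <- function(k) as.numeric(cx$atoms[cx$atoms$key == k, c("x", "y", "z")])
  out <- stats::setNames(rep(NA_real_, 17L), torsion_names())
  for (i in 2:7)
    out[paste0("phi", i)] <- measure_dihedral(g(paste0("C", i - 1L)), g(paste0("N", i)),
                                              g(paste0("CA", i)), g(paste0("C", i)))
  for (i in 1:6)
    out[paste0("psi", i)] <- measure_dihedral(g(paste0("N", i)), g(paste0("CA", i)),
                                              g(paste0("C", i)), g(paste0("N", i + 1L)))
  for (i in c(1L, 4L, 7L)) {
    key <- paste0("SG", i)
    if (key %in% cx$atoms$key)
      out[paste0("chi1", if (i == 1L) "1" else as.character(i))] <-
        measure_dihedral(g(paste0("N", i)), g(paste0("CA", i)),
                         g(paste0("CB", i)), g(key))
  }
  if ("FE1" %in% cx$atoms$key) {
    out["chi2"] <- measure_dihedral(g("CA4"), g("CB4"), g("SG4"), g("FE1"))
    sref <- cx$cluster$bonds[cx$cluster$bonds[, "row"] == 1L, "col"][1L]
    out["chi3"] <- measure_dihedral(g("CB4"), g("SG4"), g("FE1"),
                                    g(paste0("SCL", sref)))
  }
  out
}

#' Mirror a structure through a plane
#'
#' Reflection helper exploiting the achirality of the cluster: all
#' interatomic distances are preserved and applying it twice is the
#' identity.
#'
#' @param cx a `conformation` or `fs_complex`.
#' @param normal,point plane specification (default the xy-plane).
#' @return the reflected object (same class).
#' @export
mirror_complex <- function(cx, normal = c(0, 0, 1), point = c(0, 0, 0)) {
  xyz <- reflect_coords(atom_xyz(cx), normal, point)
  cx$atoms$x <- xyz[, 1L]; cx$atoms$y <- xyz[, 2L]; cx$atoms$z <- xyz[, 3L]
  if (!is.null(cx$state)) cx$state <- NULL  # torsions no longer those of the build
  cx
}

#' Verify L configuration at alpha carbons
#'
#' Signed-volume test: for each residue with a CB, the determinant of
#' (N-CA, C-CA, CB-CA) must be positive for the L configuration.
#'
#' @param cx a `conformation` or `fs_complex`.
#' @return named logical vector (one entry per CB-bearing residue).
#' @export
is_l_configured <- function(cx) {
  res <- which(vapply(seq_along(cx$resnames), function(i)
    paste0("CB", i) %in% cx$atoms$key, logical(1L)))
  g <- function(k) as.numeric(cx$atoms[cx$atoms$key == k, c("x", "y", "z")])
  out <- vapply(res, function(i) {
    det(rbind(g(paste0("N", i)) - g(paste0("CA", i)),
              g(paste0("C", i)) - g(paste0("CA", i)),
              g(paste0("CB", i)) - g(paste0("CA", i)))) > 0
  }, logical(1L))
  stats::setNames(out, cx$resnames[res])
}

#' Write a complex as a PDB file
#'
#' Peptide atoms are ATOM records; cluster atoms are HETATM records in
#' residue SF4 (atom names FE1-FE4, S1-S4), so models open in standard
#' molecular viewers.
#'
#' @param cx a `conformation` or `fs_complex`.
#' @param file output path.
#' @param chain chain identifier.
#' @return `file`, invisibly.
#' @export
write_complex_pdb <- function(cx, file, chain = "A") {
  a <- cx$atoms
  het <- a$resid == "SF4"
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                   elety = a$elety, chain = rep(chain, nrow(a)),
                   elesy = ifelse(a$elem == "FE", "FE", a$elem))
  invisible(file)
}
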