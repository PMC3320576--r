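# Survey of experimental structures: find Fe4S4 clusters bound through
# CXXCXXC motifs, locate the outlier cysteine, and compute topology angles.
#
# PDB files are parsed with bio3d; mmCIF files with a minimal atom_site
# reader (no installed R package parses mmCIF).  Only the first model is
# kept and alternate locations resolve to the highest-occupancy copy.

#' Read a structure file (PDB or mmCIF)
#'
#' @param path file path; format chosen by extension (`.cif`/`.mmcif` for
#'   mmCIF, anything else is treated as PDB).
#' @return object of class `structure_model`: list with `atoms` (data frame:
#'   `chain`, `resno` (author numbering), `label_seq` (ordinal position in
#'   the chain), `resid`, `elety`, `elem`, `x`, `y`, `z`, `het`) and
#'   `path`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  ext <- tolower(tools::file_ext(path))
  atoms <- if (ext %in% c("cif", "mmcif")) read_cif_atoms(path)
           else read_pdb_atoms(path)
  # ordinal sequence position per chain (insertion-code safe)
  key <- paste(atoms$chain, atoms$resno, atoms$insert)
  atoms$label_seq <- NA_integer_
  for (ch in unique(atoms$chain)) {
    sel <- atoms$chain == ch
    atoms$label_seq[sel] <- match(key[sel], unique(key[sel]))
  }
  structure(list(atoms = atoms, path = path), class = "structure_model")
}

read_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("format error reading ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  a$o[is.na(a$o)] <- 1
  a <- resolve_altloc(a)
  data.frame(chain = ifelse(is.na(a$chain), "A", a$chain),
             resno = a$resno,
             insert = ifelse(is.na(a$insert), "", a$insert),
             resid = a$resid, elety = a$elety,
             elem = normalize_element(a$elesy, a$elety),
             x = a$x, y = a$y, z = a$z,
             het = a$type == "HETATM", stringsAsFactors = FALSE)
}

resolve_altloc <- function(a) {
  alt <- ifelse(is.na(a$alt) | a$alt == "", "", a$alt)
  if (!any(alt != "")) return(a)
  gid <- paste(a$chain, a$resno, a$insert, a$elety)
  keep <- rep(TRUE, nrow(a))
  for (g in unique(gid[alt != ""])) {
    rows <- which(gid == g)
    if (length(rows) > 1L) {
      best <- rows[which.max(a$o[rows])]
      keep[setdiff(rows, best)] <- FALSE
    }
  }
  a[keep, , drop = FALSE]
}

normalize_element <- function(elesy, elety) {
  e <- toupper(trimws(ifelse(is.na(elesy) | elesy == "", NA, elesy)))
  miss <- is.na(e)
  e[miss] <- toupper(substr(trimws(elety[miss]), 1L, 1L))
  e[grepl("^FE", toupper(elety)) & nchar(e) <= 1L] <- "FE"
  e
}

# Minimal mmCIF atom_site reader: handles the standard loop_ layout with
# whitespace-separated values and single-quoted tokens.
read_cif_atoms <- function(path) {
  ln <- readLines(path, warn = FALSE)
  start <- grep("^_atom_site\\.", ln)
  if (!length(start)) stop("format error reading ", path,
                           ": no _atom_site loop found")
  tags <- c()
  i <- start[1L]
  while (i <= length(ln) && grepl("^_atom_site\\.", ln[i])) {
    tags <- c(tags, sub("^_atom_site\\.", "", trimws(ln[i])))
    i <- i + 1L
  }
  rows <- list()
  while (i <= length(ln)) {
    l <- trimws(ln[i])
    if (l == "" || grepl("^(#|loop_|_|data_)", l)) break
    tok <- scan(text = l, what = "", quiet = TRUE)
    if (length(tok) != length(tags))
      stop("format error reading ", path, ": line ", i,
           " has ", length(tok), " fields, expected ", length(tags))
    rows[[length(rows) + 1L]] <- tok
    i <- i + 1L
  }
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% tags) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  model <- pick("pdbx_PDB_model_num")
  keep <- if (all(is.na(model))) rep(TRUE, nrow(m)) else model == model[1L]
  a <- data.frame(type = pick("group_PDB")[keep],
                  chain = pick("auth_asym_id", "label_asym_id")[keep],
                  resno = as.integer(pick("auth_seq_id", "label_seq_id")[keep]),
                  insert = pick("pdbx_PDB_ins_code")[keep],
                  resid = pick("auth_comp_id", "label_comp_id")[keep],
                  elety = pick("auth_atom_id", "label_atom_id")[keep],
                  elesy = pick("type_symbol")[keep],
                  alt = pick("label_alt_id")[keep],
                  o = as.numeric(pick("occupancy")[keep]),
                  x = as.numeric(pick("Cartn_x")[keep]),
                  y = as.numeric(pick("Cartn_y")[keep]),
                  z = as.numeric(pick("Cartn_z")[keep]),
                  stringsAsFactors = FALSE)
  a$insert[is.na(a$insert) | a$insert %in% c(".", "?")] <- ""
  a$alt[a$alt %in% c(".", "?")] <- ""
  a$o[is.na(a$o)] <- 1
  a <- resolve_altloc(a)
  data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
             resid = a$resid, elety = a$elety,
             elem = normalize_element(a$elesy, a$elety),
             x = a$x, y = a$y, z = a$z,
             het = a$type == "HETATM", stringsAsFactors = FALSE)
}

#' Find Fe4S4 cubane clusters in a structure
#'
#' Identifies heterogroups with exactly 4 Fe and 4 S atoms (residue name
#' `SF4` or any matching stoichiometry) whose geometry passes the cubane
#' tolerances.
#'
#' @param model a [read_structure()] result.
#' @return list of cluster instances: each a list with `id`, `atoms` (the 8
#'   rows), `geometry` (a `cluster_geometry`), and `centroid`.
#' @export
find_clusters <- function(model) {
  a <- model$atoms
  grp <- a[a$het | a$resid == "SF4", , drop = FALSE]
  if (!nrow(grp)) return(list())
  gid <- paste(grp$chain, grp$resno, grp$resid)
  out <- list()
  for (g in unique(gid)) {
    rows <- grp[gid == g, , drop = FALSE]
    if (sum(rows$elem == "FE") != 4L || sum(rows$elem == "S") != 4L) next
    geom <- tryCatch(
      build_cubane("table", coords = data.frame(element = rows$elem,
                                                x = rows$x, y = rows$y,
                                                z = rows$z)),
      error = function(e) NULL)
    if (is.null(geom)) next
    out[[length(out) + 1L]] <-
      list(id = g, atoms = rows, geometry = geom,
           centroid = colMeans(as.matrix(rows[, c("x", "y", "z")])))
  }
  out
}

#' Find cluster-binding CXXCXXC motifs
#'
#' Coordinating cysteines have Sgamma within `ligation_cutoff` of a cluster
#' Fe; a motif is three coordinating cysteines at sequence spacing
#' i, i+3, i+6 within one chain (ordinal positions, so insertion codes do
#' not break spacing); the outlier is a fourth coordinating cysteine
#' elsewhere (Type A if C-terminal to the motif, Type B if N-terminal).
#'
#' @param model a [read_structure()] result.
#' @param cluster one element of [find_clusters()].
#' @param ligation_cutoff Sgamma...Fe distance cutoff in Angstrom.
#' @return data frame of motif hits: `structure`, `chain`, motif residue
#'   numbers, `outlier_resno`, `outlier_type` (`A`/`B`/`none`), `theta`,
#'   `handedness`.
#' @export
find_motifs <- function(model, cluster, ligation_cutoff = 3.0) {
  a <- model$atoms
  fe <- as.matrix(cluster$atoms[cluster$atoms$elem == "FE", c("x", "y", "z")])
  sg <- a[a$resid == "CYS" & a$elety == "SG", , drop = FALSE]
  if (!nrow(sg)) return(motif_hit_empty())
  coord <- vapply(seq_len(nrow(sg)), function(r) {
    p <- as.numeric(sg[r, c("x", "y", "z")])
    min(sqrt(rowSums(sweep(fe, 2L, p)^2))) < ligation_cutoff
  }, logical(1L))
  sg <- sg[coord, , drop = FALSE]
  if (!nrow(sg)) return(motif_hit_empty())
  hits <- list()
  for (ch in unique(sg$chain)) {
    cc <- sg[sg$chain == ch, , drop = FALSE]
    cc <- cc[order(cc$label_seq), , drop = FALSE]
    ls <- cc$label_seq
    for (k in seq_len(nrow(cc))) {
      m2 <- match(ls[k] + 3L, ls); m3 <- match(ls[k] + 6L, ls)
      if (is.na(m2) || is.na(m3)) next
      trio <- c(k, m2, m3)
      ca <- lapply(trio, function(t)
        as.numeric(a[a$chain == ch & a$label_seq == ls[t] & a$elety == "CA",
                     c("x", "y", "z")][1L, ]))
      if (any(vapply(ca, anyNA, logical(1L)))) next
      tp <- topology_angle(ca[[1L]], ca[[2L]], ca[[3L]], cluster$centroid)
      # outlier: any other coordinating Cys (any chain)
      others <- sg[!(sg$chain == ch & sg$label_seq %in% ls[trio]), , drop = FALSE]
      if (nrow(others)) {
        ot <- others[1L, ]
        type <- if (ot$chain != ch) "none"
                else if (ot$label_seq > ls[trio[3L]]) "A"
                else if (ot$label_seq < ls[trio[1L]]) "B" else "none"
        orn <- ot$resno
      } else { type <- "none"; orn <- NA_integer_ }
      hits[[length(hits) + 1L]] <- data.frame(
        structure = basename(model$path), chain = ch,
        cys1 = cc$resno[k], cys2 = cc$resno[m2], cys3 = cc$resno[m3],
        outlier_resno = orn, outlier_type = type, cluster_id = cluster$id,
        theta = tp$theta, handedness = tp$handedness,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits)) do.call(rbind, hits) else motif_hit_empty()
}

motif_hit_empty <- function() {
  data.frame(structure = character(0L), chain = character(0L),
             cys1 = integer(0L), cys2 = integer(0L), cys3 = integer(0L),
             outlier_resno = integer(0L), outlier_type = character(0L),
             cluster_id = character(0L), theta = numeric(0L),
             handedness = character(0L), stringsAsFactors = FALSE)
}

#' Survey structure files for cluster-binding motifs
#'
#' Scans each file for Fe4S4 clusters and CXXCXXC motifs; files that fail to
#' parse are logged and skipped, never abort the batch.
#'
#' @param paths character vector of PDB/mmCIF files.
#' @param out_dir optional directory for `hits.tsv` and `theta_hist.tsv`.
#' @param theta_bin histogram bin width in degrees.
#' @return list with `hits` (one row per motif), `theta_histogram`, and
#'   `skipped` (files that failed to parse, with messages).
#' @export
survey_structures <- function(paths, out_dir = NULL, theta_bin = 5) {
  if (!length(paths)) stop("input error: no structure files supplied")
  hits <- list(); skipped <- list()
  for (p in paths) {
    res <- tryCatch({
      model <- read_structure(p)
      do.call(rbind, c(list(motif_hit_empty()),
                       lapply(find_clusters(model), function(cl)
                         find_motifs(model, cl))))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping ", p, ": ", conditionMessage(res), call. = FALSE)
      skipped[[length(skipped) + 1L]] <- data.frame(path = p,
                                                   message = conditionMessage(res))
    } else if (nrow(res)) hits[[length(hits) + 1L]] <- res
  }
  hits <- if (length(hits)) do.call(rbind, hits) else motif_hit_empty()
  rownames(hits) <- NULL
  hist <- hist_table(hits$theta, theta_bin, 0, 180)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(hits, file.path(out_dir, "hits.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(hist, file.path(out_dir, "theta_hist.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  list(hits = hits, theta_histogram = hist,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}
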