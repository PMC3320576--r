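# Loaders for the plain-text parameter tables shipped under extdata:
# residue templates (ideal covalent geometry), Lennard-Jones parameters and
# partial charges.  All three are memoised per file path.

.ferro_cache <- new.env(parent = emptyenv())

default_param_file <- function(name) {
  system.file("extdata", name, package = "ferrotopo", mustWork = TRUE)
}

read_param_lines <- function(file) {
  ln <- readLines(file, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln[nzchar(ln)]
}

#' Residue templates: ideal covalent geometry
#'
#' Parses the plain-text template table (bond lengths, bond angles, fixed
#' torsion parameters and residue atom lists) that defines the ideal internal
#' coordinates used by every builder in the package.  The file format is
#' documented in the shipped default
#' (`system.file("extdata", "residue_templates.txt", package = "ferrotopo")`).
#'
#' @param file path to a template file; default the shipped table.
#' @return an object of class `residue_templates`: a list with named numeric
#'   vectors `lengths` (Angstrom) and `angles` (degrees), a named numeric
#'   vector `params`, and a named list `residues` of heavy-atom names.
#' @export
residue_templates <- function(file = default_param_file("residue_templates.txt")) {
  key <- paste0("tpl:", normalizePath(file))
  if (!is.null(.ferro_cache[[key]])) return(.ferro_cache[[key]])
  lens <- c(); angs <- c(); pars <- c(); res <- list()
  for (l in read_param_lines(file)) {
    f <- strsplit(l, "[[:space:]]+")[[1L]]
    switch(f[1L],
      length = { lens[f[2L]] <- as.numeric(f[3L]) },
      angle  = { angs[f[2L]] <- as.numeric(f[3L]) },
      param  = { pars[f[2L]] <- as.numeric(f[3L]) },
      residue = { res[[f[2L]]] <- f[-(1:2)] },
      stop("unrecognized template record: ", l)
    )
  }
  bad <- lens[!(lens > 0.8 & lens < 2.5)]
  if (length(bad)) stop("template bond length outside (0.8, 2.5) A: ",
                        paste(names(bad), collapse = ", "))
  tpl <- structure(list(lengths = lens, angles = angs, params = pars,
                        residues = res, file = file),
                   class = "residue_templates")
  .ferro_cache[[key]] <- tpl
  tpl
}

tpl_len <- function(tpl, key) {
  v <- tpl$lengths[[key]]
  if (is.null(v)) stop("template is missing bond length ", key)
  v
}

tpl_ang <- function(tpl, key) {
  v <- tpl$angles[[key]]
  if (is.null(v)) stop("template is missing bond angle ", key)
  v
}

#' Lennard-Jones parameter table
#'
#' Reads the per-element sigma/epsilon table.  A `scale` directive in the
#' file multiplies every sigma at load time; the shipped set scales radii by
#' 0.9, the protein-design convention for screening discretely sampled
#' conformations whose small strains fixed sampling cannot relieve.
#'
#' @param file path to a per-element sigma/epsilon table; default the shipped
#'   set.
#' @return data frame with columns `element`, `sigma` (Angstrom, after
#'   scaling), `epsilon` (kcal/mol); the applied factor is kept in
#'   `attr(, "scale")`.
#' @export
lj_params <- function(file = default_param_file("lj_params.txt")) {
  key <- paste0("lj:", normalizePath(file))
  if (!is.null(.ferro_cache[[key]])) return(.ferro_cache[[key]])
  rows <- lapply(read_param_lines(file), function(l) strsplit(l, "[[:space:]]+")[[1L]])
  first <- vapply(rows, `[`, "", 1L)
  scale <- 1
  if (any(tolower(first) == "scale")) {
    scale <- as.numeric(rows[[which(tolower(first) == "scale")[1L]]][2L])
    rows <- rows[tolower(first) != "scale"]
  }
  out <- data.frame(element = toupper(vapply(rows, `[`, "", 1L)),
                    sigma   = as.numeric(vapply(rows, `[`, "", 2L)) * scale,
                    epsilon = as.numeric(vapply(rows, `[`, "", 3L)),
                    stringsAsFactors = FALSE)
  attr(out, "scale") <- scale
  .ferro_cache[[key]] <- out
  out
}

#' Partial-charge set
#'
#' Reads the atom-key to charge table (keys `<residue>.<atom>`, wildcard
#' residue `*`) and exposes the cluster charges as named fields.  The shipped
#' defaults give the oxidized cluster plus three coordinating cysteines a net
#' charge of -1 e.
#'
#' @param file path to a charge table; default the shipped set.
#' @return an object of class `charge_set`: list with the lookup `table`
#'   plus convenience scalars `q_fe`, `q_s_cluster`, `q_sg`.
#' @export
charge_set <- function(file = default_param_file("charges.txt")) {
  key <- paste0("q:", normalizePath(file))
  if (!is.null(.ferro_cache[[key]])) return(.ferro_cache[[key]])
  rows <- lapply(read_param_lines(file), function(l) strsplit(l, "[[:space:]]+")[[1L]])
  tab <- stats::setNames(as.numeric(vapply(rows, `[`, "", 2L)),
                         vapply(rows, `[`, "", 1L))
  get0 <- function(k) if (k %in% names(tab)) unname(tab[[k]]) else NA_real_
  cs <- structure(list(table = tab,
                       q_fe = get0("SF4.FE"),
                       q_s_cluster = get0("SF4.S"),
                       q_sg = get0("*.SG"),
                       file = file),
                  class = "charge_set")
  .ferro_cache[[key]] <- cs
  cs
}

#' Look up per-atom charges for a complex
#'
#' @param meta data frame with columns `resid` and `elety` (as in a
#'   `fs_complex` atom table).
#' @param charges a [charge_set()].
#' @return numeric vector of charges (e), one per row of `meta`.
#' @export
atom_charges <- function(meta, charges = charge_set()) {
  tab <- charges$table
  # cluster atom types FE1..FE4 / S1..S4 map onto the SF4.FE / SF4.S keys
  base <- ifelse(grepl("^FE", meta$elety), "FE",
          ifelse(meta$resid == "SF4", "S", meta$elety))
  if ("resno" %in% names(meta)) {
    pep <- meta$resid != "SF4"
    if (any(pep))
      base[pep & meta$resno == min(meta$resno[pep]) & meta$elety == "N"] <- "NT"
  }
  keys <- paste(meta$resid, base, sep = ".")
  wild <- paste("*", base, sep = ".")
  q <- unname(tab[keys])
  q[is.na(q)] <- unname(tab[wild[is.na(q)]])
  if (anyNA(q))
    stop("no charge for atom key(s): ",
         paste(unique(keys[is.na(q)]), collapse = ", "))
  q
}
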