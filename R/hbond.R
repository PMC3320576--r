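# Backbone amide-to-sulfur hydrogen-bond census with discrete geometric
# cutoffs.  Two rules are supported:
#   H-S rule:  H...S < 3.5 A and N-H...S angle in [120, 180] degrees
#   N-S rule:  N...S < 3.8 A and N-H...S angle in [110, 180] degrees
# Acceptors are the four inorganic sulfides plus (by default) the ligating
# cysteine Sgamma thiolates.

#' Hydrogen-bond criteria
#'
#' @param hs_dist_max strict upper bound on the H...S distance (Angstrom).
#' @param nhs_angle_range closed N-H...S angle window for the H-S rule
#'   (degrees).
#' @param ns_dist_max strict upper bound on the N...S distance (Angstrom).
#' @param ns_angle_range closed angle window for the N-S rule (degrees).
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(hs_dist_max = 3.5, nhs_angle_range = c(120, 180),
                           ns_dist_max = 3.8, ns_angle_range = c(110, 180)) {
  if (hs_dist_max <= 0 || ns_dist_max <= 0) stop("distance cutoffs must be positive")
  rngs <- c(nhs_angle_range, ns_angle_range)
  if (any(rngs < 0 | rngs > 180)) stop("angle ranges must lie within [0, 180]")
  structure(list(hs_dist_max = hs_dist_max,
                 nhs_angle_range = sort(nhs_angle_range),
                 ns_dist_max = ns_dist_max,
                 ns_angle_range = sort(ns_angle_range)),
            class = "hbond_criteria")
}

# Donor table for a complex: backbone amide N-H pairs (residues 2-7; the
# N-terminus has no amide H).
hbond_donors <- function(cx) {
  keys <- cx$atoms$key
  res <- which(vapply(2:7, function(i)
    paste0("H", i) %in% keys && paste0("N", i) %in% keys, logical(1L))) + 1L
  data.frame(resno = res, n_key = paste0("N", res), h_key = paste0("H", res),
             stringsAsFactors = FALSE)
}

# Acceptor table: inorganic sulfides and (optionally) ligating Sgamma atoms.
hbond_acceptors <- function(cx, include_sg = TRUE, criteria_fe_sg = 3.0) {
  a <- cx$atoms
  acc <- a[a$resid == "SF4" & a$elem == "S", c("key", "elety")]
  names(acc) <- c("key", "label")
  if (include_sg) {
    sg <- a[a$elety == "SG", , drop = FALSE]
    if (nrow(sg)) {
      fe <- as.matrix(a[a$elem == "FE", c("x", "y", "z")])
      keep <- vapply(seq_len(nrow(sg)), function(r) {
        p <- as.numeric(sg[r, c("x", "y", "z")])
        min(sqrt(rowSums(sweep(fe, 2L, p)^2))) < criteria_fe_sg
      }, logical(1L))
      if (any(keep))
        acc <- rbind(acc, data.frame(key = sg$key[keep],
                                     label = paste0("SG", sg$resno[keep])))
    }
  }
  acc
}

#' Census backbone amide-to-sulfur hydrogen bonds
#'
#' Counts donor-acceptor pairs under the H-S rule and under the N-S rule.
#' Each (donor, acceptor) pair is counted once per rule; a donor may
#' contact several acceptors (bifurcation counts each pair, switchable via
#' `per_donor`).
#'
#' @param cx an `fs_complex` (amide hydrogens are present by construction;
#'   for structures lacking them an error is raised).
#' @param criteria an [hbond_criteria()].
#' @param include_sg also accept ligating cysteine Sgamma atoms (default
#'   `TRUE`); set `FALSE` to restrict to the inorganic sulfides.
#' @param per_donor if `TRUE`, count at most one contact per donor per rule.
#' @return object of class `hbond_census`: list with the `contacts` data
#'   frame (donor resno, acceptor, H...S, N-H...S angle, N...S, rule hits)
#'   and counts `n_hs` / `n_ns`.
#' @export
find_hbonds <- function(cx, criteria = hbond_criteria(), include_sg = TRUE,
                        per_donor = FALSE) {
  don <- hbond_donors(cx)
  if (!nrow(don))
    stop("missing donor: no backbone amide hydrogens in this structure")
  acc <- hbond_acceptors(cx, include_sg)
  xyz <- atom_xyz(cx)
  rows <- list()
  for (d in seq_len(nrow(don))) {
    N <- xyz[don$n_key[d], ]; H <- xyz[don$h_key[d], ]
    for (a in seq_len(nrow(acc))) {
      S <- xyz[acc$key[a], ]
      hs <- sqrt(sum((H - S)^2))
      ns <- sqrt(sum((N - S)^2))
      ang <- measure_angle(N, H, S)
      hit_hs <- hs < criteria$hs_dist_max &&
        ang >= criteria$nhs_angle_range[1L] && ang <= criteria$nhs_angle_range[2L]
      hit_ns <- ns < criteria$ns_dist_max &&
        ang >= criteria$ns_angle_range[1L] && ang <= criteria$ns_angle_range[2L]
      if (hit_hs || hit_ns)
        rows[[length(rows) + 1L]] <-
          data.frame(donor_resno = don$resno[d], donor = don$n_key[d],
                     acceptor = acc$label[a], hs_dist = hs,
                     nhs_angle = ang, ns_dist = ns,
                     hit_hs = hit_hs, hit_ns = hit_ns)
    }
  }
  contacts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor_resno = integer(0L), donor = character(0L),
               acceptor = character(0L), hs_dist = numeric(0L),
               nhs_angle = numeric(0L), ns_dist = numeric(0L),
               hit_hs = logical(0L), hit_ns = logical(0L))
  if (per_donor && nrow(contacts)) {
    n_hs <- length(unique(contacts$donor_resno[contacts$hit_hs]))
    n_ns <- length(unique(contacts$donor_resno[contacts$hit_ns]))
  } else {
    n_hs <- sum(contacts$hit_hs)
    n_ns <- sum(contacts$hit_ns)
  }
  structure(list(contacts = contacts, n_hs = n_hs, n_ns = n_ns,
                 criteria = criteria), class = "hbond_census")
}

#' @export
print.hbond_census <- function(x, ...) {
  cat(sprintf("hydrogen bonds: %d (H-S rule), %d (N-S rule)\n", x$n_hs, x$n_ns))
  invisible(x)
}

# Vectorized H-S-rule census for many states (used by ensemble annotation):
# P is the per-atom coordinate list; returns counts and mean H...S contact
# distance per state.
hbond_counts_states <- function(P, rows, criteria = hbond_criteria(),
                                sg_keys = c("SG1", "SG4", "SG7"),
                                fe_sg_max = 3.0) {
  n <- length(rows)
  getm <- function(k) {
    m <- as_rowmat(P[[k]])
    m[if (nrow(m) == 1L) rep(1L, n) else rows, , drop = FALSE]
  }
  # acceptor availability: sulfides always; SG only when ligating
  acc <- paste0("SCL", 1:4)
  fe <- lapply(paste0("FE", 1:4), getm)
  sg_ok <- list()
  for (k in sg_keys) {
    if (is.null(P[[k]])) next
    m <- getm(k)
    dmin <- rep(Inf, n)
    for (f in fe) dmin <- pmin(dmin, row_norm(m - f))
    sg_ok[[k]] <- dmin < fe_sg_max
  }
  sg_ok[["SG4"]] <- rep(TRUE, n)  # covalently ligated by construction
  count <- numeric(n); dsum <- numeric(n)
  for (i in 2:7) {
    hk <- paste0("H", i)
    if (is.null(P[[hk]])) next
    H <- getm(hk); N <- getm(paste0("N", i))
    for (k in c(acc, names(sg_ok))) {
      if (is.null(P[[k]])) next
      S <- getm(k)
      hs <- row_norm(H - S)
      ang <- measure_angle(N, H, S)
      hit <- hs < criteria$hs_dist_max &
        ang >= criteria$nhs_angle_range[1L] & ang <= criteria$nhs_angle_range[2L]
      if (k %in% names(sg_ok)) hit <- hit & sg_ok[[k]]
      count <- count + hit
      dsum <- dsum + ifelse(hit, hs, 0)
    }
  }
  list(n_hs = count, mean_hs_dist = ifelse(count > 0, dsum / count, NA_real_))
}
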