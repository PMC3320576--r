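# The topology angle theta: a scalar measure of fold handedness for a
# CXXCXXC motif around an Fe4S4 cluster.  A plane is defined by the three
# cysteine alpha carbons (in N- to C-terminal order); theta is the angle
# between the plane normal and the vector from the middle Calpha to the
# cluster centroid.  Right-handed folds score 0 < theta < 90, left-handed
# 90 < theta < 180.

#' Classify handedness from a topology angle
#'
#' @param theta angle in degrees, in `[0, 180]`.
#' @param tolerance half-width (degrees) of the `UNDEFINED` band around the
#'   boundaries 0, 90 and 180.
#' @return `"RIGHT"`, `"LEFT"` or `"UNDEFINED"` (vectorized over `theta`).
#' @export
classify_handedness <- function(theta, tolerance = 1e-6) {
  out <- ifelse(abs(theta - 90) <= tolerance | theta <= tolerance |
                  theta >= 180 - tolerance, "UNDEFINED",
                ifelse(theta < 90, "RIGHT", "LEFT"))
  out
}

#' Topology angle of a cysteine triple around a cluster
#'
#' The plane is spanned by `ca2 - ca1` and `ca3 - ca1`; theta is the angle
#' between the plane normal and `centroid - ca2`.  The normal orientation
#' (the cross product `(ca3 - ca1) x (ca2 - ca1)`) is a convention,
#' calibrated so that the natural ferredoxin fold - the conformation whose
#' backbone amide network hydrogen-bonds the cluster - classifies
#' right-handed (theta below 90 degrees); mirroring a structure maps theta
#' to 180 - theta exactly.
#'
#' @param ca1,ca2,ca3 Calpha coordinates of the three motif cysteines in
#'   N- to C-terminal order.
#' @param cluster_centroid centroid of the 8 cubane atoms.
#' @param tolerance passed to [classify_handedness()].
#' @return object of class `topology_result`: list with `theta` (degrees in
#'   `[0, 180]`), `handedness` and `frame` (the four points used).
#' @export
topology_angle <- function(ca1, ca2, ca3, cluster_centroid, tolerance = 1e-6) {
  v1 <- ca3 - ca1; v2 <- ca2 - ca1
  nrm <- c(v1[2L] * v2[3L] - v1[3L] * v2[2L],
           v1[3L] * v2[1L] - v1[1L] * v2[3L],
           v1[1L] * v2[2L] - v1[2L] * v2[1L])
  nl <- sqrt(sum(nrm^2))
  if (nl < 1e-8 * sqrt(sum(v1^2)) * sqrt(sum(v2^2)) || nl == 0)
    stop("degenerate plane: the three Calpha positions are collinear")
  w <- cluster_centroid - ca2
  theta <- acos(min(1, max(-1, sum(nrm * w) / (nl * sqrt(sum(w^2)))))) * 180 / pi
  structure(list(theta = theta,
                 handedness = classify_handedness(theta, tolerance),
                 frame = list(ca1 = ca1, ca2 = ca2, ca3 = ca3,
                              centroid = cluster_centroid)),
            class = "topology_result")
}

#' Topology angle of a built complex
#'
#' Convenience wrapper extracting the motif Calpha triple (residues 1, 4, 7)
#' and the cluster centroid from an `fs_complex`.
#'
#' @param cx an `fs_complex`.
#' @param tolerance passed to [classify_handedness()].
#' @return a `topology_result`.
#' @export
complex_topology <- function(cx, tolerance = 1e-6) {
  g <- function(k) as.numeric(cx$atoms[cx$atoms$key == k, c("x", "y", "z")])
  cl <- cx$atoms[cx$atoms$resid == "SF4", c("x", "y", "z")]
  if (!nrow(cl)) stop("complex has no cluster atoms")
  topology_angle(g("CA1"), g("CA4"), g("CA7"), colMeans(as.matrix(cl)),
                 tolerance)
}

#' @export
print.topology_result <- function(x, ...) {
  cat(sprintf("topology angle: %.2f deg (%s)\n", x$theta, x$handedness))
  invisible(x)
}
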