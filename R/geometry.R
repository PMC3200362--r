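## Internal-coordinate geometry helpers used by the synthetic-structure
## builders and the hydrogen placer.

#' Place a point by distance, angle and dihedral (NeRF construction)
#'
#' Returns the position of atom D such that |C-D| = dist, angle(B,C,D) =
#' ang (degrees) and dihedral(A,B,C,D) = dih (degrees).
#' @param a,b,c 3-vectors of the three reference atoms
#' @param dist bond length in Angstrom
#' @param ang bond angle in degrees
#' @param dih dihedral in degrees
#' @return 3-vector
#' @keywords internal
place_internal <- function(a, b, c, dist, ang, dih) {
  ang <- ang * pi / 180
  dih <- dih * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) {  # colinear reference frame: pick any perpendicular
    n <- pracma_cross(bc, c(1, 0, 0))
    if (sqrt(sum(n^2)) < 1e-10) n <- pracma_cross(bc, c(0, 1, 0))
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- pracma_cross(n, bc)
  d2 <- c(-dist * cos(ang),
          dist * sin(ang) * cos(dih),
          dist * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# cross product (avoids pulling in a package for one primitive)
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Angle A-B-C in degrees
#' @keywords internal
vec_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Random rigid-body rotation matrix from three Euler angles
#' @keywords internal
rot_matrix <- function(ax, ay, az) {
  cx <- cos(ax); sx <- sin(ax)
  cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  rz %*% ry %*% rx
}
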