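# Rigid-body transforms and internal-coordinate geometry used by the
# lattice and tail builders.  All coordinates are in Angstrom, axes are
# right-handed, rotations are proper (det = +1).

#' Create a rigid-body transform
#'
#' A rigid transform maps a coordinate `x` to `R x + t` with `R` a proper
#' rotation.  Transforms are the currency of the lattice builder: the
#' protofilament transform, ring translations and superposition results are
#' all `rigid_transform` objects.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 translation vector (Angstrom).
#' @param tol tolerance on orthonormality and determinant (default 1e-6).
#' @return an object of class `rigid_transform` with elements `R` and `t`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0), tol = 1e-6) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 100 * tol)
    stop("rotation matrix is not orthonormal within tolerance")
  if (abs(det(rotation) - 1) > 100 * tol)
    stop("rotation matrix must be proper (det = +1); got det = ",
         format(det(rotation)))
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' Identity transform
#' @return a `rigid_transform` that leaves coordinates unchanged.
#' @export
identity_transform <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Apply a rigid transform to coordinates
#'
#' @param tr a `rigid_transform`.
#' @param xyz an n x 3 coordinate matrix (or length-3 vector).
#' @return transformed coordinates, same shape as the input.
#' @export
apply_transform <- function(tr, xyz) {
  stopifnot(inherits(tr, "rigid_transform"))
  if (is.null(dim(xyz))) {
    as.numeric(tr$R %*% xyz + tr$t)
  } else {
    sweep(xyz %*% t(tr$R), 2, tr$t, "+")
  }
}

#' Compose two rigid transforms
#'
#' `compose_transform(f, g)` is the transform "apply `g`, then `f`", i.e.
#' \eqn{x \mapsto R_f (R_g x + t_g) + t_f}.
#'
#' @param f,g `rigid_transform` objects.
#' @return the composed `rigid_transform`.
#' @export
compose_transform <- function(f, g) {
  rigid_transform(f$R %*% g$R, as.numeric(f$R %*% g$t) + f$t)
}

#' Integer power of a rigid transform
#'
#' @param tr a `rigid_transform`.
#' @param n non-negative integer exponent.
#' @return `tr` composed with itself `n` times (`n = 0` gives the identity).
#' @export
transform_power <- function(tr, n) {
  stopifnot(n >= 0, n == round(n))
  out <- identity_transform()
  for (i in seq_len(n)) out <- compose_transform(tr, out)
  out
}

#' Invert a rigid transform
#' @param tr a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(tr) {
  rigid_transform(t(tr$R), as.numeric(-t(tr$R) %*% tr$t))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rotation angle",
      format(rotation_angle(x$R) * 180 / pi, digits = 6), "deg,",
      "translation", paste(format(x$t, digits = 6), collapse = " "), "\n")
  invisible(x)
}

#' Rotation angle of a rotation matrix (radians)
#' @param R 3x3 rotation matrix.
#' @return rotation angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Rotation axis of a rotation matrix
#'
#' Returns the unit eigenvector of `R` with eigenvalue 1.  The sign is
#' arbitrary; callers orient it against a reference direction.
#'
#' @param R 3x3 rotation matrix.
#' @return unit length-3 axis vector.
#' @export
rotation_axis <- function(R) {
  ang <- rotation_angle(R)
  if (ang < 1e-9) return(c(0, 0, 1))
  if (abs(ang - pi) > 1e-6) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  } else {
    # near-180-degree rotation: use the dominant column of R + I
    M <- R + diag(3)
    ax <- M[, which.max(colSums(M^2))]
  }
  ax / sqrt(sum(ax^2))
}

#' Rotation about an axis through the origin
#' @param axis length-3 axis (normalized internally).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' \eqn{\sum_i \| R x_i + t - y_i \|^2} for paired coordinate sets.
#'
#' @param mobile,target n x 3 coordinate matrices with paired rows.
#' @return list with the fitted `rigid_transform` (`transform`) and the
#'   post-fit root-mean-square deviation (`rmsd`, Angstrom).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(nrow(mobile) == nrow(target), ncol(mobile) == 3, ncol(target) == 3,
            nrow(mobile) >= 3)
  mc <- colMeans(mobile); tc <- colMeans(target)
  H <- crossprod(sweep(mobile, 2, mc), sweep(target, 2, tc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(R, tc - as.numeric(R %*% mc))
  fitted <- apply_transform(tr, mobile)
  list(transform = tr, rmsd = sqrt(mean(rowSums((fitted - target)^2))))
}

# --- internal-coordinate placement (NeRF) ------------------------------------

deg2rad <- function(x) x * pi / 180

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates
#'
#' Given three reference positions `a`, `b`, `c`, returns the position `d`
#' such that `|c-d| = bond`, the angle b-c-d equals `angle` and the dihedral
#' a-b-c-d equals `torsion` (both in degrees).  This is the standard
#' natural-extension reference-frame construction used to grow peptide
#' chains residue by residue.
#'
#' @param a,b,c length-3 reference positions.
#' @param bond bond length c-d in Angstrom.
#' @param angle planar angle b-c-d in degrees.
#' @param torsion dihedral a-b-c-d in degrees.
#' @return length-3 position of the new atom.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- deg2rad(torsion)
  bc <- unitv(c - b)
  n  <- unitv(cross3(b - a, bc))
  m  <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
           bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + bc * d2[1] + m * d2[2] + n * d2[3]
}

#' Dihedral angle a-b-c-d in degrees
#' @param a,b,c,d length-3 positions.
#' @return signed dihedral in degrees, in `(-180, 180]`.
#' @export
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Planar angle a-b-c in degrees
#' @param a,b,c length-3 positions.
#' @return angle in degrees.
#' @export
bond_angle <- function(a, b, c) {
  v1 <- unitv(a - b); v2 <- unitv(c - b)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

# Run code with a private, restorable RNG state so builders are
# deterministic per seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}
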