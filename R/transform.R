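#' Rigid-body transforms
#'
#' A rigid transform is a proper rotation plus a translation,
#' `x -> R x + t`, used for superposition, ligand transplantation and
#' synthetic-data perturbation. The rotation must be orthonormal with
#' determinant +1 (reflections are rejected).
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation Numeric length-3 translation, in Angstrom.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' tf <- rigid_transform(diag(3), c(1, 0, 0))
#' apply_transform(matrix(0, 1, 3), tf)
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3L))) > 1e-8)
    stop("rotation matrix is not orthonormal", call. = FALSE)
  if (det(rotation) < 0)
    stop("rotation has determinant -1 (reflection not allowed)", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform()

#' Apply a rigid transform to coordinates
#'
#' @param x An n x 3 coordinate matrix (or a length-3 vector).
#' @param tf A [rigid_transform()].
#' @return Transformed coordinates with the same shape as `x`.
#' @export
apply_transform <- function(x, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (is.null(dim(x))) {
    drop(tf$rotation %*% x) + tf$translation
  } else {
    sweep(x %*% t(tf$rotation), 2L, tf$translation, "+")
  }
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  Rt <- t(tf$rotation)
  rigid_transform(Rt, drop(-Rt %*% tf$translation))
}

#' @rdname apply_transform
#' @param a,b Transforms; `compose_transform(a, b)` applies `b` first, then `a`.
#' @export
compose_transform <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Random rigid transform
#'
#' Draws a rotation uniformly over SO(3) (via a normalised quaternion) and a
#' Gaussian translation. Uses the current RNG stream; wrap with
#' `withr::with_seed()` or `set.seed()` for reproducibility.
#'
#' @param translation_sd Standard deviation of each translation component (A).
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(translation_sd = 10) {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3L, 3L, byrow = TRUE)
  rigid_transform(R, stats::rnorm(3L, sd = translation_sd))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (x -> R x + t)\n")
  cat("  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(sprintf("%.3f", x$translation), collapse = " "), "\n")
  invisible(x)
}
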