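#' Multi-shell diffusion acquisition scheme
#'
#' An acquisition scheme stores one b-value and one gradient direction per
#' acquired volume, in the FSL convention (b = 0 volumes carry a zero
#' vector). The default scheme mirrors a clinical multi-shell protocol:
#' shells at b = 700 / 1000 / 2855 s/mm^2 along 6 / 30 / 60 non-collinear
#' directions plus 10 b = 0 volumes (106 volumes in total).
#'
#' @param bvals Numeric vector of per-volume b-values in s/mm^2.
#' @param bvecs Numeric matrix (n_volumes x 3) of gradient directions.
#'   Rows with b > 0 must be unit vectors; rows with b = 0 must be zero.
#' @return An object of class `acquisition_scheme`: a list with elements
#'   `bvals`, `bvecs`, `n_b0` (count of b = 0 volumes) and `shells`
#'   (sorted unique nonzero b-values).
#' @examples
#' sch <- default_scheme()
#' n_volumes(sch)   # 106
#' @export
acquisition_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (any(!is.finite(bvals)) || any(bvals < 0)) {
    stop("b-values must be finite and non-negative")
  }
  if (ncol(bvecs) != 3L) {
    stop("bvecs must have 3 columns (x, y, z components)")
  }
  if (nrow(bvecs) != length(bvals)) {
    stop(sprintf(
      "number of gradient directions (%d) does not match number of b-values (%d)",
      nrow(bvecs), length(bvals)
    ))
  }
  nrm <- sqrt(rowSums(bvecs^2))
  w <- bvals > 0
  if (any(w & nrm == 0)) {
    stop("nonzero b-value with a zero gradient vector")
  }
  if (any(w)) {
    dev <- abs(nrm[w] - 1)
    if (any(dev > 1e-3)) {
      warning(sprintf(
        "%d gradient direction(s) deviate from unit norm by more than 1e-3; renormalizing",
        sum(dev > 1e-3)
      ))
    }
    bvecs[w, ] <- bvecs[w, , drop = FALSE] / nrm[w]
  }
  bvecs[!w, ] <- 0
  structure(
    list(
      bvals = bvals,
      bvecs = bvecs,
      n_b0 = sum(!w),
      shells = sort(unique(bvals[w]))
    ),
    class = "acquisition_scheme"
  )
}

#' @rdname acquisition_scheme
#' @export
n_volumes <- function(scheme) length(scheme$bvals)

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf(
    "<acquisition_scheme> %d volumes: %d b=0 + shells %s (n = %s)\n",
    n_volumes(x), x$n_b0,
    paste(x$shells, collapse = "/"),
    paste(vapply(x$shells, function(b) sum(x$bvals == b), 1L), collapse = "/")
  ))
  invisible(x)
}

#' Deterministic quasi-uniform directions on the hemisphere
#'
#' Golden-angle (Fibonacci) spiral on the upper hemisphere; used to build
#' reproducible non-collinear gradient tables and orientation candidate
#' sets. Directions are unit vectors with z >= 0.
#'
#' @param n Number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- i / n                     # hemisphere: z in (0, 1)
  phi <- i * pi * (3 - sqrt(5))  # golden angle
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' @rdname acquisition_scheme
#' @param n_b0 Number of b = 0 volumes (default 10).
#' @export
default_scheme <- function(n_b0 = 10) {
  shells <- c(700, 1000, 2855)
  ndirs <- c(6L, 30L, 60L)
  bvals <- rep(0, n_b0)
  bvecs <- matrix(0, n_b0, 3)
  for (s in seq_along(shells)) {
    d <- fibonacci_directions(ndirs[s])
    # offset each shell's spiral so shells are not collinear with each other
    rot <- rotation_about_z(0.41 * s)
    bvals <- c(bvals, rep(shells[s], ndirs[s]))
    bvecs <- rbind(bvecs, d %*% t(rot))
  }
  acquisition_scheme(bvals, bvecs)
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Read / write FSL-format bval and bvec files
#'
#' FSL dialect: `bval` is one whitespace-separated row of b-values; `bvec`
#' is three rows holding the x, y and z components of each direction.
#' Directions are renormalized to unit length on read (a warning is raised
#' above 1e-3 deviation); zero vectors are allowed only at b = 0.
#'
#' @param bval_path,bvec_path File paths.
#' @return `read_bval_bvec` returns an [acquisition_scheme()].
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = numeric(), quiet = TRUE)
  lines <- readLines(bvec_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 3L) {
    stop(sprintf("bvec file must have 3 rows (found %d)", length(lines)))
  }
  rows <- lapply(lines, function(l) scan(text = l, what = numeric(), quiet = TRUE))
  nn <- vapply(rows, length, 1L)
  if (length(unique(nn)) != 1L) stop("bvec rows have unequal lengths")
  bvecs <- t(do.call(rbind, rows))
  acquisition_scheme(bvals, bvecs)
}

#' @rdname read_bval_bvec
#' @param scheme An [acquisition_scheme()].
#' @export
write_bval_bvec <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(t(scheme$bvecs), 1, function(r) {
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")
  }), bvec_path)
  invisible(c(bval_path, bvec_path))
}
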