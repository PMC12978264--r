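#' Acquisition protocol
#'
#' An unordered collection of q-space acquisition points. Each point has a
#' b-value (ms/um^2) and a unit diffusion-encoding direction; its q-space
#' position is q = sqrt(b) g, so that typical experiments give coordinates
#' of order unity. Direction rows at b = 0 are ignored (q = origin).
#'
#' @param b numeric vector of b-values, ms/um^2, >= 0
#' @param g N x 3 matrix of encoding directions (unit rows where b > 0;
#'   non-unit rows are renormalised with a warning)
#' @param label short text tag ("HCP", "UKBB", "DSI", "random", ...)
#' @return an object of class `protocol` with elements `b`, `g`, `q`
#'   (N x 3), `n`, `b0_indices`, `label`
#' @export
protocol <- function(b, g, label = "custom") {
  g <- as.matrix(g)
  if (ncol(g) != 3 || nrow(g) != length(b)) stop("g must be an N x 3 matrix aligned with b")
  if (length(b) < 1) stop("a protocol needs at least one acquisition point")
  if (any(b < 0)) stop("b-values must be non-negative")
  dwi <- b > 0
  g[!dwi, ] <- 0
  if (any(dwi)) {
    nrm <- sqrt(rowSums(g[dwi, , drop = FALSE]^2))
    if (any(nrm == 0)) stop("zero direction vector at non-zero b")
    if (any(abs(nrm - 1) > 1e-6)) {
      warning("non-unit directions at b > 0 renormalised")
    }
    g[dwi, ] <- g[dwi, , drop = FALSE] / nrm
  }
  q <- sqrt(b) * g
  structure(list(b = as.numeric(b), g = g, q = q, n = length(b),
                 b0_indices = which(b == 0), label = label),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  shells <- sort(unique(round(x$b[x$b > 0], 6)))
  cat(sprintf("<protocol '%s': %d points (%d b0, %d DWI), %d distinct b>\n",
              x$label, x$n, length(x$b0_indices), x$n - length(x$b0_indices),
              length(shells)))
  invisible(x)
}

#' Uniform directions on the upper hemisphere
#'
#' i.i.d. uniform unit vectors with z >= 0. The hemisphere convention is
#' immaterial to the forward model, which is antipodally symmetric.
#'
#' @param n number of directions, >= 1
#' @return n x 3 matrix of unit vectors
#' @export
sample_hemisphere_directions <- function(n) {
  if (n < 1) stop("n must be at least 1")
  z <- runif(n, 0, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Uniform directions on the full sphere
#' @param n number of directions
#' @return n x 3 matrix of unit vectors
#' @export
sample_sphere_directions <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Randomised multi-shell training protocol
#'
#' Draws the acquisition distribution used to train the network: the shell
#' count uniform on \{2, 3, 4, 5\}, each shell's b-value from U(0.25, 5)
#' ms/um^2, each shell's direction count uniform on \{12, ..., 128\}, and
#' directions uniform on the hemisphere. One b = 0 measurement is included
#' per shell.
#'
#' @param n_b0_per_shell b0 measurements added per shell
#' @return a [protocol()] labelled "random"
#' @export
sample_training_protocol <- function(n_b0_per_shell = 1) {
  n_shells <- sample(2:5, 1)
  bs <- runif(n_shells, 0.25, 5)
  nd <- sample(12:128, n_shells, replace = TRUE)
  b <- rep(0, n_shells * n_b0_per_shell)
  g <- matrix(0, length(b), 3)
  for (s in seq_len(n_shells)) {
    dirs <- sample_hemisphere_directions(nd[s])
    b <- c(b, rep(bs[s], nd[s]))
    g <- rbind(g, dirs)
  }
  protocol(b, g, label = "random")
}

#' Fixed multi-shell protocol
#'
#' Builds a shell protocol from per-shell b-values and direction counts,
#' with hemisphere-uniform directions. When `seed` is given the directions
#' are reproducible and the caller's RNG stream is left untouched.
#'
#' @param bvalues numeric vector, one b-value per shell, ms/um^2
#' @param n_dirs integer vector, directions per shell
#' @param n_b0 number of b = 0 measurements
#' @param label protocol tag
#' @param seed optional integer for reproducible directions
#' @return a [protocol()]
#' @export
make_shell_protocol <- function(bvalues, n_dirs, n_b0 = length(bvalues),
                                label = "shell", seed = NULL) {
  stopifnot(length(bvalues) == length(n_dirs), all(bvalues > 0), all(n_dirs >= 1))
  build <- function() {
    b <- rep(0, n_b0)
    g <- matrix(0, n_b0, 3)
    for (s in seq_along(bvalues)) {
      b <- c(b, rep(bvalues[s], n_dirs[s]))
      g <- rbind(g, sample_hemisphere_directions(n_dirs[s]))
    }
    protocol(b, g, label = label)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Human Connectome Project style 3-shell protocol
#'
#' b = 1, 2, 3 ms/um^2 with 90 directions per shell (270 DWIs) plus b0s.
#' Directions are hemisphere-uniform under a fixed seed.
#'
#' @param n_b0 number of b = 0 measurements
#' @return a [protocol()] labelled "HCP"
#' @export
hcp_protocol <- function(n_b0 = 3) {
  make_shell_protocol(c(1, 2, 3), c(90, 90, 90), n_b0 = n_b0,
                      label = "HCP", seed = 202001L)
}

#' UK Biobank style 2-shell protocol
#'
#' b = 1, 2 ms/um^2 with 50 directions per shell (100 DWIs) plus b0s.
#'
#' @param n_b0 number of b = 0 measurements
#' @return a [protocol()] labelled "UKBB"
#' @export
ukbb_protocol <- function(n_b0 = 2) {
  make_shell_protocol(c(1, 2), c(50, 50), n_b0 = n_b0,
                      label = "UKBB", seed = 202002L)
}

#' Diffusion spectrum imaging grid protocol
#'
#' 303 q-space points on a Cartesian lattice restricted to a hemisphere,
#' with b proportional to the squared lattice radius and a maximum b-value
#' of 5 ms/um^2. Lattice points are taken in order of increasing |n|^2
#' (lexicographic within a shell) up to exactly 303 points; the boundary
#' shell |n|^2 = 27 carries b = 5. Fully deterministic.
#'
#' @param n_b0 number of b = 0 measurements
#' @param b_max maximum b-value, ms/um^2
#' @return a [protocol()] labelled "DSI"
#' @export
make_dsi_protocol <- function(n_b0 = 3, b_max = 5) {
  r <- 6L
  gr <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  n2 <- gr$x^2 + gr$y^2 + gr$z^2
  hemi <- (gr$z > 0) | (gr$z == 0 & gr$y > 0) | (gr$z == 0 & gr$y == 0 & gr$x > 0)
  keep <- n2 > 0 & hemi
  gr <- gr[keep, ]
  n2 <- n2[keep]
  ord <- order(n2, gr$z, gr$y, gr$x)
  gr <- gr[ord, ][1:303, ]
  n2 <- n2[ord][1:303]
  b <- b_max * n2 / max(n2)
  g <- as.matrix(gr) / sqrt(n2)
  protocol(c(rep(0, n_b0), b), rbind(matrix(0, n_b0, 3), unname(g)),
           label = "DSI")
}

#' Read and write FSL-style gradient tables
#'
#' The on-disk dialect is FSL's: the bval file is a single line of
#' whitespace-separated b-values in s/mm^2 (scanner convention), the bvec
#' file has three lines holding the x, y and z components. Values are
#' converted to ms/um^2 (divided by 1000) internally.
#'
#' @param bval_path path to the bval file
#' @param bvec_path path to the bvec file
#' @param label protocol tag for the returned object
#' @return [read_gradient_table()] returns a [protocol()];
#'   [write_gradient_table()] invisibly returns the two paths.
#' @export
read_gradient_table <- function(bval_path, bvec_path, label = "file") {
  b <- scan(bval_path, quiet = TRUE)
  rows <- strsplit(trimws(readLines(bvec_path, warn = FALSE)), "[ \t]+")
  rows <- rows[vapply(rows, function(r) length(r) > 0 && any(nzchar(r)), logical(1))]
  if (length(rows) != 3) stop("bvec file must have exactly 3 rows (x, y, z)")
  g <- t(vapply(rows, as.numeric, numeric(length(b))))
  if (ncol(g) != length(b)) stop("bval and bvec files disagree on the number of measurements")
  protocol(b / 1000, t(g), label = label)
}

#' @rdname read_gradient_table
#' @param protocol a [protocol()] to write
#' @export
write_gradient_table <- function(protocol, bval_path, bvec_path) {
  stopifnot(inherits(protocol, "protocol"))
  writeLines(paste(format(protocol$b * 1000, trim = TRUE, scientific = FALSE,
                          digits = 10), collapse = " "), bval_path)
  gm <- t(protocol$g)
  writeLines(apply(gm, 1, function(r) {
    paste(format(r, trim = TRUE, scientific = FALSE, digits = 10), collapse = " ")
  }), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Sample microstructure parameters from the training prior
#'
#' NDI, ODI and FWF independently uniform on (0.025, 0.975) and the fibre
#' direction uniform on the full sphere.
#'
#' @param n number of parameter sets
#' @return data frame with columns ndi, odi, fwf, mu_x, mu_y, mu_z
#' @export
sample_params <- function(n = 1) {
  mu <- sample_sphere_directions(n)
  data.frame(ndi = runif(n, 0.025, 0.975),
             odi = runif(n, 0.025, 0.975),
             fwf = runif(n, 0.025, 0.975),
             mu_x = mu[, 1], mu_y = mu[, 2], mu_z = mu[, 3])
}
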