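#' Spherical head model
#'
#' Single homogeneous conducting sphere. MNI coordinates (mm) map to the
#' head frame (m, origin at the sphere centre) by translation only.
#'
#' @param sphere_center_mni centre in MNI mm (default c(0, 0, 20)).
#' @param sphere_radius radius in m (default 0.09).
#' @return List of class \code{"head_model"}.
#' @export
head_model <- function(sphere_center_mni = c(0, 0, 20), sphere_radius = 0.09) {
  stopifnot(sphere_radius > 0)
  h <- list(center_mni = sphere_center_mni, radius = sphere_radius)
  class(h) <- "head_model"
  h
}

#' Map MNI coordinates (mm) to head-frame metres
#' @param mni n x 3 matrix or length-3 vector, mm.
#' @param head a \code{\link{head_model}}.
#' @export
mni_to_head <- function(mni, head = head_model()) {
  if (is.null(dim(mni))) mni <- matrix(mni, 1)
  sweep(mni, 2, head$center_mni) / 1000
}

#' CTF-like axial gradiometer array
#'
#' Quasi-uniform (Fibonacci-lattice) placement of axial gradiometers on a
#' spherical cap covering the upper head, radially oriented, with a fixed
#' coil baseline. A deterministic stand-in for a 275-channel CTF layout.
#'
#' @param n number of sensors (default 274).
#' @param radius inner-coil distance from the sphere centre (m).
#' @param baseline axial gradiometer baseline (m).
#' @param max_polar maximal polar angle from +z (radians); default 2*pi/3
#'   gives a helmet-like cap extending below the sphere's equator.
#' @return List of class \code{"sensor_array"} with \code{position} (n x 3, m,
#'   inner coil), \code{orientation} (n x 3 unit radial), \code{baseline},
#'   \code{n} and a per-sensor \code{hemisphere} tag (sign of x).
#' @export
sensor_array <- function(n = 274, radius = 0.11, baseline = 0.05,
                         max_polar = 2 * pi / 3) {
  i <- seq_len(n) - 0.5
  cmin <- cos(max_polar)
  ct <- 1 - (1 - cmin) * i / n
  st <- sqrt(pmax(0, 1 - ct^2))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * seq_len(n)
  ori <- cbind(st * cos(phi), st * sin(phi), ct)
  pos <- radius * ori
  arr <- list(position = pos, orientation = ori, baseline = baseline, n = n,
              radius = radius,
              hemisphere = ifelse(pos[, 1] >= 0, "right", "left"))
  class(arr) <- "sensor_array"
  arr
}

#' Magnetic field of a current dipole in a conducting sphere
#'
#' Closed-form spherical-conductor solution for the field outside a
#' homogeneous sphere centred at the origin. Linear in the dipole moment;
#' radial moments are magnetically silent.
#'
#' @param dipole_pos 3-vector, m (strictly inside the sphere, not at its
#'   centre).
#' @param moment 3-vector, A m.
#' @param sensor_pos m x 3 matrix of field points (outside the sphere).
#' @return m x 3 matrix of B (Tesla).
#' @export
sarvas_field <- function(dipole_pos, moment, sensor_pos) {
  if (is.null(dim(sensor_pos))) sensor_pos <- matrix(sensor_pos, 1)
  r0 <- as.numeric(dipole_pos)
  if (sqrt(sum(r0^2)) < 1e-9)
    stop("dipole at the sphere centre: radial direction undefined")
  q <- as.numeric(moment)
  mu0_4pi <- 1e-7
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  out <- matrix(0, nrow(sensor_pos), 3)
  for (k in seq_len(nrow(sensor_pos))) {
    r <- sensor_pos[k, ]
    a <- r - r0
    na <- sqrt(sum(a^2)); nr <- sqrt(sum(r^2))
    ar <- sum(a * r)
    f <- na * (nr * na + nr^2 - sum(r0 * r))
    gradf <- (na^2 / nr + ar / na + 2 * na + 2 * nr) * r -
      (na + 2 * nr + ar / na) * r0
    out[k, ] <- mu0_4pi / f^2 * (f * qxr0 - sum(qxr0 * r) * gradf)
  }
  out
}

#' Axial gradiometer response to a dipole
#'
#' Output per sensor: radial field component at the outer coil minus that at
#' the inner coil.
#' @param dipole_pos,moment dipole position (m) and moment (A m).
#' @param sensors a \code{\link{sensor_array}}.
#' @return Numeric vector, length \code{sensors$n} (T).
#' @export
gradiometer_response <- function(dipole_pos, moment, sensors) {
  inner <- sarvas_field(dipole_pos, moment, sensors$position)
  outer_pos <- sensors$position + sensors$baseline * sensors$orientation
  outer <- sarvas_field(dipole_pos, moment, outer_pos)
  rowSums((outer - inner) * sensors$orientation)
}

#' Build the lead field for a source set
#'
#' Three gain columns per source (free dipole moment), evaluated through the
#' axial gradiometer array in the spherical head model.
#'
#' @param sources a \code{dcm_sources} data.frame (MNI mm).
#' @param sensors a \code{\link{sensor_array}}.
#' @param head a \code{\link{head_model}}.
#' @return List of class \code{"lead_field"} with \code{gain}
#'   (sensors x 3*sources, T per A m), \code{source_pos} (head frame, m)
#'   and the source names.
#' @export
build_leadfield <- function(sources, sensors = sensor_array(),
                            head = head_model()) {
  pos <- mni_to_head(as.matrix(sources[, c("x", "y", "z")]), head)
  rad <- sqrt(rowSums(pos^2))
  if (any(rad >= head$radius))
    stop("source(s) outside the head sphere: ",
         paste(sources$name[rad >= head$radius], collapse = ", "))
  n_src <- nrow(pos)
  gain <- matrix(0, sensors$n, 3 * n_src)
  for (s in seq_len(n_src)) {
    for (k in 1:3) {
      m <- c(0, 0, 0); m[k] <- 1
      gain[, 3 * (s - 1) + k] <- gradiometer_response(pos[s, ], m, sensors)
    }
  }
  colnames(gain) <- paste(rep(sources$name, each = 3), c("x", "y", "z"),
                          sep = ".")
  lf <- list(gain = gain, source_pos = pos, source_names = sources$name,
             n_sources = n_src)
  class(lf) <- "lead_field"
  lf
}

# random unit vector orthogonal to the radial direction at p
random_tangential <- function(p) {
  r <- p / sqrt(sum(p^2))
  repeat {
    v <- stats::rnorm(3)
    v <- v - sum(v * r) * r
    nv <- sqrt(sum(v^2))
    if (nv > 1e-6) return(v / nv)
  }
}

#' Relative MEG sensitivity of the deep sources
#'
#' Monte-Carlo sensitivity simulation: for each structure, the RMS axial
#' gradiometer response to a unit tangential dipole (random orientation,
#' jittered position) is computed and expressed relative to V1 within the
#' same repeat. Reported as mean and standard error over repeats; V1 is 1 by
#' construction. With the canonical geometry the pulvinar, the deepest
#' source, has the lowest relative sensitivity.
#'
#' @param sources a \code{dcm_sources} data.frame.
#' @param sensors a \code{\link{sensor_array}}; \code{head} a
#'   \code{\link{head_model}}.
#' @param n_repeats number of Monte-Carlo repeats (>= 2).
#' @param position_jitter_mm SD of the isotropic position jitter (mm).
#' @param seed RNG seed.
#' @return data.frame with columns \code{structure}, \code{mean}, \code{sem}.
#' @export
sensitivity_simulation <- function(sources, sensors = sensor_array(),
                                   head = head_model(), n_repeats = 20,
                                   position_jitter_mm = 2, seed = 1) {
  stopifnot(n_repeats >= 2)
  set.seed(seed)
  structs <- unique(sources$structure)
  rel <- matrix(NA_real_, n_repeats, length(structs),
                dimnames = list(NULL, structs))
  pos_all <- mni_to_head(as.matrix(sources[, c("x", "y", "z")]), head)
  for (r in seq_len(n_repeats)) {
    rms <- numeric(length(structs)); names(rms) <- structs
    for (s in structs) {
      idx <- which(sources$structure == s)
      v <- 0
      for (i in idx) {
        p <- pos_all[i, ] + stats::rnorm(3, 0, position_jitter_mm / 1000)
        m <- random_tangential(p)
        b <- gradiometer_response(p, m, sensors)
        v <- v + sqrt(mean(b^2))
      }
      rms[s] <- v / length(idx)
    }
    if (rms["V1"] <= 0) stop("degenerate V1 sensitivity")
    rel[r, ] <- rms / rms["V1"]
  }
  data.frame(structure = structs,
             mean = colMeans(rel),
             sem = apply(rel, 2, stats::sd) / sqrt(n_repeats),
             row.names = NULL)
}
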