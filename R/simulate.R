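#' Species-dependent AFM contrast kernels
#'
#' The simulator represents the constant-height HR-AFM signal of a molecule
#' as a sum of per-atom anisotropic bell-shaped kernels with exponential
#' height decay. The kernel table encodes the contrast phenomenology the
#' identification networks exploit: hydrogens bonded to sp2 carbon are nearly
#' invisible (amplitude far below carbon), heavy halogens show bright oval
#' features elongated along the bond axis (the sigma-hole), and substitutional
#' nitrogen shows a sharper vertex (super-Gaussian exponent above 1). This is
#' deliberately not a probe-particle or DFT simulation; it reproduces only the
#' species-discriminative, height-dependent statistical structure of the
#' contrast.
#'
#' @return data frame indexed by species symbol with columns `amplitude`
#'   (signal units), `sigma` (lateral width, Angstrom), `lambda` (vertical
#'   decay length, Angstrom), `eccentricity` (>= 1, elongation along the bond
#'   axis), `sharpness` (super-Gaussian exponent; 1 = Gaussian).
#' @export
species_kernel_table <- function() {
  tab <- data.frame(
    amplitude    = c(H = 0.08, C = 1.00, N = 1.10, O = 1.15, F = 1.05,
                     Cl = 1.25, Br = 1.35, I = 1.45, S = 1.20),
    sigma        = c(H = 0.30, C = 0.45, N = 0.42, O = 0.40, F = 0.38,
                     Cl = 0.55, Br = 0.62, I = 0.70, S = 0.60),
    lambda       = c(H = 0.35, C = 0.55, N = 0.50, O = 0.50, F = 0.45,
                     Cl = 0.60, Br = 0.65, I = 0.70, S = 0.62),
    eccentricity = c(H = 1.00, C = 1.00, N = 1.00, O = 1.00, F = 1.15,
                     Cl = 1.35, Br = 1.45, I = 1.55, S = 1.00),
    sharpness    = c(H = 1.00, C = 1.00, N = 1.60, O = 1.20, F = 1.00,
                     Cl = 1.00, Br = 1.00, I = 1.00, S = 1.00)
  )
  stopifnot(all(tab$amplitude >= 0), all(tab$lambda > 0))
  tab
}

#' Operational-parameter grid
#'
#' The cartesian product of cantilever oscillation-amplitude settings and CO
#' tilt-stiffness settings used as rendering variants and as the training
#' augmentation pool: 6 x 4 = 24 combinations by default. Each combination
#' maps to a distinct pair of smooth global kernel modulations: the amplitude
#' index scales signal amplitudes (oscillation averaging reduces peak
#' contrast) and the stiffness index scales lateral widths (a softer CO tilts
#' further, broadening features).
#'
#' @param n_amplitude number of oscillation-amplitude settings (default 6).
#' @param n_stiffness number of tilt-stiffness settings (default 4).
#' @return data frame with columns `amplitude`, `stiffness` (indices),
#'   `amp_factor`, `width_factor`.
#' @export
parameter_grid <- function(n_amplitude = 6L, n_stiffness = 4L) {
  stopifnot(n_amplitude >= 1L, n_stiffness >= 1L)
  amp_f <- if (n_amplitude == 1L) 1 else seq(1.00, 0.80, length.out = n_amplitude)
  wid_f <- if (n_stiffness == 1L) 1 else seq(0.92, 1.10, length.out = n_stiffness)
  g <- expand.grid(amplitude = seq_len(n_amplitude),
                   stiffness = seq_len(n_stiffness))
  g$amp_factor <- amp_f[g$amplitude]
  g$width_factor <- wid_f[g$stiffness]
  g
}

#' Image stack container
#'
#' @param planes numeric array `npix x npix x n_heights`, finite values.
#' @param heights numeric vector of tip-sample heights (Angstrom), strictly
#'   increasing; with more than one plane the step must be constant.
#' @param params length-2 integer vector `(amplitude, stiffness)` combo
#'   indices.
#' @param molecule_id provenance string.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(planes, heights, params = c(amplitude = 1L,
                                                    stiffness = 1L),
                        molecule_id = NA_character_) {
  planes <- as.array(planes)
  if (length(dim(planes)) == 2L) dim(planes) <- c(dim(planes), 1L)
  if (dim(planes)[3] != length(heights))
    stop("plane count (", dim(planes)[3], ") must equal number of heights (",
         length(heights), ")")
  if (length(heights) > 1L) {
    d <- diff(heights)
    if (any(d <= 0)) stop("heights must be strictly increasing")
    if (max(d) - min(d) > 1e-9) stop("heights must have a constant step")
  }
  if (!all(is.finite(planes))) stop("pixel values must be finite")
  structure(
    list(planes = planes, heights = as.numeric(heights),
         params = params, molecule_id = molecule_id),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$planes)
  cat(sprintf(
    "<image_stack> %dx%d px, %d planes (%.1f..%.1f A), combo (a=%d, k=%d)\n",
    d[1], d[2], d[3], min(x$heights), max(x$heights),
    x$params[[1]], x$params[[2]]))
  invisible(x)
}

# pixel-center coordinate axes for a square field of view centred on (cx, cy)
.image_axes <- function(npix, fov, cx = 0, cy = 0) {
  half <- fov / 2
  step <- fov / npix
  ax <- seq(-half + step / 2, half - step / 2, length.out = npix)
  list(x = ax + cx, y = ax + cy, step = step)
}

# per-atom lateral kernel maps (windowed), shared across heights.
# Returns list of (idx, val, weight0, lambda, zoff) per atom.
.atom_kernel_maps <- function(layout, table, params, npix, fov) {
  atoms <- layout$atoms
  unknown <- setdiff(unique(atoms$species), rownames(table))
  if (length(unknown) > 0L)
    stop("unknown species in kernel table: ", sQuote(unknown[[1]]))
  cx <- mean(range(atoms$x)); cy <- mean(range(atoms$y))
  axes <- .image_axes(npix, fov, cx, cy)
  amp_f <- params$amp_factor %||% 1
  wid_f <- params$width_factor %||% 1

  maps <- vector("list", nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    sp <- atoms$species[i]
    k <- table[sp, ]
    sig <- k$sigma * wid_f
    ecc <- k$eccentricity
    # bond axis for anisotropic species: direction away from the first
    # bonded neighbor (terminal halogens have exactly one bond)
    if (ecc > 1 && !is.null(layout$bonds) && nrow(layout$bonds) > 0) {
      hit <- which(layout$bonds[, 1] == i | layout$bonds[, 2] == i)[1]
      if (!is.na(hit)) {
        other <- setdiff(layout$bonds[hit, ], i)[1]
        u <- c(atoms$x[i] - atoms$x[other], atoms$y[i] - atoms$y[other])
        u <- u / sqrt(sum(u^2))
      } else u <- c(1, 0)
    } else u <- c(1, 0)
    sig_par <- sig * ecc
    sig_perp <- sig
    r_cut <- 4 * sig_par + 1e-9   # epsilon keeps the window symmetric
    ix <- which(abs(axes$x - atoms$x[i]) <= r_cut)
    iy <- which(abs(axes$y - atoms$y[i]) <= r_cut)
    if (length(ix) == 0L || length(iy) == 0L) { maps[[i]] <- NULL; next }
    dx <- axes$x[ix] - atoms$x[i]
    dy <- axes$y[iy] - atoms$y[i]
    DX <- matrix(dx, length(ix), length(iy))
    DY <- matrix(dy, length(ix), length(iy), byrow = TRUE)
    t_par <- DX * u[1] + DY * u[2]
    n_sq <- DX^2 + DY^2 - t_par^2
    q <- t_par^2 / sig_par^2 + n_sq / sig_perp^2
    val <- exp(-0.5 * q^k$sharpness)
    idx <- as.vector(outer(ix, (iy - 1L) * npix, `+`))
    maps[[i]] <- list(idx = idx, val = as.vector(val),
                      weight0 = k$amplitude * amp_f,
                      lambda = k$lambda, zoff = atoms$z[i])
  }
  maps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render one constant-height AFM plane
#'
#' The image is the sum over atoms of an anisotropic bell kernel centred at
#' the atom, scaled by `amplitude * exp(-(z - z_atom) / lambda)`. Halogens are
#' elongated along their bond axis by the species eccentricity; nitrogen
#' kernels are sharpened. Fully deterministic.
#'
#' @param layout a [build_layout()] result.
#' @param z tip-sample height in Angstrom, within \[2.0, 5.0\].
#' @param table a [species_kernel_table()].
#' @param params one row of [parameter_grid()] (or `NULL` for the neutral
#'   modulation).
#' @param npix image size in pixels (square).
#' @param fov field of view in Angstrom.
#' @return `npix x npix` numeric matrix (raw signal, not normalized).
#' @export
render_plane <- function(layout, z, table = species_kernel_table(),
                         params = NULL, npix = 128L, fov = 12.8) {
  if (z < 2.0 || z > 5.0)
    stop("height z must lie within [2.0, 5.0] Angstrom")
  maps <- .atom_kernel_maps(layout, table, params, npix, fov)
  img <- matrix(0, npix, npix)
  for (m in maps) {
    if (is.null(m)) next
    w <- m$weight0 * exp(-(z - m$zoff) / m$lambda)
    img[m$idx] <- img[m$idx] + w * m$val
  }
  img
}

#' Render a constant-height image stack
#'
#' One plane per height of the schedule (default ten heights spanning
#' 2.8-3.7 Angstrom in 0.1 Angstrom steps). The per-atom lateral kernels are
#' shared across heights; only the exponential height weights differ, so the
#' noise-free molecular signal is per-pixel non-increasing in z. When
#' `normalize` is `TRUE` the whole stack is affinely rescaled to \[0, 1\]
#' (a single scale for all planes, preserving inter-plane ordering).
#'
#' @inheritParams render_plane
#' @param heights strictly increasing, constant-step height schedule
#'   (Angstrom).
#' @param normalize rescale the stack to \[0, 1\] (default `TRUE`).
#' @param molecule_id provenance string stored in the stack.
#' @return an [image_stack()].
#' @export
render_stack <- function(layout, table = species_kernel_table(),
                         params = NULL,
                         heights = seq(2.8, 3.7, by = 0.1),
                         npix = 128L, fov = 12.8, normalize = TRUE,
                         molecule_id = NA_character_) {
  if (length(heights) > 1L && any(diff(heights) <= 0))
    stop("height schedule must be strictly increasing")
  if (any(heights < 2.0 | heights > 5.0))
    stop("heights must lie within [2.0, 5.0] Angstrom")
  maps <- .atom_kernel_maps(layout, table, params, npix, fov)
  planes <- array(0, c(npix, npix, length(heights)))
  for (p in seq_along(heights)) {
    img <- matrix(0, npix, npix)
    for (m in maps) {
      if (is.null(m)) next
      w <- m$weight0 * exp(-(heights[p] - m$zoff) / m$lambda)
      img[m$idx] <- img[m$idx] + w * m$val
    }
    planes[, , p] <- img
  }
  if (normalize) {
    rng <- range(planes)
    if (rng[2] > rng[1]) planes <- (planes - rng[1]) / (rng[2] - rng[1])
  }
  pidx <- if (is.null(params)) c(amplitude = 1L, stiffness = 1L) else
    c(amplitude = as.integer(params$amplitude %||% 1L),
      stiffness = as.integer(params$stiffness %||% 1L))
  image_stack(planes, heights, params = pidx, molecule_id = molecule_id)
}

#' Image-deformation augmentation (IDG) configuration
#'
#' On-the-fly geometric and noise deformations emulating slight CO-tip
#' asymmetries and experimental artifacts: a stack-coherent affine map
#' (rotation, shift, zoom, shear, identical for all planes), additive
#' Gaussian noise, and occasional bright diagonal line artifacts crossing the
#' images. All ranges may be zero, making the identity transform reachable.
#' The defaults are declared package choices.
#'
#' @param rotation max |rotation| in degrees.
#' @param shift max |shift| in pixels (each axis).
#' @param zoom max |log-zoom deviation| (0.05 = +-5 percent).
#' @param shear max |shear| coefficient.
#' @param noise additive Gaussian noise standard deviation (stack is in
#'   \[0, 1\] units).
#' @param line_prob probability that a stack receives a diagonal line
#'   artifact.
#' @param line_width line half-width in pixels.
#' @param line_gain brightness added on the line.
#' @return object of class `idg_config`.
#' @export
idg_config <- function(rotation = 5, shift = 2, zoom = 0.05, shear = 0.03,
                       noise = 0.02, line_prob = 0.3, line_width = 1,
                       line_gain = 0.6) {
  structure(
    list(rotation = rotation, shift = shift, zoom = zoom, shear = shear,
         noise = noise, line_prob = line_prob, line_width = line_width,
         line_gain = line_gain),
    class = "idg_config"
  )
}

#' Apply a stack-coherent deformation to an image stack
#'
#' Draws one deformation from the configuration and applies the same
#' geometry to all planes of the stack; heights and parameters are left
#' untouched. With every range set to zero the stack is returned unchanged.
#' Seeding makes the draw reproducible without perturbing the caller's RNG
#' stream.
#'
#' @param stack an [image_stack()].
#' @param cfg an [idg_config()].
#' @param seed optional integer seed for the deformation draw.
#' @return a deformed [image_stack()].
#' @export
apply_idg <- function(stack, cfg = idg_config(), seed = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(cfg, "idg_config"))
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  d <- dim(stack$planes)
  npix <- d[1]
  theta <- if (cfg$rotation > 0) stats::runif(1, -cfg$rotation, cfg$rotation) else 0
  tx <- if (cfg$shift > 0) stats::runif(1, -cfg$shift, cfg$shift) else 0
  ty <- if (cfg$shift > 0) stats::runif(1, -cfg$shift, cfg$shift) else 0
  zm <- if (cfg$zoom > 0) exp(stats::runif(1, -cfg$zoom, cfg$zoom)) else 1
  sh <- if (cfg$shear > 0) stats::runif(1, -cfg$shear, cfg$shear) else 0

  planes <- stack$planes
  if (theta != 0 || tx != 0 || ty != 0 || zm != 1 || sh != 0) {
    a <- theta * pi / 180
    # linear part: rotation * zoom * shear, about the image centre
    L <- zm * matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2) %*%
      matrix(c(1, 0, sh, 1), 2, 2)
    ctr <- c((npix + 1) / 2, (npix + 1) / 2)
    off <- ctr - as.vector(ctr %*% L) + c(tx, ty)
    m <- rbind(L, off)
    for (p in seq_len(d[3]))
      planes[, , p] <- EBImage::affine(planes[, , p], m, filter = "bilinear")
  }

  if (cfg$line_prob > 0 && stats::runif(1) < cfg$line_prob) {
    sgn <- sample(c(1, -1), 1)
    offset <- sample(seq(-npix %/% 2, npix %/% 2), 1)
    ix <- matrix(seq_len(npix), npix, npix) - (npix + 1) / 2
    iy <- matrix(seq_len(npix), npix, npix, byrow = TRUE) - (npix + 1) / 2
    mask <- abs(ix - sgn * iy - offset) <= cfg$line_width
    for (p in seq_len(d[3])) {
      pl <- planes[, , p]
      pl[mask] <- pl[mask] + cfg$line_gain
      planes[, , p] <- pl
    }
  }

  if (cfg$noise > 0)
    planes <- planes + stats::rnorm(length(planes), 0, cfg$noise)

  image_stack(planes, stack$heights, stack$params, stack$molecule_id)
}
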