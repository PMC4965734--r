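# Synthetic H&E-like scene generator: ring-bordered bright-interior glandular
# objects on a textured background of scattered dark nuclei, with ground
# truth instance masks.

#' Parameters of a synthetic scene
#'
#' Defaults emulate intestinal glands at 40x magnification: bright epithelial
#' interior with a brighter central lumen, a dark epithelial-nucleus ring
#' border, mid-gray stroma speckled with small dark nuclei. Gland long
#' diameters span 80-160 px (radius 40-80). The intensity palette (border
#' 0.15, interior 0.75, lumen 0.95, background 0.55, background nuclei 0.2)
#' reproduces the H&E contrast ordering: nuclei stain dark, cytoplasm and
#' lumen bright.
#'
#' @param side image side in pixels
#' @param n_glands number of glands to place
#' @param radius_range gland body radius range in pixels (long diameter is
#'   about twice this)
#' @param border_thickness thickness of the dark nucleus ring, pixels
#' @param border_darkness intensity of the ring
#' @param interior_brightness intensity of the gland body (cytoplasm)
#' @param lumen_brightness intensity of the central lumen disk
#' @param background background (stroma) intensity
#' @param nucleus_density expected background nuclei per pixel
#' @param nucleus_darkness intensity of background nuclei
#' @param gap_fraction fraction of each ring erased (one contiguous arc) to
#'   emulate weak gland boundaries, in \[0, 1\]
#' @param irregularity radial perturbation amplitude in \[0, 1\] (smooth
#'   low-order harmonics, keeping the shape star-shaped about its center)
#' @param noise_sigma standard deviation of added Gaussian noise
#' @param seam if TRUE draw a dark seam across each gland interior, splitting
#'   it visually in two (controlled over-segmentation for merge experiments)
#' @param seam_darkness intensity of the seam line
#' @param seam_thickness seam thickness in pixels
#' @param seed RNG seed; the generator is fully deterministic under it
#' @return a list of class \code{gs_scene_params}
#' @export
scene_params <- function(side = 512L, n_glands = 8L,
                         radius_range = c(40, 80),
                         border_thickness = 8,
                         border_darkness = 0.15,
                         interior_brightness = 0.75,
                         lumen_brightness = 0.95,
                         background = 0.55,
                         nucleus_density = 8e-4,
                         nucleus_darkness = 0.2,
                         gap_fraction = 0,
                         irregularity = 0.2,
                         noise_sigma = 0,
                         seam = FALSE,
                         seam_darkness = 0.12,
                         seam_thickness = 2,
                         seed = 1L) {
  stopifnot(side >= 32L, n_glands >= 0L, length(radius_range) == 2L,
            gap_fraction >= 0, gap_fraction <= 1,
            irregularity >= 0, irregularity <= 1, noise_sigma >= 0)
  structure(as.list(environment()), class = "gs_scene_params")
}

# smooth star-shaped radial perturbation: sum of low-order harmonics scaled
# to unit peak amplitude
radial_profile <- function(irregularity) {
  if (irregularity <= 0) return(function(theta) rep(1, length(theta)))
  amp <- runif(3L, -1, 1)
  phs <- runif(3L, 0, 2 * pi)
  raw <- function(theta) {
    amp[1L] * cos(2 * theta + phs[1L]) + amp[2L] * cos(3 * theta + phs[2L]) +
      amp[3L] * cos(4 * theta + phs[3L])
  }
  peak <- max(abs(raw(seq(0, 2 * pi, length.out = 720L))))
  if (peak == 0) return(function(theta) rep(1, length(theta)))
  function(theta) 1 + irregularity * raw(theta) / peak
}

#' Generate a synthetic gland scene
#'
#' Glands are placed by rejection sampling so that instances never overlap
#' (if a gland cannot be placed after many attempts, fewer are returned and a
#' message is logged). Each gland is a star-shaped blob: a dark ring border
#' of the given thickness around a bright interior with a brighter central
#' lumen disk; the ring can have a contiguous arc erased (border gap) and the
#' interior a dark seam. The background holds Poisson-scattered small dark
#' disks (stromal/immune nuclei) and Gaussian noise. Fully deterministic
#' under the seed.
#'
#' @param params a [scene_params()]
#' @return object of class \code{gs_scene}: \code{image} ([gs_image]),
#'   \code{gt} (\code{gs_mask}), \code{params}, \code{glands} (data.frame of
#'   placed centers and radii)
#' @export
generate_scene <- function(params = scene_params()) {
  set.seed(params$seed)
  side <- params$side
  t <- params$border_thickness
  img <- matrix(params$background, side, side)
  gt <- matrix(0L, side, side)

  # place gland centers and radii without instance overlap; larger glands
  # first (easier packing, fewer placement failures)
  radii <- sort(runif(params$n_glands, params$radius_range[1L],
                      params$radius_range[2L]), decreasing = TRUE)
  placed <- data.frame(x = numeric(0), y = numeric(0), radius = numeric(0))
  for (k in seq_len(params$n_glands)) {
    R <- radii[k]
    ok <- FALSE
    for (att in seq_len(4000L)) {
      margin <- R * (1 + params$irregularity) + t + 2
      if (2 * margin >= side) break
      cx <- runif(1L, margin, side - 1 - margin)
      cy <- runif(1L, margin, side - 1 - margin)
      if (nrow(placed) > 0L) {
        d <- sqrt((placed$x - cx)^2 + (placed$y - cy)^2)
        lim <- (placed$radius + R) * (1 + params$irregularity) + 2 * t + 6
        if (any(d < lim)) next
      }
      placed <- rbind(placed, data.frame(x = cx, y = cy, radius = R))
      ok <- TRUE
      break
    }
    if (!ok) gs_log("could not place gland ", k, "; scene holds ",
                    nrow(placed), " glands")
  }

  for (k in seq_len(nrow(placed))) {
    cx <- placed$x[k]; cy <- placed$y[k]; R <- placed$radius[k]
    prof <- radial_profile(params$irregularity)
    gap_start <- runif(1L, 0, 2 * pi)
    gap_len <- params$gap_fraction * 2 * pi
    seam_angle <- runif(1L, 0, pi)
    rmax <- R * (1 + params$irregularity) + t
    r0 <- max(1L, floor(cy - rmax) + 1L); r1 <- min(side, ceiling(cy + rmax) + 1L)
    c0 <- max(1L, floor(cx - rmax) + 1L); c1 <- min(side, ceiling(cx + rmax) + 1L)
    rows <- r0:r1; cols <- c0:c1
    dy <- matrix(rows - 1 - cy, length(rows), length(cols))
    dx <- matrix(cols - 1 - cx, length(rows), length(cols), byrow = TRUE)
    d <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    rb <- R * prof(as.vector(th))
    dim(rb) <- dim(d)
    inside <- d < rb
    ring <- d >= rb & d < rb + t
    # contiguous erased arc of the ring
    if (gap_len > 0) {
      rel <- (as.vector(th) - gap_start) %% (2 * pi)
      ingap <- matrix(rel < gap_len, nrow(d), ncol(d))
    } else ingap <- matrix(FALSE, nrow(d), ncol(d))
    lumen <- d < 0.45 * rb
    sub_img <- img[rows, cols]
    sub_img[inside] <- params$interior_brightness
    sub_img[lumen] <- params$lumen_brightness
    weak <- (params$interior_brightness + params$background) / 2
    sub_img[ring] <- ifelse(ingap[ring], weak, params$border_darkness)
    if (isTRUE(params$seam)) {
      # distance to the diameter line at seam_angle
      dist_line <- abs(-sin(seam_angle) * dx + cos(seam_angle) * dy)
      seam_px <- dist_line <= params$seam_thickness / 2 & d < rb
      sub_img[seam_px] <- params$seam_darkness
    }
    img[rows, cols] <- sub_img
    sub_gt <- gt[rows, cols]
    sub_gt[d < rb + t] <- k
    gt[rows, cols] <- sub_gt
  }

  # background nuclei: Poisson-scattered dark disks outside the glands
  n_nuc <- rpois(1L, params$nucleus_density * side^2)
  if (n_nuc > 0L) {
    nx <- runif(n_nuc, 0, side - 1)
    ny <- runif(n_nuc, 0, side - 1)
    nr <- runif(n_nuc, 2, 4)
    for (k in seq_len(n_nuc)) {
      rr <- max(1L, floor(ny[k] - nr[k]) + 1L):min(side, ceiling(ny[k] + nr[k]) + 1L)
      cc <- max(1L, floor(nx[k] - nr[k]) + 1L):min(side, ceiling(nx[k] + nr[k]) + 1L)
      dy <- matrix(rr - 1 - ny[k], length(rr), length(cc))
      dx <- matrix(cc - 1 - nx[k], length(rr), length(cc), byrow = TRUE)
      hit <- (dx^2 + dy^2 <= nr[k]^2) & gt[rr, cc] == 0L
      sub <- img[rr, cc]
      sub[hit] <- params$nucleus_darkness
      img[rr, cc] <- sub
    }
  }

  if (params$noise_sigma > 0)
    img <- img + matrix(rnorm(side^2, 0, params$noise_sigma), side, side)
  img <- pmin(pmax(img, 0), 1)

  structure(list(image = gs_image(img), gt = as_gs_mask(gt),
                 params = params, glands = placed),
            class = "gs_scene")
}

#' @export
print.gs_scene <- function(x, ...) {
  cat(sprintf("<gs_scene %dx%d, %d glands, seed %d>\n",
              x$params$side, x$params$side, nrow(x$glands), x$params$seed))
  invisible(x)
}

#' Generate a dataset of synthetic scenes
#'
#' Scenes use seeds \code{base_seed .. base_seed + n_scenes - 1}. The default
#' of 10 scenes mirrors a leave-one-image-out cross-validation design over
#' 10 images.
#'
#' @param n_scenes number of scenes (at least 2)
#' @param params a [scene_params()] shared by all scenes (its seed field is
#'   overridden per scene)
#' @param base_seed first seed
#' @return list of \code{gs_scene}
#' @export
generate_dataset <- function(n_scenes = 10L, params = scene_params(),
                             base_seed = 1L) {
  stopifnot(n_scenes >= 2L)
  lapply(seq_len(n_scenes), function(k) {
    p <- params
    p$seed <- as.integer(base_seed + k - 1L)
    generate_scene(p)
  })
}
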