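# Structural observables of droplet configurations: radial probability
# profiles per species, region boundaries and occupancies, per-oxygen
# insertion depths, and orientation-angle distributions of the antioxidant.
# Frames are treated as an unordered ensemble; coordinates are Cartesian
# angstroms with no periodic wrapping.

PROFILE_SPECIES <- c("oleic", "antioxidant", "water",
                     "surf_ring", "surf_hydroxyl", "surf_tail")

#' Center of mass of the droplet oil core
#'
#' Mass-weighted center of the oleic-acid atoms only.  The solvent and
#' solute are excluded on purpose: distances are measured from the center
#' of the oil core, and a water-inclusive center would depend on the box.
#'
#' @param frame a `droplet_frame`.
#' @return numeric length-3 point (A).
#' @export
droplet_com <- function(frame) {
  stopifnot(inherits(frame, "droplet_frame"))
  sel <- frame$species == "OLE"
  if (!any(sel))
    stop("missing species: frame contains no oleic-acid atoms",
         call. = FALSE)
  w <- frame$mass[sel]
  c(sum(frame$x[sel] * w), sum(frame$y[sel] * w),
    sum(frame$z[sel] * w)) / sum(w)
}

# Per-molecule reference-point radii for one frame: COM distance to the
# droplet center for whole molecules, or single-site distance for the three
# surfactant sites.
reference_radii <- function(frame, species) {
  ctr <- droplet_com(frame)
  pick <- switch(species,
    oleic = list(sp = "OLE", atom = NULL),
    antioxidant = list(sp = "GAL", atom = NULL),
    water = list(sp = "HOH", atom = NULL),
    surf_ring = list(sp = "TW80", atom = "RNG"),
    surf_hydroxyl = list(sp = "TW80", atom = "EOH"),
    surf_tail = list(sp = "TW80", atom = "TAIL"),
    stop("unknown species tag '", species, "'; expected one of: ",
         paste(PROFILE_SPECIES, collapse = ", "), call. = FALSE))
  sel <- frame$species == pick$sp
  if (!is.null(pick$atom)) sel <- sel & frame$atom == pick$atom
  if (!any(sel))
    stop("missing species: no atoms match '", species, "'", call. = FALSE)
  sub <- frame[sel, ]
  dx <- sub$x - ctr[1L]; dy <- sub$y - ctr[2L]; dz <- sub$z - ctr[3L]
  if (is.null(pick$atom) && anyDuplicated(sub$molid)) {
    w <- sub$mass
    cx <- tapply(dx * w, sub$molid, sum) / tapply(w, sub$molid, sum)
    cy <- tapply(dy * w, sub$molid, sum) / tapply(w, sub$molid, sum)
    cz <- tapply(dz * w, sub$molid, sum) / tapply(w, sub$molid, sum)
    sqrt(cx^2 + cy^2 + cz^2)
  } else {
    sqrt(dx^2 + dy^2 + dz^2)
  }
}

as_trajectory <- function(x) {
  if (inherits(x, "droplet_frame")) droplet_trajectory(list(x)) else {
    stopifnot(inherits(x, "droplet_trajectory"))
    x
  }
}

#' Radial probability profile of a species
#'
#' Histogram of per-molecule reference-point distances from the oil-core
#' center, pooled over frames and normalized to unit integral (probability
#' per angstrom).  Reference points are molecular centers of mass for
#' oleic acid, antioxidant and water, and the three per-molecule sites
#' (`surf_ring`, `surf_hydroxyl`, `surf_tail`) for the surfactant.
#'
#' With `volume_corrected = TRUE` each count is weighted by the inverse
#' volume of its spherical shell before renormalizing, turning the raw
#' probability-per-distance into a relative number density; this is the
#' appropriate variant for locating region boundaries, since for uniformly
#' filled regions it is flat rather than growing with the shell volume.
#'
#' @param traj a `droplet_trajectory` (or a single `droplet_frame`).
#' @param species one of `"oleic"`, `"antioxidant"`, `"water"`,
#'   `"surf_ring"`, `"surf_hydroxyl"`, `"surf_tail"`.
#' @param bin_width histogram bin width, A (default 1).
#' @param volume_corrected weight counts by inverse shell volume.
#' @return object of class `radial_profile`: `species`, `breaks` (bin
#'   edges, A), `density` (probability per A), `n_samples`,
#'   `volume_corrected`.
#' @export
radial_profile <- function(traj, species, bin_width = 1,
                           volume_corrected = FALSE) {
  stopifnot(bin_width > 0)
  traj <- as_trajectory(traj)
  radii <- unlist(lapply(traj$frames, reference_radii, species = species))
  n <- length(radii)
  breaks <- seq(0, (floor(max(radii) / bin_width) + 1L) * bin_width,
                by = bin_width)
  h <- graphics::hist(radii, breaks = breaks, plot = FALSE)
  w <- h$counts
  if (volume_corrected) {
    vol <- (4 / 3) * pi * diff(breaks^3)
    w <- w / vol
  }
  dens <- w / (sum(w) * bin_width)
  structure(list(species = species, breaks = breaks, density = dens,
                 n_samples = n, bin_width = bin_width,
                 volume_corrected = volume_corrected),
            class = "radial_profile")
}

#' Construct a radial profile from explicit bins
#'
#' For toy profiles built by hand (e.g. step functions); the density is
#' renormalized to unit integral.
#'
#' @param breaks bin edges, A.
#' @param density nonnegative densities, one per bin.
#' @param species species tag.
#' @return object of class `radial_profile`.
#' @export
radial_profile_from_bins <- function(breaks, density, species = "toy") {
  stopifnot(length(breaks) == length(density) + 1L, all(diff(breaks) > 0),
            all(density >= 0), sum(density) > 0)
  widths <- diff(breaks)
  dens <- density / sum(density * widths)
  structure(list(species = species, breaks = breaks, density = dens,
                 n_samples = NA_integer_, bin_width = widths[1L],
                 volume_corrected = FALSE),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %s: %d bins x %.3g A, n = %s%s\n",
              x$species, length(x$density), x$bin_width,
              format(x$n_samples),
              if (x$volume_corrected) " (volume-corrected)" else ""))
  invisible(x)
}

#' Estimate region boundaries from oleic and water radial profiles
#'
#' The oil-core radius is the right edge of the first bin whose oleic
#' cumulative mass exceeds `core_cut`; the water onset is the
#' left edge of the first bin whose water density reaches `bulk_cut` of the
#' bulk plateau (the mean density over the outer 20 percent of the water
#' bins).  The interfacial thickness is their difference.  Pass
#' volume-corrected profiles (see [radial_profile()]) so that uniformly
#' filled regions read as flat plateaus.
#'
#' @param oleic,water `radial_profile` objects.
#' @param core_cut oleic cumulative-mass threshold (default 0.95).
#' @param bulk_cut fraction of the water plateau (default 0.90).
#' @return object of class `region_boundaries`: `core_radius`,
#'   `interface_thickness`, `water_onset` (A).
#' @export
estimate_regions <- function(oleic, water, core_cut = 0.95,
                             bulk_cut = 0.90) {
  stopifnot(inherits(oleic, "radial_profile"),
            inherits(water, "radial_profile"),
            core_cut > 0, core_cut < 1, bulk_cut > 0, bulk_cut < 1)
  cdf <- cumsum(oleic$density * diff(oleic$breaks))
  ix <- which(cdf > core_cut + 1e-9)
  if (!length(ix))
    stop("boundary-estimation error: oleic cumulative never reaches ",
         core_cut, call. = FALSE)
  core_radius <- oleic$breaks[ix[1L] + 1L]

  nb <- length(water$density)
  outer_ix <- seq.int(max(1L, nb - ceiling(0.2 * nb) + 1L), nb)
  plateau <- mean(water$density[outer_ix])
  if (plateau <= 0)
    stop("boundary-estimation error: water profile has no outer plateau",
         call. = FALSE)
  # reject profiles still rising at the box edge
  if (length(outer_ix) >= 3L) {
    sl <- stats::coef(stats::lm(water$density[outer_ix] ~ outer_ix))[2L]
    rise <- sl * length(outer_ix)
    if (is.finite(rise) && rise > 0.25 * plateau)
      stop("boundary-estimation error: water profile is still rising at ",
           "the box edge (plateau undetectable); use a volume-corrected ",
           "profile or a larger box", call. = FALSE)
  }
  jx <- which(water$density >= bulk_cut * plateau - 1e-12)
  if (!length(jx))
    stop("boundary-estimation error: water density never reaches ",
         bulk_cut, " of its plateau", call. = FALSE)
  water_onset <- water$breaks[jx[1L]]
  if (water_onset <= core_radius)
    stop("boundary-estimation error: water onset (", water_onset,
         " A) does not exceed the core radius (", core_radius, " A)",
         call. = FALSE)
  structure(list(core_radius = core_radius,
                 interface_thickness = water_onset - core_radius,
                 water_onset = water_onset),
            class = "region_boundaries")
}

#' Explicit region boundaries
#'
#' @param core_radius oil-core radius, A.
#' @param interface_thickness interfacial shell thickness, A.
#' @return object of class `region_boundaries`.
#' @export
region_boundaries <- function(core_radius, interface_thickness) {
  stopifnot(core_radius > 0, interface_thickness > 0)
  structure(list(core_radius = core_radius,
                 interface_thickness = interface_thickness,
                 water_onset = core_radius + interface_thickness),
            class = "region_boundaries")
}

#' @export
print.region_boundaries <- function(x, ...) {
  cat(sprintf("<region_boundaries> core %.3g A | interface %.3g A | water onset %.3g A\n",
              x$core_radius, x$interface_thickness, x$water_onset))
  invisible(x)
}

#' Percentage of a species in the oil, interfacial and aqueous regions
#'
#' Classifies each molecule's reference-point radius into
#' `[0, core)`, `[core, water_onset)`, `[water_onset, Inf)` per frame and
#' averages the per-frame percentages.
#'
#' @inheritParams radial_profile
#' @param boundaries a `region_boundaries`.
#' @return named numeric vector `c(pct_oil, pct_interfacial, pct_aqueous)`
#'   summing to 100.
#' @export
region_fractions <- function(traj, boundaries, species = "antioxidant") {
  stopifnot(inherits(boundaries, "region_boundaries"))
  traj <- as_trajectory(traj)
  if (!length(traj$frames))
    stop("empty trajectory", call. = FALSE)
  per_frame <- vapply(traj$frames, function(fr) {
    r <- reference_radii(fr, species)
    cls <- findInterval(r, c(boundaries$core_radius, boundaries$water_onset))
    100 * tabulate(cls + 1L, nbins = 3L) / length(r)
  }, numeric(3L))
  out <- rowMeans(per_frame)
  names(out) <- c("pct_oil", "pct_interfacial", "pct_aqueous")
  out
}

#' Mean distance of each antioxidant oxygen from the droplet center
#'
#' Pools every gallic-acid oxygen position over molecules and frames and
#' reports, per oxygen label, the mean and standard deviation of its
#' distance to the oil-core center of mass (insertion depth).
#'
#' @inheritParams radial_profile
#' @return data.frame with columns `atom`, `mean`, `sd`, `n`, ordered
#'   O0..O4.
#' @export
oxygen_distances <- function(traj) {
  traj <- as_trajectory(traj)
  labels <- paste0("O", 0:4)
  pool <- lapply(traj$frames, function(fr) {
    ctr <- droplet_com(fr)
    sel <- fr$species == "GAL" & fr$atom %in% labels
    if (!any(sel))
      stop("template mismatch: no gallic-acid oxygen atoms found",
           call. = FALSE)
    sub <- fr[sel, ]
    data.frame(atom = sub$atom,
               r = sqrt((sub$x - ctr[1L])^2 + (sub$y - ctr[2L])^2 +
                          (sub$z - ctr[3L])^2))
  })
  pool <- do.call(rbind, pool)
  missing <- setdiff(labels, unique(pool$atom))
  if (length(missing))
    stop("template mismatch: missing oxygen labels ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(
    atom = labels,
    mean = vapply(labels, function(l) mean(pool$r[pool$atom == l]),
                  numeric(1L)),
    sd = vapply(labels, function(l) stats::sd(pool$r[pool$atom == l]),
                numeric(1L)),
    n = vapply(labels, function(l) sum(pool$atom == l), integer(1L)))
  out$sd[is.na(out$sd)] <- 0
  rownames(out) <- NULL
  out
}

#' Orientation angles of one antioxidant molecule
#'
#' For gallic acid with the standard label set, against the radial vector R
#' pointing from the molecular center of mass toward the droplet center:
#' * `alpha` — angle between R and the para axis A (total-least-squares
#'   line through O4, C4, C1, C7, oriented O4 to C7), degrees on \[0, 180\];
#' * `beta` — angle between R and the COM-to-C6 vector, \[0, 180\];
#' * `gamma` — angle between R and the least-squares plane of the six ring
#'   carbons, folded to \[0, 90\] (the plane is unsigned); 90 degrees means
#'   the ring lies parallel to the droplet surface.
#'
#' @param frame a `droplet_frame`.
#' @param molid antioxidant molecule id.
#' @param com optional precomputed droplet center (A).
#' @return object of class `orientation_record`: list with `molid`,
#'   `alpha`, `beta`, `gamma` (degrees) and `com_radius` (A).
#' @export
orientation_angles <- function(frame, molid, com = NULL) {
  stopifnot(inherits(frame, "droplet_frame"))
  if (is.null(com)) com <- droplet_com(frame)
  sel <- frame$species == "GAL" & frame$molid == molid
  mol <- frame[sel, ]
  need <- c(paste0("C", 1:7), paste0("O", 0:4))
  if (!all(need %in% mol$atom))
    stop("antioxidant molecule ", molid, " lacks the full label set",
         call. = FALSE)
  xyz <- as.matrix(mol[match(need, mol$atom), c("x", "y", "z")])
  rownames(xyz) <- need
  w <- mol$mass[match(need, mol$atom)]
  com_g <- colSums(xyz * w) / sum(w)
  rvec <- com - com_g
  rlen <- vnorm(rvec)
  if (rlen < 1e-8)
    stop("degenerate geometry: molecule sits at the droplet center",
         call. = FALSE)
  a_axis <- tls_direction(xyz[c("O4", "C4", "C1", "C7"), ])
  b_vec <- xyz["C6", ] - com_g
  n_vec <- ring_normal(xyz[paste0("C", 1:6), ])
  theta <- angle_deg(rvec, n_vec)
  structure(list(molid = molid,
                 alpha = angle_deg(rvec, a_axis),
                 beta = angle_deg(rvec, b_vec),
                 gamma = 90 - min(theta, 180 - theta),
                 com_radius = rlen),
            class = "orientation_record")
}

#' @export
print.orientation_record <- function(x, ...) {
  cat(sprintf("<orientation_record> mol %s: alpha %.2f | beta %.2f | gamma %.2f | R %.2f A\n",
              format(x$molid), x$alpha, x$beta, x$gamma, x$com_radius))
  invisible(x)
}

# All orientation records of a trajectory as a data.frame.
orientation_table <- function(traj) {
  traj <- as_trajectory(traj)
  rows <- lapply(seq_along(traj$frames), function(i) {
    fr <- traj$frames[[i]]
    ctr <- droplet_com(fr)
    ids <- unique(fr$molid[fr$species == "GAL"])
    if (!length(ids)) return(NULL)
    do.call(rbind, lapply(ids, function(id) {
      o <- orientation_angles(fr, id, com = ctr)
      data.frame(frame = i, molid = id, alpha = o$alpha, beta = o$beta,
                 gamma = o$gamma, com_radius = o$com_radius)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out))
    stop("empty trajectory: no antioxidant molecules found", call. = FALSE)
  out
}

#' Distribution of one orientation angle
#'
#' Histogram over frames and molecules, normalized to unit integral
#' (probability per degree).  Local maxima are centers of bins strictly
#' exceeding both neighbors.
#'
#' @inheritParams radial_profile
#' @param angle `"alpha"`, `"beta"` (range \[0, 180\]) or `"gamma"`
#'   (\[0, 90\]).
#' @param bin_width bin width in degrees (default 3; the half-degree bin
#'   centers 1.5, 4.5, ... then tile both ranges exactly).
#' @return object of class `angle_distribution`: `angle`, `breaks`,
#'   `density` (probability per degree), `maxima` (bin centers), `n_samples`.
#' @export
angle_distribution <- function(traj, angle = c("alpha", "beta", "gamma"),
                               bin_width = 3) {
  angle <- match.arg(angle)
  stopifnot(bin_width > 0)
  tab <- orientation_table(traj)
  vals <- tab[[angle]]
  top <- if (angle == "gamma") 90 else 180
  breaks <- seq(0, top + bin_width * 1e-9, by = bin_width)
  if (breaks[length(breaks)] < top) breaks <- c(breaks, top)
  h <- graphics::hist(pmin(vals, top), breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  widths <- diff(breaks)
  dens <- h$counts / sum(h$counts * widths)
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  is_max <- local_maxima_1d(dens)
  structure(list(angle = angle, breaks = breaks, density = dens,
                 maxima = centers[is_max], n_samples = length(vals)),
            class = "angle_distribution")
}

local_maxima_1d <- function(d) {
  n <- length(d)
  if (n == 1L) return(d > 0)
  left <- c(-Inf, d[-n])
  right <- c(d[-1L], -Inf)
  d > left & d > right
}

#' @export
print.angle_distribution <- function(x, ...) {
  cat(sprintf("<angle_distribution> %s: %d bins, n = %d; maxima at %s deg\n",
              x$angle, length(x$density), x$n_samples,
              paste(signif(x$maxima, 4), collapse = ", ")))
  invisible(x)
}

#' Joint (alpha, beta) orientation density with ranked maxima
#'
#' Two-dimensional histogram of the (alpha, beta) pairs pooled over frames
#' and molecules, normalized to unit mass (`sum(density) * bin_width^2 = 1`).
#' Maxima are bin centers strictly dominating their 8-neighborhood, ranked
#' by density.
#'
#' @inheritParams angle_distribution
#' @return object of class `joint_angle_distribution`: `breaks` (shared by
#'   both axes), `density` (matrix, alpha rows x beta columns), `maxima`
#'   (data.frame `alpha`, `beta`, `density`, ranked), `n_samples`.
#' @export
joint_angle_distribution <- function(traj, bin_width = 3) {
  stopifnot(bin_width > 0)
  tab <- orientation_table(traj)
  breaks <- seq(0, 180 + bin_width * 1e-9, by = bin_width)
  if (breaks[length(breaks)] < 180) breaks <- c(breaks, 180)
  nb <- length(breaks) - 1L
  ia <- pmin(pmax(findInterval(tab$alpha, breaks, rightmost.closed = TRUE),
                  1L), nb)
  ib <- pmin(pmax(findInterval(tab$beta, breaks, rightmost.closed = TRUE),
                  1L), nb)
  counts <- matrix(0, nb, nb)
  for (k in seq_along(ia))
    counts[ia[k], ib[k]] <- counts[ia[k], ib[k]] + 1
  dens <- counts / (sum(counts) * bin_width^2)
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  mx <- local_maxima_2d(dens)
  ord <- order(dens[mx], decreasing = TRUE)
  idx <- which(mx, arr.ind = TRUE)[ord, , drop = FALSE]
  maxima <- data.frame(alpha = centers[idx[, 1L]],
                       beta = centers[idx[, 2L]],
                       density = dens[mx][ord])
  structure(list(breaks = breaks, density = dens, maxima = maxima,
                 n_samples = nrow(tab), bin_width = bin_width),
            class = "joint_angle_distribution")
}

local_maxima_2d <- function(d) {
  nr <- nrow(d); nc <- ncol(d)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- d
  out <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
    out <- out & (d > nb)
  }
  out & d > 0
}

#' @export
print.joint_angle_distribution <- function(x, ...) {
  cat(sprintf("<joint_angle_distribution> %d x %d bins, n = %d\n",
              nrow(x$density), ncol(x$density), x$n_samples))
  if (nrow(x$maxima)) {
    top <- utils::head(x$maxima, 3L)
    cat("  top maxima (alpha, beta):",
        paste(sprintf("(%.1f, %.1f)", top$alpha, top$beta),
              collapse = ", "), "\n")
  }
  invisible(x)
}
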