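# Synthetic spherical-droplet generator.  Emulates stored molecular
# configurations of an oil-in-water nanoemulsion droplet: an oleic-acid
# core, a surfactant shell represented by three reference sites per
# molecule, bulk water beyond the interface, and rigid-body placements of a
# gallic-acid heavy-atom template with prescribed radial and orientation
# laws.  Molecules other than the antioxidant are represented by their
# reference points only (one point per oleic acid / water molecule, three
# per surfactant), because only those points are ever analyzed.

SPECIES_MASS <- c(OLE = 282.468, HOH = 18.015,
                  RNG = 84.073, EOH = 17.007, TAIL = 265.0)

#' Specification of a synthetic droplet configuration
#'
#' Molecule counts and geometric laws for [build_droplet()] and
#' [sample_trajectory()].  The defaults describe a 1:9 (v:v) oil-in-water
#' nanoemulsion droplet at surfactant volume fraction 0.04: 200 oleic acid,
#' 20 Tween-80 surfactant and 8 gallic acid molecules, a ~20 A oil core and
#' a ~17 A interfacial shell, water filling the box beyond, the antioxidant
#' center-of-mass radius drawn from a gaussian with mode 31 A, and its
#' orientation drawn from a two-component (alpha, beta) mixture centered on
#' the two preferred interfacial tilts at (55.5, 64.5) and (82.5, 154.5)
#' degrees.  The default water count matches the full solvated system; most
#' analyses are insensitive to it, and tests use far fewer.
#'
#' @param n_oleic,n_surfactant,n_antioxidant,n_water molecule counts.
#' @param core_radius oil-core radius, A.
#' @param interface_thickness interfacial shell thickness, A.
#' @param box_radius outer bound of the water shell, A; default
#'   `core_radius + interface_thickness + 23`.
#' @param radial_law `dist_law` for the antioxidant center-of-mass radius, A.
#' @param orientation_law an [orient_alpha_beta()]-family descriptor.
#' @param seed integer seed; every draw of the generator flows from it.
#' @return object of class `species_spec`.
#' @examples
#' spec <- species_spec(n_water = 500, seed = 7)
#' frame <- build_droplet(spec)
#' @export
species_spec <- function(n_oleic = 200L, n_surfactant = 20L,
                         n_antioxidant = 8L, n_water = 33804L,
                         core_radius = 20, interface_thickness = 17,
                         box_radius = core_radius + interface_thickness + 23,
                         radial_law = law_gaussian(31, 3),
                         orientation_law = orient_joint(
                           rbind(c(55.5, 64.5), c(82.5, 154.5)), sd = 6),
                         seed = 1L) {
  counts <- c(n_oleic, n_surfactant, n_antioxidant, n_water)
  stopifnot(all(counts >= 0), all(counts == round(counts)),
            core_radius > 0, interface_thickness > 0,
            inherits(radial_law, "dist_law"),
            inherits(orientation_law, "orientation_law"),
            length(seed) == 1L, is.finite(seed))
  if (box_radius <= core_radius + interface_thickness)
    stop("geometry error: box_radius must exceed ",
         "core_radius + interface_thickness", call. = FALSE)
  structure(list(n_oleic = as.integer(n_oleic),
                 n_surfactant = as.integer(n_surfactant),
                 n_antioxidant = as.integer(n_antioxidant),
                 n_water = as.integer(n_water),
                 core_radius = core_radius,
                 interface_thickness = interface_thickness,
                 box_radius = box_radius,
                 radial_law = radial_law,
                 orientation_law = orientation_law,
                 seed = as.integer(seed)),
            class = "species_spec")
}

#' @export
print.species_spec <- function(x, ...) {
  cat(sprintf(paste0("<species_spec> %d oleic | %d surfactant | ",
                     "%d antioxidant | %d water\n"),
              x$n_oleic, x$n_surfactant, x$n_antioxidant, x$n_water))
  cat(sprintf("  core %.3g A | interface %.3g A | box %.3g A | seed %d\n",
              x$core_radius, x$interface_thickness, x$box_radius, x$seed))
  invisible(x)
}

# uniform point in the spherical shell [a, b] (volume-uniform)
runif_shell <- function(n, a, b) {
  if (n == 0L) return(matrix(numeric(0L), 0L, 3L))
  r <- (a^3 + stats::runif(n) * (b^3 - a^3))^(1 / 3)
  u <- matrix(stats::rnorm(3L * n), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  u * r
}

droplet_frame_df <- function(species, molid, atom, xyz, mass) {
  structure(data.frame(species = species, molid = molid, atom = atom,
                       x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                       mass = mass, stringsAsFactors = FALSE),
            class = c("droplet_frame", "data.frame"))
}

#' Build one synthetic droplet configuration
#'
#' Places all species of a [species_spec()]:
#' * oleic acid reference points uniform in the core sphere, recentered so
#'   their mass-weighted center sits exactly at the origin (the droplet
#'   center of mass is then the origin by construction);
#' * surfactant as three reference sites per molecule along one outward ray:
#'   the oleate tail inside the core surface, the five-carbon ring just
#'   outside it, and the ethylene-oxide hydroxyl termini near the outer edge
#'   of the interfacial shell;
#' * water points uniform in the shell from the water onset to the box bound;
#' * antioxidant molecules as rigid-body placements of
#'   [gallic_acid_template()], center-of-mass radius drawn from the radial
#'   law and orientation realized from the orientation law.
#'
#' Deterministic given `spec$seed`.
#'
#' @param spec a [species_spec()].
#' @return object of class `droplet_frame`: a data.frame with columns
#'   `species` (`OLE`, `TW80`, `GAL`, `HOH`), `molid`, `atom`, `x`, `y`,
#'   `z` (A), `mass` (amu).
#' @export
build_droplet <- function(spec) {
  stopifnot(inherits(spec, "species_spec"))
  local_rng(spec$seed, function() build_droplet_impl(spec))
}

build_droplet_impl <- function(spec) {
  core <- spec$core_radius
  onset <- core + spec$interface_thickness
  parts <- list()

  # oil core, recentered to put its COM exactly at the origin
  if (spec$n_oleic > 0L) {
    xyz <- runif_shell(spec$n_oleic, 0, core)
    xyz <- sweep(xyz, 2L, colMeans(xyz))
    parts$ole <- droplet_frame_df("OLE", seq_len(spec$n_oleic), "C",
                                  xyz, SPECIES_MASS[["OLE"]])
  }

  # surfactant: three sites per molecule along one outward ray
  if (spec$n_surfactant > 0L) {
    n <- spec$n_surfactant
    u <- matrix(stats::rnorm(3L * n), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    r_tail <- pmax(1, core - 4 + stats::rnorm(n, 0, 1))
    r_ring <- core + 1.5 + stats::rnorm(n, 0, 1)
    r_eoh <- onset - 1.5 + stats::rnorm(n, 0, 1)
    xyz <- rbind(u * r_ring, u * r_eoh, u * r_tail)
    parts$tw <- droplet_frame_df("TW80", rep(seq_len(n), 3L),
                                 rep(c("RNG", "EOH", "TAIL"), each = n), xyz,
                                 rep(SPECIES_MASS[c("RNG", "EOH", "TAIL")],
                                     each = n))
  }

  # antioxidant: rigid-body template placements
  if (spec$n_antioxidant > 0L) {
    body <- ga_body_frame()
    n <- spec$n_antioxidant
    radii <- sample_law(spec$radial_law, n, lower = 0,
                        upper = spec$box_radius)
    ga <- vector("list", n)
    for (i in seq_len(n)) {
      u_pos <- unit3(stats::rnorm(3L))
      com <- radii[i] * u_pos
      Q <- orientation_rotation(spec$orientation_law, -u_pos, body)
      xyz <- sweep(body$xyz, 2L, body$com) %*% t(Q)
      xyz <- sweep(xyz, 2L, com, `+`)
      ga[[i]] <- droplet_frame_df("GAL", i, body$tpl$atom, xyz,
                                  body$tpl$mass)
    }
    parts$gal <- do.call(rbind, ga)
  }

  # bulk water beyond the interface
  if (spec$n_water > 0L) {
    xyz <- runif_shell(spec$n_water, onset, spec$box_radius)
    parts$hoh <- droplet_frame_df("HOH", seq_len(spec$n_water), "O",
                                  xyz, SPECIES_MASS[["HOH"]])
  }

  out <- do.call(rbind, unname(parts))
  rownames(out) <- NULL
  class(out) <- c("droplet_frame", "data.frame")
  out
}

# Rotation matrix realizing one draw from an orientation law, for a molecule
# whose inward radial unit vector (GA COM -> droplet COM) is r_hat.
orientation_rotation <- function(law, r_hat, body) {
  basis <- onb_from(r_hat)
  switch(law$mode,
    random = random_rotation(),
    gamma = {
      g <- sample_law(law$gamma, 1L, lower = 0, upper = 90)
      theta <- 90 - g                      # angle(normal, r_hat)
      chi <- stats::runif(1L, 0, 360)
      n_w <- cos(theta * pi / 180) * basis$e3 +
        sin(theta * pi / 180) * (cos(chi * pi / 180) * basis$e1 +
                                   sin(chi * pi / 180) * basis$e2)
      if (stats::runif(1L) < 0.5) n_w <- -n_w   # plane normal is unsigned
      ref <- if (abs(sum(body$n * body$a)) < 0.99) body$a else body$b
      # align body normal onto n_w, then spin freely about it
      ax <- cross3(body$n, n_w)
      Q0 <- if (vnorm(ax) < 1e-12) {
        if (sum(body$n * n_w) > 0) diag(3L) else rot_axis(basis$e1, 180)
      } else rot_axis(ax, angle_deg(body$n, n_w))
      rot_axis(n_w, stats::runif(1L, 0, 360)) %*% Q0
    },
    {
      ab <- sample_alpha_beta(law, body$delta)
      Q <- alpha_beta_rotation(ab[1L], ab[2L], basis, body)
      rot_axis(basis$e3, stats::runif(1L, 0, 360)) %*% Q
    })
}

# Draw one feasible (alpha, beta) pair.  Feasibility: the fixed body angle
# delta between the para axis and the COM->C6 vector bounds the achievable
# pairs by the spherical triangle inequality.
sample_alpha_beta <- function(law, delta, max_tries = 500L) {
  draw <- function() {
    if (law$mode == "joint") {
      k <- sample.int(nrow(law$centers), 1L, prob = law$weights)
      if (law$sd[k] == 0) law$centers[k, ]
      else c(stats::rnorm(1L, law$centers[k, 1L], law$sd[k]),
             stats::rnorm(1L, law$centers[k, 2L], law$sd[k]))
    } else {
      c(sample_law(law$alpha, 1L, 0, 180), sample_law(law$beta, 1L, 0, 180))
    }
  }
  for (i in seq_len(max_tries)) {
    ab <- draw()
    if (ab[1L] < 0 || ab[1L] > 180 || ab[2L] < 0 || ab[2L] > 180) next
    if (!is.na(alpha_beta_azimuth(ab[1L], ab[2L], delta))) return(ab)
  }
  stop("orientation law yielded no geometrically feasible (alpha, beta) ",
       "pair in ", max_tries, " draws (body angle delta = ",
       signif(delta, 4), " deg)", call. = FALSE)
}

# Azimuth phi of the B-vector cone solution; NA when (alpha, beta, delta)
# violates the spherical triangle inequality.
alpha_beta_azimuth <- function(alpha, beta, delta) {
  a <- alpha * pi / 180; b <- beta * pi / 180; d <- delta * pi / 180
  sa <- sin(a); sb <- sin(b)
  if (sa < 1e-9 || sb < 1e-9) {
    # degenerate cones: feasible only if the triangle closes exactly
    ok <- abs(cos(d) - cos(a) * cos(b)) < 1e-9
    return(if (ok) 0 else NA_real_)
  }
  cphi <- (cos(d) - cos(a) * cos(b)) / (sa * sb)
  if (abs(cphi) > 1 + 1e-12) return(NA_real_)
  acos(min(1, max(-1, cphi)))
}

# Constructive alignment: rotation placing the body para axis at angle alpha
# and the COM->C6 vector at angle beta from e3 (the inward radial vector),
# choosing the mirror branch at random.
alpha_beta_rotation <- function(alpha, beta, basis, body) {
  phi <- alpha_beta_azimuth(alpha, beta, body$delta)
  if (is.na(phi))
    stop("infeasible (alpha, beta) = (", signif(alpha, 4), ", ",
         signif(beta, 4), ") for body angle delta = ",
         signif(body$delta, 4), call. = FALSE)
  if (stats::runif(1L) < 0.5) phi <- -phi
  ar <- alpha * pi / 180; br <- beta * pi / 180
  a_w <- cos(ar) * basis$e3 + sin(ar) * basis$e1
  b_w <- cos(br) * basis$e3 +
    sin(br) * (cos(phi) * basis$e1 + sin(phi) * basis$e2)
  triad_rotation(body$a, body$b, a_w, b_w)
}

#' Sample a synthetic droplet trajectory
#'
#' Draws `n_frames` independent configurations from the same generative
#' laws.  Frame 1 is identical to `build_droplet(spec)`.
#'
#' @inheritParams build_droplet
#' @param n_frames number of frames (>= 1).
#' @return object of class `droplet_trajectory`: a list with elements
#'   `frames` (list of `droplet_frame`) and `spec`.
#' @export
sample_trajectory <- function(spec, n_frames) {
  stopifnot(inherits(spec, "species_spec"))
  if (length(n_frames) != 1L || n_frames < 1L)
    stop("empty trajectory: n_frames must be >= 1", call. = FALSE)
  frames <- local_rng(spec$seed, function() {
    lapply(seq_len(n_frames), function(i) build_droplet_impl(spec))
  })
  droplet_trajectory(frames, spec = spec)
}

#' Construct a droplet trajectory from frames
#'
#' @param frames list of `droplet_frame` objects sharing one atom roster.
#' @param spec optional [species_spec()] metadata.
#' @param frame_interval optional time between frames (metadata only; frames
#'   are analyzed as an unordered ensemble).
#' @return object of class `droplet_trajectory`.
#' @export
droplet_trajectory <- function(frames, spec = NULL, frame_interval = NULL) {
  stopifnot(length(frames) >= 1L,
            all(vapply(frames, inherits, logical(1L), "droplet_frame")))
  roster <- frames[[1L]][, c("species", "molid", "atom")]
  for (i in seq_along(frames)) {
    if (!identical(frames[[i]][, c("species", "molid", "atom")], roster))
      stop("frame ", i, " does not share the atom roster of frame 1",
           call. = FALSE)
  }
  structure(list(frames = frames, spec = spec,
                 frame_interval = frame_interval),
            class = "droplet_trajectory")
}

#' @export
print.droplet_trajectory <- function(x, ...) {
  cat(sprintf("<droplet_trajectory> %d frames x %d atoms\n",
              length(x$frames), nrow(x$frames[[1L]])))
  invisible(x)
}

#' @export
print.droplet_frame <- function(x, ...) {
  tab <- table(x$species[!duplicated(paste(x$species, x$molid))])
  cat("<droplet_frame>", nrow(x), "atoms;",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Per-species molecule counts of a droplet frame
#'
#' @param frame a `droplet_frame`.
#' @return named integer vector of molecule (not atom) counts.
#' @export
species_counts <- function(frame) {
  stopifnot(inherits(frame, "droplet_frame"))
  mol <- unique(frame[, c("species", "molid")])
  table(factor(mol$species))
}
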