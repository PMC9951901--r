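# File interfaces: droplet configurations as multi-MODEL PDB or multi-frame
# XYZ, kinetic series and oxidation curves as CSV, plus the configuration-
# driven pipeline runner.  CSV dialect throughout: comma-separated, '.'
# decimal, header row, UTF-8.

# species tag <-> PDB residue name (PDB residue names are 3 characters)
PDB_RESID <- c(OLE = "OLE", TW80 = "TWN", GAL = "GAL", HOH = "HOH")
DEFAULT_MAPPING <- c(OLE = "OLE", TWN = "TW80", GAL = "GAL", HOH = "HOH")

atom_mass <- function(species, atom) {
  m <- numeric(length(species))
  ga <- species == "GAL"
  m[ga] <- ifelse(startsWith(atom[ga], "O"), 15.999, 12.011)
  for (s in c("OLE", "HOH")) m[species == s] <- SPECIES_MASS[[s]]
  tw <- species == "TW80"
  m[tw] <- SPECIES_MASS[atom[tw]]
  if (anyNA(m) || any(m == 0))
    stop("mapping error: unknown species/atom combination", call. = FALSE)
  m
}

#' Write a droplet trajectory to PDB or XYZ
#'
#' PDB frames are `MODEL`-separated records with species encoded in the
#' residue name (`OLE`, `TWN` for the surfactant, `GAL`, `HOH`), molecule
#' ids in the residue number and site labels in the atom name.  XYZ frames
#' are standard multi-frame blocks whose atom token encodes
#' `SPECIES_MOLID_ATOM` (e.g. `GAL_3_O4`), written at 1e-6 A precision.
#'
#' @param traj a `droplet_trajectory` (or single `droplet_frame`).
#' @param path output file.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_frames <- function(traj, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  traj <- as_trajectory(traj)
  fr1 <- traj$frames[[1L]]
  n_atoms <- nrow(fr1)
  xyz_mat <- t(vapply(traj$frames, function(fr)
    as.numeric(t(as.matrix(fr[, c("x", "y", "z")]))), numeric(3L * n_atoms)))
  if (length(traj$frames) == 1L) xyz_mat <- matrix(xyz_mat, nrow = 1L)
  if (format == "pdb") {
    if (max(fr1$molid) > 9999L)
      stop("PDB residue numbers are limited to 9999; use format = 'xyz' ",
           "for this trajectory", call. = FALSE)
    bio3d::write.pdb(file = path, xyz = xyz_mat,
                     resno = fr1$molid,
                     resid = unname(PDB_RESID[fr1$species]),
                     elety = fr1$atom,
                     chain = rep("A", n_atoms))
  } else {
    token <- paste(fr1$species, fr1$molid, fr1$atom, sep = "_")
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (f in seq_len(nrow(xyz_mat))) {
      co <- matrix(xyz_mat[f, ], ncol = 3L, byrow = TRUE)
      writeLines(c(as.character(n_atoms), paste("frame", f),
                   sprintf("%s %.6f %.6f %.6f",
                           token, co[, 1L], co[, 2L], co[, 3L])), con)
    }
  }
  invisible(path)
}

#' Read a droplet trajectory from PDB or XYZ
#'
#' Inverse of [write_frames()].  For PDB, `mapping` translates residue
#' names to species tags (defaults cover the package's own convention) so
#' that converted output of other tools can be read with a custom map,
#' e.g. from a YAML file `yaml::read_yaml(f)` giving `resname: species`
#' pairs.
#'
#' @param path input file.
#' @param format `"pdb"` or `"xyz"`.
#' @param mapping named character vector or list, residue name -> species
#'   tag (`OLE`, `TW80`, `GAL`, `HOH`).
#' @return a `droplet_trajectory`.
#' @export
read_frames <- function(path, format = c("pdb", "xyz"), mapping = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "pdb") {
    map <- DEFAULT_MAPPING
    if (!is.null(mapping)) {
      mapping <- unlist(mapping)
      map[names(mapping)] <- mapping
    }
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    resid <- pdb$atom$resid
    if (!all(resid %in% names(map)))
      stop("mapping error: unmapped residue names ",
           paste(unique(setdiff(resid, names(map))), collapse = ", "),
           call. = FALSE)
    species <- unname(map[resid])
    molid <- pdb$atom$resno
    atom <- pdb$atom$elety
    mass <- atom_mass(species, atom)
    frames <- lapply(seq_len(nrow(pdb$xyz)), function(f) {
      co <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)
      droplet_frame_df(species, molid, atom, co, mass)
    })
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    frames <- list()
    i <- 1L
    while (i <= length(lines)) {
      if (!grepl("^\\s*\\d+\\s*$", lines[i]))
        stop("parse error at line ", i, ": expected an atom count",
             call. = FALSE)
      n <- as.integer(lines[i])
      if (i + 1L + n > length(lines))
        stop("parse error at line ", i, ": truncated frame (expected ", n,
             " atom lines)", call. = FALSE)
      body <- lines[(i + 2L):(i + 1L + n)]
      parts <- strsplit(trimws(body), "\\s+")
      if (any(lengths(parts) != 4L))
        stop("parse error at line ",
             i + 1L + which(lengths(parts) != 4L)[1L],
             ": expected 'token x y z'", call. = FALSE)
      token <- vapply(parts, `[[`, character(1L), 1L)
      tk <- strsplit(token, "_", fixed = TRUE)
      if (any(lengths(tk) != 3L))
        stop("parse error: atom token must be SPECIES_MOLID_ATOM",
             call. = FALSE)
      species <- vapply(tk, `[[`, character(1L), 1L)
      molid <- as.integer(vapply(tk, `[[`, character(1L), 2L))
      atom <- vapply(tk, `[[`, character(1L), 3L)
      co <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                   ncol = 3L, byrow = TRUE)
      frames[[length(frames) + 1L]] <-
        droplet_frame_df(species, molid, atom, co,
                         atom_mass(species, atom))
      i <- i + 2L + n
    }
    if (!length(frames)) stop("parse error: no frames found", call. = FALSE)
  }
  droplet_trajectory(frames)
}

#' Read and write observed-rate-constant series as CSV
#'
#' Columns `phi_I`, `k_obs` and optionally `sigma_kobs`.  The stoichiometric
#' concentration and oil fraction are experiment-level constants supplied
#' alongside the file.
#'
#' @param series a [kobs_series()].
#' @param path CSV file path.
#' @return `write_kobs_csv`: `path` invisibly; `read_kobs_csv`: a
#'   [kobs_series()].
#' @export
write_kobs_csv <- function(series, path) {
  stopifnot(inherits(series, "kobs_series"))
  df <- as.data.frame(series)
  names(df)[1:2] <- c("phi_I", "k_obs")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kobs_csv
#' @inheritParams kobs_series
#' @export
read_kobs_csv <- function(path, ao_total, phi_oil) {
  df <- utils::read.csv(path)
  if (!all(c("phi_I", "k_obs") %in% names(df)))
    stop("CSV must have columns phi_I and k_obs", call. = FALSE)
  kobs_series(df$phi_I, df$k_obs, ao_total = ao_total, phi_oil = phi_oil,
              sigma_kobs = df$sigma_kobs)
}

#' Read and write oxidation curves as CSV
#'
#' Columns `time`, `signal`, `label`.
#'
#' @param curve an [oxidation_curve()].
#' @param path CSV file path.
#' @return `write_curve_csv`: `path` invisibly; `read_curve_csv`: an
#'   [oxidation_curve()].
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "oxidation_curve"))
  df <- data.frame(time = curve$time, signal = curve$signal,
                   label = attr(curve, "label"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time", "signal") %in% names(df)))
    stop("CSV must have columns time and signal", call. = FALSE)
  lbl <- if ("label" %in% names(df)) as.character(df$label[1L]) else "curve"
  oxidation_curve(df$time, df$signal, label = lbl)
}

law_from_config <- function(x) {
  if (inherits(x, "dist_law")) return(x)
  stopifnot(is.list(x), !is.null(x$family))
  switch(x$family,
         gaussian = law_gaussian(x$mean, x$sd),
         uniform = law_uniform(x$min, x$max),
         delta = law_delta(x$at),
         stop("unsupported law family in config: ", x$family,
              call. = FALSE))
}

PIPELINE_KEYS <- c("seed", "stages", "composition", "partition", "droplet",
                   "analysis", "oxidation", "kinetics")

#' Validate a pipeline configuration
#'
#' Checks key names, volume-fraction consistency and seed presence before
#' any stage runs.  `config` may be a list or the path of a YAML file.
#'
#' @param config list or YAML path.
#' @return the validated config list, invisibly on error-free input.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$seed) || !is.finite(config$seed))
    stop("config must carry an integer seed", call. = FALSE)
  comp <- config$composition
  if (is.null(comp$phi_oil) || is.null(comp$ao_total))
    stop("config$composition must give phi_oil and ao_total", call. = FALSE)
  phis <- config$partition$phi_list
  if (!is.null(phis) && any(comp$phi_oil + phis >= 1))
    stop("validation error: phi_oil + phi_I must be < 1 for every ",
         "phi_list entry", call. = FALSE)
  invisible(config)
}

#' Run the synthetic-to-analysis pipeline
#'
#' Executes the requested stages in order `synth` (droplet trajectory,
#' rate-constant series, oxidation curve pair), `analyze` (radial profiles,
#' region boundaries and occupancies, oxygen depths, angle distributions),
#' `fit` (partition fit and distribution table) and `kinetics` (induction
#' times and effectiveness ratio), writing every artifact under `out_dir`
#' together with a JSON manifest carrying the seed, the parameters and an
#' MD5 checksum per file.  All randomness flows from `config$seed` via
#' fixed per-stage offsets (droplet `+0`, rate series `+1000`), so an
#' identical config and seed reproduce byte-identical numeric outputs.
#'
#' @param config list or YAML path; see [validate_config()] and the
#'   bundled example in `inst/extdata/pipeline_demo.yaml`.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  comp <- config$composition
  part <- config$partition
  stages <- config$stages %||% c("synth", "analyze", "fit", "kinetics")
  files <- character(0L)
  record <- function(f) files <<- c(files, f)

  drop_cfg <- config$droplet %||% list()
  spec_args <- drop_cfg[intersect(names(drop_cfg),
                                  c("n_oleic", "n_surfactant",
                                    "n_antioxidant", "n_water",
                                    "core_radius", "interface_thickness",
                                    "box_radius"))]
  if (!is.null(drop_cfg$radial_law))
    spec_args$radial_law <- law_from_config(drop_cfg$radial_law)
  spec_args$seed <- seed
  spec <- do.call(species_spec, spec_args)
  n_frames <- drop_cfg$n_frames %||% 20L

  phi_list <- part$phi_list %||% seq(0.005, 0.04, length.out = 8L)
  ox_cfg <- config$oxidation %||% list()
  ox_args <- ox_cfg[intersect(names(ox_cfg),
                              names(formals(kinetic_scheme_params)))]
  params_ao <- do.call(kinetic_scheme_params, ox_args)
  ctrl_args <- ox_args; ctrl_args$aoh0 <- 0
  params_ctrl <- do.call(kinetic_scheme_params, ctrl_args)
  t_grid <- seq(0, ox_cfg$t_max %||% 100, by = ox_cfg$t_step %||% 0.5)

  paths <- list(traj = file.path(out_dir, "trajectory.xyz"),
                kobs = file.path(out_dir, "kobs_series.csv"),
                ox_ao = file.path(out_dir, "oxidation_antioxidant.csv"),
                ox_ctrl = file.path(out_dir, "oxidation_control.csv"),
                sidecar = file.path(out_dir, "generator_params.json"))

  if ("synth" %in% stages) {
    traj <- sample_trajectory(spec, n_frames)
    write_frames(traj, paths$traj, "xyz"); record(paths$traj)
    series <- generate_kobs_series(part$p_wi %||% 93,
                                   part$k_i %||% 1e4,
                                   comp$ao_total, comp$phi_oil, phi_list,
                                   noise_cv = part$noise_cv %||% 0.05,
                                   seed = seed + 1000L)
    write_kobs_csv(series, paths$kobs); record(paths$kobs)
    write_curve_csv(simulate_oxidation(params_ao, t_grid, "antioxidant"),
                    paths$ox_ao); record(paths$ox_ao)
    write_curve_csv(simulate_oxidation(params_ctrl, t_grid, "control"),
                    paths$ox_ctrl); record(paths$ox_ctrl)
    sidecar <- list(seed = seed,
                    species_spec = unclass(spec)[setdiff(names(spec),
                      c("radial_law", "orientation_law"))],
                    n_frames = n_frames, phi_list = phi_list,
                    oxidation = unclass(params_ao))
    jsonlite::write_json(sidecar, paths$sidecar, auto_unbox = TRUE,
                         digits = NA)
    record(paths$sidecar)
  }

  ana <- config$analysis %||% list()
  if ("analyze" %in% stages) {
    traj <- read_frames(paths$traj, "xyz")
    bw <- ana$bin_width %||% 1
    prof <- lapply(c("oleic", "antioxidant", "water"), function(sp)
      radial_profile(traj, sp, bin_width = bw))
    prof_df <- do.call(rbind, lapply(prof, function(p)
      data.frame(species = p$species,
                 bin_center = (p$breaks[-1L] + p$breaks[-length(p$breaks)]) / 2,
                 density = p$density)))
    f <- file.path(out_dir, "radial_profiles.csv")
    utils::write.csv(prof_df, f, row.names = FALSE); record(f)

    bounds <- estimate_regions(
      radial_profile(traj, "oleic", bw, volume_corrected = TRUE),
      radial_profile(traj, "water", bw, volume_corrected = TRUE),
      core_cut = ana$core_cut %||% 0.95,
      bulk_cut = ana$bulk_cut %||% 0.90)
    fracs <- region_fractions(traj, bounds, "antioxidant")
    f <- file.path(out_dir, "regions.json")
    jsonlite::write_json(c(unclass(bounds), as.list(fracs)), f,
                         auto_unbox = TRUE, digits = NA)
    record(f)

    f <- file.path(out_dir, "oxygen_distances.csv")
    utils::write.csv(oxygen_distances(traj), f, row.names = FALSE)
    record(f)

    abw <- ana$angle_bin_width %||% 3
    ang_df <- do.call(rbind, lapply(c("alpha", "beta", "gamma"),
      function(a) {
        d <- angle_distribution(traj, a, bin_width = abw)
        data.frame(angle = a,
                   bin_center = (d$breaks[-1L] +
                                   d$breaks[-length(d$breaks)]) / 2,
                   density = d$density)
      }))
    f <- file.path(out_dir, "angle_distributions.csv")
    utils::write.csv(ang_df, f, row.names = FALSE); record(f)

    jd <- joint_angle_distribution(traj, bin_width = abw)
    f <- file.path(out_dir, "joint_angle_maxima.json")
    jsonlite::write_json(jd$maxima, f, digits = NA); record(f)
  }

  if ("fit" %in% stages) {
    series <- read_kobs_csv(paths$kobs, comp$ao_total, comp$phi_oil)
    fit <- fit_partition(series, method = part$method %||% "nonlinear")
    f <- file.path(out_dir, "partition_fit.json")
    jsonlite::write_json(unclass(fit), f, auto_unbox = TRUE, digits = NA)
    record(f)
    tab <- distribution_table(fit$p_wi, comp$ao_total, comp$phi_oil,
                              phi_list)
    f <- file.path(out_dir, "distribution_table.csv")
    utils::write.csv(tab, f, row.names = FALSE); record(f)
  }

  if ("kinetics" %in% stages) {
    cv_ao <- read_curve_csv(paths$ox_ao)
    cv_ctrl <- read_curve_csv(paths$ox_ctrl)
    ms <- (config$kinetics %||% list())$min_segment %||% 3L
    res_ao <- induction_time(cv_ao, ms)
    res_ctrl <- induction_time(cv_ctrl, ms)
    f <- file.path(out_dir, "induction.json")
    jsonlite::write_json(list(antioxidant = unclass(res_ao),
                              control = unclass(res_ctrl),
                              effectiveness_ratio =
                                res_ao$tau_ind / res_ctrl$tau_ind),
                         f, auto_unbox = TRUE, digits = NA)
    record(f)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("emulsiphase")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, stages = stages, config = config,
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
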