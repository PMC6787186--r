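# Trajectory interchange (XYZ + JSON provenance sidecar) and YAML run
# configuration.

#' Write a trajectory as XYZ
#'
#' Standard multi-frame XYZ: per frame an atom-count line, a comment
#' line carrying the frame time (`t= <ns> frame= <i>`), then one
#' `C x y 0.0` record per bead (the planar chain embeds with z = 0).  A
#' JSON sidecar `<path>.json` stores the provenance (parameters,
#' pattern, field, dt, seed) so a written run is fully reproducible.
#'
#' @param traj A trajectory tibble (`frame`, `time`, `bead`, `x`, `y`).
#' @param path Output file path.
#' @param sidecar Write the provenance sidecar (default TRUE).
#' @param digits Coordinate digits written.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, sidecar = TRUE, digits = 8) {
  m <- traj_matrices(as_traj_tbl(traj))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("C %.", digits, "f %.", digits, "f 0.0")
  for (f in seq_len(m$n_frames)) {
    writeLines(as.character(m$n_beads), con)
    writeLines(sprintf("t= %.9f frame= %d", m$time[f], f), con)
    writeLines(sprintf(fmt, m$X[f, ], m$Y[f, ]), con)
  }
  if (sidecar) {
    prov <- trajectory_provenance(traj)
    if (is.null(prov)) prov <- list()
    jsonlite::write_json(strip_classes(prov), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' Parses a multi-frame XYZ file written by [write_xyz()] (or any
#' standard XYZ with x, y in nm); z coordinates are dropped.  A
#' `<path>.json` sidecar, when present, restores the provenance.
#' Malformed or truncated files raise an error naming the offending
#' line and the last complete frame.
#'
#' @param path File path.
#' @return A `bd_trajectory` tibble.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  times <- c()
  i <- 1L
  nframe <- 0L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i])) {
      stop("malformed XYZ at line ", i, ": expected atom count (last complete frame: ",
           nframe, ")")
    }
    nat <- as.integer(lines[i])
    if (i + 1L + nat > length(lines)) {
      stop("truncated XYZ: frame ", nframe + 1L, " starting at line ", i,
           " is incomplete (last complete frame: ", nframe, ")")
    }
    comment <- lines[i + 1L]
    tmatch <- regmatches(comment,
                         regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
    t_val <- if (length(tmatch) == 2) as.numeric(tmatch[2]) else nframe
    rows <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 3L)
    if (length(bad)) {
      stop("malformed XYZ record at line ", i + 1L + bad[1],
           " (last complete frame: ", nframe, ")")
    }
    xs <- as.numeric(vapply(parts, `[[`, "", 2L))
    ys <- as.numeric(vapply(parts, `[[`, "", 3L))
    if (anyNA(xs) || anyNA(ys)) {
      stop("non-numeric coordinates in frame ", nframe + 1L,
           " starting at line ", i)
    }
    nframe <- nframe + 1L
    frames[[nframe]] <- cbind(xs, ys)
    times[nframe] <- t_val
    i <- i + 2L + nat
  }
  if (nframe == 0L) stop("empty XYZ file: ", path)
  nb <- nrow(frames[[1]])
  tbl <- tibble::tibble(
    frame = rep(seq_len(nframe), each = nb),
    time = rep(times, each = nb),
    bead = rep(seq_len(nb), times = nframe),
    x = unlist(lapply(frames, function(f) f[, 1])),
    y = unlist(lapply(frames, function(f) f[, 2]))
  )
  side <- paste0(path, ".json")
  prov <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  attr(tbl, "provenance") <- prov
  class(tbl) <- c("bd_trajectory", class(tbl))
  tbl
}

# ---- run configuration ------------------------------------------------

config_schema <- list(
  chain = c("n_beads", "bond_length", "target_lp", "bond_stiffness",
            "bend_stiffness", "excluded_volume", "ev_diameter",
            "ev_strength", "bead_charge", "bead_friction",
            "chain_diffusion", "temperature"),
  surface = c("geometry", "delta_eps_kcal", "base_eps_kcal",
              "stripe_width", "smoothing"),
  field = c("E", "voltage", "box_length"),
  scenario = c("name", "initial_conformation", "offset", "n_steps", "dt",
               "sample_every", "discard_frac", "seed", "field_E"),
  analysis = c("lp_fit_min", "lp_fit_max", "msd_window_frac",
               "n_backbone_charges", "bjerrum_length")
)

#' Read and validate a YAML run configuration
#'
#' Configuration files have sections `chain`, `surface`, `field`,
#' `scenario` and `analysis`; every key is optional and defaults to the
#' standard study values recorded in [chain_params()],
#' [surface_pattern()], [field_spec()] and [scenario()].  Unknown
#' sections or keys are rejected with the offending name.
#'
#' @param path Path to a YAML file.
#' @return The validated configuration as a named list of class
#'   `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A configuration list (as parsed from YAML).
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  bad_sec <- setdiff(names(cfg), names(config_schema))
  if (length(bad_sec)) {
    stop("unknown configuration section: '", bad_sec[1], "'")
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad)) {
      stop("unknown key '", bad[1], "' in section [", sec, "]")
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Run a scenario from a configuration
#'
#' Resolves a (possibly partial) configuration against the package
#' defaults, runs the scenario and returns the trajectory; the fully
#' resolved configuration is embedded in the trajectory provenance.
#'
#' @param cfg A `run_config` (from [read_run_config()]) or a plain list.
#' @param seed Optional seed overriding the configuration.
#' @param quiet Passed to [run_scenario()].
#' @return A `bd_trajectory`.
#' @export
run_from_config <- function(cfg, seed = NULL, quiet = TRUE) {
  cfg <- validate_run_config(unclass(cfg))
  sc_args <- cfg$scenario %||% list()
  if (!is.null(seed)) sc_args$seed <- seed
  if (is.null(sc_args$name)) sc_args$name <- "free_uniform"
  # a [chain] section overrides the preset's parameter defaults wholesale
  if (!is.null(cfg$chain)) {
    sc_args$params <- do.call(chain_params, cfg$chain)
  }
  sc <- do.call(scenario, sc_args)
  params <- sc$params
  if (!is.null(cfg$surface)) {
    sc$pattern <- do.call(surface_pattern, cfg$surface)
  }
  if (!is.null(cfg$field)) {
    sc$field <- do.call(field_spec, cfg$field)
  }
  traj <- run_scenario(sc, quiet = quiet)
  prov <- attr(traj, "provenance")
  prov$resolved_config <- list(
    chain = unclass(params), surface = unclass(sc$pattern),
    field = unclass(sc$field),
    scenario = sc[c("name", "conformation", "offset", "n_steps",
                    "sample_every", "discard_frac", "seed")]
  )
  attr(traj, "provenance") <- prov
  traj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# recursively drop S3 classes so provenance serialises as plain JSON
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}
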