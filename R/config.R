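config_defaults <- function() {
  list(
    # domain / flow (stock values reproduce the full-scale study setup:
    # channel [0, 10H] x [0, H], H discretized with 200 nodes)
    H_nodes = 200L,
    domain_H = 10,
    tau = 1.1,
    Re = 0.1,
    # particle
    shape = "circle",
    aspect_ratio = 1,
    d_over_H = NULL,
    theta0 = 0,
    y0_H = 3e-3,
    y_c0_H = NULL,
    # adhesion
    rho_l = 0.5,
    sigma = 2,
    y_cr_H = 6.8e-3,
    kf_kr0 = 8.5e3,
    kr0_dt = NULL,
    kBT_lat = NULL,
    Hk_lat = NULL,
    hk_scale = 0.3,
    eps_floor = 0.05,
    # numerics
    probe_len = 1.2,
    mls_rs = 2.5,
    nsteps = 150000L,
    sample_every = 200L,
    window = 0.25,
    seed = 1L,
    # classification thresholds
    vel_threshold = 5e-3,
    persist_hi = 0.5,
    persist_lo = 0.1,
    # output
    dump_every = 0L,
    dump_dir = "."
  )
}

#' Build and validate a simulation configuration
#'
#' Returns the full configuration for a near-wall adhesion run, with every
#' unset field filled from the stock defaults (geometry `[0, 10H] x [0, H]`
#' with 200 wall-normal nodes, `y_cr = 6.8e-3 H`, `y_0 = 3e-3 H`,
#' affinity `k_f/k_r0 = 8.5e3`, circle of diameter 0.18 H, ...).  Reduced
#' problem sizes for desk-scale runs are obtained by overriding `H_nodes`
#' (50-100) and `domain_H` (4-5).
#'
#' @param ... configuration fields overriding the defaults; unknown field
#'   names are an error.
#' @return a validated list of class `lbad_config`.
#' @export
#' @examples
#' cfg <- simulation_config(H_nodes = 64, domain_H = 4, Re = 0.1,
#'                          rho_l = 0.5)
simulation_config <- function(...) {
  defaults <- config_defaults()
  user <- list(...)
  if (length(user) == 1L && is.list(user[[1]]) && is.null(names(user))) {
    user <- user[[1]]
  }
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0)
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  cfg <- defaults
  for (nm in names(user)) cfg[nm] <- list(user[[nm]])
  validate_config(cfg)
  structure(cfg, class = "lbad_config")
}

validate_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$H_nodes >= 17, "H_nodes: need at least 17 wall-normal nodes")
  chk(cfg$domain_H >= 1, "domain_H: channel must be at least one H long")
  chk(cfg$tau > 0.5, "tau: relaxation time must exceed 1/2")
  chk(cfg$Re > 0, "Re: Reynolds number must be positive")
  chk(cfg$shape %in% c("circle", "ellipse"), "shape: circle or ellipse")
  chk(cfg$aspect_ratio %in% c(1, 2, 3), "aspect_ratio: 1, 2 or 3")
  chk(cfg$rho_l >= 0 && cfg$rho_l <= 1, "rho_l: ligand density in [0, 1]")
  chk(cfg$sigma > 0, "sigma: bond strength must be positive")
  chk(cfg$y_cr_H > 0, "y_cr_H: critical distance must be positive")
  chk(cfg$y0_H > 0, "y0_H: initial gap must be positive")
  if (is.null(cfg$y_c0_H)) {
    chk(cfg$y0_H < cfg$y_cr_H,
        "y0_H: initial gap must lie below y_cr_H so bonds can form")
  }
  chk(cfg$nsteps >= cfg$sample_every, "nsteps: shorter than sample_every")
  chk(cfg$window > 0 && cfg$window <= 1, "window: fraction in (0, 1]")
  if (length(problems) > 0)
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  invisible(cfg)
}

#' Load a simulation configuration from a YAML file
#'
#' Reads a plain-text key-value (YAML) configuration, fills every unset
#' field with the stock defaults, and validates ranges.  Unknown keys are
#' reported as errors.
#'
#' @param path YAML file path.
#' @return an `lbad_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  simulation_config(raw)
}

#' Save a configuration to YAML
#'
#' @param cfg an `lbad_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' Polynomial rolling hash of the canonical JSON encoding; identical
#' hashes (plus seed) imply bit-identical trajectories on one machine.
#'
#' @param cfg an `lbad_config`.
#' @return an 8-character hexadecimal string.
#' @export
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(
    unclass(cfg)[order(names(unclass(cfg)))],
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  bytes <- as.integer(charToRaw(as.character(js)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483648
  sprintf("%08x", as.integer(h))
}

#' Run manifest for reproducibility bookkeeping
#'
#' @param cfg an `lbad_config`.
#' @param path optional JSON output file.
#' @return manifest list (config hash, seed, package version, parameter
#'   echo, timestamp), invisibly written to `path` when given.
#' @export
run_manifest <- function(cfg, path = NULL) {
  man <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    package = "lbadhesion",
    version = as.character(packageVersion("lbadhesion")),
    parameters = unclass(cfg),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(man)
}
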