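#' Default run configuration
#'
#' Nested list of all model parameters with their packaged defaults and
#' unit strings, suitable for serialization to YAML.  Units are explicit
#' so that a config file can override both values and unit conventions
#' (pressures accept `"mmHg"` or `"Pa"`; the membrane density accepts
#' `"kg/m^3"` or, for sources quoting a surface density, `"kg/m^2"`,
#' which is converted by dividing by the wall thickness).
#'
#' @return A nested list of parameter blocks.
#' @export
default_config <- function() {
  list(
    material = list(c1 = -22.5e5, c2 = 1.26, c3 = -7.8e5,
                    units = list(c1 = "N/m^2", c2 = "1", c3 = "N/m^2")),
    geometry = list(H = 1e-3, R = 1e-2, units = list(H = "m", R = "m")),
    membrane = list(rho_m = 1050, mu_m = 7e-2,
                    units = list(rho_m = "kg/m^3", mu_m = "Pa.s")),
    fluid = list(rho_f = 980.3, mu_f = 1.48e-3, p_inf = 0,
                 units = list(rho_f = "kg/m^3", mu_f = "Pa.s",
                              p_inf = "mmHg")),
    breathing = list(components = breathing_table(), R_b = 1,
                     baseline = 760,
                     units = list(A = "L/s", f = "Hz", phi = "rad",
                                  R_b = "mmHg.s/L", baseline = "mmHg")),
    pressure = list(P_transmural = 760, units = "mmHg"),
    limiter = list(phi = NULL, units = "J/m^3"),
    remodeling = list(elastin_b = 7.8e5, Ac0 = 100, Ae0 = 50,
                      k1 = 1e7, k2 = 1e3, n_exp = 1,
                      rho_c = 5.10, rho_e = 5.10,
                      units = list(elastin_b = "N/m^2", k = "1/s",
                                   rho = "kg/m^3")),
    simulation = list(ic = c(1, 0), tau_end = 50, dt = 1e-3,
                      stress = "taylor", record_every = 1),
    imaging = list(n_sectors = 36, threshold_fraction = 0.25, sigma = 1,
                   n_frames = 64, frame_interval = 2e-5, pixel_size = 1e-4,
                   n_px = 384, noise_sd = 0),
    seed = 1
  )
}

# recursive merge of user values over defaults
merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.data.frame(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]; omitted fields
#' keep their defaults.  The breathing components may be given inline
#' (lists of `A`, `f`, `phi`) or as a `components_csv` path.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated config list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user$breathing$components_csv)) {
      user$breathing$components <- utils::read.csv(user$breathing$components_csv)
      user$breathing$components_csv <- NULL
    }
    if (!is.null(user$breathing$components) &&
        !is.data.frame(user$breathing$components))
      user$breathing$components <- as.data.frame(
        do.call(cbind, user$breathing$components))
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  cfg
}

# field-level validation; stops with a report of every offending field
validate_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(cfg$material$c1 < 0, "material.c1 must be negative")
  chk(cfg$material$c2 > 0, "material.c2 must be positive")
  chk(cfg$material$c3 < 0, "material.c3 must be negative")
  chk(cfg$geometry$H > 0, "geometry.H must be positive")
  chk(cfg$geometry$R > 0, "geometry.R must be positive")
  chk(cfg$membrane$rho_m > 0, "membrane.rho_m must be positive")
  chk(cfg$membrane$mu_m >= 0, "membrane.mu_m must be non-negative")
  chk(cfg$fluid$rho_f > 0, "fluid.rho_f must be positive")
  chk(cfg$fluid$mu_f >= 0, "fluid.mu_f must be non-negative")
  chk(all(cfg$breathing$components$A >= 0), "breathing amplitudes must be >= 0")
  chk(all(cfg$breathing$components$f > 0), "breathing frequencies must be > 0")
  chk(cfg$breathing$R_b > 0, "breathing.R_b must be positive")
  chk(cfg$simulation$dt > 0, "simulation.dt must be positive")
  chk(cfg$simulation$tau_end > 0, "simulation.tau_end must be positive")
  chk(cfg$imaging$n_sectors >= 4, "imaging.n_sectors must be >= 4")
  chk(is.null(cfg$limiter$phi) || cfg$limiter$phi > 0,
      "limiter.phi must be positive when given")
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(cfg)
}

# pressure in stated units -> Pa
pressure_to_Pa <- function(value, units) {
  switch(units, mmHg = mmHg_to_Pa(value), Pa = value,
         stop("unknown pressure unit: ", units))
}

#' Build model objects from a configuration
#'
#' Converts a (validated) config list into the parameter-block objects the
#' computational functions take, applying unit conversions: pressures to
#' Pa and, when `membrane.units.rho_m` is `"kg/m^2"`, the surface density
#' to a volumetric one via the wall thickness.
#'
#' @param cfg A config list from [load_config()] or [default_config()].
#' @return A list with `mat`, `geom`, `mem`, `fluid`, `bm`,
#'   `P_transmural` (Pa) and the remaining raw blocks.
#' @export
config_blocks <- function(cfg = default_config()) {
  validate_config(cfg)
  geom <- lesion_geometry(cfg$geometry$H, cfg$geometry$R)
  rho_m <- cfg$membrane$rho_m
  if (identical(cfg$membrane$units$rho_m, "kg/m^2"))
    rho_m <- rho_m / geom$H
  p_inf <- pressure_to_Pa(cfg$fluid$p_inf, cfg$fluid$units$p_inf)
  list(
    mat = material_parameters(cfg$material$c1, cfg$material$c2,
                              cfg$material$c3),
    geom = geom,
    mem = membrane_properties(rho_m, cfg$membrane$mu_m),
    fluid = fluid_properties(cfg$fluid$rho_f, cfg$fluid$mu_f, p_inf),
    bm = breathing_model(cfg$breathing$components, cfg$breathing$R_b,
                         cfg$breathing$baseline),
    P_transmural = pressure_to_Pa(cfg$pressure$P_transmural,
                                  cfg$pressure$units),
    limiter = cfg$limiter, remodeling = cfg$remodeling,
    simulation = cfg$simulation, imaging = cfg$imaging, seed = cfg$seed
  )
}
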