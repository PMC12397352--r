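#' Default run configuration
#'
#' The standard parameter set for a healthy tracheal ASL strip: 100 cilia
#' (length 5 um, diameter 0.15 um, 15 Hz, antiplectic metachrony over a
#' 55 um wavelength), 7 um PCL + 10 um mucus depth, density 1000 kg/m3,
#' Newtonian viscosity 0.001 Pa s, five-mode Giesekus mucus rheology and a
#' 5 um Salbutamol sulfate particle.
#'
#' @return nested list of configuration defaults.
#' @export
default_config <- function() {
  list(
    grid = list(preset = "M3", nx = NULL, ny = NULL, nz = NULL,
                Lz_um = 17, z_interface_um = 7),
    cilia = list(count = 100, length_um = 5, diameter_um = 0.15,
                 spacing_um = NULL, frequency_hz = 15, wavelength_um = 55,
                 metachrony = "antiplectic"),
    fluid = list(density_kg_m3 = 1000, viscosity_Pa_s = 0.001),
    giesekus = list(
      lambda = c(0.0089, 0.0821, 0.466, 3.129, 49.733),
      eta_p = c(0.0298, 0.062, 0.2493, 1.4215, 2.2034),
      alpha = c(0.2, 0.3, 0.5, 0.5, 0.5)),
    drug = list(name = "SAL", diameter_um = 5),
    transport = list(kappa_att = 0, n_mass_iter = 4, dt = NULL,
                     deposition_area_um2 = NULL),
    output = list(dir = ".", snapshot_every = 0, format = "vtk")
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML key-value document, overlays it on [default_config()],
#' rejects unknown keys and validates ranges. An empty file yields the full
#' default (standard healthy-trachea) parameter set.
#'
#' @param path YAML file path, or `NULL`/missing file content for pure
#'   defaults.
#' @return validated configuration list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (length(user)) {
      errs <- character(0)
      for (blk in names(user)) {
        if (!blk %in% names(cfg)) {
          errs <- c(errs, sprintf("unknown block '%s'", blk))
          next
        }
        for (key in names(user[[blk]])) {
          if (!key %in% names(cfg[[blk]])) {
            errs <- c(errs, sprintf("unknown key '%s.%s'", blk, key))
          } else {
            cfg[[blk]][[key]] <- user[[blk]][[key]]
          }
        }
      }
      if (length(errs)) {
        stop("configuration errors:\n  - ", paste(errs, collapse = "\n  - "))
      }
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(all(ok))) errs <<- c(errs, msg)
  chk(cfg$grid$Lz_um > 0, "grid.Lz_um must be positive")
  chk(cfg$grid$z_interface_um > 0 &&
        cfg$grid$z_interface_um < cfg$grid$Lz_um,
      "grid.z_interface_um must lie inside (0, Lz_um)")
  chk(cfg$cilia$count >= 1, "cilia.count must be >= 1")
  chk(cfg$cilia$length_um > 0, "cilia.length_um must be positive")
  chk(cfg$cilia$diameter_um > 0, "cilia.diameter_um must be positive")
  chk(cfg$cilia$frequency_hz > 0, "cilia.frequency_hz must be positive")
  chk(cfg$cilia$wavelength_um > 0, "cilia.wavelength_um must be positive")
  chk(is.null(cfg$cilia$spacing_um) || cfg$cilia$spacing_um > 0,
      "cilia.spacing_um must be positive")
  chk(cfg$fluid$density_kg_m3 > 0, "fluid.density_kg_m3 must be positive")
  chk(cfg$fluid$viscosity_Pa_s > 0, "fluid.viscosity_Pa_s must be positive")
  chk(cfg$transport$kappa_att >= 0 && cfg$transport$kappa_att <= 1,
      "transport.kappa_att must be in [0, 1]")
  if (length(errs)) {
    stop("configuration errors:\n  - ", paste(errs, collapse = "\n  - "))
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Build simulation objects from a configuration
#'
#' @param cfg a [load_config()] result.
#' @return list with `grid`, `lattice`, `fluid`, `giesekus`, `drug`.
#' @export
config_objects <- function(cfg) {
  g <- cfg$grid
  grid <- if (!is.null(g$preset)) {
    grid_spec(preset = g$preset, Lz_um = g$Lz_um,
              z_interface_um = g$z_interface_um)
  } else {
    grid_spec(nx = g$nx, ny = g$ny, nz = g$nz, Lz_um = g$Lz_um,
              z_interface_um = g$z_interface_um)
  }
  ci <- cfg$cilia
  lattice <- build_lattice(
    n_cilia = ci$count, wavelength_um = ci$wavelength_um,
    spacing_um = ci$spacing_um, frequency_hz = ci$frequency_hz,
    length_um = ci$length_um, diameter_um = ci$diameter_um,
    metachrony = ci$metachrony)
  list(
    grid = grid,
    lattice = lattice,
    fluid = fluid_props(cfg$fluid$density_kg_m3, cfg$fluid$viscosity_Pa_s),
    giesekus = giesekus_params(cfg$giesekus$lambda, cfg$giesekus$eta_p,
                               cfg$giesekus$alpha),
    drug = drug_spec(cfg$drug$name)
  )
}

#' Round-trip a configuration through YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
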