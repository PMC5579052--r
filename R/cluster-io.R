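## Cluster-set I/O. A set lives in one directory: a YAML manifest
## (cluster_set.yaml) with the monomer definition and one entry per cluster,
## plus one frequencies file (one wavenumber per line) and optionally one
## standard XYZ geometry per cluster. All unit conversion happens here; the
## in-memory objects are always in canonical units (kJ/mol, cm^-1, GHz, A^3).

.energy_to_kJ <- function(value, unit) {
  switch(unit,
         "kJ/mol"   = value,
         "kj/mol"   = value,
         "hartree"  = value * .const$hartree_kJ,
         "kcal/mol" = value * .const$kcal_kJ,
         stop("unknown energy unit tag '", unit,
              "' (accepted: hartree, kJ/mol, kcal/mol)"))
}

#' Read a standard XYZ geometry file
#'
#' First line: atom count; second line: comment; then one
#' \code{element x y z} row per atom (Angstrom).
#'
#' @param path Path to the XYZ file.
#' @return Data frame with columns \code{element}, \code{x}, \code{y}, \code{z}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("not an XYZ file (fewer than 3 lines): ", path)
  nat <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(nat) || nat < 1L) stop("bad atom count on line 1 of ", path)
  if (length(lines) < nat + 2L) stop("XYZ file truncated: ", path)
  rows <- strsplit(trimws(lines[3:(nat + 2L)]), "\\s+")
  bad <- vapply(rows, length, integer(1)) < 4L
  if (any(bad)) stop("malformed XYZ atom line in ", path)
  data.frame(element = vapply(rows, `[`, character(1), 1L),
             x = as.numeric(vapply(rows, `[`, character(1), 2L)),
             y = as.numeric(vapply(rows, `[`, character(1), 3L)),
             z = as.numeric(vapply(rows, `[`, character(1), 4L)))
}

#' Write a standard XYZ geometry file
#'
#' @param geometry Data frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z}.
#' @param path Output path.
#' @param comment Comment line.
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(geometry, path, comment = "") {
  lines <- c(nrow(geometry), comment,
             sprintf("%-2s %18.10f %18.10f %18.10f",
                     geometry$element, geometry$x, geometry$y, geometry$z))
  writeLines(lines, path)
  invisible(path)
}

#' Load a cluster set from its on-disk directory format
#'
#' Reads the \code{cluster_set.yaml} manifest in \code{path} (or \code{path}
#' itself if it names a YAML file), the per-cluster frequency files (one
#' wavenumber per line) and any XYZ geometries, converts energies to kJ/mol
#' (accepted unit tags: \code{hartree}, \code{kJ/mol}, \code{kcal/mol};
#' 1 hartree = 2625.4996 kJ/mol) and validates the result. A cluster entry
#' may omit \code{volume} if it has a geometry, in which case the volume is
#' computed from the union of Bondi spheres via [cluster_volume()].
#'
#' @param path Directory containing \code{cluster_set.yaml}, or the manifest
#'   file itself.
#' @return A validated \code{"qce_cluster_set"}.
#' @seealso [write_cluster_set()] for the inverse, [synthetic_cluster_set()]
#'   to generate sets in code.
#' @examples
#' d <- system.file("extdata", "toy_water_set", package = "qcewater")
#' load_cluster_set(d)
#' @export
load_cluster_set <- function(path) {
  if (dir.exists(path)) {
    manifest <- file.path(path, "cluster_set.yaml")
    base <- path
  } else {
    manifest <- path
    base <- dirname(path)
  }
  if (!file.exists(manifest)) stop("no cluster-set manifest at ", manifest)
  m <- yaml::read_yaml(manifest)
  if (is.null(m$monomer)) stop("manifest is missing the monomer entry")
  mono <- monomer(m$monomer$label, m$monomer$mass,
                  if (!is.null(m$monomer$molar_mass)) m$monomer$molar_mass
                  else m$monomer$mass)
  if (!length(m$clusters)) stop("manifest lists no clusters")
  clusters <- lapply(m$clusters, function(e) {
    unit <- if (!is.null(e$energy_unit)) e$energy_unit else "kJ/mol"
    freq <- as.numeric(readLines(file.path(base, e$frequencies_file), warn = FALSE))
    if (anyNA(freq)) stop(e$label, ": non-numeric line in frequencies file")
    if (any(freq <= 0))
      stop(e$label, ": imaginary mode (frequency ", min(freq),
           " cm^-1); supply minima, not transition states")
    geom <- NULL
    if (!is.null(e$geometry_file))
      geom <- read_xyz(file.path(base, e$geometry_file))
    vol <- if (!is.null(e$volume)) e$volume
           else if (!is.null(geom)) cluster_volume(geom)
           else stop(e$label, ": needs either a volume or a geometry_file")
    cluster(label = e$label, n_monomers = e$n_monomers,
            n_hydronium = if (!is.null(e$n_hydronium)) e$n_hydronium else 0L,
            n_hydroxide = if (!is.null(e$n_hydroxide)) e$n_hydroxide else 0L,
            interaction_energy = .energy_to_kJ(e$energy, unit),
            frequencies = freq,
            rotational_constants = as.numeric(e$rotational_constants),
            symmetry_number = if (!is.null(e$sigma)) e$sigma else 1L,
            volume = vol, geometry = geom)
  })
  cluster_set(mono, clusters,
              name = if (!is.null(m$name)) m$name else basename(base))
}

#' Write a cluster set to the on-disk directory format
#'
#' Writes \code{cluster_set.yaml} plus one \code{<label>.freq} file per
#' cluster and \code{<label>.xyz} where a geometry is present. Numbers are
#' written with 17 significant digits so that
#' \code{load_cluster_set(write_cluster_set(cs, d))} round-trips every field
#' to full double precision.
#'
#' @param cs A \code{"qce_cluster_set"}.
#' @param path Output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_cluster_set <- function(cs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  num <- function(x) as.numeric(formatC(x, digits = 17, format = "g"))
  entries <- lapply(cs$clusters, function(cl) {
    ffile <- paste0(cl$label, ".freq")
    writeLines(formatC(cl$frequencies, digits = 17, format = "g"),
               file.path(path, ffile))
    e <- list(label = cl$label, n_monomers = cl$n_monomers,
              n_hydronium = cl$n_hydronium, n_hydroxide = cl$n_hydroxide,
              energy = num(cl$interaction_energy), energy_unit = "kJ/mol",
              volume = num(cl$volume), sigma = cl$symmetry_number,
              rotational_constants = num(cl$rotational_constants),
              frequencies_file = ffile)
    if (!is.null(cl$geometry)) {
      gfile <- paste0(cl$label, ".xyz")
      write_xyz(cl$geometry, file.path(path, gfile), comment = cl$label)
      e$geometry_file <- gfile
    }
    e
  })
  m <- list(name = cs$name,
            monomer = list(label = cs$monomer$label,
                           mass = num(cs$monomer$mass),
                           molar_mass = num(cs$monomer$molar_mass)),
            clusters = entries)
  yaml::write_yaml(m, file.path(path, "cluster_set.yaml"), precision = 17L)
  invisible(path)
}
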