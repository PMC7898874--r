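# Molecular geometries and quantum-chemistry property sidecars: the on-disk
# contracts every other module consumes.

#' Construct a molecular geometry
#'
#' A geometry is an ordered list of atoms: element symbols plus Cartesian
#' coordinates in Angstrom. Atom order is significant and is never permuted
#' by any operation in the package.
#'
#' @param elements Character vector of element symbols (normalized on input).
#' @param coords Numeric n x 3 matrix of Cartesian coordinates, Angstrom.
#' @param label Text identifier for the complex.
#' @return An object of class `mol_geometry` with fields `label`, `elements`,
#'   `coords`.
#' @export
molecular_geometry <- function(elements, coords, label = "") {
  coords <- as.matrix(coords)
  if (length(elements) < 1L) stop("a geometry needs at least 1 atom")
  if (!is.numeric(coords) || ncol(coords) != 3L) {
    stop("coords must be an n x 3 numeric matrix")
  }
  if (nrow(coords) != length(elements)) {
    stop("elements and coords disagree on atom count")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  elements <- normalize_element(elements)
  n <- nrow(coords)
  if (n > 1L) {
    dmin <- min(stats::dist(coords))
    if (dmin < 0.1) {
      stop(sprintf("two atoms within 0.1 A of each other (min distance %.4f A)",
                   dmin))
    }
  }
  dimnames(coords) <- NULL
  structure(list(label = as.character(label)[1L],
                 elements = elements,
                 coords = coords),
            class = "mol_geometry")
}

#' Number of atoms in a geometry
#' @param geom A `mol_geometry`.
#' @return Integer atom count.
#' @export
n_atoms <- function(geom) {
  stopifnot(inherits(geom, "mol_geometry"))
  length(geom$elements)
}

#' @export
print.mol_geometry <- function(x, ...) {
  cat(sprintf("<mol_geometry> '%s': %d atoms (%s)\n",
              x$label, n_atoms(x),
              paste(names(sort(-table(x$elements))), collapse = ", ")))
  invisible(x)
}

#' Read an XYZ file
#'
#' Standard XYZ format: line 1 is the atom count, line 2 a comment/label,
#' then one "symbol x y z" record per atom. Coordinates are taken as
#' Angstrom; atom order is preserved.
#'
#' @param path Path to an XYZ file.
#' @return A [molecular_geometry()].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("XYZ format error: empty file: ", path)
  count <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(count) || count < 1L) {
    stop("XYZ format error: line 1 must be a positive integer atom count")
  }
  if (length(lines) < 2L + count) {
    stop(sprintf("XYZ format error: declared %d atoms but file has %d record lines",
                 count, max(0L, length(lines) - 2L)))
  }
  label <- if (length(lines) >= 2L) trimws(lines[2L]) else ""
  body <- lines[seq.int(3L, 2L + count)]
  # any extra non-blank trailing lines mean the declared count is wrong
  if (length(lines) > 2L + count &&
      any(nzchar(trimws(lines[seq.int(3L + count, length(lines))])))) {
    stop("XYZ format error: more atom records than the declared count")
  }
  elements <- character(count)
  coords <- matrix(NA_real_, count, 3L)
  for (i in seq_len(count)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(tok) < 4L) {
      stop(sprintf("XYZ format error at line %d: expected 'symbol x y z'", i + 2L))
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) {
      stop(sprintf("XYZ format error at line %d: unparseable coordinate", i + 2L))
    }
    elements[i] <- tok[1L]
    coords[i, ] <- xyz
  }
  molecular_geometry(elements, coords, label = label)
}

#' Write an XYZ file
#'
#' @param geom A [molecular_geometry()].
#' @param path Output path.
#' @param digits Decimal places for coordinates (at least 6).
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(geom, path, digits = 8L) {
  stopifnot(inherits(geom, "mol_geometry"))
  digits <- max(6L, as.integer(digits))
  fmt <- sprintf("%%-3s %%%d.%df %%%d.%df %%%d.%df",
                 digits + 6L, digits, digits + 6L, digits, digits + 6L, digits)
  rec <- sprintf(fmt, geom$elements,
                 geom$coords[, 1L], geom$coords[, 2L], geom$coords[, 3L])
  out <- c(as.character(n_atoms(geom)), geom$label, rec)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open path for writing: ", path)
  })
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Construct a quantum-chemistry property record
#'
#' Electronic quantities computed externally for one complex: total electronic
#' energy and frontier-orbital energies in hartree (a.u.), and optional
#' per-atom partial charges in units of e. The charge-partition scheme is not
#' prescribed; record it in `provenance`.
#'
#' @param label Text identifier (should match the geometry label).
#' @param total_energy Total electronic energy, a.u.
#' @param homo,lumo Frontier orbital energies, a.u.; `lumo >= homo`.
#' @param charges Optional numeric vector of per-atom partial charges (e),
#'   same length and order as the geometry's atoms.
#' @param provenance Free-text description of the level of theory / charge
#'   scheme.
#' @return An object of class `qc_properties`.
#' @export
qc_properties <- function(label = "", total_energy = NULL, homo = NULL,
                          lumo = NULL, charges = NULL, provenance = NULL) {
  num1 <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) != 1L || !is.finite(x)) stop(what, " must be a finite scalar")
    x
  }
  total_energy <- num1(total_energy, "total_energy")
  homo <- num1(homo, "homo")
  lumo <- num1(lumo, "lumo")
  if (!is.null(homo) && !is.null(lumo) && lumo < homo) {
    stop("validation error: lumo < homo")
  }
  if (!is.null(charges)) {
    charges <- as.numeric(charges)
    if (!all(is.finite(charges))) stop("charges must be finite")
  }
  structure(list(label = as.character(label)[1L],
                 total_energy = total_energy,
                 homo = homo, lumo = lumo,
                 charges = charges,
                 provenance = provenance),
            class = "qc_properties")
}

#' Read a property sidecar record
#'
#' One YAML or JSON document per complex with keys `label`, `total_energy`,
#' `homo`, `lumo`, `charges` (all optional except at point of use); missing
#' keys yield absent fields, never zeros. If `geom` is supplied the charges
#' length is validated against the atom count.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` sidecar.
#' @param geom Optional [molecular_geometry()] to validate charges against.
#' @return A [qc_properties()].
#' @export
read_properties <- function(path, geom = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(doc)) stop("property sidecar must be a key-value document")
  props <- qc_properties(label = if (is.null(doc$label)) "" else doc$label,
                         total_energy = doc$total_energy,
                         homo = doc$homo, lumo = doc$lumo,
                         charges = doc$charges,
                         provenance = doc$provenance)
  if (!is.null(geom)) validate_charges(props, geom)
  props
}

#' Write a property sidecar record
#'
#' @param props A [qc_properties()].
#' @param path Output path (`.yaml` or `.json` by extension).
#' @return Invisibly, `path`.
#' @export
write_properties <- function(props, path) {
  stopifnot(inherits(props, "qc_properties"))
  doc <- Filter(Negate(is.null), unclass(props))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path, precision = 12L)
  }
  invisible(path)
}

#' Validate charges against a geometry
#'
#' @param props A [qc_properties()] whose charges must be present.
#' @param geom The matching [molecular_geometry()].
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
validate_charges <- function(props, geom) {
  stopifnot(inherits(props, "qc_properties"), inherits(geom, "mol_geometry"))
  if (is.null(props$charges)) stop("precondition error: charges absent")
  if (length(props$charges) != n_atoms(geom)) {
    stop(sprintf("validation error: %d charges for %d atoms",
                 length(props$charges), n_atoms(geom)))
  }
  invisible(TRUE)
}
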