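# The catalyst descriptors: geometric measures on the paddlewheel scaffold,
# frontier-orbital and charge quantities, the distance-weighted steric
# volume, the eight-helium axial probe, and the carbene coordination energy.

.vnorm <- function(v) sqrt(sum(v^2))

# angle at vertex b between rays b->a and b->c, degrees
.angle_deg <- function(a, b, c) {
  u <- a - b; w <- c - b
  nu <- .vnorm(u); nw <- .vnorm(w)
  if (nu < 1e-12 || nw < 1e-12) stop("numeric error: degenerate (zero-length) vector in angle")
  cosang <- sum(u * w) / (nu * nw)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Rh-Rh bond length
#'
#' @param geom A [molecular_geometry()].
#' @param topo Its [detect_paddlewheel()] topology.
#' @return Euclidean distance between the two Rh atoms, Angstrom.
#' @export
rh_rh_distance <- function(geom, topo) {
  stopifnot(inherits(geom, "mol_geometry"),
            inherits(topo, "paddlewheel_topology"))
  .vnorm(geom$coords[topo$rh_indices[1L], ] - geom$coords[topo$rh_indices[2L], ])
}

#' Mean Rh-Rh-donor angle
#'
#' Arithmetic mean over all 8 donor attachments (both Rh centres) of the
#' angle at the donor-bound Rh between the other Rh and the donor atom.
#'
#' @inheritParams rh_rh_distance
#' @return Mean angle in degrees, in [0, 180].
#' @export
mean_rh_rh_donor_angle <- function(geom, topo) {
  stopifnot(inherits(geom, "mol_geometry"),
            inherits(topo, "paddlewheel_topology"))
  rh <- topo$rh_indices
  angles <- unlist(lapply(topo$donors, function(d) {
    vapply(seq_len(nrow(d)), function(i) {
      bound <- d$rh[i]
      other <- if (bound == rh[1L]) rh[2L] else rh[1L]
      .angle_deg(geom$coords[other, ], geom$coords[bound, ],
                 geom$coords[d$atom[i], ])
    }, numeric(1L))
  }))
  if (length(angles) != 8L) {
    stop(sprintf("topology error: expected 8 donor attachments, found %d",
                 length(angles)))
  }
  mean(angles)
}

#' Mean ligand bite angle
#'
#' For each bridging ligand, the angle donor--bridgehead--donor, where the
#' bridgehead is the unique ligand atom bonded to both donor atoms (the
#' carboxylate/amidate carbon). Returns the mean over the 4 ligands, degrees.
#'
#' @inheritParams rh_rh_distance
#' @return Mean bite angle in degrees.
#' @export
mean_bite_angle <- function(geom, topo) {
  stopifnot(inherits(geom, "mol_geometry"),
            inherits(topo, "paddlewheel_topology"))
  adj <- topo$graph$adj
  angles <- vapply(seq_along(topo$ligands), function(li) {
    don <- topo$donors[[li]]$atom
    bridge <- intersect(adj[[don[1L]]], adj[[don[2L]]])
    bridge <- intersect(bridge, topo$ligands[[li]])
    if (length(bridge) != 1L) {
      stop(sprintf("topology error: ligand %d has no unique bridge atom bonded to both donors",
                   li))
    }
    .angle_deg(geom$coords[don[1L], ], geom$coords[bridge, ],
               geom$coords[don[2L], ])
  }, numeric(1L))
  mean(angles)
}

#' Carbene C-C-C angle
#'
#' Angle at the Rh-bound carbene carbon between its two carbonyl-carbon
#' neighbours, degrees.
#'
#' @inheritParams rh_rh_distance
#' @return Angle in degrees.
#' @export
carbene_angle <- function(geom, topo) {
  stopifnot(inherits(geom, "mol_geometry"),
            inherits(topo, "paddlewheel_topology"))
  cb <- topo$carbene
  if (is.null(cb)) stop("precondition error: topology has no carbene")
  if (length(cb$c_neighbors) != 2L) {
    stop(sprintf("topology error: carbene carbon has %d carbon neighbours (need 2)",
                 length(cb$c_neighbors)))
  }
  .angle_deg(geom$coords[cb$c_neighbors[1L], ],
             geom$coords[cb$c_carbene, ],
             geom$coords[cb$c_neighbors[2L], ])
}

#' Distance-weighted steric volume
#'
#' Sums van der Waals-radius-weighted contributions of atoms by proximity to
#' a focus atom: sum over atoms i of r_i^k / d_i^l, with r_i the vdW radius
#' and d_i the distance from atom i to the focus. The focus atom itself and
#' any atom listed in `exclude` (typically the two Rh centres) are omitted.
#'
#' @param geom A [molecular_geometry()].
#' @param focus Index of the focus atom.
#' @param k,l Exponents (defaults 3 and 3).
#' @param exclude Integer vector of atom indices to omit from the sum.
#' @return Dimensionless steric volume.
#' @export
distance_weighted_volume <- function(geom, focus, k = 3, l = 3,
                                     exclude = integer()) {
  stopifnot(inherits(geom, "mol_geometry"))
  n <- n_atoms(geom)
  if (!(focus %in% seq_len(n))) stop("focus atom index out of range")
  idx <- setdiff(seq_len(n), c(focus, exclude))
  if (length(idx) == 0L) return(0)
  r <- vdw_radius(geom$elements[idx])  # errors on missing radius
  d <- sqrt(rowSums((geom$coords[idx, , drop = FALSE] -
                       rep(geom$coords[focus, ], each = length(idx)))^2))
  if (any(d < 1e-12)) stop("numeric error: atom coincides with the focus (d = 0)")
  sum(r^k / d^l)
}

#' Build the eight-helium axial steric probe
#'
#' Places a ring of 8 He atoms on the axial face of the stripped complex:
#' the ring centre lies `distance` Angstrom from the carbene-binding Rh
#' along the Rh-Rh axis (pointing away from the other Rh), and the 8 atoms
#' are equally spaced on a circle of the given radius in the perpendicular
#' plane. The ring phase is fixed deterministically: the first He is placed
#' along the in-plane projection of the donor atom nearest the
#' carbene-binding Rh (ties broken by lower atom index), the rest at 45
#' degree steps.
#'
#' @param topo A `paddlewheel_topology` that identifies the carbene-binding
#'   Rh (from the pre-strip perception; [strip_carbene()] preserves it).
#' @param geom The stripped [molecular_geometry()] the topology indexes.
#' @param distance Ring-centre distance from the carbene-binding Rh, Angstrom
#'   (default 1.9).
#' @param radius Ring radius, Angstrom (default 2.5).
#' @return An object of class `he8_probe`: `positions` (8 x 3 matrix),
#'   `center`, `axis`, `distance`, `radius`.
#' @export
build_he8_probe <- function(topo, geom, distance = 1.9, radius = 2.5) {
  stopifnot(inherits(geom, "mol_geometry"),
            inherits(topo, "paddlewheel_topology"))
  if (!is.null(topo$carbene)) {
    stop("precondition error: strip the carbene before building the probe")
  }
  if (distance <= 0 || radius <= 0) stop("distance and radius must be positive")
  rh_a <- topo$rh_indices["rh_a"]
  rh_b <- topo$rh_indices["rh_b"]
  if (is.na(rh_a)) stop("precondition error: no carbene-binding Rh identifiable")
  # recompute the axis from the coordinates at hand, so the probe follows
  # the geometry even if the topology was perceived on an untransformed copy
  v <- geom$coords[rh_a, ] - geom$coords[rh_b, ]
  axis <- v / .vnorm(v)
  center <- geom$coords[rh_a, ] + distance * axis

  # phase: in-plane projection of the donor nearest Rh_a
  donors <- do.call(rbind, topo$donors)
  d_a <- sqrt(rowSums((geom$coords[donors$atom, , drop = FALSE] -
                         rep(geom$coords[rh_a, ], each = nrow(donors)))^2))
  # round before ordering so symmetry-equivalent donors tie exactly and the
  # atom-index tie-break is stable under rigid motion
  ord <- order(round(d_a, 6L), donors$atom)
  u1 <- NULL
  for (i in ord) {
    v <- geom$coords[donors$atom[i], ] - geom$coords[rh_a, ]
    vp <- v - sum(v * axis) * axis
    if (.vnorm(vp) > 1e-8) { u1 <- vp / .vnorm(vp); break }
  }
  if (is.null(u1)) {
    # all donors axial (degenerate): any perpendicular direction
    ref <- if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    vp <- ref - sum(ref * axis) * axis
    u1 <- vp / .vnorm(vp)
  }
  u2 <- c(axis[2L] * u1[3L] - axis[3L] * u1[2L],
          axis[3L] * u1[1L] - axis[1L] * u1[3L],
          axis[1L] * u1[2L] - axis[2L] * u1[1L])
  phi <- (0:7) * pi / 4
  pos <- t(vapply(phi, function(p) {
    center + radius * (cos(p) * u1 + sin(p) * u2)
  }, numeric(3L)))
  structure(list(positions = pos, center = center, axis = axis,
                 distance = distance, radius = radius),
            class = "he8_probe")
}

#' Probe + stripped complex as one geometry
#'
#' Concatenates the stripped complex and the 8 He probe atoms into a single
#' geometry, for emission as an XYZ/QM input for external single-point
#' evaluation.
#'
#' @param probe A [build_he8_probe()] result.
#' @param geom The stripped [molecular_geometry()].
#' @return A [molecular_geometry()] with the He atoms appended.
#' @export
he8_composite_geometry <- function(probe, geom) {
  stopifnot(inherits(probe, "he8_probe"), inherits(geom, "mol_geometry"))
  molecular_geometry(c(geom$elements, rep("He", 8L)),
                     rbind(geom$coords, probe$positions),
                     label = paste0(geom$label, " + He8 probe"))
}

#' He8 interaction energy
#'
#' Counterpoise-free interaction energy of the stripped complex with the
#' eight-helium ring, from three externally computed single-point energies:
#' E(He8.complex) - E(He8) - E(complex), converted from hartree to kcal/mol.
#'
#' @param e_complex_he8 Energy of the composite (complex + He8 ring), a.u.
#' @param e_he8 Energy of the isolated He8 ring, a.u.
#' @param e_complex Energy of the isolated stripped complex, a.u.
#' @return Interaction energy in kcal/mol.
#' @export
he8_interaction_energy <- function(e_complex_he8, e_he8, e_complex) {
  for (x in list(e_complex_he8, e_he8, e_complex)) {
    if (is.null(x) || length(x) != 1L || !is.finite(x)) {
      stop("precondition error: all three energies must be supplied")
    }
  }
  (e_complex_he8 - e_he8 - e_complex) * hartree_to_kcal()
}

#' Carbene coordination energy
#'
#' Electronic energy change for the diazo precursor binding to the unbound
#' complex as a carbene with loss of N2:
#' (E(complex 1) + E(diazo)) - (E(complex 2) + E(N2)), in kcal/mol.
#' No zero-point correction is applied.
#'
#' @param e1 Energy of the unbound complex, a.u.
#' @param e_diazo Energy of the free diazo precursor, a.u.
#' @param e2 Energy of the carbene complex, a.u.
#' @param e_n2 Energy of free N2, a.u.
#' @return Coordination energy in kcal/mol.
#' @export
coordination_energy <- function(e1, e_diazo, e2, e_n2) {
  for (x in list(e1, e_diazo, e2, e_n2)) {
    if (is.null(x) || length(x) != 1L || !is.finite(x)) {
      stop("precondition error: all four energies must be supplied")
    }
  }
  ((e1 + e_diazo) - (e2 + e_n2)) * hartree_to_kcal()
}

#' Frontier-orbital gap
#'
#' @param homo,lumo Orbital energies in a.u.; `lumo >= homo`.
#' @return `lumo - homo`, a.u.
#' @export
fmo_gap <- function(homo, lumo) {
  if (is.null(homo) || is.null(lumo)) stop("precondition error: homo/lumo missing")
  if (lumo < homo) stop("validation error: lumo < homo")
  lumo - homo
}

#' Mean charge on the rhodium atoms
#'
#' Arithmetic mean of the two Rh partial charges, so the value is comparable
#' to a single-centre charge.
#'
#' @param props A [qc_properties()] with charges present.
#' @param topo The matching `paddlewheel_topology`.
#' @return Mean Rh charge, e.
#' @export
rh_charge <- function(props, topo) {
  stopifnot(inherits(props, "qc_properties"),
            inherits(topo, "paddlewheel_topology"))
  if (is.null(props$charges)) stop("precondition error: charges absent")
  n_need <- max(topo$rh_indices, unlist(topo$ligands))
  if (length(props$charges) < n_need) {
    stop("validation error: charges list shorter than the atom count")
  }
  mean(props$charges[topo$rh_indices])
}

#' Mean ligand charge
#'
#' Mean over the 4 bridging ligands of the sum of per-atom charges within
#' each ligand.
#'
#' @inheritParams rh_charge
#' @return Mean ligand charge, e.
#' @export
mean_ligand_charge <- function(props, topo) {
  stopifnot(inherits(props, "qc_properties"),
            inherits(topo, "paddlewheel_topology"))
  if (is.null(props$charges)) stop("precondition error: charges absent")
  n_need <- max(topo$rh_indices, unlist(topo$ligands))
  if (length(props$charges) < n_need) {
    stop("validation error: charges list shorter than the atom count")
  }
  mean(vapply(topo$ligands, function(a) sum(props$charges[a]), numeric(1L)))
}

#' Canonical descriptor names
#'
#' The 14 descriptors in canonical column order: metal-metal distance and
#' mean Rh-Rh-donor angle for the unbound (1) and carbene (2) complexes,
#' bite angle (1), carbene angle (2), frontier-orbital energies and gap (1),
#' Rh and ligand charges (1), the distance-weighted volume, the He8 probe
#' interaction energy, and the carbene coordination energy.
#'
#' @return Character vector of length 14.
#' @export
descriptor_names <- function() {
  c("r_rhrh_1", "r_rhrh_2", "ang_rhrhl_1", "ang_rhrhl_2",
    "bite_angle_1", "carbene_angle_2",
    "homo_1", "lumo_1", "de_fmo_1", "q_rh_1", "q_ligand_mean_1",
    "wv", "he8", "de_coord")
}

#' Compute the full descriptor record for one catalyst
#'
#' Assembles all 14 descriptors from the unbound complex (geometry 1 +
#' properties 1), the carbene complex (geometry 2 + properties 2), and the
#' auxiliary single-point energies. The steric descriptors (distance-weighted
#' volume and He8 probe) are computed on the carbene-complex geometry with
#' the carbene removed; the volume's focus atom is the carbene-binding Rh
#' and the two Rh centres are excluded from the sum.
#'
#' @param catalyst_id Text identifier.
#' @param geom1 Unbound-complex geometry (no carbene).
#' @param props1 Its [qc_properties()] (total energy, HOMO/LUMO, charges).
#' @param geom2 Carbene-complex geometry.
#' @param props2 Its [qc_properties()] (total energy).
#' @param aux Named list of auxiliary energies, a.u.: `e_he8_complex`
#'   (composite single point), `e_he8_ring`, `e_stripped` (stripped complex),
#'   `e_diazo`, `e_n2`.
#' @param wv_k,wv_l Exponents of the distance-weighted volume.
#' @param he8_distance,he8_radius Probe placement parameters, Angstrom.
#' @param bond_scale Bond-perception scale factor.
#' @return An object of class `descriptor_record`: `catalyst_id`, `values`
#'   (named numeric of length 14), `metadata` (the parameter choices).
#' @export
compute_descriptor_record <- function(catalyst_id, geom1, props1, geom2, props2,
                                      aux, wv_k = 3, wv_l = 3,
                                      he8_distance = 1.9, he8_radius = 2.5,
                                      bond_scale = 1.2) {
  with_name <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("descriptor '%s' failed for catalyst '%s': %s",
                   name, catalyst_id, conditionMessage(e)), call. = FALSE)
    })
  }
  topo1 <- with_name("topology(1)", detect_paddlewheel(geom1, scale = bond_scale))
  if (!is.null(topo1$carbene)) {
    stop(sprintf("catalyst '%s': geometry 1 must not contain a carbene", catalyst_id))
  }
  topo2 <- with_name("topology(2)", detect_paddlewheel(geom2, scale = bond_scale))
  if (is.null(topo2$carbene)) {
    stop(sprintf("catalyst '%s': geometry 2 must contain a carbene", catalyst_id))
  }
  stripped <- with_name("strip_carbene", strip_carbene(geom2, topo2))
  gs <- stripped$geometry; ts <- stripped$topology

  vals <- c(
    r_rhrh_1 = with_name("r_rhrh_1", rh_rh_distance(geom1, topo1)),
    r_rhrh_2 = with_name("r_rhrh_2", rh_rh_distance(geom2, topo2)),
    ang_rhrhl_1 = with_name("ang_rhrhl_1", mean_rh_rh_donor_angle(geom1, topo1)),
    ang_rhrhl_2 = with_name("ang_rhrhl_2", mean_rh_rh_donor_angle(geom2, topo2)),
    bite_angle_1 = with_name("bite_angle_1", mean_bite_angle(geom1, topo1)),
    carbene_angle_2 = with_name("carbene_angle_2", carbene_angle(geom2, topo2)),
    homo_1 = with_name("homo_1", {
      if (is.null(props1$homo)) stop("homo absent from properties")
      props1$homo
    }),
    lumo_1 = with_name("lumo_1", {
      if (is.null(props1$lumo)) stop("lumo absent from properties")
      props1$lumo
    }),
    de_fmo_1 = with_name("de_fmo_1", fmo_gap(props1$homo, props1$lumo)),
    q_rh_1 = with_name("q_rh_1", rh_charge(props1, topo1)),
    q_ligand_mean_1 = with_name("q_ligand_mean_1", mean_ligand_charge(props1, topo1)),
    wv = with_name("wv", distance_weighted_volume(
      gs, focus = ts$rh_indices["rh_a"], k = wv_k, l = wv_l,
      exclude = ts$rh_indices)),
    he8 = with_name("he8", he8_interaction_energy(
      aux$e_he8_complex, aux$e_he8_ring, aux$e_stripped)),
    de_coord = with_name("de_coord", coordination_energy(
      props1$total_energy, aux$e_diazo, props2$total_energy, aux$e_n2))
  )
  structure(list(catalyst_id = as.character(catalyst_id),
                 values = vals,
                 metadata = list(wv_k = wv_k, wv_l = wv_l,
                                 he8_distance = he8_distance,
                                 he8_radius = he8_radius,
                                 bond_scale = bond_scale)),
            class = "descriptor_record")
}

#' @export
print.descriptor_record <- function(x, ...) {
  cat(sprintf("<descriptor_record> %s\n", x$catalyst_id))
  print(round(x$values, 6))
  invisible(x)
}

#' Emit a generic QM single-point input deck
#'
#' Writes a template-driven text input for an external quantum-chemistry
#' single point on a geometry (used for the He8 composite, the isolated
#' ring, and the stripped complex). The template may reference `{label}`,
#' `{natoms}` and `{coords}`.
#'
#' @param geom A [molecular_geometry()].
#' @param path Output path.
#' @param template Character vector of template lines.
#' @return Invisibly, `path`.
#' @export
write_qm_deck <- function(geom, path,
                          template = c("! single point", "# {label}",
                                       "natoms {natoms}", "geometry",
                                       "{coords}", "end")) {
  stopifnot(inherits(geom, "mol_geometry"))
  coords <- sprintf("%-3s %14.8f %14.8f %14.8f", geom$elements,
                    geom$coords[, 1L], geom$coords[, 2L], geom$coords[, 3L])
  out <- unlist(lapply(template, function(line) {
    if (grepl("{coords}", line, fixed = TRUE)) return(coords)
    line <- gsub("{label}", geom$label, line, fixed = TRUE)
    gsub("{natoms}", n_atoms(geom), line, fixed = TRUE)
  }))
  writeLines(out, path)
  invisible(path)
}
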