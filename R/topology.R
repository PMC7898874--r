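# Perception of the Rh2L4 paddlewheel motif: metal axis, four bridging
# bidentate ligands with their donor atoms, and the axial carbene fragment.

#' Perceive bonds from interatomic distances
#'
#' An edge is present iff the distance between two atoms is at most
#' `scale` times the sum of their covalent radii. This is the standard
#' heuristic; no bond orders are assigned.
#'
#' @param geom A [molecular_geometry()].
#' @param scale Dimensionless factor in (0.8, 1.6); default 1.2.
#' @return An object of class `bond_graph`: `n` (atom count), `edges`
#'   (two-column matrix of atom index pairs, i < j), `adj` (neighbor list).
#' @export
perceive_bonds <- function(geom, scale = 1.2) {
  stopifnot(inherits(geom, "mol_geometry"))
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0.8 || scale >= 1.6) {
    stop("scale must lie in (0.8, 1.6)")
  }
  n <- n_atoms(geom)
  radii <- covalent_radius(geom$elements)  # errors on unknown element
  d <- as.matrix(stats::dist(geom$coords))
  thr <- outer(radii, radii, "+") * scale
  bonded <- d <= thr & upper.tri(d)
  idx <- which(bonded, arr.ind = TRUE)
  edges <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("i", "j"))
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  structure(list(n = n, edges = edges, adj = adj), class = "bond_graph")
}

# connected components of a neighbor list restricted to `keep` (logical)
.components <- function(adj, keep) {
  n <- length(adj)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!keep[s] || comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (keep[w] && comp[w] == 0L) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' Detect the Rh2L4 paddlewheel topology
#'
#' Ligands are the connected components of the bond graph after removing both
#' Rh atoms; the four components bridging both Rh centres are the bridging
#' ligands, and a component bound through carbon to exactly one Rh is the
#' axial carbene. Donor atoms are the ligand atoms bonded to a Rh; an atom
#' within bonding distance of both Rh is assigned to the nearer one (ties
#' broken by lower Rh index). The Rh-Rh edge is asserted regardless of the
#' distance threshold. The reported axis points from the carbene-free Rh
#' toward the carbene-binding Rh (or from the lower- to the higher-index Rh
#' when no carbene is present).
#'
#' Tethered bis-carboxylates that bridge as a single connected component
#' (two donor pairs in one ligand, as in Rh2esp2) are not split
#' automatically: the "expected 4 bridging components" error invites a manual
#' topology override via [read_topology()].
#'
#' @param geom A [molecular_geometry()] containing exactly 2 Rh atoms.
#' @param scale Bond-perception scale factor, forwarded to [perceive_bonds()].
#' @return An object of class `paddlewheel_topology` with fields:
#'   `rh_indices` (c(rh_a, rh_b); `rh_a` binds the carbene), `axis`
#'   (unit vector from Rh_b to Rh_a), `ligands` (list of 4 integer vectors),
#'   `donors` (per ligand, data.frame `atom`, `rh`), `carbene` (NULL, or list
#'   `atoms`, `c_carbene`, `c_neighbors`), `graph` (the bond graph).
#' @export
detect_paddlewheel <- function(geom, scale = 1.2) {
  stopifnot(inherits(geom, "mol_geometry"))
  rh <- which(geom$elements == "Rh")
  if (length(rh) != 2L) {
    stop(sprintf("topology error: expected exactly 2 Rh atoms, found %d",
                 length(rh)))
  }
  g <- perceive_bonds(geom, scale = scale)
  # assert the Rh-Rh edge: the paddlewheel scaffold guarantees it
  if (!(rh[2L] %in% g$adj[[rh[1L]]])) {
    g$adj[[rh[1L]]] <- sort(c(g$adj[[rh[1L]]], rh[2L]))
    g$adj[[rh[2L]]] <- sort(c(g$adj[[rh[2L]]], rh[1L]))
    g$edges <- rbind(g$edges, sort(rh))
  }
  keep <- rep(TRUE, g$n)
  keep[rh] <- FALSE
  comp <- .components(g$adj, keep)
  ncomp <- max(comp, 0L)
  if (ncomp == 0L) stop("topology error: no ligand atoms found")

  coords <- geom$coords
  d_rh <- cbind(sqrt(rowSums((coords - rep(coords[rh[1L], ], each = g$n))^2)),
                sqrt(rowSums((coords - rep(coords[rh[2L], ], each = g$n))^2)))

  bridging <- list(); bridging_donors <- list()
  axial <- list()
  for (cid in seq_len(ncomp)) {
    atoms <- which(comp == cid)
    # atoms of this component bonded to each Rh
    att <- lapply(1:2, function(k) atoms[atoms %in% g$adj[[rh[k]]]])
    # resolve ambiguous attachments (atom bonded to both Rh): nearer Rh wins,
    # ties by lower atom index of the Rh pair
    both <- intersect(att[[1L]], att[[2L]])
    for (a in both) {
      nearer <- if (d_rh[a, 1L] <= d_rh[a, 2L]) 1L else 2L
      drop_from <- 3L - nearer
      att[[drop_from]] <- setdiff(att[[drop_from]], a)
    }
    n1 <- length(att[[1L]]); n2 <- length(att[[2L]])
    if (n1 > 0L && n2 > 0L) {
      bridging[[length(bridging) + 1L]] <- atoms
      bridging_donors[[length(bridging_donors) + 1L]] <-
        data.frame(atom = c(att[[1L]], att[[2L]]),
                   rh = c(rep(rh[1L], n1), rep(rh[2L], n2)))
    } else if (n1 + n2 > 0L) {
      axial[[length(axial) + 1L]] <-
        list(atoms = atoms,
             attach = c(att[[1L]], att[[2L]]),
             rh = if (n1 > 0L) rh[1L] else rh[2L])
    }
    # components attached to no Rh are spectators; rejected below
    if (n1 + n2 == 0L) {
      stop("topology error: fragment not bonded to any Rh atom (atoms ",
           paste(atoms, collapse = ","), ")")
    }
  }
  if (length(bridging) != 4L) {
    stop(sprintf(paste0("topology error: expected 4 bridging components, found %d; ",
                        "for tethered bis-carboxylate ligands supply a manual ",
                        "topology override (see read_topology())"),
                 length(bridging)))
  }
  for (li in seq_along(bridging)) {
    don <- bridging_donors[[li]]
    if (nrow(don) != 2L || length(unique(don$rh)) != 2L) {
      stop(sprintf("topology error: ligand %d has %d Rh-bonded atoms (need 2, one per Rh)",
                   li, nrow(don)))
    }
  }

  carbene <- NULL
  rh_a <- NULL
  if (length(axial) > 0L) {
    if (length(axial) > 1L) {
      stop("topology error: more than one axial fragment found")
    }
    ax <- axial[[1L]]
    if (length(ax$attach) != 1L ||
        geom$elements[ax$attach] != "C") {
      stop("topology error: axial fragment is not bound through a single carbon; ",
           "not a carbene (axial solvent/counterion fragments are not guessed)")
    }
    c_carbene <- ax$attach
    nb <- setdiff(g$adj[[c_carbene]], c(rh, c_carbene))
    c_nb <- nb[geom$elements[nb] == "C"]
    carbene <- list(atoms = sort(ax$atoms), c_carbene = c_carbene,
                    c_neighbors = sort(c_nb))
    rh_a <- ax$rh
  }
  if (is.null(rh_a)) {
    rh_a <- min(rh)
  }
  rh_b <- setdiff(rh, rh_a)
  v <- coords[rh_a, ] - coords[rh_b, ]
  axis <- v / sqrt(sum(v^2))

  # deterministic ligand order: by smallest atom index within each ligand
  ord <- order(vapply(bridging, min, integer(1L)))
  structure(list(rh_indices = c(rh_a = rh_a, rh_b = rh_b),
                 axis = axis,
                 ligands = lapply(bridging[ord], sort),
                 donors = bridging_donors[ord],
                 carbene = carbene,
                 graph = g),
            class = "paddlewheel_topology")
}

#' @export
print.paddlewheel_topology <- function(x, ...) {
  cat(sprintf("<paddlewheel_topology> Rh %d/%d, 4 ligands (%s atoms), carbene: %s\n",
              x$rh_indices[1L], x$rh_indices[2L],
              paste(vapply(x$ligands, length, integer(1L)), collapse = "+"),
              if (is.null(x$carbene)) "none"
              else sprintf("%d atoms via C%d", length(x$carbene$atoms),
                           x$carbene$c_carbene)))
  invisible(x)
}

#' Remove the axial carbene from a geometry
#'
#' Deletes the carbene atoms; all remaining coordinates are unchanged. The
#' returned topology has the carbene field cleared but keeps the identity of
#' the carbene-binding Rh, so axial probes can still be oriented.
#'
#' @param geom A [molecular_geometry()].
#' @param topo Its [detect_paddlewheel()] topology; must contain a carbene.
#' @return List with `geometry` (stripped), `topology` (remapped), and
#'   `index_map` (integer vector: old index -> new index, NA for removed).
#' @export
strip_carbene <- function(geom, topo) {
  stopifnot(inherits(geom, "mol_geometry"),
            inherits(topo, "paddlewheel_topology"))
  if (is.null(topo$carbene)) {
    stop("precondition error: topology has no carbene to strip")
  }
  n <- n_atoms(geom)
  keep <- setdiff(seq_len(n), topo$carbene$atoms)
  index_map <- rep(NA_integer_, n)
  index_map[keep] <- seq_along(keep)
  new_geom <- molecular_geometry(geom$elements[keep],
                                 geom$coords[keep, , drop = FALSE],
                                 label = paste0(geom$label, " (carbene removed)"))
  remap <- function(v) index_map[v]
  new_topo <- topo
  new_topo$rh_indices <- stats::setNames(remap(topo$rh_indices),
                                         names(topo$rh_indices))
  new_topo$ligands <- lapply(topo$ligands, remap)
  new_topo$donors <- lapply(topo$donors, function(d) {
    data.frame(atom = remap(d$atom), rh = remap(d$rh))
  })
  new_topo$carbene <- NULL
  new_topo$graph <- perceive_bonds(new_geom)
  list(geometry = new_geom, topology = new_topo, index_map = index_map)
}

#' Write a topology override document
#'
#' Serializes a paddlewheel topology to YAML (1-based atom index lists) so
#' that perception failures can be corrected by hand and re-imported.
#'
#' @param topo A `paddlewheel_topology`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_topology <- function(topo, path) {
  stopifnot(inherits(topo, "paddlewheel_topology"))
  doc <- list(
    rh_indices = as.integer(topo$rh_indices),
    axis = as.numeric(topo$axis),
    ligands = lapply(topo$ligands, as.integer),
    donors = lapply(topo$donors, function(d) {
      list(atoms = as.integer(d$atom), rh = as.integer(d$rh))
    }),
    carbene = if (is.null(topo$carbene)) NULL else list(
      atoms = as.integer(topo$carbene$atoms),
      c_carbene = as.integer(topo$carbene$c_carbene),
      c_neighbors = as.integer(topo$carbene$c_neighbors))
  )
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

#' Read a topology override document
#'
#' @param path Path to a YAML document written by [write_topology()] or by
#'   hand.
#' @param geom The [molecular_geometry()] it indexes into (used to rebuild
#'   the bond graph and validate index ranges).
#' @param scale Bond-perception scale used to rebuild the bond graph.
#' @return A `paddlewheel_topology`.
#' @export
read_topology <- function(path, geom, scale = 1.2) {
  stopifnot(inherits(geom, "mol_geometry"))
  doc <- yaml::read_yaml(path)
  n <- n_atoms(geom)
  chk <- function(v) {
    v <- as.integer(v)
    if (any(v < 1L | v > n)) stop("topology document: atom index out of range")
    v
  }
  rh <- chk(doc$rh_indices)
  if (length(rh) != 2L) stop("topology document: need exactly 2 Rh indices")
  if (length(doc$ligands) != 4L) stop("topology document: need exactly 4 ligand sets")
  v <- geom$coords[rh[1L], ] - geom$coords[rh[2L], ]
  structure(list(
    rh_indices = c(rh_a = rh[1L], rh_b = rh[2L]),
    axis = v / sqrt(sum(v^2)),
    ligands = lapply(doc$ligands, chk),
    donors = lapply(doc$donors, function(d) {
      data.frame(atom = chk(d$atoms), rh = chk(d$rh))
    }),
    carbene = if (is.null(doc$carbene)) NULL else list(
      atoms = chk(doc$carbene$atoms),
      c_carbene = chk(doc$carbene$c_carbene),
      c_neighbors = chk(doc$carbene$c_neighbors)),
    graph = perceive_bonds(geom, scale = scale)
  ), class = "paddlewheel_topology")
}
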