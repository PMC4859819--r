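#' @title Grid-based pocket volumetrics
#' @name volumetrics
#' @description Measures the volume of an interface cavity on a cubic
#'   lattice bounded by inclusion spheres (the sampling region) and
#'   exclusion spheres (carving away cavities distinct from the pocket and
#'   bulk solvent), removing lattice points that clash with protein atoms
#'   within vdW radius + padding. Ligand-occupied sub-volumes are counted
#'   within a search radius around the ligand, and the "common pocket" of
#'   two ligands is the arithmetic mean of their cross-occupied volumes.
NULL

#' Sphere specification for grid bounding
#'
#' @param center length-3 numeric, Angstrom.
#' @param radius positive radius, Angstrom.
#' @param role "inclusion" or "exclusion".
#' @return A `sphere_spec`.
#' @examples
#' sphere_spec(c(83, 4, -32), 12)           # an inclusion sphere
#' sphere_spec(c(91, 12, -31), 5)
#' @export
sphere_spec <- function(center, radius, role = c("inclusion", "exclusion")) {
  role <- match.arg(role)
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, all(is.finite(center)))
  if (!is.finite(radius) || radius <= 0) usage_error("sphere radius must be > 0")
  structure(list(center = center, radius = radius, role = role),
            class = "sphere_spec")
}

#' Grid specification
#'
#' @param spacing lattice spacing in Angstrom (default 1.0).
#' @param padding distance added to each atom's vdW radius in the
#'   protein-clash test, Angstrom (default 1.09).
#' @return A `grid_spec`.
#' @export
grid_spec <- function(spacing = 1.0, padding = 1.09) {
  if (!is.finite(spacing) || spacing <= 0) usage_error("spacing must be > 0")
  if (!is.finite(padding) || padding < 0) usage_error("padding must be >= 0")
  structure(list(spacing = spacing, padding = padding), class = "grid_spec")
}

.as_sphere_list <- function(x) {
  if (inherits(x, "sphere_spec")) return(list(x))
  if (is.null(x)) return(list())
  stopifnot(is.list(x))
  x
}

#' Build the candidate lattice from inclusion/exclusion spheres
#'
#' An axis-aligned cubic lattice with the given spacing covers the bounding
#' box of the inclusion spheres, anchored at the box's minimum corner (the
#' anchor is recorded: absolute point counts depend on the lattice phase).
#' Points are kept when they lie within at least one inclusion sphere and
#' within no exclusion sphere.
#'
#' @param inclusion a `sphere_spec` or list of them (>= 1 required).
#' @param exclusion optional `sphere_spec` or list of them.
#' @param spec a `grid_spec`.
#' @return A `grid_points` object: `points` (n x 3 matrix), `spec`, `origin`
#'   (lattice anchor) and `n_points`.
#' @export
build_grid <- function(inclusion, exclusion = NULL, spec = grid_spec()) {
  inclusion <- .as_sphere_list(inclusion)
  exclusion <- .as_sphere_list(exclusion)
  if (!length(inclusion)) usage_error("at least one inclusion sphere is required")
  centers <- t(vapply(inclusion, function(s) s$center, numeric(3)))
  radii <- vapply(inclusion, function(s) s$radius, numeric(1))
  lo <- apply(centers - radii, 2, min)
  hi <- apply(centers + radii, 2, max)
  axes <- lapply(1:3, function(k) seq(lo[k], hi[k] + 1e-9, by = spec$spacing))
  pts <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  colnames(pts) <- c("x", "y", "z")
  keep <- rep(FALSE, nrow(pts))
  for (s in inclusion) {
    keep <- keep | dist2_point(pts, s$center) <= s$radius^2
  }
  pts <- pts[keep, , drop = FALSE]
  for (s in exclusion) {
    if (!nrow(pts)) break
    pts <- pts[dist2_point(pts, s$center) > s$radius^2, , drop = FALSE]
  }
  structure(
    list(points = pts, spec = spec, origin = lo, n_points = nrow(pts)),
    class = "grid_points"
  )
}

#' @export
print.grid_points <- function(x, ...) {
  cat(sprintf("<grid_points> %d points, spacing %.3g A (volume %.1f A^3)\n",
              x$n_points, x$spec$spacing, x$n_points * x$spec$spacing^3))
  invisible(x)
}

# Drop the rows of `points` lying within `radius[i]` of any row of `atoms`.
# Per-atom bounding-box prefilter keeps this linear in practice.
.remove_near <- function(points, atoms, radius) {
  keep <- rep(TRUE, nrow(points))
  for (i in seq_len(nrow(atoms))) {
    r <- radius[i]
    p <- atoms[i, ]
    cand <- which(keep &
                    abs(points[, 1] - p[1]) <= r &
                    abs(points[, 2] - p[2]) <= r &
                    abs(points[, 3] - p[3]) <= r)
    if (!length(cand)) next
    d2 <- dist2_point(points[cand, , drop = FALSE], p)
    keep[cand[d2 <= r^2]] <- FALSE
  }
  keep
}

#' Pocket volume: remove protein-clashed lattice points
#'
#' Removes every candidate point within (vdW radius + padding) of any heavy
#' protein atom; the remainder is the pocket. Ligand and water atoms must be
#' removed by the caller beforehand — the pocket is the empty interface
#' space with inhibitors taken out.
#'
#' @param candidates a `grid_points` object from [build_grid()].
#' @param protein a `mol_structure` (ligands/waters already stripped), or
#'   `NULL` for no clash removal.
#' @param spec grid spec; defaults to the candidates' spec.
#' @return A `grid_pocket`: `points`, `spec`, `volume` (A^3 =
#'   count x spacing^3), `n_points`, `n_candidates`, `origin`.
#' @export
pocket_volume <- function(candidates, protein, spec = candidates$spec) {
  pts <- candidates$points
  if (!is.null(protein)) {
    at <- protein$atoms
    at <- at[!(toupper(at$element) %in% c("H", "D")), , drop = FALSE]
    if (nrow(at)) {
      keep <- .remove_near(pts, as.matrix(at[, c("x", "y", "z")]),
                           at$vdw + spec$padding)
      pts <- pts[keep, , drop = FALSE]
    }
  }
  structure(
    list(points = pts, spec = spec,
         volume = nrow(pts) * spec$spacing^3,
         n_points = nrow(pts),
         n_candidates = candidates$n_points,
         origin = candidates$origin),
    class = "grid_pocket"
  )
}

#' @export
print.grid_pocket <- function(x, ...) {
  cat(sprintf("<grid_pocket> %d / %d lattice points kept; volume %.1f A^3\n",
              x$n_points, x$n_candidates, x$volume))
  invisible(x)
}

#' Ligand-occupied pocket volume
#'
#' Counts the pocket lattice points lying within `search_radius` of any
#' heavy ligand atom (default 1.6 Angstrom, a neighbour-search radius around
#' the compound).
#'
#' @param pocket a `grid_pocket`.
#' @param ligand a `mol_structure` holding the ligand pose.
#' @param search_radius Angstrom.
#' @return An `occupancy_result`: `pocket_volume`, `ligand_volume`,
#'   `search_radius`, `n_points`.
#' @export
ligand_occupied_volume <- function(pocket, ligand, search_radius = 1.6) {
  if (pocket$n_points == 0L) usage_error("empty pocket")
  lig <- .as_coords(ligand, heavy_only = TRUE)
  if (nrow(lig) == 0L) usage_error("empty ligand (after hydrogen exclusion)")
  # occupied = NOT kept when "removing" points near ligand atoms
  occupied <- !.remove_near(pocket$points, lig,
                            rep(search_radius, nrow(lig)))
  structure(
    list(pocket_volume = pocket$volume,
         ligand_volume = sum(occupied) * pocket$spec$spacing^3,
         search_radius = search_radius,
         n_points = sum(occupied)),
    class = "occupancy_result"
  )
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf(
    "<occupancy_result> ligand occupies %.1f of %.1f A^3 (search radius %.2f A)\n",
    x$ligand_volume, x$pocket_volume, x$search_radius))
  invisible(x)
}

#' Common pocket volume of two ligands
#'
#' The arithmetic mean of the volume occupied by ligand A in ligand B's
#' cavity and vice versa.
#'
#' @param vol_a_in_b,vol_b_in_a cross-occupied volumes in A^3 (numbers or
#'   `occupancy_result` objects).
#' @return mean volume in A^3.
#' @examples
#' common_pocket(100, 50)  # 75
#' @export
common_pocket <- function(vol_a_in_b, vol_b_in_a) {
  v1 <- if (inherits(vol_a_in_b, "occupancy_result")) vol_a_in_b$ligand_volume else vol_a_in_b
  v2 <- if (inherits(vol_b_in_a, "occupancy_result")) vol_b_in_a$ligand_volume else vol_b_in_a
  if (v1 < 0 || v2 < 0) usage_error("volumes must be >= 0")
  (v1 + v2) / 2
}

#' Keep only the lattice component connected to a seed point
#'
#' Optional flood fill on the 6-connected lattice, for pockets whose
#' exclusion spheres do not already isolate the cavity of interest.
#'
#' @param pocket a `grid_pocket`.
#' @param seed length-3 numeric; the lattice point nearest the seed starts
#'   the fill.
#' @return A `grid_pocket` restricted to the connected component.
#' @export
connected_component <- function(pocket, seed) {
  pts <- pocket$points
  if (!nrow(pts)) return(pocket)
  sp <- pocket$spec$spacing
  key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3])
  ijk <- round(sweep(pts, 2, pocket$origin) / sp)
  idx <- stats::setNames(seq_len(nrow(pts)), key(ijk))
  start <- which.min(dist2_point(pts, as.numeric(seed)))
  visited <- rep(FALSE, nrow(pts))
  queue <- start
  visited[start] <- TRUE
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    nb <- sweep(shifts, 2, as.numeric(ijk[cur, ]), `+`)
    hit <- idx[key(nb)]
    hit <- hit[!is.na(hit)]
    new <- hit[!visited[hit]]
    visited[new] <- TRUE
    queue <- c(queue, new)
  }
  pocket$points <- pts[visited, , drop = FALSE]
  pocket$n_points <- sum(visited)
  pocket$volume <- pocket$n_points * sp^3
  pocket
}

#' Dump lattice points as a PDB of pseudo-atoms
#'
#' For visual inspection of a grid or pocket in a molecular viewer.
#'
#' @param x a `grid_points` or `grid_pocket`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_grid_pdb <- function(x, file) {
  pts <- x$points
  s <- mol_structure(
    data.frame(
      name = "DU", element = "C", chain = "G",
      res_num = 1L, res_name = "GRD",
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      is_hetero = TRUE, stringsAsFactors = FALSE
    ),
    id = "grid"
  )
  write_structure(s, file)
}

#' Read sphere specifications from JSON or a data.frame
#'
#' JSON layout: an array of objects with fields `center` (length-3),
#' `radius` and `role` ("inclusion"/"exclusion"); or a data.frame with
#' columns `x`, `y`, `z`, `radius`, `role`.
#'
#' @param x path to a JSON file, or a data.frame.
#' @return list of `sphere_spec` objects.
#' @export
read_spheres <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) usage_error(paste0("sphere config not found: ", x))
    raw <- jsonlite::read_json(x, simplifyVector = FALSE)
    return(lapply(raw, function(s) {
      sphere_spec(unlist(s$center), s$radius, s$role %||% "inclusion")
    }))
  }
  stopifnot(is.data.frame(x))
  lapply(seq_len(nrow(x)), function(i) {
    sphere_spec(c(x$x[i], x$y[i], x$z[i]), x$radius[i], x$role[i])
  })
}
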