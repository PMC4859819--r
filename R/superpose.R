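#' @title Rigid-body superposition and C-alpha RMSD
#' @name superpose
#' @description Least-squares optimal superposition (Kabsch algorithm,
#'   reflection excluded) between structures paired by chain and residue
#'   number, as used to check that isomorphous crystal forms of the same
#'   construct are essentially identical (C-alpha RMSD of a few tenths of an
#'   Angstrom).
NULL

#' Pair C-alpha atoms of two structures by residue number
#'
#' For each chain pair in `chain_map`, residues present in both structures
#' with a C-alpha atom in each are paired; residues lacking a C-alpha in
#' either partner are skipped (counted in the report). Pairing is by residue
#' number, not sequence alignment: the intended inputs are isomorphous
#' same-construct structures.
#'
#' @param a,b `mol_structure` objects.
#' @param chain_map named character vector mapping chains of `a` to chains of
#'   `b`, e.g. `c(A = "A", B = "B")`. Defaults to the identity map over the
#'   chains shared by both structures.
#' @return list with elements `a`, `b` (paired coordinate matrices, ascending
#'   (chain, res_num) order), `pairs` (data.frame chain_a, chain_b, res_num)
#'   and `per_chain` (pair counts per chain pair).
#' @export
pair_ca <- function(a, b, chain_map = NULL) {
  if (is.null(chain_map)) {
    shared <- intersect(unique(a$atoms$chain), unique(b$atoms$chain))
    shared <- setdiff(shared, "W")
    chain_map <- stats::setNames(shared, shared)
  }
  if (!length(chain_map)) usage_error("chain_map must be non-empty")
  ca_table <- function(s, chain) {
    at <- s$atoms
    at <- at[at$chain == chain & at$name == "CA" & !at$is_hetero, , drop = FALSE]
    # one CA per residue: keep first occurrence (altlocs already resolved)
    at[!duplicated(at$res_num), , drop = FALSE]
  }
  coords_a <- coords_b <- NULL
  pairs <- NULL
  per_chain <- integer(0)
  for (ca_chain in names(chain_map)) {
    cb_chain <- chain_map[[ca_chain]]
    ta <- ca_table(a, ca_chain)
    tb <- ca_table(b, cb_chain)
    shared <- sort(intersect(ta$res_num, tb$res_num))
    per_chain[paste0(ca_chain, "->", cb_chain)] <- length(shared)
    if (!length(shared)) next
    ia <- match(shared, ta$res_num)
    ib <- match(shared, tb$res_num)
    coords_a <- rbind(coords_a, as.matrix(ta[ia, c("x", "y", "z")]))
    coords_b <- rbind(coords_b, as.matrix(tb[ib, c("x", "y", "z")]))
    pairs <- rbind(pairs, data.frame(
      chain_a = ca_chain, chain_b = cb_chain, res_num = shared,
      stringsAsFactors = FALSE
    ))
  }
  if (is.null(coords_a) || nrow(coords_a) == 0L) {
    numeric_error("no C-alpha pairs found for the given chain map")
  }
  list(a = coords_a, b = coords_b, pairs = pairs, per_chain = per_chain)
}

#' Optimal rigid superposition of paired coordinates (Kabsch)
#'
#' Computes the proper rotation (determinant +1; reflections excluded) and
#' translation minimising the RMSD between two equal-length coordinate sets,
#' via singular value decomposition of the covariance matrix.
#'
#' @param a_coords,b_coords n x 3 matrices of paired coordinates (n >= 3).
#' @return A `superposition` object: `rotation` (3 x 3, maps centred `a` onto
#'   centred `b`), `translation` (so that `a %*% t(rotation) + translation`
#'   approximates `b`), `rmsd` (Angstrom, after transformation) and
#'   `n_atoms`.
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' kabsch(a, a)$rmsd   # 0
#' @export
kabsch <- function(a_coords, b_coords) {
  a_coords <- as.matrix(a_coords)
  b_coords <- as.matrix(b_coords)
  if (nrow(a_coords) != nrow(b_coords)) {
    usage_error("coordinate sets must have equal length")
  }
  n <- nrow(a_coords)
  if (n < 3L) numeric_error("superposition needs at least 3 paired atoms")
  ca <- colMeans(a_coords)
  cb <- colMeans(b_coords)
  A <- sweep(a_coords, 2, ca)
  B <- sweep(b_coords, 2, cb)
  # degenerate (collinear) geometry leaves the rotation underdetermined
  sv_a <- svd(A)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1)) {
    numeric_error("degenerate geometry: paired atoms are collinear")
  }
  H <- crossprod(A, B)                      # 3 x 3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)                 # proper rotation: R a ~ b
  rotated <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((rotated - B)^2)))
  structure(
    list(
      rotation = R,
      translation = as.numeric(cb - R %*% ca),
      rmsd = rmsd,
      n_atoms = n
    ),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d paired atoms, RMSD %.3f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Superpose two structures on paired C-alpha atoms
#'
#' Convenience composition of [pair_ca()] and [kabsch()].
#'
#' @inheritParams pair_ca
#' @return A `superposition` with an added `per_chain` pair-count vector and
#'   `pairs` table.
#' @export
superpose_ca <- function(a, b, chain_map = NULL) {
  p <- pair_ca(a, b, chain_map)
  res <- kabsch(p$a, p$b)
  res$per_chain <- p$per_chain
  res$pairs <- p$pairs
  res
}

#' Write a superposition report as JSON
#'
#' @param x a `superposition`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_superposition_report <- function(x, file) {
  write_json_report(
    list(
      n_atoms = x$n_atoms,
      rmsd = x$rmsd,
      per_chain = as.list(x$per_chain %||% stats::setNames(integer(0), character(0))),
      rotation = x$rotation,
      translation = x$translation
    ),
    file
  )
}

#' Apply a rigid transformation to a structure
#'
#' @param s a `mol_structure`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return The transformed `mol_structure`.
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  new_xyz <- sweep(xyz %*% t(rotation), 2, -translation)
  s$atoms$x <- new_xyz[, 1]
  s$atoms$y <- new_xyz[, 2]
  s$atoms$z <- new_xyz[, 3]
  s
}
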