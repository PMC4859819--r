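#' @title Minimum-distance interaction fingerprints
#' @name fingerprints
#' @description A bound (or docked) ligand pose is summarised as the vector
#'   of minimum heavy-atom distances from the ligand to each entry of a
#'   residue panel lining the pocket. Rows (ligands) of the resulting matrix
#'   are the input to binding-mode clustering; thresholding a row gives the
#'   pose's contact map.
NULL

#' Minimum heavy-atom distance between two atom sets
#'
#' Minimum euclidean distance over all cross pairs. Hydrogens (and
#' deuterium) are excluded by default so that crystal structures (which carry
#' none at typical resolution) and docked poses (which may) are comparable.
#'
#' @param ligand_atoms,residue_atoms atom tables (data.frame with x/y/z and
#'   element columns), `mol_structure` objects, or plain n x 3 coordinate
#'   matrices.
#' @param include_hydrogens keep hydrogens in the computation.
#' @return minimum distance in Angstrom.
#' @examples
#' min_distance(matrix(c(0, 0, 0), 1), matrix(c(3, 0, 0), 1))  # 3
#' @export
min_distance <- function(ligand_atoms, residue_atoms, include_hydrogens = FALSE) {
  a <- .as_coords(ligand_atoms, heavy_only = !include_hydrogens)
  b <- .as_coords(residue_atoms, heavy_only = !include_hydrogens)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    numeric_error("min_distance: empty atom set (after hydrogen exclusion)")
  }
  best <- Inf
  for (i in seq_len(nrow(a))) {
    best <- min(best, dist2_point(b, a[i, ]))
  }
  sqrt(best)
}

.as_coords <- function(x, heavy_only = TRUE) {
  if (inherits(x, "mol_structure")) x <- x$atoms
  if (is.data.frame(x)) {
    if (heavy_only && "element" %in% names(x)) {
      x <- x[!(toupper(x$element) %in% c("H", "D")), , drop = FALSE]
    }
    return(as.matrix(x[, c("x", "y", "z")]))
  }
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3L)
  x
}

#' Fingerprint matrix of ligand poses against a residue panel
#'
#' For each complex, the named ligand is extracted and its minimum
#' heavy-atom distance to every panel entry is computed (whole residues,
#' backbone included). Panel entries that do not resolve in a complex (e.g.
#' waters absent from a docked pose file) yield a missing value; when a
#' `cap` is given, missing values are encoded as the cap (sentinel) and all
#' finite values are truncated at the cap. Without a cap, missing values are
#' kept as `NA` and must be dropped column-wise before clustering. The policy
#' in effect is recorded on the object.
#'
#' @param complexes list of `mol_structure` complexes; names (or structure
#'   ids) become ligand ids.
#' @param ligands character vector of ligand residue names, recycled to
#'   `length(complexes)`.
#' @param panel a `residue_panel`.
#' @param cap optional distance cap in Angstrom.
#' @param include_hydrogens include hydrogens in distances.
#' @return A `fingerprint_matrix`: list with `values` (ligands x tokens
#'   matrix), `ligand_ids`, `panel`, `cap`, `missing` (logical matrix of
#'   unresolved entries) and `missing_policy`.
#' @export
fingerprint_matrix <- function(complexes, ligands, panel, cap = NULL,
                               include_hydrogens = FALSE) {
  if (inherits(complexes, "mol_structure")) complexes <- list(complexes)
  n <- length(complexes)
  if (!n) usage_error("no complexes given")
  ligands <- rep_len(ligands, n)
  ids <- names(complexes) %||% vapply(complexes, function(s) s$id, "")
  if (is.null(names(complexes))) names(complexes) <- ids
  ids[!nzchar(ids)] <- paste0("ligand_", which(!nzchar(ids)))

  values <- matrix(NA_real_, nrow = n, ncol = nrow(panel),
                   dimnames = list(ids, panel$token))
  missing <- matrix(FALSE, nrow = n, ncol = nrow(panel),
                    dimnames = dimnames(values))
  for (i in seq_len(n)) {
    s <- complexes[[i]]
    lig <- extract_ligand(s, ligands[i])
    for (j in seq_len(nrow(panel))) {
      sel <- select_atoms(s, panel[j, , drop = FALSE],
                          heavy_only = !include_hydrogens)
      if (nrow(sel) == 0L) {
        missing[i, j] <- TRUE
      } else {
        values[i, j] <- min_distance(lig, sel,
                                     include_hydrogens = include_hydrogens)
      }
    }
    if (all(missing[i, ])) {
      numeric_error(sprintf("no panel entry resolves for ligand row '%s'", ids[i]))
    }
  }
  all_missing_cols <- colnames(values)[colSums(missing) == n]
  if (length(all_missing_cols)) {
    warning("panel entries unresolved in every complex: ",
            paste(all_missing_cols, collapse = ", "))
  }
  if (!is.null(cap)) {
    stopifnot(cap > 0)
    values[missing] <- cap
    values <- pmin(values, cap)
    policy <- sprintf("missing entries set to cap sentinel (%.3g A); values truncated at cap", cap)
  } else {
    policy <- "no cap: missing entries kept as NA (drop columns before clustering)"
  }
  structure(
    list(values = values, ligand_ids = rownames(values), panel = panel,
         cap = cap, missing = missing, missing_policy = policy),
    class = "fingerprint_matrix"
  )
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("<fingerprint_matrix> %d ligands x %d panel entries%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$cap)) sprintf(", cap %.3g A", x$cap) else ""))
  cat("  ", x$missing_policy, "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.fingerprint_matrix <- function(x, ...) x$values

#' Drop panel columns with any missing value
#'
#' The no-cap missing-value policy: columns (panel entries) that failed to
#' resolve in at least one complex are removed before clustering.
#'
#' @param m a `fingerprint_matrix`.
#' @return A `fingerprint_matrix` restricted to fully observed columns.
#' @export
drop_missing_columns <- function(m) {
  keep <- colSums(m$missing) == 0L
  m$values <- m$values[, keep, drop = FALSE]
  m$missing <- m$missing[, keep, drop = FALSE]
  m$panel <- m$panel[keep, , drop = FALSE]
  m$missing_policy <- sprintf("%s; %d unresolved column(s) dropped",
                              m$missing_policy, sum(!keep))
  m
}

#' Contact map of one ligand pose
#'
#' Panel entries whose minimum heavy-atom distance to the ligand is within
#' the cutoff — the residues in direct contact with the pose.
#'
#' @param s a `mol_structure` complex.
#' @param ligand ligand residue name.
#' @param panel a `residue_panel`.
#' @param cutoff contact cutoff in Angstrom (commonly 4.0).
#' @param include_hydrogens include hydrogens in distances.
#' @return A `contact_map`: list with `ligand_id`, `contacts` (character
#'   vector of tokens, panel order), `cutoff` and the full `distances`
#'   vector.
#' @export
contact_map <- function(s, ligand, panel, cutoff = 4.0,
                        include_hydrogens = FALSE) {
  fm <- fingerprint_matrix(list(s), ligand, panel,
                           include_hydrogens = include_hydrogens)
  d <- fm$values[1, ]
  structure(
    list(
      ligand_id = fm$ligand_ids[1],
      contacts = names(d)[!is.na(d) & d <= cutoff],
      cutoff = cutoff,
      distances = d
    ),
    class = "contact_map"
  )
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %s @ %.2f A: %s\n", x$ligand_id, x$cutoff,
              paste(x$contacts, collapse = " ")))
  invisible(x)
}

#' Write a fingerprint matrix as CSV
#'
#' Ligands as rows (first column `ligand_id`), panel tokens as column
#' headers.
#'
#' @param m a `fingerprint_matrix` (or plain matrix).
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_fingerprint_csv <- function(m, file) {
  v <- if (inherits(m, "fingerprint_matrix")) m$values else as.matrix(m)
  df <- data.frame(ligand_id = rownames(v), round(v, 4),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read a fingerprint matrix from CSV
#'
#' Inverse of [write_fingerprint_csv()].
#'
#' @param file CSV path (first column `ligand_id`, remaining columns panel
#'   tokens).
#' @return A `fingerprint_matrix`.
#' @export
read_fingerprint_csv <- function(file) {
  if (!file.exists(file)) usage_error(paste0("file not found: ", file))
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"ligand_id" %in% names(df)) {
    parse_error("fingerprint CSV lacks a 'ligand_id' column")
  }
  v <- as.matrix(df[, setdiff(names(df), "ligand_id"), drop = FALSE])
  rownames(v) <- df$ligand_id
  structure(
    list(values = v, ligand_ids = df$ligand_id,
         panel = residue_panel(colnames(v)), cap = NULL,
         missing = is.na(v),
         missing_policy = "read from CSV"),
    class = "fingerprint_matrix"
  )
}
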