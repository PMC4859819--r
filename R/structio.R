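#' @title Structure input/output and atom selection
#' @name structio
#' @description Read and write macromolecular structures (PDB format, first
#'   model only) into a light atom-table container, select atoms by
#'   chain/residue tokens, and extract bound ligands. Parsing is backed by
#'   \pkg{bio3d}; the container keeps exactly the fields the downstream
#'   distance and volume computations need.
NULL

# Bondi-style van der Waals radii (Angstrom), by element symbol.  Pinned here
# so that every volume and clash computation uses one explicit, versioned
# table.
.vdw_table <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, B = 1.92,
  SE = 1.90, ZN = 1.39, MG = 1.73, "NA" = 2.27, K = 2.75, CA = 2.31,
  FE = 1.94, MN = 2.05, CU = 1.40
)

.vdw_default <- 1.70

.water_names <- c("HOH", "WAT", "DOD", "TIP", "SOL")

#' Van der Waals radius for an element symbol
#'
#' Looks up the package's pinned Bondi-style radius table. Unknown elements
#' fall back to the carbon-like default of 1.70 Angstrom with a warning.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom.
#' @examples
#' vdw_radius(c("C", "N", "O"))
#' @export
vdw_radius <- function(element) {
  key <- toupper(trimws(as.character(element)))
  r <- unname(.vdw_table[key])
  if (anyNA(r)) {
    unknown <- unique(key[is.na(r)])
    warning(
      "unknown element(s) ", paste(unknown, collapse = ", "),
      "; using default vdW radius ", .vdw_default, " A"
    )
    r[is.na(r)] <- .vdw_default
  }
  r
}

new_mol_structure <- function(atoms, id) {
  stopifnot(is.data.frame(atoms))
  structure(list(atoms = atoms, id = id), class = "mol_structure")
}

#' Build a structure from an atom table
#'
#' Constructor for the package's structure container: an ordered atom table
#' with chain, residue number/name, atom name, element, coordinates and a
#' hetero flag. Van der Waals radii are assigned from the element table.
#'
#' @param atoms data.frame with columns `name`, `element`, `chain`,
#'   `res_num`, `res_name`, `x`, `y`, `z`, `is_hetero` (and optionally
#'   `serial`).
#' @param id free-text label for the structure.
#' @return An object of class `mol_structure`.
#' @export
mol_structure <- function(atoms, id = "structure") {
  required <- c("name", "element", "chain", "res_num", "res_name",
                "x", "y", "z", "is_hetero")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    stop("non-finite coordinates in atom table")
  }
  atoms$res_num <- as.integer(atoms$res_num)
  if (anyNA(atoms$res_num)) stop("residue numbers must be integers")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  atoms$vdw <- vdw_radius(atoms$element)
  rownames(atoms) <- NULL
  new_mol_structure(
    atoms[, c("serial", "name", "element", "chain", "res_num", "res_name",
              "x", "y", "z", "is_hetero", "vdw")],
    id
  )
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf(
    "<mol_structure> %s: %d atoms, chains [%s], %d residues\n",
    x$id, nrow(x$atoms), paste(sort(unique(x$atoms$chain)), collapse = ","),
    nrow(unique(x$atoms[, c("chain", "res_num")]))
  ))
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param s a `mol_structure`.
#' @param heavy_only drop hydrogens (and deuterium) when `TRUE`.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
atom_coords <- function(s, heavy_only = FALSE) {
  at <- s$atoms
  if (heavy_only) at <- at[!(toupper(at$element) %in% c("H", "D")), , drop = FALSE]
  as.matrix(at[, c("x", "y", "z")])
}

#' Parse PDB-format text into a structure
#'
#' Reads ATOM/HETATM records of the first model. Alternate locations keep
#' altloc ' ' or 'A' only (the highest-default-occupancy convention), so every
#' downstream distance refers to a single conformer. Records carrying an
#' insertion code are rejected: the computations address residues by plain
#' integer numbers. Hydrogens are parsed and retained; the distance and
#' volume routines exclude them by default.
#'
#' @param text PDB content: a single string or a character vector of lines.
#' @param id label for the resulting structure.
#' @return A `mol_structure`.
#' @examples
#' pdb <- c(
#'   "ATOM      1  CA  ALA A  75       0.000   0.000   0.000  1.00  0.00           C",
#'   "HETATM    2  C1  LIG L 900       3.000   0.000   0.000  1.00  0.00           C"
#' )
#' parse_structure(pdb, id = "toy")
#' @export
parse_structure <- function(text, id = "structure") {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  endmdl <- which(startsWith(text, "ENDMDL"))
  if (length(endmdl)) text <- text[seq_len(endmdl[1] - 1L)]
  rec <- which(startsWith(text, "ATOM  ") | startsWith(text, "HETATM"))
  if (!length(rec)) {
    parse_error("no ATOM/HETATM records found in input")
  }
  # Validate fixed-width coordinate fields up front so parse failures name the
  # offending line.
  for (i in rec) {
    ln <- text[i]
    if (nchar(ln) < 54) {
      parse_error(sprintf("line %d: record too short for coordinates: '%s'", i, ln))
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (anyNA(xyz)) {
      parse_error(sprintf("line %d: unparseable coordinates: '%s'", i, ln))
    }
  }
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f), add = TRUE)
  writeLines(text, f)
  pdb <- bio3d::read.pdb(f, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom

  if (any(!is.na(at$insert) & nzchar(at$insert))) {
    bad <- which(!is.na(at$insert) & nzchar(at$insert))[1]
    parse_error(sprintf(
      "insertion codes are not supported (first at %s%d%s); renumber the input",
      at$chain[bad], at$resno[bad], at$insert[bad]
    ))
  }
  keep_alt <- is.na(at$alt) | at$alt %in% c("", " ", "A")
  at <- at[keep_alt, , drop = FALSE]
  if (nrow(at) == 0L) parse_error("no atoms left after alternate-location filtering")

  element <- at$elesy
  missing_el <- is.na(element) | !nzchar(trimws(element))
  if (any(missing_el)) {
    guess <- suppressWarnings(bio3d::atom2ele(at$elety[missing_el]))
    element[missing_el] <- guess
  }
  chain <- at$chain
  chain[is.na(chain)] <- ""

  mol_structure(
    data.frame(
      serial = at$eleno,
      name = trimws(at$elety),
      element = toupper(trimws(element)),
      chain = chain,
      res_num = at$resno,
      res_name = trimws(at$resid),
      x = at$x, y = at$y, z = at$z,
      is_hetero = at$type == "HETATM",
      stringsAsFactors = FALSE
    ),
    id = id
  )
}

#' Read a structure from a PDB file
#'
#' @param file path to a PDB file.
#' @param id label; defaults to the file name without extension.
#' @return A `mol_structure`.
#' @export
read_structure <- function(file, id = NULL) {
  if (!file.exists(file)) usage_error(paste0("file not found: ", file))
  parse_structure(readLines(file, warn = FALSE),
                  id = id %||% sub("\\.[^.]*$", "", basename(file)))
}

#' Write a structure as PDB
#'
#' Fixed-width ATOM/HETATM records; coordinates at 3 decimals (the format's
#' precision), so `parse_structure(write_structure(s))` round-trips counts,
#' ordering, chains, residue numbers and coordinates.
#'
#' @param s a `mol_structure`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_structure <- function(s, file) {
  at <- s$atoms
  bio3d::write.pdb(
    file = file,
    type = ifelse(at$is_hetero, "HETATM", "ATOM"),
    eleno = at$serial,
    elety = at$name,
    resid = at$res_name,
    chain = at$chain,
    resno = at$res_num,
    xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
    o = rep(1, nrow(at)),
    b = rep(0, nrow(at)),
    elesy = at$element
  )
  invisible(file)
}

#' Read a standalone ligand pose from an SDF file
#'
#' Uses only the coordinate block (positions + element symbols); connectivity
#' is ignored. The atoms are returned as a single hetero residue so the pose
#' can be combined with a receptor and fingerprinted. Requires the
#' \pkg{ChemmineR} package.
#'
#' @param file path to an SDF file (first molecule is read).
#' @param res_name residue name to assign (default "LIG").
#' @param chain chain identifier to assign.
#' @param res_num residue number to assign.
#' @return A `mol_structure` holding the pose.
#' @export
read_sdf_pose <- function(file, res_name = "LIG", chain = "L", res_num = 900L) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("reading SDF poses requires the ChemmineR package")
  }
  sdf <- ChemmineR::read.SDFset(file)
  ab <- ChemmineR::atomblock(sdf[[1]])
  element <- toupper(gsub("[_0-9]+$", "", rownames(ab)))
  mol_structure(
    data.frame(
      name = paste0(element, seq_along(element)),
      element = element,
      chain = chain,
      res_num = res_num,
      res_name = res_name,
      x = ab[, 1], y = ab[, 2], z = ab[, 3],
      is_hetero = TRUE,
      stringsAsFactors = FALSE
    ),
    id = sub("\\.[^.]*$", "", basename(file))
  )
}

#' Parse residue-panel tokens
#'
#' Tokens have the form `"<chain>:<res_num>"` (e.g. `"A:75"`, `"B:176"`) for
#' protein residues and `"W:<num>"` for waters. By the panel convention chain
#' 'A' is GluN1, 'B' is GluN2B and 'W' marks water molecules.
#'
#' @param tokens character vector of tokens; `"A75"` shorthand is accepted.
#' @return A `residue_panel`: data.frame with columns `kind`, `chain`,
#'   `res_num`, `token`, in input order.
#' @examples
#' residue_panel(c("A:75", "B:176", "W:100"))
#' @export
residue_panel <- function(tokens) {
  tokens <- as.character(tokens)
  if (!length(tokens)) usage_error("empty residue panel")
  norm <- ifelse(grepl(":", tokens, fixed = TRUE),
                 tokens,
                 sub("^([A-Za-z]+)([0-9]+)$", "\\1:\\2", tokens))
  parts <- strsplit(norm, ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    usage_error(paste0("malformed panel token(s): ",
                       paste(tokens[bad], collapse = ", ")))
  }
  chain <- vapply(parts, `[`, "", 1L)
  res_num <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  if (anyNA(res_num)) {
    usage_error(paste0("non-integer residue number in token(s): ",
                       paste(tokens[is.na(res_num)], collapse = ", ")))
  }
  token <- paste0(chain, ":", res_num)
  if (anyDuplicated(token)) {
    usage_error(paste0("duplicate panel token(s): ",
                       paste(unique(token[duplicated(token)]), collapse = ", ")))
  }
  out <- data.frame(
    kind = ifelse(toupper(chain) == "W", "water", "protein"),
    chain = chain, res_num = res_num, token = token,
    stringsAsFactors = FALSE
  )
  class(out) <- c("residue_panel", "data.frame")
  out
}

#' Read a residue panel from a text or JSON file
#'
#' Plain-text files hold one token per line (blank lines and `#` comments
#' ignored); JSON files hold an array of token strings.
#'
#' @param file path to the panel file.
#' @return A `residue_panel`.
#' @export
read_panel <- function(file) {
  if (!file.exists(file)) usage_error(paste0("panel file not found: ", file))
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    tokens <- unlist(jsonlite::read_json(file, simplifyVector = TRUE))
  } else {
    tokens <- readLines(file, warn = FALSE)
    tokens <- trimws(sub("#.*$", "", tokens))
    tokens <- tokens[nzchar(tokens)]
  }
  if (!length(tokens)) usage_error(paste0("panel file is empty: ", file))
  residue_panel(tokens)
}

#' The GluN1/GluN2B NTD dimer-interface residue panel
#'
#' The 34 amino acids (13 on GluN1 = chain A, 21 on GluN2B = chain B) plus
#' three water molecules that line the allosteric antagonist pocket at the
#' NTD dimer interface. These define the columns of the interaction
#' fingerprint used to classify GluN2B-selective antagonist binding modes.
#'
#' @param include_waters include the three water tokens (default `TRUE`).
#' @return A `residue_panel` of 37 (or 34) tokens.
#' @export
interface_panel <- function(include_waters = TRUE) {
  a <- c(75, 106, 108, 109, 110, 112, 113, 115, 131, 132, 133, 134, 135)
  b <- c(78, 82, 106, 107, 110, 111, 113, 114, 115, 134, 135, 136, 137,
         174, 175, 176, 177, 207, 233, 235, 236)
  tokens <- c(paste0("A:", a), paste0("B:", b))
  if (include_waters) tokens <- c(tokens, paste0("W:", c(100, 134, 304)))
  residue_panel(tokens)
}

#' Select atoms addressed by a panel token
#'
#' Protein tokens select every atom of the residue with the given chain and
#' residue number. Water tokens select water atoms (residue name HOH/WAT/...,
#' or chain 'W') with the given number in any chain, since water numbering is
#' file-local. An empty selection is returned as a zero-row table, never an
#' error, except when a protein token addresses a chain absent from the
#' structure.
#'
#' @param s a `mol_structure`.
#' @param token a single panel token string (e.g. `"B:176"`) or one row of a
#'   `residue_panel`.
#' @param heavy_only drop hydrogens from the selection.
#' @return data.frame of selected atoms (possibly zero rows).
#' @export
select_atoms <- function(s, token, heavy_only = FALSE) {
  if (is.character(token)) token <- residue_panel(token)
  stopifnot(nrow(token) == 1L)
  at <- s$atoms
  if (token$kind == "water") {
    sel <- at[(at$res_name %in% .water_names | at$chain == token$chain) &
                at$res_num == token$res_num &
                (at$res_name %in% .water_names), , drop = FALSE]
  } else {
    chains <- unique(at$chain)
    if (!token$chain %in% chains) {
      usage_error(sprintf(
        "token %s addresses chain '%s' absent from structure '%s' (available: %s)",
        token$token, token$chain, s$id, paste(sort(chains), collapse = ", ")
      ))
    }
    sel <- at[at$chain == token$chain & at$res_num == token$res_num &
                !(at$res_name %in% .water_names), , drop = FALSE]
  }
  if (heavy_only) sel <- sel[!(toupper(sel$element) %in% c("H", "D")), , drop = FALSE]
  sel
}

#' Extract a bound ligand from a complex
#'
#' Pulls the hetero residue with the given residue name out of a complex. If
#' several copies are present an explicit `instance` (file order) must be
#' given.
#'
#' @param s a `mol_structure` holding the complex.
#' @param res_name 3-letter residue name of the ligand.
#' @param instance which copy to take when several are present (1-based, file
#'   order).
#' @return A `mol_structure` containing only the ligand's atoms.
#' @export
extract_ligand <- function(s, res_name, instance = NULL) {
  at <- s$atoms
  het <- at[at$is_hetero & !(at$res_name %in% .water_names), , drop = FALSE]
  hit <- het[het$res_name == res_name, , drop = FALSE]
  if (nrow(hit) == 0L) {
    usage_error(sprintf(
      "no hetero residue '%s' in structure '%s' (hetero residue names: %s)",
      res_name, s$id,
      paste(sort(unique(het$res_name)), collapse = ", ") %|e|% "none"
    ))
  }
  key <- paste(hit$chain, hit$res_num)
  copies <- unique(key)
  if (length(copies) > 1L && is.null(instance)) {
    usage_error(sprintf(
      "%d copies of ligand '%s' in '%s'; give an instance index",
      length(copies), res_name, s$id
    ))
  }
  pick <- copies[instance %||% 1L]
  if (is.na(pick)) {
    usage_error(sprintf("instance %d out of range (only %d copies of '%s')",
                        instance, length(copies), res_name))
  }
  new_mol_structure(hit[key == pick, , drop = FALSE],
                    id = paste0(s$id, ":", res_name))
}

`%|e|%` <- function(a, b) if (nzchar(a)) a else b

#' Concatenate two structures into one complex
#'
#' @param a,b `mol_structure` objects (e.g. a receptor and a ligand pose).
#' @param id label for the combined structure.
#' @return A `mol_structure` with `a`'s atoms followed by `b`'s, reserialed.
#' @export
combine_structures <- function(a, b, id = paste(a$id, b$id, sep = "+")) {
  atoms <- rbind(a$atoms, b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  new_mol_structure(atoms, id = id)
}
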