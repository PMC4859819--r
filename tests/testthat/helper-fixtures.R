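# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

# One fixed-width PDB record.
pdb_record <- function(serial, name, res_name, chain, res_num, x, y, z,
                       type = "ATOM", element = substr(name, 1, 1),
                       altloc = " ", insert = "") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, altloc, res_name, chain, res_num, insert,
          x, y, z, 1.0, 0.0, element)
}

# A small protein + ligand complex as PDB text: `n_res` glycine stubs on
# chain A plus a 4-atom LIG hetero residue.
toy_complex_text <- function(n_res = 3, lig_res_num = 900) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n_res)) {
    for (at in c("N", "CA", "C")) {
      serial <- serial + 1L
      off <- switch(at, N = -1.2, CA = 0, C = 1.2)
      lines <- c(lines, pdb_record(serial, at, "GLY", "A", 70 + i,
                                   3 * i + off, 0, 0,
                                   element = substr(at, 1, 1)))
    }
  }
  for (j in 1:4) {
    serial <- serial + 1L
    lines <- c(lines, pdb_record(serial, paste0("C", j), "LIG", "L",
                                 lig_res_num, j, 5, 0, type = "HETATM",
                                 element = "C"))
  }
  c(lines, "END")
}

# Random rotation matrix (uniform via QR of a Gaussian matrix).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Minimal V2000 SDF text for a set of atoms, bonded as a simple chain.
sdf_text <- function(coords, elements, title = "toy") {
  n <- nrow(coords)
  bonds <- if (n > 1) {
    vapply(seq_len(n - 1), function(i) {
      sprintf("%3d%3d%3d  0", i, i + 1L, 1L)
    }, "")
  } else character(0)
  c(title, "  generated", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, length(bonds)),
    vapply(seq_len(n), function(i) {
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              coords[i, 1], coords[i, 2], coords[i, 3], elements[i])
    }, ""),
    bonds,
    "M  END", "$$$$")
}

# Deposited-entry loader for the crystal-structure checks: looks for
# <id>.pdb in a local cache directory, otherwise attempts a download via
# bio3d. Offline and without a cache this fails, and the checks that need
# the deposited coordinates fail with it.
fetch_deposited <- function(id) {
  cache <- getOption("ligmodes.pdb_dir", file.path("..", "..", "scratch", "pdb"))
  local <- file.path(cache, paste0(id, ".pdb"))
  if (file.exists(local)) return(read_structure(local, id = id))
  path <- tryCatch(
    suppressWarnings(bio3d::get.pdb(id, path = tempdir(), verbose = FALSE)),
    error = function(e) NULL
  )
  if (is.null(path) || !is.character(path) || !file.exists(path)) {
    stop("deposited entry '", id, "' unavailable: not in the local cache (",
         cache, ") and download failed")
  }
  read_structure(path, id = id)
}

# In the deposited heterodimer entries the GluN2B NTD construct ends near
# residue 394 while GluN1 runs to 408; pick the GluN2B chain accordingly.
glun2b_chain <- function(s) {
  at <- s$atoms[!s$atoms$is_hetero, ]
  spans <- tapply(at$res_num, at$chain, max)
  names(spans)[which.min(abs(spans - 394))]
}

# Largest non-water hetero residue = the bound antagonist.
main_ligand_name <- function(s) {
  het <- s$atoms[s$atoms$is_hetero & !(s$atoms$res_name %in%
                                         c("HOH", "WAT", "DOD")), ]
  names(sort(table(het$res_name), decreasing = TRUE))[1]
}
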