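#' @title Synthetic fixtures: receptors, poses, pockets, dose-response data
#' @name synthetic_data
#' @description Seeded generators that emulate the study conditions without
#'   any downloads: a two-chain pseudo-receptor whose cleft carries every
#'   token of the dimer-interface panel, ligand poses drawn from two
#'   geometrically distinct archetypes sharing one anchor subcavity
#'   (ifenprodil-like vs EVT-101-like binding modes), wall-atom pocket
#'   fixtures with closed-form accessible volumes, and Hill-model
#'   dose-response datasets. All generators are pure functions of
#'   (spec, seed).
NULL

# Site centres of the synthetic cleft (Angstrom): a shared hydrophobic
# anchor subcavity plus two mode-specific branch subcavities.
.site_centers <- list(
  anchor = c(0, 0, 0),
  lower = c(8, 0, 0),    # lower-lobe subcavity: ifenprodil-like branch
  groove = c(0, 8, 0),   # solvent-exposed groove: EVT-101-like branch
  mid = c(4, 4, 0)
)

# Panel tokens grouped by which subcavity they line in the synthetic cleft.
.site_tokens <- list(
  anchor = c("A:75", "B:78", "B:82", "B:106", "B:107", "B:113", "B:114", "B:115"),
  lower = c("A:133", "A:135", "B:174", "B:175", "B:176", "B:177",
            "B:207", "B:233", "B:235", "B:236"),
  groove = c("A:108", "A:109", "A:110", "A:112", "A:113", "A:115",
             "B:110", "B:111", "B:134", "B:135", "B:136", "B:137"),
  mid = c("A:106", "A:131", "A:132", "A:134")
)

.site_waters <- c(`W:100` = "groove", `W:134` = "anchor", `W:304` = "lower")

#' Generate the synthetic two-chain receptor
#'
#' Builds a pseudo-receptor of two chains ('A' and 'B') of tri-atom
#' (N, CA, C) residue stubs arranged as two walls of a cleft with three
#' subcavities (shared anchor, lower-lobe branch, groove branch), plus three
#' water molecules. Residue numbering covers every token of
#' [interface_panel()], so all 37 panel selections resolve. Chain A residues
#' form the wall at z > 0, chain B at z < 0. A small seeded coordinate
#' jitter (sd 0.15 Angstrom) makes different seeds geometrically distinct
#' while preserving the topology.
#'
#' @param seed integer RNG seed.
#' @return A `mol_structure`.
#' @examples
#' r <- make_two_chain_receptor(seed = 1)
#' nrow(select_atoms(r, "B:176"))  # 3 (N, CA, C stub)
#' @export
make_two_chain_receptor <- function(seed = 1L) {
  with_seed(seed, {
    rows <- list()
    for (site in names(.site_tokens)) {
      tokens <- .site_tokens[[site]]
      center <- .site_centers[[site]]
      m <- length(tokens)
      ang <- 2 * pi * (seq_len(m) - 1) / m
      for (i in seq_len(m)) {
        tk <- residue_panel(tokens[i])
        wall_z <- if (tk$chain == "A") 3.5 else -3.5
        ca <- center + c(5 * cos(ang[i]), 5 * sin(ang[i]), wall_z)
        ca <- ca + stats::rnorm(3, sd = 0.15)
        for (at in c("N", "CA", "C")) {
          off <- switch(at,
                        N = c(-1.2, 0, 0.6),
                        CA = c(0, 0, 0),
                        C = c(1.2, 0, 0.6))
          p <- ca + off
          rows[[length(rows) + 1L]] <- data.frame(
            name = at, element = if (at == "N") "N" else "C",
            chain = tk$chain, res_num = tk$res_num, res_name = "GLY",
            x = p[1], y = p[2], z = p[3], is_hetero = FALSE,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    for (wt in names(.site_waters)) {
      tk <- residue_panel(wt)
      center <- .site_centers[[.site_waters[[wt]]]]
      p <- center + c(2, 2, 1.5) + stats::rnorm(3, sd = 0.15)
      rows[[length(rows) + 1L]] <- data.frame(
        name = "O", element = "O", chain = "W", res_num = tk$res_num,
        res_name = "HOH", x = p[1], y = p[2], z = p[3], is_hetero = TRUE,
        stringsAsFactors = FALSE
      )
    }
    mol_structure(do.call(rbind, rows),
                  id = sprintf("synthetic-receptor-seed%d", seed))
  })
}

#' Archetype specification for synthetic poses
#'
#' The two named archetypes emulate the study's binding modes: both anchor
#' half their atoms in the shared hydrophobic subcavity; "ifenprodil_like"
#' places its branch atoms in the lower-lobe subcavity, "evt101_like" in the
#' solvent-exposed groove.
#'
#' @param name "ifenprodil_like" or "evt101_like" (or any label when
#'   `branch_offset` is given explicitly).
#' @param anchor_offset 3-vector added to the anchor site centre, Angstrom.
#' @param branch_offset 3-vector: the branch site centre; defaults by
#'   archetype name.
#' @param n_atoms ligand heavy-atom count (>= 3).
#' @param jitter_sd isotropic Gaussian jitter per coordinate, Angstrom.
#' @param seed integer RNG seed.
#' @return An `archetype_spec`.
#' @export
archetype_spec <- function(name = c("ifenprodil_like", "evt101_like"),
                           anchor_offset = c(0, 0, 0), branch_offset = NULL,
                           n_atoms = 12L, jitter_sd = 0, seed = 1L) {
  if (is.null(branch_offset)) {
    name <- match.arg(name)
    branch_offset <- switch(name,
                            ifenprodil_like = .site_centers$lower,
                            evt101_like = .site_centers$groove)
  }
  if (n_atoms < 3L) usage_error("n_atoms must be >= 3")
  if (jitter_sd < 0) usage_error("jitter_sd must be >= 0")
  structure(
    list(name = name, anchor_offset = as.numeric(anchor_offset),
         branch_offset = as.numeric(branch_offset),
         n_atoms = as.integer(n_atoms), jitter_sd = jitter_sd,
         seed = as.integer(seed)),
    class = "archetype_spec"
  )
}

#' Generate one synthetic ligand pose
#'
#' Splits the ligand's atoms between the shared anchor subcavity and the
#' archetype's branch subcavity (spread along the anchor-branch axis and on
#' a small ring), then adds seeded Gaussian jitter. Returned as a hetero
#' residue (`LIG`, chain L) ready to combine with the receptor.
#'
#' @param receptor the `mol_structure` from [make_two_chain_receptor()]
#'   (used only for its label; the cleft geometry is fixed by convention).
#' @param spec an `archetype_spec`.
#' @return A `mol_structure` holding the pose.
#' @export
make_pose <- function(receptor, spec) {
  stopifnot(inherits(spec, "archetype_spec"))
  with_seed(spec$seed, {
    n <- spec$n_atoms
    n_anchor <- ceiling(n / 2)
    anchor <- .site_centers$anchor + spec$anchor_offset
    branch <- spec$branch_offset
    place <- function(center, m, phase) {
      ang <- 2 * pi * (seq_len(m) - 1) / max(m, 1) + phase
      cbind(center[1] + 1.2 * cos(ang),
            center[2] + 1.2 * sin(ang),
            center[3] + 0.4 * ((seq_len(m) %% 2) - 0.5))
    }
    xyz <- rbind(place(anchor, n_anchor, 0),
                 place(branch, n - n_anchor, pi / 4))
    if (spec$jitter_sd > 0) {
      xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = spec$jitter_sd),
                          ncol = 3)
    }
    mol_structure(
      data.frame(
        name = paste0("C", seq_len(n)), element = "C", chain = "L",
        res_num = 900L, res_name = "LIG",
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
        is_hetero = TRUE, stringsAsFactors = FALSE
      ),
      id = sprintf("%s-seed%d", spec$name, spec$seed)
    )
  })
}

#' Generate a two-archetype set of synthetic complexes
#'
#' `n_per_class` poses per archetype, each combined with the receptor, with
#' per-pose seeds drawn deterministically from `seed`.
#'
#' @param receptor from [make_two_chain_receptor()].
#' @param n_per_class poses per archetype.
#' @param jitter_sd per-coordinate pose jitter, Angstrom.
#' @param n_atoms ligand heavy-atom count.
#' @param seed integer RNG seed.
#' @return named list of `mol_structure` complexes (names `ifen_01`, ...,
#'   `evt_01`, ...), with an `archetype` attribute giving the true class of
#'   each.
#' @export
make_pose_set <- function(receptor, n_per_class = 10L, jitter_sd = 0.3,
                          n_atoms = 12L, seed = 1L) {
  pose_seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 2,
                                           2L * n_per_class))
  ids <- c(sprintf("ifen_%02d", seq_len(n_per_class)),
           sprintf("evt_%02d", seq_len(n_per_class)))
  archetype <- rep(c("ifenprodil_like", "evt101_like"), each = n_per_class)
  complexes <- vector("list", 2L * n_per_class)
  names(complexes) <- ids
  for (i in seq_along(ids)) {
    sp <- archetype_spec(archetype[i], n_atoms = n_atoms,
                         jitter_sd = jitter_sd, seed = pose_seeds[i])
    complexes[[i]] <- combine_structures(receptor, make_pose(receptor, sp),
                                         id = ids[i])
  }
  attr(complexes, "archetype") <- stats::setNames(archetype, ids)
  complexes
}

#' Pocket fixture with a closed-form accessible volume
#'
#' Builds a shell (sphere) or box of wall pseudo-atoms (carbon, vdW 1.70)
#' enclosing an empty core. With clash removal at vdW radius + padding, the
#' accessible region is known in closed form: a sphere of radius
#' `wall_radius - vdw - padding`, or a box with each half-edge reduced by
#' `vdw + padding`. The generator rejects wall spacings coarse enough for
#' the lattice to leak between wall atoms.
#'
#' @param geometry "sphere_core" or "box_core".
#' @param wall_radius sphere geometry: wall shell radius, Angstrom.
#' @param half_lengths box geometry: half edge lengths of the wall box.
#' @param wall_atom_spacing approximate spacing between wall atoms,
#'   Angstrom.
#' @param padding clash padding the fixture is calibrated for (must match
#'   the `grid_spec` used for measuring), Angstrom.
#' @param seed integer seed (wall construction is deterministic; the seed
#'   only relabels the fixture).
#' @return list with `structure` (wall atoms), `analytic_volume` (A^3),
#'   `accessible_radius` or `accessible_half_lengths`, and `inclusion` (a
#'   covering inclusion `sphere_spec`).
#' @examples
#' fx <- make_pocket_fixture()  # r = 9 - 1.7 - 1.09 = 6.21 A, ~1003 A^3
#' fx$analytic_volume
#' @export
make_pocket_fixture <- function(geometry = c("sphere_core", "box_core"),
                                wall_radius = 9, half_lengths = c(8, 7, 6),
                                wall_atom_spacing = 1.0, padding = 1.09,
                                seed = 1L) {
  geometry <- match.arg(geometry)
  vdw <- unname(.vdw_table[["C"]])
  clash <- vdw + padding
  if (wall_atom_spacing > clash) {
    usage_error(sprintf(
      "wall_atom_spacing %.2f exceeds clash radius %.2f: cavity would leak",
      wall_atom_spacing, clash
    ))
  }
  if (geometry == "sphere_core") {
    r_acc <- wall_radius - clash
    if (r_acc <= 0) usage_error("wall_radius too small: no accessible core")
    n <- max(100L, ceiling(4 * pi * wall_radius^2 / wall_atom_spacing^2))
    # Fibonacci sphere: near-uniform coverage of the shell
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)
    theta <- pi * (1 + sqrt(5)) * i
    xyz <- wall_radius * cbind(sin(phi) * cos(theta),
                               sin(phi) * sin(theta),
                               cos(phi))
    analytic <- 4 / 3 * pi * r_acc^3
    inclusion <- sphere_spec(c(0, 0, 0), r_acc + 1)
    extra <- list(accessible_radius = r_acc)
  } else {
    acc <- half_lengths - clash
    if (any(acc <= 0)) usage_error("half_lengths too small: no accessible core")
    s <- wall_atom_spacing
    faces <- list()
    grid2 <- function(h1, h2) {
      as.matrix(expand.grid(seq(-h1, h1, by = s), seq(-h2, h2, by = s)))
    }
    g <- grid2(half_lengths[2], half_lengths[3])
    faces[[1]] <- cbind(half_lengths[1], g)
    faces[[2]] <- cbind(-half_lengths[1], g)
    g <- grid2(half_lengths[1], half_lengths[3])
    faces[[3]] <- cbind(g[, 1], half_lengths[2], g[, 2])
    faces[[4]] <- cbind(g[, 1], -half_lengths[2], g[, 2])
    g <- grid2(half_lengths[1], half_lengths[2])
    faces[[5]] <- cbind(g, half_lengths[3])
    faces[[6]] <- cbind(g, -half_lengths[3])
    xyz <- do.call(rbind, faces)
    analytic <- prod(2 * acc)
    # inclusion sphere: covers the accessible core corners, but stays
    # shielded by the walls (beyond any face plane it penetrates less than
    # the clash distance)
    r_inc <- sqrt(sum(acc^2)) + 0.2
    if (r_inc > min(half_lengths) + clash) {
      usage_error("box proportions too elongated for a shielded inclusion sphere")
    }
    inclusion <- sphere_spec(c(0, 0, 0), r_inc)
    extra <- list(accessible_half_lengths = acc)
  }
  st <- mol_structure(
    data.frame(
      name = "C", element = "C", chain = "X", res_num = 1L, res_name = "WAL",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_hetero = FALSE,
      stringsAsFactors = FALSE
    ),
    id = sprintf("pocket-fixture-%s-seed%d", geometry, seed)
  )
  c(list(structure = st, analytic_volume = analytic, inclusion = inclusion,
         padding = padding, geometry = geometry), extra)
}

#' Generate a synthetic Hill dose-response dataset
#'
#' Relative currents at the given concentrations from the Hill model, with
#' multiplicative Gaussian noise (`i_rel * (1 + e)`, `e ~ N(0, noise_sd)`,
#' truncated at 0). The default design is 8 log-spaced concentrations over
#' [IC50/100, IC50*100] in triplicate with 3% noise — the simulation
#' conditions used throughout the package's recovery studies.
#'
#' @param ic50 generating IC50, nM.
#' @param n_h generating Hill coefficient.
#' @param a generating maximal inhibition.
#' @param concentrations optional explicit concentration vector, nM.
#' @param n_rep replicates per concentration.
#' @param noise_sd multiplicative noise sd.
#' @param seed integer RNG seed.
#' @return A `dose_response` data.frame aggregated per concentration (mean,
#'   sd, n), with the replicate-level values in `attr(, "replicates")`.
#' @export
make_dose_response <- function(ic50, n_h = 1, a = 1, concentrations = NULL,
                               n_rep = 3L, noise_sd = 0.03, seed = 1L) {
  if (ic50 <= 0) usage_error("ic50 must be > 0")
  if (is.null(concentrations)) {
    concentrations <- exp(seq(log(ic50 / 100), log(ic50 * 100), length.out = 8))
  }
  with_seed(seed, {
    conc <- rep(concentrations, each = n_rep)
    mu <- hill_model(conc, ic50, n_h, a)
    y <- pmax(0, mu * (1 + stats::rnorm(length(conc), sd = noise_sd)))
    reps <- data.frame(concentration_nM = conc, i_rel = y,
                       replicate = rep(seq_len(n_rep), times = length(concentrations)))
    agg_mean <- tapply(y, conc, mean)
    agg_sd <- tapply(y, conc, stats::sd)
    cs <- as.numeric(names(agg_mean))
    ord <- order(cs)
    out <- dose_response_points(cs[ord], as.numeric(agg_mean)[ord],
                                sd = as.numeric(agg_sd)[ord],
                                n_obs = rep(n_rep, length(cs)))
    attr(out, "replicates") <- reps
    out
  })
}
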