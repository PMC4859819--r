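#' Simulated recovery of a mutant/wild-type fold change
#'
#' Benchmarks the dose-response pipeline end to end: for each seed, synthetic
#' datasets are generated for the wild-type and one mutant receptor from the
#' published parameter estimates ([reference_ic50_panel()]; 8 log-spaced
#' concentrations centred on each receptor's IC50, triplicate, multiplicative
#' noise), both are fitted with [fit_hill()] (the maximal inhibition is fixed
#' to 1 exactly where the published fit fixed it), and the IC50 fold change is
#' formed with [ic50_ratio()].
#'
#' @param glun1,glun2b mutation labels identifying the mutant row (e.g.
#'   `glun1 = "Y109S"`, `glun2b = "wt"`).
#' @param compound "ifenprodil" or "EVT-101".
#' @param n_seeds number of simulation replicates.
#' @param noise_sd multiplicative noise level.
#' @param n_rep replicates per concentration.
#' @param n_h generating Hill coefficient.
#' @param seed base seed; per-replicate seeds are derived from it.
#' @return list with `ratios` (per-seed fold changes), `expected` (the
#'   published printed ratio, NA when censored), and the mutant/wt rows used.
#' @examples
#' \donttest{
#' rec <- simulate_ratio_recovery("wt", "F114S", "EVT-101", n_seeds = 3)
#' mean(rec$ratios)   # ~56
#' }
#' @export
simulate_ratio_recovery <- function(glun1, glun2b, compound,
                                    n_seeds = 10L, noise_sd = 0.03,
                                    n_rep = 3L, n_h = 1, seed = 1L) {
  panel <- reference_ic50_panel(compound)
  wt <- panel[panel$glun1 == "wt" & panel$glun2b == "wt", ]
  mut <- panel[panel$glun1 == glun1 & panel$glun2b == glun2b, ]
  if (nrow(mut) != 1L) {
    usage_error(sprintf("no unique panel row for %s/%s with %s",
                        glun1, glun2b, compound))
  }
  if (mut$censored) {
    usage_error("censored (bound-only) IC50 rows cannot be simulated for ratios")
  }
  ratios <- vapply(seq_len(n_seeds), function(i) {
    base <- as.integer(seed) * 1000L + 2L * i
    pts_wt <- make_dose_response(wt$ic50_nM, n_h = n_h, a = wt$max_inhib,
                                 n_rep = n_rep, noise_sd = noise_sd,
                                 seed = base)
    pts_mut <- make_dose_response(mut$ic50_nM, n_h = n_h, a = mut$max_inhib,
                                  n_rep = n_rep, noise_sd = noise_sd,
                                  seed = base + 1L)
    fit_wt <- fit_hill(pts_wt, fix_a = wt$a_fixed)
    fit_mut <- fit_hill(pts_mut, fix_a = mut$a_fixed)
    ic50_ratio(fit_mut, fit_wt)
  }, 1.0)
  list(ratios = ratios, expected = mut$ratio_printed, mutant = mut, wt = wt)
}

#' Simulated two-class binding-mode recovery rate
#'
#' Runs the full synthetic pipeline — receptor, two-archetype pose set,
#' fingerprints, euclidean distances, agglomerative clustering, 50%
#' relative-height cut — once per seed and scores whether exactly two
#' clusters are found with no archetype mixing.
#'
#' @param n_seeds number of independent pose-set simulations.
#' @param n_per_class poses per archetype.
#' @param jitter_sd pose jitter, Angstrom.
#' @param linkage linkage method.
#' @param seed base seed.
#' @return list with `success_rate` (fraction of seeds recovering the
#'   designed partition) and the per-seed logical vector `pure`.
#' @export
simulate_mode_recovery <- function(n_seeds = 100L, n_per_class = 10L,
                                   jitter_sd = 0.3, linkage = "complete",
                                   seed = 1L) {
  receptor <- make_two_chain_receptor(seed)
  panel <- interface_panel()
  pure <- vapply(seq_len(n_seeds), function(i) {
    cxs <- make_pose_set(receptor, n_per_class, jitter_sd,
                         seed = as.integer(seed) * 1000L + i)
    fm <- fingerprint_matrix(cxs, "LIG", panel)
    asg <- cut_dendrogram(agglomerate(row_distances(fm), linkage),
                          "relative_height", 0.5)
    truth <- attr(cxs, "archetype")
    asg$k == 2L &&
      all(vapply(split(asg$labels, truth[names(asg$labels)]),
                 function(x) length(unique(x)) == 1L, TRUE))
  }, TRUE)
  list(success_rate = mean(pure), pure = pure)
}
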