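#' Published dose-response parameters for the GluN1/GluN2B mutant panel
#'
#' The wild-type and mutant receptor IC50 and maximal-inhibition estimates
#' for ifenprodil and EVT-101 used to parameterise simulations and to
#' benchmark fold-change recovery. One row per (receptor, compound). IC50
#' values reported only as a bound (">10000 nM") are censored: `ic50_nM` is
#' the bound, `censored` is `TRUE`, and such rows are excluded from ratio
#' arithmetic. The relative MK-801 inhibition time constant (`rel_tau_on`,
#' an index of channel open probability) is carried as given data; it is
#' never recomputed here.
#'
#' @param compound optionally restrict to "ifenprodil" or "EVT-101".
#' @param include_censored keep censored rows (default `TRUE`).
#' @return data.frame with columns `glun1`, `glun2b`, `receptor`,
#'   `compound`, `ic50_nM`, `ic50_sd_nM`, `censored`, `max_inhib`,
#'   `max_inhib_sd`, `a_fixed`, `ratio_printed` (NA when censored or not
#'   determined), `rel_tau_on`, `n_cells`.
#' @examples
#' p <- reference_ic50_panel("EVT-101")
#' subset(p, receptor == "wt/wt")$ic50_nM  # 12
#' @export
reference_ic50_panel <- function(compound = NULL, include_censored = TRUE) {
  row <- function(glun1, glun2b, cmpd, ic50, sd, cens, a, a_sd, a_fix,
                  ratio, tau, n) {
    data.frame(
      glun1 = glun1, glun2b = glun2b,
      receptor = paste(glun1, glun2b, sep = "/"),
      compound = cmpd, ic50_nM = ic50, ic50_sd_nM = sd, censored = cens,
      max_inhib = a, max_inhib_sd = a_sd, a_fixed = a_fix,
      ratio_printed = ratio, rel_tau_on = tau, n_cells = n,
      stringsAsFactors = FALSE
    )
  }
  ife <- rbind(
    row("wt",    "wt",    "ifenprodil",   130,   4, FALSE, 0.95, 0.01, FALSE,  1.0, 1.0, 12),
    row("Y109C", "wt",    "ifenprodil",   856, 122, FALSE, 1.00,   NA, TRUE,   6.6, 1.1,  4),
    row("Y109S", "wt",    "ifenprodil",   224,  36, FALSE, 0.97, 0.07, FALSE,  1.7, 0.7,  4),
    row("I133A", "wt",    "ifenprodil",    80,   7, FALSE, 0.69, 0.02, FALSE,  0.6, 2.9,  3),
    row("I133C", "wt",    "ifenprodil",  1400, 104, FALSE, 1.00,   NA, TRUE,  11,   0.6,  4),
    row("I133W", "wt",    "ifenprodil",    32,   5, FALSE, 0.47, 0.02, FALSE,  0.3, 2.6,  5),
    row("L135A", "wt",    "ifenprodil",   101,   9, FALSE, 0.90, 0.03, FALSE,  0.8, 5.4,  5),
    row("L135H", "wt",    "ifenprodil", 10000,  NA, TRUE,  1.00,   NA, TRUE,   NA,  6.0,  3),
    row("L135M", "wt",    "ifenprodil",    73,   2, FALSE, 0.86, 0.01, FALSE,  0.6, 2.4,  3),
    row("L135R", "wt",    "ifenprodil",   300,  36, FALSE, 1.00,   NA, TRUE,   2.3, 3.5,  3),
    row("L135W", "wt",    "ifenprodil",   767,  78, FALSE, 1.00,   NA, TRUE,   5.9, 2.1,  5),
    row("wt",    "Q110G", "ifenprodil",   124,   3, FALSE, 0.99, 0.01, FALSE,  1.0, 0.4,  3),
    row("wt",    "F114S", "ifenprodil", 10000,  NA, TRUE,  1.00,   NA, TRUE,   NA,  0.4,  4),
    row("wt",    "A135G", "ifenprodil",    50,   3, FALSE, 0.80, 0.01, FALSE,  0.4, 3.0,  4),
    row("wt",    "A135P", "ifenprodil",   587,  43, FALSE, 1.00,   NA, TRUE,   4.5, 2.1,  3),
    row("wt",    "F176A", "ifenprodil",  7500,  58, FALSE, 1.00,   NA, TRUE,  58,   1.3,  4),
    row("wt",    "P177C", "ifenprodil", 10000,  NA, TRUE,  1.00,   NA, TRUE,   NA,  2.7,  6),
    row("wt",    "E236C", "ifenprodil",  1800,  14, FALSE, 1.00,   NA, TRUE,  14,   0.9,  4)
  )
  evt <- rbind(
    row("wt",    "wt",    "EVT-101",      12,  0.2, FALSE, 0.90, 0.01, FALSE,   1.0, 1.0, 12),
    row("Y109C", "wt",    "EVT-101",    7300,  260, FALSE, 1.00,   NA, TRUE,  608,   1.1,  3),
    row("Y109S", "wt",    "EVT-101",    9618,  700, FALSE, 1.00,   NA, TRUE,  800,   0.7,  3),
    row("I133A", "wt",    "EVT-101",      52,    4, FALSE, 0.65, 0.01, FALSE,   4.3, 2.9,  4),
    row("I133C", "wt",    "EVT-101",      62,   22, FALSE, 0.48, 0.03, FALSE,   5.2, 0.6,  3),
    row("I133W", "wt",    "EVT-101",      32,    9, FALSE, 0.54, 0.03, FALSE,   2.7, 2.6,  3),
    row("L135A", "wt",    "EVT-101",      25,    2, FALSE, 0.60, 0.01, FALSE,   2.0, 5.4,  8),
    row("L135H", "wt",    "EVT-101",      71,    7, FALSE, 0.48, 0.01, FALSE,   5.9, 6.0,  3),
    row("L135R", "wt",    "EVT-101",      53,    6, FALSE, 0.69, 0.02, FALSE,   4.4, 3.5,  3),
    row("L135W", "wt",    "EVT-101",       9,    1, FALSE, 0.86, 0.02, FALSE,   0.7, 2.1,  6),
    row("wt",    "Q110G", "EVT-101",     502,   14, FALSE, 0.97, 0.01, FALSE,  42,   0.4,  3),
    row("wt",    "F114S", "EVT-101",     676,   10, FALSE, 0.91, 0.01, FALSE,  56,   0.4,  3),
    row("wt",    "A135G", "EVT-101",      72,    7, FALSE, 0.80, 0.02, FALSE,   6.0, 3.0,  3),
    row("wt",    "A135P", "EVT-101",     404,   15, FALSE, 0.78, 0.02, FALSE,  34,   2.1,  3),
    row("wt",    "F176A", "EVT-101",   11400, 1000, FALSE, 1.00,   NA, TRUE,  950,   1.3,  3),
    row("wt",    "P177C", "EVT-101",      75,   12, FALSE, 0.64, 0.03, FALSE,   6.2, 2.7,  5),
    row("wt",    "E236C", "EVT-101",     332,    2, FALSE, 0.87, 0.01, FALSE,  28,   0.9,  4)
  )
  out <- rbind(ife, evt)
  if (!is.null(compound)) {
    cmpd <- match.arg(compound, unique(out$compound))
    out <- out[out$compound == cmpd, , drop = FALSE]
  }
  if (!include_censored) out <- out[!out$censored, , drop = FALSE]
  rownames(out) <- NULL
  out
}
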