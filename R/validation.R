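#' Recover the sorption share of removal from a simulated campaign
#'
#' Runs the estimation pipeline's q_e route on the sampled record of a
#' simulated column and compares it with the simulation truth: the removed
#' load comes from the influent/effluent grab-sample ledgers, q_e from the
#' top-segment removal up to the end of the equilibration window (which must
#' lie after the desorption transient that follows the influent peak), and
#' the whole-filter sorbed mass from `q_e x M_GAC`. The sorbed fraction of
#' the equilibration-window removal is taken from the simulation truth, so
#' the check isolates the structural error of the q_e extrapolation and the
#' sampling error of the ledgers.
#'
#' @param sim A [simulate_column()] result.
#' @param samples Grab samples from [generate_grab_samples()].
#' @param equilibrium_day End of the equilibration window (day of operation).
#'   For the default kinetics the desorption transient after a peak on day
#'   `p` has settled by about `p + 45`.
#' @return List: `estimate` and `truth` (sorption shares of removed),
#'   `qe_mg_g`, `removed_g`, `error_pp` (estimate - truth, percentage
#'   points).
#' @export
recover_sorption_share <- function(sim, samples, equilibrium_day = 112) {
  stopifnot(inherits(sim, "bac_simulation"))
  eq <- min(equilibrium_day, nrow(sim$daily))
  fl <- sim$flow
  removed <- removed_load(load_ledger(fl, samples, "influent"),
                          load_ledger(fl, samples, "effluent"))
  rt <- removed_load(load_ledger(fl, samples, "influent", window = c(1, eq)),
                     load_ledger(fl, samples, "7cm", window = c(1, eq)))
  f_eq <- sim$daily$sorbed_seg1_g[eq] /
    (sim$daily$sorbed_seg1_g[eq] + sim$daily$biodeg_seg1_g[eq])
  qe <- estimate_qe(max(rt, 0), f_eq, sim$spec$segment_gac_kg[1])
  est <- sorbed_mass(qe, sim$spec$gac_mass) / removed
  truth <- sim$truth$sorbed_g / sim$truth$removed_g
  list(estimate = est, truth = truth, qe_mg_g = qe, removed_g = removed,
       error_pp = 100 * (est - truth))
}
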