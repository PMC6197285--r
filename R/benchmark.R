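#' Self-consistency benchmark of the WCS indices
#'
#' Simulates dyads whose joint decisions follow the confidence-sharing rule
#' exactly — the generative model under which the Weighted Confidence Sharing
#' prediction holds — and measures each dyad with the full psychometric
#' pipeline. Under this null the optimality index `S_dyad/S_WCS` converges to
#' 1 as the trial count grows, and for members of equal sensitivity the
#' collective benefit `S_dyad/S_max` converges to `sqrt(2)`.
#'
#' Member noise SDs are drawn uniformly from `sigma_range` (pass equal
#' endpoints for identical observers); biases are fixed at `b`. Each dyad gets
#' its own design and behavioural seed derived from `seed`.
#'
#' @param n_dyads Number of simulated dyads.
#' @param sigma_range Length-2 range for each member's noise SD (contrast
#'   units).
#' @param b Common bias.
#' @param config [experiment_config()] for the trial schedule.
#' @param rule [joint_rule()] under which disagreements are resolved.
#' @param seed Root seed.
#' @return A data frame of per-dyad metrics (one [compute_dyad_summary()] row
#'   per dyad, plus the generative `sigma_m1`, `sigma_m2`).
#' @export
#' @examples
#' bench <- simulate_wcs_null(n_dyads = 20, seed = 1)
#' mean(bench$optimality)   # near 1
simulate_wcs_null <- function(n_dyads = 200L,
                              sigma_range = c(0.15, 0.25),
                              b = 0,
                              config = experiment_config(),
                              rule = joint_rule("wcs_confidence"),
                              seed = 1L) {
  if (length(sigma_range) == 1L) sigma_range <- rep(sigma_range, 2L)
  stopifnot(length(sigma_range) == 2L, all(sigma_range > 0))
  seeds <- child_seeds(seed, n_dyads)
  rows <- vector("list", n_dyads)
  for (i in seq_len(n_dyads)) {
    set.seed(seeds[i])
    sig <- stats::runif(2L, sigma_range[1L], sigma_range[2L])
    obs1 <- observer_params(b = b, sigma = sig[1L])
    obs2 <- observer_params(b = b, sigma = sig[2L])
    cfg <- config
    cfg$seed <- sample.int(2147483646L, 1L)
    behav_seed <- sample.int(2147483646L, 1L)
    log <- simulate_experiment(obs1, obs2, cfg, rule = rule, seed = behav_seed,
                               dyad_id = sprintf("dyad_%03d", i))
    row <- as.data.frame(compute_dyad_summary(log))
    row$sigma_m1 <- sig[1L]
    row$sigma_m2 <- sig[2L]
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
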