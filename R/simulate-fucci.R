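# Synthetic Fucci2BL reporter traces. The reporter marks G1/G0 by red
# (mCherry-hCdt1), S by yellow (both probes), and G2/M by green
# (mVenus-hGem). Under sustained enzalutamide the G0 (red-only) fraction
# rises gradually to a plateau; drug washout restores the cycling mixture.

#' Simulate weekly Fucci2BL fluorescence traces
#'
#' For each cell and week a cell-cycle state is drawn and red/green
#' intensities are emitted from well-separated on/off lognormal
#' distributions. During a run of consecutive `ENZA` weeks the probability of
#' the red-only G0 state rises linearly from `baseline_g0` to `plateau` over
#' `ramp_weeks` weeks; under any other condition (and after washout) the
#' stationary cycling mixture applies, so removing enzalutamide restores
#' red/yellow/green heterogeneity.
#'
#' @param n_cells number of cells imaged each week.
#' @param schedule character vector of per-week treatment labels, each one of
#'   [apdt_conditions()]; e.g. `c("ENZA","ENZA","ENZA","ENZA","VEH")` is four
#'   weeks of enzalutamide followed by washout.
#' @param plateau G0 probability reached after `ramp_weeks` of enzalutamide.
#' @param baseline_g0 G0 probability of the cycling (non-ENZA) mixture; the
#'   remaining mass is split between S and G2/M as `cycling_s_g2m`.
#' @param ramp_weeks weeks of enzalutamide needed to reach the plateau.
#' @param cycling_s_g2m length-2 positive weights for S and G2/M within the
#'   non-G0 mass.
#' @param intensity_on,intensity_off `c(meanlog, sdlog)` of the lognormal
#'   on/off intensity distributions (arbitrary units).
#' @param seed RNG seed.
#' @return Long-format data.frame: `cell_id`, `week`, `treatment`, `red`,
#'   `green`, `true_state`.
#' @export
simulate_fucci <- function(n_cells = 200L,
                           schedule = c("ENZA", "ENZA", "ENZA", "ENZA", "VEH"),
                           plateau = 0.9,
                           baseline_g0 = 0.25,
                           ramp_weeks = 4L,
                           cycling_s_g2m = c(0.45, 0.55),
                           intensity_on = c(meanlog = log(500), sdlog = 0.3),
                           intensity_off = c(meanlog = log(20), sdlog = 0.4),
                           seed = 1L) {
  if (length(schedule) < 1L) stop("schedule must have at least one week")
  bad <- setdiff(schedule, apdt_conditions())
  if (length(bad) > 0L)
    stop("unknown treatment label(s): ", paste(unique(bad), collapse = ", "))
  if (plateau < 0 || plateau > 1 || baseline_g0 < 0 || baseline_g0 > 1)
    stop("plateau and baseline_g0 must be probabilities")
  set.seed(seed)

  states <- c("G1_G0", "S", "G2_M")
  w_sg <- cycling_s_g2m / sum(cycling_s_g2m)
  enza_run <- 0L
  out <- vector("list", length(schedule))
  for (t in seq_along(schedule)) {
    enza_run <- if (schedule[t] == "ENZA") enza_run + 1L else 0L
    p_g0 <- if (enza_run > 0L)
      baseline_g0 + (plateau - baseline_g0) * min(enza_run, ramp_weeks) / ramp_weeks
    else baseline_g0
    probs <- c(p_g0, (1 - p_g0) * w_sg)
    st <- sample(states, n_cells, replace = TRUE, prob = probs)
    red_on <- st %in% c("G1_G0", "S")
    green_on <- st %in% c("S", "G2_M")
    draw <- function(on) ifelse(
      on,
      stats::rlnorm(n_cells, intensity_on[[1L]], intensity_on[[2L]]),
      stats::rlnorm(n_cells, intensity_off[[1L]], intensity_off[[2L]]))
    out[[t]] <- data.frame(
      cell_id = sprintf("c%04d", seq_len(n_cells)),
      week = t, treatment = schedule[t],
      red = draw(red_on), green = draw(green_on),
      true_state = st, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write Fucci traces as long-format TSV
#' @param traces data.frame from [simulate_fucci()].
#' @param path output path.
#' @export
write_fucci_tsv <- function(traces, path) {
  utils::write.table(traces, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
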