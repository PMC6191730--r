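#' Ground-truth tracer kinetics parameters for one patient
#'
#' Parameters of the six-compartment model (pharynx, upper / mid / lower
#' oesophagus, stomach, lungs) that generates a patient's tracer kinetics.
#' The swallowed bolus transits to the stomach within the first frame,
#' leaving a small oesophageal residue; the stomach empties first-order with
#' half-time \code{gastric_half_time}; reflux events arrive as a Poisson
#' process at the posture-specific rate, each instantaneously moving
#' \code{reflux_fraction} of the current gastric activity up to
#' \code{max_reflux_height} (spread equally over the traversed
#' compartments); oesophageal and pharyngeal activity clears back to the
#' stomach first-order at \code{clearance_rate}; during pharyngeal events a
#' fraction \code{aspiration_fraction} of the pharyngeal share is trapped
#' irreversibly in the lungs. All activity decays with the Tc-99m physical
#' half-life.
#'
#' @param gastric_half_time gastric emptying half-time, minutes (> 0)
#' @param reflux_event_rate_upright reflux events per minute when upright
#' @param reflux_event_rate_supine reflux events per minute when supine
#' @param max_reflux_height highest compartment reached by reflux events:
#'   one of \code{"lower"}, \code{"mid"}, \code{"upper"}, \code{"pharynx"}
#' @param reflux_fraction fraction of gastric activity moved per event (0-1)
#' @param clearance_rate oesophageal clearance rate, per minute (lower with
#'   more severe ineffective oesophageal motility)
#' @param aspiration_fraction fraction of the pharyngeal share of an event
#'   trapped in the lungs (0-1); must be 0 unless
#'   \code{max_reflux_height == "pharynx"}
#' @param administered_activity administered Tc-99m DTPA activity, MBq
#'   (40-60)
#' @param colloid_activity activity of the second (colloid) administration,
#'   MBq; defaults to \code{administered_activity}
#' @param transit_residue_fraction fraction of the bolus left lining the
#'   oesophagus and pharynx after the initial swallow; distributed
#'   distally-weighted (50\% lower, 30\% mid, 16.5\% upper oesophagus,
#'   3.5\% pharynx), as most post-swallow residue coats the distal
#'   oesophagus and the pharynx is rinsed by the water flush
#' @param residue_clearance_rate washout rate (per minute) of the adherent
#'   mucosal film left by the initial swallow; salivary washout of the
#'   coating is much slower than bolus transit, so this is separate from
#'   \code{clearance_rate}
#' @return an object of class \code{kinetics_params}
#' @export
kinetics_params <- function(gastric_half_time = 25.2,
                            reflux_event_rate_upright = 0.5,
                            reflux_event_rate_supine = 0.3,
                            max_reflux_height = "pharynx",
                            reflux_fraction = 0.05,
                            clearance_rate = 0.5,
                            aspiration_fraction = 0,
                            administered_activity = 50,
                            colloid_activity = administered_activity,
                            transit_residue_fraction = 0.02,
                            residue_clearance_rate = 0.08) {
  vals <- c(gastric_half_time, reflux_event_rate_upright,
            reflux_event_rate_supine, reflux_fraction, clearance_rate,
            aspiration_fraction, administered_activity, colloid_activity,
            transit_residue_fraction, residue_clearance_rate)
  if (any(!is.finite(vals)))
    stop("kinetics_params: all parameters must be finite numbers")
  max_reflux_height <- match.arg(max_reflux_height, REFLUX_HEIGHTS)
  if (gastric_half_time <= 0)
    stop("kinetics_params: gastric_half_time must be > 0")
  if (reflux_event_rate_upright < 0 || reflux_event_rate_supine < 0 ||
      clearance_rate < 0 || residue_clearance_rate < 0)
    stop("kinetics_params: rates must be >= 0")
  if (reflux_fraction < 0 || reflux_fraction > 1 ||
      aspiration_fraction < 0 || aspiration_fraction > 1 ||
      transit_residue_fraction < 0 || transit_residue_fraction > 1)
    stop("kinetics_params: fractions must lie in [0, 1]")
  if (administered_activity < 40 || administered_activity > 60)
    stop("kinetics_params: administered_activity must lie in [40, 60] MBq")
  if (aspiration_fraction > 0 && max_reflux_height != "pharynx")
    stop("kinetics_params: aspiration_fraction > 0 requires max_reflux_height == 'pharynx'")
  structure(list(gastric_half_time = gastric_half_time,
                 reflux_event_rate_upright = reflux_event_rate_upright,
                 reflux_event_rate_supine = reflux_event_rate_supine,
                 max_reflux_height = max_reflux_height,
                 reflux_fraction = reflux_fraction,
                 clearance_rate = clearance_rate,
                 aspiration_fraction = aspiration_fraction,
                 administered_activity = administered_activity,
                 colloid_activity = colloid_activity,
                 transit_residue_fraction = transit_residue_fraction,
                 residue_clearance_rate = residue_clearance_rate),
            class = "kinetics_params")
}

# Analytic evolution of the decay-corrected state over dt minutes with no
# events: refluxed oesophageal activity clears to the stomach at kc, the
# adherent mucosal residue at kr, the stomach empties at lam_e; lungs and
# past emptying are untouched. Conservation is exact by construction
# (emptied is computed as the balance).
.evolve_state <- function(state, dt, kc, kr, lam_e) {
  if (dt <= 0) return(state)
  oes <- c("pharynx", "upper", "mid", "lower")
  res <- paste0("res_", oes)
  E0 <- sum(state[oes])
  R0 <- sum(state[res])
  s0 <- state["stomach"]
  fe <- exp(-lam_e * dt)
  inflow <- function(k, P0) {  # contribution of a pool clearing at k into the stomach
    if (P0 == 0) return(0)
    if (abs(lam_e - k) > 1e-12) k * P0 * (exp(-k * dt) - fe) / (lam_e - k)
    else k * P0 * dt * fe
  }
  s_new <- s0 * fe + inflow(kc, E0) + inflow(kr, R0)
  state[oes] <- state[oes] * exp(-kc * dt)
  state[res] <- state[res] * exp(-kr * dt)
  state["emptied"] <- state["emptied"] +
    (s0 + E0 + R0) - s_new - sum(state[oes]) - sum(state[res])
  state["stomach"] <- s_new
  state
}

.apply_reflux_event <- function(state, params) {
  h <- match(params$max_reflux_height, REFLUX_HEIGHTS)  # 1 = lower .. 4 = pharynx
  moved <- params$reflux_fraction * state["stomach"]
  if (moved <= 0) return(state)
  share <- moved / h
  comps <- REFLUX_HEIGHTS[seq_len(h)]
  state[comps] <- state[comps] + share
  if (params$max_reflux_height == "pharynx" && params$aspiration_fraction > 0) {
    asp <- params$aspiration_fraction * share
    state["pharynx"] <- state["pharynx"] - asp
    state["lungs"] <- state["lungs"] + asp
  }
  state["stomach"] <- state["stomach"] - moved
  state
}

#' Simulate compartmental tracer kinetics for one patient
#'
#' Runs the six-compartment reflux model over the full study timeline:
#' upright dynamic acquisition, supine dynamic acquisition, an interim
#' upright period after the colloid administration, and the delayed static
#' time point. Activities (MBq, physical, i.e. including isotope decay) are
#' reported at every frame midpoint of both dynamic segments plus the
#' delayed time point. The colloid administration re-labels the gastric
#' compartment with fresh activity at the end of supine imaging.
#'
#' @param params a \code{\link{kinetics_params}} object
#' @param protocol an \code{\link{acquisition_protocol}}
#' @param seed integer seed for the Poisson event process
#' @return a data frame of class \code{kinetics_series} with columns
#'   \code{time_min} (minutes since DTPA administration), \code{phase}
#'   (\code{upright}/\code{supine}/\code{delayed}), one column per
#'   compartment (MBq), \code{emptied} (cumulative gastric outflow, decayed
#'   to the same time) and \code{administered_cum} (total administered
#'   activity decayed to the same time, so that the row sum of compartments
#'   plus \code{emptied} equals it exactly)
#' @export
simulate_kinetics <- function(params, protocol = acquisition_protocol(),
                              seed = 1L) {
  stopifnot(inherits(params, "kinetics_params"))
  lam <- decay_lambda_per_min(protocol)
  lam_e <- log(2) / params$gastric_half_time
  kc <- params$clearance_rate
  kr <- params$residue_clearance_rate

  upright_end <- protocol$upright_duration_seconds / 60
  supine_end <- upright_end + protocol$supine_duration_seconds / 60
  colloid_time <- supine_end
  delayed_time <- colloid_time + protocol$delayed_time_minutes

  # sample times: frame midpoints (minutes since t = 0) plus delayed point
  t_up <- (seq_len(protocol$upright_n_frames) - 0.5) *
    protocol$upright_frame_seconds / 60
  t_sup <- upright_end + (seq_len(protocol$supine_n_frames) - 0.5) *
    protocol$supine_frame_seconds / 60
  sample_times <- c(t_up, t_sup, delayed_time)
  phases <- c(rep("upright", length(t_up)), rep("supine", length(t_sup)),
              "delayed")

  # Poisson reflux event times per posture segment
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  seg <- rbind(c(0, upright_end, params$reflux_event_rate_upright),
               c(upright_end, supine_end, params$reflux_event_rate_supine),
               c(supine_end, delayed_time, params$reflux_event_rate_upright))
  event_times <- numeric(0)
  for (i in seq_len(nrow(seg))) {
    len <- seg[i, 2] - seg[i, 1]
    n <- if (seg[i, 3] > 0) stats::rpois(1, seg[i, 3] * len) else 0L
    if (n > 0) event_times <- c(event_times, seg[i, 1] + sort(stats::runif(n)) * len)
  }

  # decay-corrected state (reference time t = 0); res_* pools hold the
  # adherent mucosal film left by the initial swallow
  state <- c(pharynx = 0, upper = 0, mid = 0, lower = 0, stomach = 0,
             lungs = 0, emptied = 0,
             res_pharynx = 0, res_upper = 0, res_mid = 0, res_lower = 0)
  A <- params$administered_activity
  res <- A * params$transit_residue_fraction
  state[c("res_pharynx", "res_upper", "res_mid", "res_lower")] <-
    res * c(0.035, 0.165, 0.3, 0.5)
  state["stomach"] <- A - res
  administered <- A  # decay-corrected cumulative administration

  actions <- rbind(
    data.frame(time = event_times, what = rep("event", length(event_times))),
    data.frame(time = colloid_time, what = "colloid"),
    data.frame(time = sample_times, what = "sample")
  )
  # colloid applies before any event/sample at the identical instant
  actions <- actions[order(actions$time, match(actions$what, c("colloid", "event", "sample"))), ]

  out <- matrix(NA_real_, nrow = length(sample_times), ncol = 9)
  colnames(out) <- c("time_min", COMPARTMENTS, "emptied", "administered_cum")
  k <- 1L
  now <- 0
  for (i in seq_len(nrow(actions))) {
    state <- .evolve_state(state, actions$time[i] - now, kc, kr, lam_e)
    now <- actions$time[i]
    switch(actions$what[i],
      event = { state <- .apply_reflux_event(state, params) },
      colloid = {
        add <- params$colloid_activity * exp(lam * now)
        state["stomach"] <- state["stomach"] + add
        administered <- administered + add
      },
      sample = {
        decay <- exp(-lam * now)
        comp <- state[COMPARTMENTS]
        oes <- c("pharynx", "upper", "mid", "lower")
        comp[oes] <- comp[oes] + state[paste0("res_", oes)]
        out[k, ] <- c(now, comp * decay,
                      state["emptied"] * decay, administered * decay)
        k <- k + 1L
      })
  }
  df <- as.data.frame(out)
  df$phase <- phases
  df <- df[, c("time_min", "phase", COMPARTMENTS, "emptied", "administered_cum")]
  attr(df, "params") <- params
  attr(df, "event_times") <- event_times
  class(df) <- c("kinetics_series", "data.frame")
  df
}
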