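# Spiking theta-gamma buffer: after-depolarization (ADP) working-memory
# maintenance, feedback inhibition for gamma-slot segregation, and the
# cross-buffer excitation/inhibition that conceptually aligns the question
# buffer (qWM) to the answer buffer (aWM).
#
# Voltages are relative to rest (0 mV). A neuron fires when
#   theta(t) + ADP(t - last spike) + synaptic input >= threshold.
# The ADP is a saturating ramp peaking near one theta period after the last
# spike, so an active ensemble re-fires once per theta cycle at a preserved
# phase; feedback inhibition after each ensemble volley keeps distinct
# ensembles in distinct gamma subcycles.

#' Configuration of a spiking theta-gamma buffer
#'
#' Defaults reproduce the published alignment simulation: ADP amplitude
#' 6.7 mV, cross-buffer excitation 6 mV with a 7 ms decay, cross-buffer
#' inhibition -2 mV and feedback inhibition with a 3 ms decay. Theta drive
#' amplitude, spike threshold, ADP kernel shape and feedback-inhibition
#' amplitude are not constrained by those values and are set here so that (a)
#' an ensemble's ADP plus theta crosses threshold once per cycle at a
#' preserved phase, (b) the net cross-buffer kick (the counterpart EPSP plus
#' the inhibition the same firing ensemble delivers) plus theta stays
#' subthreshold for a neuron without ADP, so alignment can move active
#' ensembles but never recruit silent ones, and (c) seven gamma slots fit in
#' the suprathreshold window of a theta cycle.
#'
#' @param n_per_pattern neurons per ensemble (pattern).
#' @param theta_period theta cycle length, ms.
#' @param A_theta theta drive amplitude, mV.
#' @param threshold spike threshold above rest, mV.
#' @param A_ADP ADP amplitude, mV.
#' @param t_ADP_peak time of ADP saturation after a spike, ms.
#' @param tau_ADP steepness of the ADP rise, ms.
#' @param t_ADP_fall centre of the slow ADP decay, ms.
#' @param tau_ADP_fall time constant of the decay, ms.
#' @param A_exc cross-buffer excitation amplitude (aWM neuron i to qWM neuron
#'   i), mV.
#' @param t_exc decay time constant of the cross-buffer excitation, ms.
#' @param A_inh_cross cross-buffer inhibition, mV, delivered once per
#'   synchronously firing aWM ensemble to all non-corresponding qWM neurons.
#' @param t_inh decay time constant of inhibition, ms.
#' @param A_fb within-buffer feedback inhibition per firing ensemble, mV.
#' @param refractory absolute refractory period, ms.
#' @param dt integration step, ms (must be smaller than `t_inh`).
#' @return an object of class `tqa_spiking_config`.
#' @export
spiking_buffer_config <- function(n_per_pattern = 10L,
                                  theta_period = 140,
                                  A_theta = 4,
                                  threshold = 8.5,
                                  A_ADP = 6.7,
                                  t_ADP_peak = theta_period,
                                  tau_ADP = 4,
                                  t_ADP_fall = t_ADP_peak + 40,
                                  tau_ADP_fall = 8,
                                  A_exc = 6,
                                  t_exc = 7,
                                  A_inh_cross = -2,
                                  t_inh = 3,
                                  A_fb = -2.5,
                                  refractory = 2,
                                  dt = 0.05) {
  cfg <- list(n_per_pattern = as.integer(n_per_pattern),
              theta_period = theta_period, A_theta = A_theta,
              threshold = threshold, A_ADP = A_ADP,
              t_ADP_peak = t_ADP_peak, tau_ADP = tau_ADP,
              t_ADP_fall = t_ADP_fall, tau_ADP_fall = tau_ADP_fall,
              A_exc = A_exc, t_exc = t_exc, A_inh_cross = A_inh_cross,
              t_inh = t_inh, A_fb = A_fb, refractory = refractory, dt = dt)
  tc <- c(theta_period = cfg$theta_period, t_exc = cfg$t_exc,
          t_inh = cfg$t_inh, tau_ADP = cfg$tau_ADP,
          tau_ADP_fall = cfg$tau_ADP_fall, dt = cfg$dt,
          refractory = cfg$refractory)
  if (any(tc <= 0))
    stop("all time constants must be positive: ",
         paste(names(tc)[tc <= 0], collapse = ", "))
  if (cfg$dt >= cfg$t_inh)
    stop("dt must be smaller than the inhibitory time constant t_inh")
  structure(cfg, class = "tqa_spiking_config")
}

# ADP kernel: logistic rise saturating at A_ADP near t_ADP_peak, multiplied by
# a slow logistic decay so a neuron silent for several cycles loses its slot.
.adp_kernel <- function(s, cfg) {
  rise <- stats::plogis((s - (cfg$t_ADP_peak - cfg$tau_ADP)) / cfg$tau_ADP)
  fall <- stats::plogis((cfg$t_ADP_fall - s) / cfg$tau_ADP_fall)
  v <- cfg$A_ADP * rise * fall
  v[!is.finite(v)] <- 0
  v
}

#' Default gamma-slot initialization times within the first theta cycle
#'
#' Slots are spread over the suprathreshold window of the theta cycle (where
#' theta plus a saturated ADP can reach threshold). Larger slot counts start
#' earlier on the rising theta phase, where small inhibition-induced delays
#' self-correct (a delayed ensemble meets a higher theta drive and recovers);
#' slots far past the theta peak would instead drift later each cycle.
#'
#' @param k number of slots.
#' @param config a `tqa_spiking_config`.
#' @return numeric vector of k spike times, ms.
#' @export
default_slot_times <- function(k, config = spiking_buffer_config()) {
  if (k <= 5L) 28 + 4 * (seq_len(k) - 1) else 12 + 4 * (seq_len(k) - 1)
}

.check_patterns <- function(patterns, label) {
  if (length(patterns) == 0L) stop(label, ": at least one pattern required")
  if (is.null(names(patterns)) || any(!nzchar(names(patterns))))
    stop(label, ": patterns must be named")
  ids <- unlist(patterns)
  if (anyDuplicated(ids))
    stop(label, ": patterns overlap; gamma-slot identity would be undefined")
  invisible(TRUE)
}

# Core two-buffer engine. `buffers` is a list of up to two buffer specs
# (patterns, init_times, n_neurons); buffer 1 ("aWM") drives buffer 2 ("qWM")
# through one-to-one excitation and ensemble-normalized all-to-all inhibition
# when `coupled` is TRUE. The first theta cycle is the initialization: the
# given patterns are clamped to fire at their initial times, free dynamics
# start with cycle 2.
.run_spiking <- function(config, buffers, n_theta, coupled) {
  cfg <- config
  dt <- cfg$dt
  t_end <- n_theta * cfg$theta_period
  steps <- seq(0, t_end - dt, by = dt)
  dec_inh <- exp(-dt / cfg$t_inh)
  dec_exc <- exp(-dt / cfg$t_exc)

  nb <- length(buffers)
  st <- lapply(buffers, function(b) {
    n <- b$n_neurons
    forced <- vector("list", length(steps))
    for (p in names(b$patterns)) {
      k <- findInterval(b$init_times[[p]], steps)
      forced[[k]] <- c(forced[[k]], b$patterns[[p]])
    }
    list(n = n, last = rep(-Inf, n), fb = 0,
         exc = numeric(n), cinh = numeric(n),
         forced = forced, spikes_t = list(), spikes_id = list())
  })

  for (si in seq_along(steps)) {
    t <- steps[si]
    theta_v <- cfg$A_theta * sin(2 * pi * t / cfg$theta_period)
    free <- t >= cfg$theta_period
    for (b in seq_len(nb)) {
      s <- st[[b]]
      s$fb <- s$fb * dec_inh
      s$exc <- s$exc * dec_exc
      s$cinh <- s$cinh * dec_inh
      since <- t - s$last
      v <- theta_v + .adp_kernel(since, cfg) + s$fb + s$exc + s$cinh
      fired <- if (free)
        which(v >= cfg$threshold & since >= cfg$refractory)
      else integer(0)
      fired <- union(fired, s$forced[[si]])
      if (length(fired)) {
        s$last[fired] <- t
        s$spikes_t[[length(s$spikes_t) + 1L]] <- rep(t, length(fired))
        s$spikes_id[[length(s$spikes_id) + 1L]] <- fired
        s$fb <- s$fb + cfg$A_fb * length(fired) / cfg$n_per_pattern
        if (coupled && b == 1L && nb == 2L) {
          q <- st[[2L]]
          hit <- fired[fired <= q$n]
          q$exc[hit] <- q$exc[hit] + cfg$A_exc
          counterpart_fired <- numeric(q$n)
          counterpart_fired[hit] <- 1
          q$cinh <- q$cinh + cfg$A_inh_cross *
            (length(fired) - counterpart_fired) / cfg$n_per_pattern
          st[[2L]] <- q
        }
      }
      st[[b]] <- s
    }
  }

  lapply(seq_len(nb), function(b) {
    s <- st[[b]]
    pat_of <- rep(NA_character_, s$n)
    for (p in names(buffers[[b]]$patterns))
      pat_of[buffers[[b]]$patterns[[p]]] <- p
    times <- unlist(s$spikes_t)
    ids <- unlist(s$spikes_id)
    if (is.null(times)) times <- numeric(0)
    if (is.null(ids)) ids <- integer(0)
    data.frame(neuron_id = ids, spike_time_ms = times,
               pattern = pat_of[ids],
               cycle = floor(times / cfg$theta_period) + 1L)
  })
}

# median firing time of each ensemble per theta cycle
.ensemble_times <- function(raster) {
  if (nrow(raster) == 0L)
    return(data.frame(pattern = character(), cycle = integer(),
                      time = numeric()))
  ag <- stats::aggregate(spike_time_ms ~ pattern + cycle,
                         data = raster[!is.na(raster$pattern), ],
                         FUN = stats::median)
  names(ag)[names(ag) == "spike_time_ms"] <- "time"
  ag[order(ag$cycle, ag$time), ]
}

#' Simulate a single spiking theta-gamma buffer
#'
#' Each initialized pattern fires as a synchronous ensemble once per theta
#' cycle; distinct patterns keep distinct gamma subcycles. The simulation is
#' fully deterministic.
#'
#' @param config a `tqa_spiking_config`.
#' @param initial_patterns named list of disjoint neuron-index sets.
#' @param n_theta number of theta cycles (>= 1); cycle 1 initializes.
#' @param init_times optional named spike times within cycle 1, ms; defaults
#'   to [default_slot_times()] in list order.
#' @return spike raster data frame (`neuron_id`, `spike_time_ms`, `pattern`,
#'   `cycle`) with a `"diagnostics"` attribute holding ensemble firing times
#'   and the pattern-to-slot map per cycle.
#' @export
simulate_buffer <- function(config, initial_patterns, n_theta,
                            init_times = NULL) {
  stopifnot(inherits(config, "tqa_spiking_config"), n_theta >= 1)
  .check_patterns(initial_patterns, "initial_patterns")
  if (is.null(init_times))
    init_times <- stats::setNames(
      default_slot_times(length(initial_patterns), config),
      names(initial_patterns))
  n <- max(unlist(initial_patterns))
  raster <- .run_spiking(config,
                         list(list(patterns = initial_patterns,
                                   init_times = init_times,
                                   n_neurons = n)),
                         n_theta, coupled = FALSE)[[1]]
  ens <- .ensemble_times(raster)
  ens$slot <- stats::ave(ens$time, ens$cycle,
                         FUN = function(x) rank(x, ties.method = "first"))
  attr(raster, "diagnostics") <- ens
  raster
}

#' Align a question buffer to an answer buffer by spiking dynamics
#'
#' Runs both buffers with one-to-one excitatory and ensemble-normalized
#' inhibitory connections from aWM to qWM. The aWM slot structure is
#' self-maintained; the qWM ensembles are pulled into the gamma slots of their
#' aWM counterparts.
#'
#' @param qwm_patterns,awm_patterns named lists of disjoint neuron-index sets;
#'   names identify corresponding patterns across buffers, and neuron i in aWM
#'   corresponds to neuron i in qWM.
#' @param config a `tqa_spiking_config`.
#' @param n_theta number of theta cycles to run (cycle 1 initializes).
#' @param qwm_init_times,awm_init_times named initial spike times, ms.
#' @return an object of class `tqa_alignment`: rasters for both buffers,
#'   ensemble/slot diagnostics per cycle, the convergence cycle, and the
#'   final-cycle qWM slot assignment.
#' @export
align_buffers <- function(qwm_patterns, awm_patterns,
                          config = spiking_buffer_config(),
                          n_theta = 4L,
                          qwm_init_times = NULL, awm_init_times = NULL) {
  stopifnot(inherits(config, "tqa_spiking_config"), n_theta >= 2)
  .check_patterns(qwm_patterns, "qwm_patterns")
  .check_patterns(awm_patterns, "awm_patterns")
  if (is.null(awm_init_times))
    awm_init_times <- stats::setNames(
      default_slot_times(length(awm_patterns), config), names(awm_patterns))
  if (is.null(qwm_init_times))
    qwm_init_times <- stats::setNames(
      default_slot_times(length(qwm_patterns), config), names(qwm_patterns))
  n_a <- max(unlist(awm_patterns))
  n_q <- max(unlist(qwm_patterns))
  out <- .run_spiking(config,
                      list(list(patterns = awm_patterns,
                                init_times = awm_init_times,
                                n_neurons = n_a),
                           list(patterns = qwm_patterns,
                                init_times = qwm_init_times,
                                n_neurons = max(n_q, n_a))),
                      n_theta, coupled = TRUE)
  awm_raster <- out[[1]]
  qwm_raster <- out[[2]]
  a_ens <- .ensemble_times(awm_raster)
  q_ens <- .ensemble_times(qwm_raster)

  cycles <- sort(unique(a_ens$cycle))
  slot_map <- list()
  aligned <- logical(length(cycles))
  names(aligned) <- cycles
  for (ci in seq_along(cycles)) {
    cy <- cycles[ci]
    a_cy <- a_ens[a_ens$cycle == cy, ]
    a_cy <- a_cy[order(a_cy$time), ]
    pitch <- if (nrow(a_cy) > 1L) stats::median(diff(a_cy$time)) else
      config$theta_period / wm_capacity()
    q_cy <- q_ens[q_ens$cycle == cy, ]
    q_slot <- vapply(seq_len(nrow(q_cy)), function(i) {
      d <- abs(a_cy$time - q_cy$time[i])
      if (length(d) && min(d) <= pitch / 2) which.min(d)
      else as.integer(round((q_cy$time[i] - a_cy$time[1]) / pitch) + 1L)
    }, integer(1))
    slot_map[[as.character(cy)]] <-
      data.frame(pattern = q_cy$pattern, time = q_cy$time, slot = q_slot,
                 cycle = cy)
    shared <- intersect(q_cy$pattern, a_cy$pattern)
    aligned[ci] <- length(shared) == length(q_cy$pattern) &&
      all(vapply(shared, function(p) {
        abs(q_cy$time[q_cy$pattern == p] - a_cy$time[a_cy$pattern == p]) <=
          pitch / 2
      }, logical(1)))
  }
  conv <- NA_integer_
  for (ci in seq_along(cycles)) {
    if (cycles[ci] >= 2L && all(aligned[ci:length(cycles)])) {
      conv <- cycles[ci]
      break
    }
  }
  final_map <- slot_map[[as.character(max(cycles))]]
  structure(list(qwm_raster = qwm_raster, awm_raster = awm_raster,
                 qwm_ensembles = q_ens, awm_ensembles = a_ens,
                 slot_map = slot_map, final_slots = final_map,
                 aligned_by_cycle = aligned,
                 convergence_cycle = conv,
                 n_theta = n_theta, config = config),
            class = "tqa_alignment")
}

#' Gamma-slot separation of two question-buffer patterns after alignment
#'
#' @param alignment a `tqa_alignment`.
#' @param p1,p2 pattern names.
#' @return separation in gamma cycles (integer), measured in the final theta
#'   cycle against the answer buffer's slot grid.
#' @export
slot_separation <- function(alignment, p1, p2) {
  fm <- alignment$final_slots
  s1 <- fm$slot[fm$pattern == p1]
  s2 <- fm$slot[fm$pattern == p2]
  if (length(s1) != 1L || length(s2) != 1L)
    stop("pattern missing from the final cycle: ",
         paste(setdiff(c(p1, p2), fm$pattern), collapse = ", "))
  abs(s1 - s2)
}

#' @export
print.tqa_alignment <- function(x, ...) {
  cat("spiking buffer alignment:", x$n_theta, "theta cycles\n")
  cat("  converged at theta cycle:", x$convergence_cycle, "\n")
  cat("  final qWM slots:\n")
  print(x$final_slots, row.names = FALSE)
  invisible(x)
}

#' Write a spike raster as tab-separated text
#'
#' @param raster a raster data frame (from [simulate_buffer()] or an
#'   alignment result).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_raster <- function(raster, path) {
  utils::write.table(raster[, c("neuron_id", "spike_time_ms")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot raster(s) of an alignment simulation
#'
#' @param alignment a `tqa_alignment`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the alignment.
#' @export
plot_alignment <- function(alignment, ...) {
  qr <- alignment$qwm_raster
  ar <- alignment$awm_raster
  n_a <- max(ar$neuron_id, 1L)
  graphics::plot(ar$spike_time_ms, ar$neuron_id, pch = 20, col = "blue",
                 xlab = "time (ms)", ylab = "neuron",
                 ylim = c(0, n_a * 2 + 1), ...)
  graphics::points(qr$spike_time_ms, qr$neuron_id + n_a, pch = 20,
                   col = "red")
  graphics::abline(v = alignment$config$theta_period *
                     seq_len(alignment$n_theta - 1), lty = 3)
  invisible(alignment)
}
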