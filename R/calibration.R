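# Protocol-design math for the pulsed-gradient spin-echo (PGSE) sequence:
# the rectangular-pulse b-value and the TE_max / b_max bounds obtained from a
# total signal-floor criterion split equally over the T2 and diffusion decays.

#' PGSE pulse timing
#'
#' @param G gradient magnitude (T/m).
#' @param delta gradient pulse width (s).
#' @param Delta pulse separation (s); must exceed `delta`.
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1).
#' @return object of class `pulse_timing` with derived `q = gamma*delta*G`
#'   (rad/m) and diffusion time `tau = Delta - delta/3` (s).
#' @export
pulse_timing <- function(G, delta, Delta, gamma = GAMMA_WATER) {
  stopifnot(is_scalar_num(G), is_scalar_num(delta), is_scalar_num(Delta))
  if (G < 0) stopf("pulse_timing: G must be >= 0")
  if (delta <= 0 || delta >= Delta) stopf("pulse_timing: need 0 < delta < Delta")
  structure(list(G = G, delta = delta, Delta = Delta, gamma = gamma,
                 q = gamma * delta * G, tau = Delta - delta / 3),
            class = "pulse_timing")
}

#' Rectangular-pulse b-value
#'
#' b = (gamma G delta)^2 (Delta - delta/3), i.e. b = q^2 tau, under the
#' rectangular-gradient approximation. SI evaluation gives s/m^2; the result
#' is returned in the conventional s/mm^2 (divide by 1e6).
#'
#' @param timing a [pulse_timing()].
#' @return b-value in s/mm^2.
#' @export
compute_b <- function(timing) {
  stopifnot(inherits(timing, "pulse_timing"))
  (timing$q^2 * timing$tau) / 1e6
}

#' Invert the rectangular-pulse b-value for the gradient magnitude
#'
#' @param b target b-value (s/mm^2).
#' @param delta,Delta pulse width and separation (s).
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1).
#' @return gradient magnitude G (T/m) such that `compute_b` reproduces `b`.
#' @export
invert_b <- function(b, delta, Delta, gamma = GAMMA_WATER) {
  if (b < 0) stopf("invert_b: b must be >= 0")
  if (delta <= 0 || delta >= Delta) stopf("invert_b: need 0 < delta < Delta")
  tau <- Delta - delta / 3
  sqrt(b * 1e6 / tau) / (gamma * delta)
}

#' Signal-floor criterion
#'
#' The minimum acceptable value of the product e^(-TE/T2) * e^(-b D), split
#' equally over the two decays: each factor must stay at or above
#' sqrt(total_floor).
#'
#' @param total_floor total floor in (0, 1); default 0.05.
#' @return object of class `signal_floor` with `total_floor` and `per_decay_floor`.
#' @export
signal_floor <- function(total_floor = 0.05) {
  stopifnot(is_scalar_num(total_floor))
  if (total_floor <= 0 || total_floor >= 1) stopf("signal_floor: total_floor must be in (0, 1)")
  structure(list(total_floor = total_floor, per_decay_floor = sqrt(total_floor)),
            class = "signal_floor")
}

#' Maximum echo time under the signal-floor criterion
#'
#' TE_max = -T2 * ln(per_decay_floor): the largest TE for which the T2 decay
#' e^(-TE/T2) stays at or above its share of the floor.
#'
#' @param t2 transverse relaxation time (ms), > 0.
#' @param floor a [signal_floor()].
#' @return TE_max in ms (unrounded; see [report_te_max()] for the integer form).
#' @export
compute_te_max <- function(t2, floor = signal_floor()) {
  stopifnot(inherits(floor, "signal_floor"))
  if (!is_scalar_num(t2) || t2 <= 0) stopf("compute_te_max: t2 must be > 0")
  -t2 * log(floor$per_decay_floor)
}

#' Maximum diffusion sensitization under the signal-floor criterion
#'
#' b_max = -ln(per_decay_floor) / D: the largest b for which the diffusion
#' decay e^(-b D) stays at or above its share of the floor.
#'
#' @param d mean diffusivity (mm^2/s), > 0.
#' @param floor a [signal_floor()].
#' @return b_max in s/mm^2 (unrounded; see [report_b_max()] for the integer form).
#' @export
compute_b_max <- function(d, floor = signal_floor()) {
  stopifnot(inherits(floor, "signal_floor"))
  if (!is_scalar_num(d) || d <= 0) stopf("compute_b_max: d must be > 0")
  -log(floor$per_decay_floor) / d
}

#' Integer-reported calibration bounds
#'
#' The protocol convention: TE_max rounded to the nearest millisecond, b_max
#' floored to an integer number of s/mm^2.
#'
#' @inheritParams compute_te_max
#' @return integer ms / integer s/mm^2.
#' @export
report_te_max <- function(t2, floor = signal_floor()) {
  as.integer(round(compute_te_max(t2, floor)))
}

#' @rdname report_te_max
#' @inheritParams compute_b_max
#' @export
report_b_max <- function(d, floor = signal_floor()) {
  as.integer(base::floor(compute_b_max(d, floor)))
}
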