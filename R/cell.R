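#' Cylindrical cell geometry
#'
#' @param diameter_um,length_um Cylinder dimensions in micrometres (> 0).
#' @return A `cell_geometry` object.
#' @export
cell_geometry <- function(diameter_um = 40, length_um = 40) {
  if (diameter_um <= 0 || length_um <= 0) stop("dimensions must be positive")
  structure(list(diameter_um = diameter_um, length_um = length_um),
            class = "cell_geometry")
}

#' Membrane surface area of a cylinder
#'
#' `pi * d * L`, plus both end caps (`2 * pi * (d/2)^2`) when requested.
#' The package default everywhere is cap-inclusive: with the default HEK
#' geometry and passive conductance this is the convention that yields the
#' canonical 947 MOhm input resistance (a cap-less cylinder gives ~1421
#' MOhm).  Set `include_end_caps = FALSE` for the lateral-surface-only
#' (NEURON-style) convention.
#'
#' @param geometry A `cell_geometry`.
#' @param include_end_caps Include the two circular end caps (default TRUE).
#' @return Area in square micrometres.
#' @export
surface_area <- function(geometry, include_end_caps = TRUE) {
  stopifnot(inherits(geometry, "cell_geometry"))
  a <- pi * geometry$diameter_um * geometry$length_um
  if (include_end_caps) a <- a + 2 * pi * (geometry$diameter_um / 2)^2
  a
}

#' Single-compartment cell model
#'
#' Geometry plus passive membrane and the potassium reversal potential.  The
#' cytoplasmic resistivity `Ra` is carried for fidelity to the source model
#' definition but is unused in a single compartment.
#'
#' @param geometry A `cell_geometry`.
#' @param g_pas Passive (leak) conductance density, S/cm^2 (>= 0).
#' @param e_pas Leak reversal / resting potential, mV.
#' @param cm Specific membrane capacitance, uF/cm^2 (> 0).
#' @param Ra Cytoplasmic resistivity, Ohm*cm (unused in one compartment).
#' @param E_K Potassium reversal potential, mV.
#' @param channels List of `channel_model` objects (may be empty).
#' @param include_end_caps Area convention; see [surface_area()].
#' @return A `cell_model` object.
#' @export
cell_model <- function(geometry = cell_geometry(), g_pas = 1.4e-5,
                       e_pas = -60, cm = 5, Ra = 100, E_K = -97.5,
                       channels = list(), include_end_caps = TRUE) {
  stopifnot(inherits(geometry, "cell_geometry"), g_pas >= 0, cm > 0)
  if (inherits(channels, "channel_model")) channels <- list(channels)
  for (ch in channels) stopifnot(inherits(ch, "channel_model"))
  structure(list(geometry = geometry, g_pas = g_pas, e_pas = e_pas, cm = cm,
                 Ra = Ra, E_K = E_K, channels = channels,
                 include_end_caps = include_end_caps),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf(
    "<cell_model> %g x %g um cylinder%s, g_pas %g S/cm^2, cm %g uF/cm^2\n",
    x$geometry$diameter_um, x$geometry$length_um,
    if (x$include_end_caps) " (+caps)" else "", x$g_pas, x$cm))
  cat(sprintf("  e_pas %g mV, E_K %g mV, R_in %.0f MOhm, C %.0f pF, %d channel(s)\n",
              x$e_pas, x$E_K, input_resistance(x), total_capacitance(x),
              length(x$channels)))
  invisible(x)
}

# internal: area in cm^2 under the cell's own convention
cell_area_cm2 <- function(cell) {
  surface_area(cell$geometry, cell$include_end_caps) * 1e-8
}

#' Input resistance of the passive cell
#'
#' `1 / (g_pas * area)` with the cell's area convention.
#'
#' @param cell A `cell_model`.
#' @return Resistance in MOhm.
#' @export
input_resistance <- function(cell) {
  stopifnot(inherits(cell, "cell_model"))
  if (cell$g_pas <= 0) stop("g_pas must be positive for a finite input resistance")
  1 / (cell$g_pas * cell_area_cm2(cell)) * 1e-6
}

#' Total membrane capacitance
#'
#' @param cell A `cell_model`.
#' @return Capacitance in pF.
#' @export
total_capacitance <- function(cell) {
  stopifnot(inherits(cell, "cell_model"))
  cell$cm * 1e-6 * cell_area_cm2(cell) * 1e12
}

#' Total passive conductance
#'
#' @param cell A `cell_model`.
#' @return Conductance in nS.
#' @export
total_leak_conductance <- function(cell) {
  cell$g_pas * cell_area_cm2(cell) * 1e9
}

#' Nernst equilibrium potential for K+
#'
#' `(R * T / F) * ln(K_out / K_in)`, in mV.  With the whole-cell solutions
#' used for HEK recordings (2.5 mM external, 120 mM internal K+) at 22 degC
#' room temperature this gives -98 mV to the nearest mV.
#'
#' @param K_out,K_in External / internal K+ concentration (mM, > 0).
#' @param temp_C Temperature in degrees Celsius.
#' @return Potential in mV.
#' @export
nernst_potential <- function(K_out = 2.5, K_in = 120, temp_C = 22) {
  if (K_out <= 0 || K_in <= 0) stop("concentrations must be positive")
  R <- 8.31446261815324   # J / (mol K)
  F <- 96485.33212        # C / mol
  T_abs <- temp_C + 273.15
  (R * T_abs / F) * log(K_out / K_in) * 1000
}

#' Holding current for a target membrane potential
#'
#' Steady-state injected current that holds the cell at `V`:
#' `g_pas_tot * (V - e_pas) + sum_i g_i_inf(V) * (V - E_K)`.
#'
#' @param cell A `cell_model`.
#' @param V Target membrane potential (mV).
#' @return Current in pA.
#' @export
holding_current <- function(cell, V) {
  stopifnot(inherits(cell, "cell_model"))
  area <- cell_area_cm2(cell)
  g_chan <- 0
  for (ch in cell$channels)
    g_chan <- g_chan + steady_conductance_density(V, ch) * area * 1e9
  total_leak_conductance(cell) * (V - cell$e_pas) + g_chan * (V - cell$E_K)
}
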