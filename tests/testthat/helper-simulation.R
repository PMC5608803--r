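# Shared builders for the study-condition fixtures used across test files.

default_protocol <- function() acquisition_protocol()

muscle_kinetics <- function() tissue_kinetics(ktrans = 0.045, ve = 0.08)

# Noise-free relaxation-rate curve of a tissue under the default protocol
# and a given AIF: Tofts concentration + linear relaxivity, returned on the
# acquisition grid in seconds.
noise_free_r1 <- function(kinetics, r10, aif = NULL,
                          protocol = default_protocol(), relaxivity = 4.7) {
  tt <- frame_times(protocol, "s")
  if (is.null(aif))
    aif <- aif_spec(arrival_time_s = protocol$n_baseline * protocol$dt_s)
  cp <- make_aif(aif, tt / 60)
  r1 <- concentration_to_r1(tofts_concentration(cp, kinetics), r10,
                            relaxivity)
  dynamic_series(tt, r1$values, unit = "1/s", time_unit = "s")
}

# Both-tissue noise-free curve pair sharing one AIF.
rr_toi_pair <- function(kinetics_toi, r10_toi = 1.0, aif = NULL,
                        kinetics_rr = muscle_kinetics(), r10_rr = 0.82) {
  list(rr = noise_free_r1(kinetics_rr, r10_rr, aif),
       toi = noise_free_r1(kinetics_toi, r10_toi, aif),
       r10_rr = r10_rr, r10_toi = r10_toi)
}

# Independent fine-grid convolution oracle for the Tofts integral: the
# sampled Cp is linearly interpolated onto a dt_fine grid and the
# convolution integral evaluated there by simple trapezoid sums, without
# touching the package's convolver.
tofts_fine_grid_oracle <- function(cp_values, times_min, ktrans, ve,
                                   dt_fine_s = 0.01) {
  tf <- seq(0, max(times_min) * 60, by = dt_fine_s) / 60
  cpf <- stats::approx(times_min, cp_values, xout = tf)$y
  kep <- ktrans / ve
  vapply(times_min, function(T) {
    i <- tf <= T + 1e-12
    x <- tf[i]
    if (length(x) < 2) return(0)
    f <- cpf[i] * exp(-kep * (T - x))
    sum(diff(x) * (f[-length(f)] + f[-1]) / 2) * ktrans
  }, numeric(1))
}
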