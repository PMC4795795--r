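# Small deterministic fixtures shared across tests.

# a reduced main-network population (keeps unit-level tests fast)
small_main_population <- function(N = 6, sigma = 15) {
  network_populations("main", N = N, sigma = sigma)
}

# one unit per call, as a one-row unit table
one_unit <- function(node, u, v = NA_real_, gain_sign = 1L, A = 30,
                     sigma = 15) {
  unit_spec(node = node, u = u, v = v, gain_sign = gain_sign, A = A,
            sigma = sigma)
}

# three noiseless toy units with exactly representable or well-posed optima;
# the eye unit's modulation onset (-35) keeps its gain un-clipped over the
# default task postures (HE >= -30), so its response is exactly a gain-scaled
# Gaussian with w = 1, g = 1/35
toy_units <- function() {
  rbind(one_unit("eye", u = 0, v = -35, gain_sign = 1L),
        one_unit("hand_dyn", u = 5),
        one_unit("eye_hand", u = 7.5, v = -10, gain_sign = 1L))
}

expect_angle_near <- function(angle, axis, tol) {
  expect_lt(axial_distance(angle, axis), tol)
}
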