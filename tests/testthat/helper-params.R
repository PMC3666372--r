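# Shared parameter blocks and small helpers for the test suite.

mat_default <- material_parameters()                    # normal lung tissue
mat_hardening <- material_parameters(-22.5e5, 1.26, -1.39e6)  # unstable point
geom_default <- lesion_geometry()
mem_default <- membrane_properties()
fluid_default <- fluid_properties()
groups_default <- nondimensional_groups()

# zero-amplitude breathing: constant baseline pressure (autonomous forcing)
quiet_breathing <- function() {
  breathing_model(data.frame(A = 0, f = 1, phi = 0))
}

# random physically-signed material parameters (log-uniform magnitudes)
random_material <- function() {
  material_parameters(-10^stats::runif(1, 5, 7), stats::runif(1, 0.05, 3),
                      -10^stats::runif(1, 5, 7))
}

# direct-arithmetic equilibrium coefficients for Table-2-style inputs
hand_coefficients <- function(c1, c2, c3, P_Pa, R = 1e-2, H = 1e-3) {
  F_bar <- P_Pa * R / (c1 * H)
  list(alpha = c1 * c2^2 * F_bar,
       beta = -c1 + 5 * c1 * c2 - 6 * c2^2 * c3,
       gamma = c1 - 3 * c1 * c2 + 4 * c2^2 * c3)
}
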