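# Published operating-condition and fitted-parameter tables for the
# cherry-seed study, embedded as plain constructors. These are inputs to
# the internal-consistency checks and convenient defaults for simulation;
# they are not recomputed by the package.

#' Experimental design of the cherry-seed extraction study
#'
#' The 15-run Box-Behnken design plus six additional runs: coded and
#' natural factor levels (pressure bar, temperature degC, CO2 flow kg/h),
#' the CO2 density at each operating point (kg/m^3) and the particle-size
#' fraction. Runs 20 and 21 repeat the (350, 70, 0.4) point with the
#' <800 um and >800 um sieve fractions; all other runs use the 741 um
#' milled material.
#'
#' @return A data.frame with one row per run (21 rows).
#' @export
sfe_design_table <- function() {
  df <- data.frame(
    run = 1:21,
    P_coded = c(-1, 1, 0, 0, 0, 1, -1, -1, 1, 0, 0, -1, 0, 0, 1, 1, 1, -1, 1, 1, 1),
    T_coded = c(1, 0, -1, 1, -1, 1, 0, 0, -1, 1, 0, -1, 0, 0, 0, 1, -1, 1, 1, 1, 1),
    F_coded = c(0, -1, 1, -1, -1, 0, 1, -1, 0, 1, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1),
    pressure = c(200, 350, 275, 275, 275, 350, 200, 200, 350, 275, 275, 200,
                 275, 275, 350, 350, 350, 200, 350, 350, 350),
    temperature = c(70, 55, 40, 70, 40, 70, 55, 55, 40, 70, 55, 40, 55, 55,
                    55, 70, 40, 70, 70, 70, 70),
    flow = c(0.3, 0.2, 0.4, 0.2, 0.2, 0.3, 0.4, 0.2, 0.3, 0.4, 0.3, 0.3,
             0.3, 0.3, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4, 0.4),
    density = c(658.95, 881.30, 894.80, 762.35, 894.80, 826.30, 754.10,
                754.10, 934.90, 762.35, 830.45, 839.90, 830.45, 830.45,
                881.30, 826.30, 934.90, 658.95, 826.30, 826.30, 826.30),
    particle_label = c(rep("741", 19), "<800", ">800"),
    particle_um = c(rep(741, 19), 600, 900),
    block = c(rep("box-behnken", 15), rep("additional", 6)),
    stringsAsFactors = FALSE
  )
  df
}

#' Fitted pseudo-first-order parameters of the cherry-seed runs
#'
#' Asymptotic yield (percent of charge) and rate constant (1/min) of the
#' single-exponential model, one row per kinetic run 1-19.
#'
#' @return A data.frame with columns `run`, `Yinf`, `k`.
#' @export
model1_param_table <- function() {
  data.frame(
    run = 1:19,
    Yinf = c(5.13, 4.32, 2.97, 3.86, 3.02, 4.07, 6.48, 4.63, 4.88, 5.42,
             4.61, 4.78, 3.95, 3.81, 5.71, 5.71, 5.13, 4.42, 5.15),
    k = c(0.002, 0.009, 0.013, 0.004, 0.007, 0.011, 0.003, 0.002, 0.012,
          0.007, 0.007, 0.003, 0.008, 0.007, 0.012, 0.013, 0.014, 0.009,
          0.003)
  )
}

#' Fitted two-phase mass-balance coefficients of the cherry-seed runs
#'
#' Fluid-phase and solid-phase volumetric mass-transfer coefficients
#' (1/min) and the two switching times (min) of the time-switched global
#' coefficient, one row per kinetic run 1-19.
#'
#' @return A data.frame with columns `run`, `kf`, `ks`, `tc1`, `tc2`.
#' @export
model6_param_table <- function() {
  data.frame(
    run = 1:19,
    kf = c(0.050, 0.030, 0.044, 0.016, 0.025, 0.019, 0.026, 0.028, 0.023,
           0.023, 0.017, 0.019, 0.021, 0.040, 0.047, 0.041, 0.040, 0.022,
           0.028),
    ks = c(0.026, 0.029, 0.020, 0.025, 0.010, 0.024, 0.004, 0.019, 0.008,
           0.016, 0.011, 0.013, 0.022, 0.026, 0.030, 0.010, 0.028, 0.026,
           0.019),
    tc1 = c(194.46, 127.88, 180.00, 182.89, 118.63, 107.56, 192.19, 179.36,
            200.00, 184.45, 197.54, 130.21, 161.25, 164.86, 92.51, 195.64,
            188.37, 128.44, 44.56),
    tc2 = c(204.81, 217.03, 205.76, 295.91, 321.91, 348.93, 209.36, 373.64,
            493.26, 489.20, 464.52, 282.01, 334.66, 249.71, 499.689, 334.39,
            477.63, 417.75, 411.69)
  )
}

#' Fitted broken-and-intact-cells parameters of the cherry-seed runs
#'
#' Per-run charge composition and the fitted parameters of the two
#' analytical Sovova solutions: oil fraction `cu`, insoluble solid mass
#' `Nmg` (g), oil load `xu`, solvent-to-solid ratio `gamma`, grinding
#' efficiency `r`, internal coefficient `ks_as` (1/min), external and
#' internal transport resistances `tau_e`, `tau_i`, coefficient `beta`,
#' and the period boundaries `qm`, `qn` (kg CO2 / kg insoluble solid).
#' `ti` (min) and `t_prime` (min), `G`, `n` and `kf_a0` are carried as
#' metadata of the published fits.
#'
#' @return A data.frame with one row per kinetic run (19 rows).
#' @export
model8_param_table <- function() {
  data.frame(
    run = 1:19,
    cu = c(0.8, 0.84, 0.75, 0.8, 0.75, 0.82, 0.85, 0.8, 0.821, 0.87, 0.84,
           0.81, 0.805, 0.8, 0.84, 0.855, 0.835, 0.875, 0.8),
    n = c(4, 4, 3, 6, 5, 4, 5, 6, 4, 4, 5, 6, 4, 5, 4, 4, 4, 6, 4),
    Nmg = c(23.764, 19.011, 29.705, 23.764, 29.705, 21.388, 17.823, 23.764,
            21.269, 15.447, 19.011, 22.576, 23.17, 23.764, 19.011, 17.229,
            19.605, 14.852, 23.764),
    xu = c(4, 5.25, 3, 4, 3, 4.556, 5.667, 4, 4.587, 6.692, 5.25, 4.263,
           4.128, 4, 5.25, 5.897, 5.061, 7, 4),
    gamma = c(0.327, 0.437, 0.444, 0.378, 0.444, 0.41, 0.374, 0.374, 0.464,
              0.378, 0.412, 0.417, 0.412, 0.412, 0.437, 0.410, 0.464, 0.327,
              0.410),
    ti = c(372.99, 192.158, 86.507, 260.264, 128.779, 136.522, 310.699,
           472.761, 68.689, 233.799, 204.36, 258.224, 147.646, 155.992,
           53.969, 89.561, 64.359, 373.873, 254.62),
    G = c(0.102, 0.32, 0.337, 0.303, 0.362, 0.362, 0.162, 0.157, 0.41,
          0.242, 0.307, 0.295, 0.291, 0.347, 0.471, 0.433, 0.482, 0.367,
          0.146),
    t_prime = c(43.637, 52.612, 30, 86.675, 58.852, 41.524, 58.866, 90,
                45.964, 44.185, 60, 90.179, 45, 57.696, 45, 43.441, 45,
                83.298, 41.478),
    tau_e = c(0.023, 0.019, 0.024, 0.027, 0.024, 0.021, 0.024, 0.018,
              0.024, 0.027, 0.023, 0.025, 0.025, 0.024, 0.019, 0.023,
              0.026, 0.025, 0.025),
    kf_a0 = c(833.043, 625.744, 625.744, 418.445, 314.795, 833.043,
              1247.642, 625.744, 625.744, 1247.642, 833.043, 625.744,
              625.744, 625.744, 1247.642, 1247.642, 833.043, 1662.241,
              418.445),
    r = c(0.07, 0.271, 0.298, 0.21, 0.285, 0.309, 0.117, 0.081, 0.294,
          0.197, 0.25, 0.195, 0.229, 0.279, 0.252, 0.363, 0.383, 0.315,
          0.099),
    ks_as = c(0.033, 0.051, 0.114, 0.044, 0.084, 0.071, 0.043, 0.031,
              0.151, 0.042, 0.052, 0.046, 0.069, 0.07, 0.201, 0.108,
              0.151, 0.025, 0.047),
    qm = c(0.326, 0.277, 0.226, 0.65, 0.338, 0.388, 1.049, 0.325, 0.381,
           0.844, 0.771, 0.941, 0.395, 0.665, 0.34, 0.7, 0.669, 2.342,
           0.212),
    tau_i = c(576.228, 233.86, 133.366, 250.59, 90.354, 239.789, 703.984,
              366.712, 100.475, 817.438, 366.737, 344.703, 226.263,
              220.058, 119.523, 261.033, 146.096, 1636.46, 216.523),
    beta = c(0.94, 1.922, 1.893, 0.814, 0.813, 1.609, 0.705, 0.616, 0.874,
             1.98, 1.126, 0.759, 1.357, 0.932, 0.747, 1.26, 1.024, 1.782,
             1.018),
    qn = c(23.907, 17.652, 11.376, 39.538, 21.36, 23.604, 83.137, 39.529,
           23.14, 38.48, 46.95, 62.399, 21.177, 39.634, 28.358, 39.709,
           33.934, 116.163, 13.812)
  )
}
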