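# Reference constants for the '87-1' grape fertilization study: the
# orthogonal design doses, published summary tables used as inputs for
# verification and model construction, fertilizer product compositions,
# and nutrient demand constants.

#' Factor names of the fertilization design (oxide basis)
#' @keywords internal
.factors <- c("N", "P2O5", "K2O", "CaO", "MgO")

#' Short factor codes used in combination labels such as "N3P1K2Ca1Mg2"
#' @keywords internal
.factor_codes <- c(N = "N", P2O5 = "P", K2O = "K", CaO = "Ca", MgO = "Mg")

#' Elemental counterparts of the oxide factors
#' @keywords internal
.factor_elements <- c(N = "N", P2O5 = "P", K2O = "K", CaO = "Ca", MgO = "Mg")

#' Per-treatment quality summary of the five-year orthogonal trial
#'
#' Published annual-mean quality traits for the 16 treatments: single
#' fruit weight (SFW, g), total soluble solids (TSS, %), fruit firmness
#' (FF, g) and the TOPSIS fruit quality index (FQI). These serve as
#' verification inputs for range analysis and percent-change claims, and
#' as calibration targets for the synthetic generator.
#'
#' @return A data.frame with columns `treatment`, `SFW`, `TSS`, `FF`, `FQI`
#'   and their standard deviations (`*_sd`).
#' @export
quality_treatment_means <- function() {
  out <- data.frame(
    treatment = paste0("T", 1:16),
    SFW = c(4.77, 4.62, 4.64, 4.73, 5.09, 4.99, 4.75, 4.86,
            4.73, 4.83, 4.83, 4.54, 4.85, 4.47, 4.60, 4.98),
    SFW_sd = c(0.50, 0.26, 0.49, 0.34, 0.35, 0.51, 0.43, 0.42,
               0.78, 0.75, 0.67, 0.63, 0.48, 0.54, 0.48, 0.33),
    TSS = c(18.11, 17.85, 18.41, 17.89, 18.63, 18.47, 19.31, 19.26,
            18.67, 18.79, 19.20, 19.90, 18.50, 20.10, 19.36, 18.22),
    TSS_sd = c(1.10, 1.74, 1.01, 1.97, 0.65, 1.11, 1.39, 1.16,
               1.23, 1.42, 1.41, 2.26, 1.60, 2.17, 1.46, 1.33),
    FF = c(412.62, 420.17, 399.10, 427.92, 436.88, 381.79, 419.92, 402.00,
           455.11, 380.28, 430.42, 416.74, 414.53, 380.42, 404.23, 408.18),
    FF_sd = c(25.71, 49.90, 52.60, 62.74, 55.16, 15.14, 61.57, 15.51,
              95.64, 46.30, 44.80, 21.86, 23.05, 66.33, 27.20, 34.71),
    FQI = c(0.4123, 0.4265, 0.4064, 0.4491, 0.5181, 0.3620, 0.5221, 0.4569,
            0.6003, 0.3889, 0.5435, 0.5336, 0.4359, 0.4356, 0.4694, 0.4176),
    FQI_sd = c(0.1131, 0.2218, 0.1478, 0.1480, 0.1065, 0.1234, 0.1584,
               0.1332, 0.2408, 0.2002, 0.1867, 0.1396, 0.1383, 0.1644,
               0.1614, 0.2265),
    stringsAsFactors = FALSE
  )
  out
}

#' Published factor-level summary of the orthogonal trial
#'
#' The level-mean block of the trial report: per trait and factor, the
#' four level means (as printed, i.e. at 2 d.p.), the best level and the
#' factor F value. Kept verbatim because the published rounding chain
#' (treatment means -> level means) is not exactly recoverable from the
#' rounded treatment means.
#'
#' @return A data.frame with columns `trait`, `factor`, `L1`..`L4`,
#'   `best_level`, `f_value`.
#' @export
quality_level_means <- function() {
  traits <- rep(c("SFW", "TSS", "FF", "FQI"), each = 5)
  fac <- rep(.factors, times = 4)
  lv <- rbind(
    c(4.68, 4.95, 4.70, 4.73), c(4.85, 4.73, 4.70, 4.78),
    c(4.90, 4.70, 4.68, 4.78), c(4.65, 4.78, 4.88, 4.75),
    c(4.78, 4.78, 4.73, 4.78),
    c(18.06, 18.92, 19.14, 19.04), c(18.48, 18.80, 19.07, 18.81),
    c(18.50, 18.94, 19.11, 18.62), c(19.35, 18.70, 18.51, 18.60),
    c(18.88, 18.51, 18.82, 18.95),
    c(414.95, 410.15, 420.64, 401.84), c(429.79, 390.66, 413.42, 413.71),
    c(408.25, 419.51, 409.16, 410.66), c(407.43, 416.78, 406.11, 417.26),
    c(399.78, 425.84, 403.04, 418.91),
    c(0.4236, 0.4648, 0.5166, 0.4396), c(0.4916, 0.4032, 0.4854, 0.4643),
    c(0.4339, 0.4869, 0.4748, 0.4490), c(0.4759, 0.4657, 0.4328, 0.4702),
    c(0.4319, 0.4916, 0.4345, 0.4866)
  )
  data.frame(
    trait = traits, factor = fac,
    L1 = lv[, 1], L2 = lv[, 2], L3 = lv[, 3], L4 = lv[, 4],
    best_level = c(2, 1, 1, 3, 2,   # SFW (Mg best prints as 1/2/4; 2 used)
                   3, 3, 3, 1, 4,   # TSS
                   3, 1, 2, 4, 2,   # FF
                   3, 1, 2, 1, 2),  # FQI
    f_value = c(0.79, 0.33, 0.64, 0.88, 0.01,
                2.14, 0.52, 0.70, 1.27, 0.32,
                0.54, 2.19, 0.23, 0.30, 1.32,
                1.17, 1.15, 0.41, 0.27, 0.74),
    stringsAsFactors = FALSE
  )
}

#' Reference table of CND cumulative-variance cubic fits
#'
#' The published diagnostic table: for each plant or soil nutrient
#' variable, the cubic coefficients of the cumulative variance-ratio
#' function of normalized FQI, the fit R-squared, the inflection-point
#' cutoff `Y = -B/(3A)`, and the optimum nutrient ranges derived from the
#' per-variable cutoff (range 1) and from the communal cutoff 0.8151
#' (range 2). Coefficients are stored at the precision of the printed
#' functional relationship. `_R` rows are composite nutrient-ratio
#' variables retained for reporting only.
#'
#' @return A data.frame with columns `type` ("plant"/"soil"), `variable`,
#'   `A`, `B`, `C`, `D`, `r_squared`, `cutoff`, `range1_low`, `range1_high`,
#'   `range2_low`, `range2_high`.
#' @export
cnd_reference_table <- function() {
  m <- rbind(
    # variable             A         B         C         D        R2     Y
    c(-61.412,  150.17,  -191.27,  105.24,  0.9918,  0.8151),  # FBS_L_N
    c(-269.76,  533.91,  -368.98,  101.40,  0.9504,  0.6597),  # VS_P_P
    c( 123.71, -204.39,   -8.7805,  99.531, 0.9960,  0.5507),  # FBS_F_K
    c(  43.685, -50.586,  -94.536, 104.11,  0.9967,  0.3860),  # FBS_F_Ca
    c( 110.30, -154.03,   -54.098, 101.26,  0.9975,  0.4655),  # FBS_F_Mg
    c( -49.511, 107.22,  -157.32,  101.89,  0.9920,  0.7219),  # P_R
    c(  28.046, -20.587,  -96.761,  91.247, 0.9941,  0.2447),  # GS_N
    c(  36.006, -23.910,  -79.894,  70.590, 0.9550,  0.2214),  # GS_P
    c(   8.6264, 10.172, -118.34,  102.38,  0.9943, -0.3931),  # GS_K
    c(  62.153, -96.819,  -59.121,  94.235, 0.9978,  0.5193),  # GS_Ca
    c(  59.112, -38.225, -121.36,  104.55,  0.9938,  0.2156),  # GS_Mg
    c( -36.161,  96.896, -120.17,   60.185, 0.8850,  0.8932),  # GS_R
    c( 164.03, -228.51,   -33.682, 101.45,  0.9979,  0.4644),  # IFS_N
    c(   3.9675, 61.777, -166.95,  107.00,  0.9920, -5.1903),  # IFS_P
    c(  40.813, -40.888,  -93.662,  95.866, 0.9965,  0.3339),  # IFS_K
    c( 242.91, -373.00,    35.339,  98.462, 0.9966,  0.5118),  # IFS_Ca
    c( 123.40, -174.27,   -48.309, 101.60,  0.9980,  0.4707),  # IFS_Mg
    c(  78.171, -88.892,  -77.024,  91.917, 0.9934,  0.3790),  # IFS_R
    c( 147.11, -231.04,    -8.6896, 98.115, 0.9973,  0.5235),  # EBS_N
    c( 109.39, -170.67,   -33.997, 100.97,  0.9962,  0.5201),  # EBS_P
    c( -18.397,  27.472,  -84.172,  76.546, 0.9736,  0.4978),  # EBS_K
    c(  73.097, -111.06,   -56.813, 101.48, 0.9960,  0.5065),  # EBS_Ca
    c( -44.971, 100.51,  -146.64,   95.082, 0.9956,  0.7450),  # EBS_Mg
    c( 137.64, -205.95,   -22.919,  97.990, 0.9972,  0.4988),  # EBS_R
    c(  26.465,   4.702, -111.76,   82.782, 0.9866, -0.0592),  # VS_N
    c(  44.319, -37.040,  -94.919,  94.100, 0.9952,  0.2786),  # VS_P
    c(  14.899,  10.976, -126.11,  105.48,  0.9919, -0.2456),  # VS_K
    c( 133.93, -209.96,   -24.111, 101.95,  0.9974,  0.5226),  # VS_Ca
    c(-213.05,  404.96,  -266.02,   71.346, 0.8856,  0.6336),  # VS_Mg
    c( -32.596,  88.467, -123.67,   70.449, 0.9479,  0.9047),  # VS_R
    c(  70.275, -104.08,   -51.727,  85.866, 0.9905, 0.4937),  # MS_N
    c(  73.229, -94.688,   -69.975, 101.00,  0.9953, 0.4310),  # MS_P
    c(  51.873, -44.305,   -98.387, 101.85,  0.9945, 0.2847),  # MS_K
    c(  31.180, -52.216,   -63.023,  89.425, 0.9942, 0.5582),  # MS_Ca
    c( -47.682, 128.50,   -165.60,   86.876, 0.9881, 0.8983),  # MS_Mg
    c(-138.77,  261.57,   -166.14,   41.788, 0.5508, 0.6283)   # MS_R
  )
  vars <- c("FBS_L_N", "VS_P_P", "FBS_F_K", "FBS_F_Ca", "FBS_F_Mg", "P_R",
            "GS_N", "GS_P", "GS_K", "GS_Ca", "GS_Mg", "GS_R",
            "IFS_N", "IFS_P", "IFS_K", "IFS_Ca", "IFS_Mg", "IFS_R",
            "EBS_N", "EBS_P", "EBS_K", "EBS_Ca", "EBS_Mg", "EBS_R",
            "VS_N", "VS_P", "VS_K", "VS_Ca", "VS_Mg", "VS_R",
            "MS_N", "MS_P", "MS_K", "MS_Ca", "MS_Mg", "MS_R")
  r1 <- rbind(
    c(7.192, 12.516), c(3.097, 7.122), c(18.375, 27.350),
    c(23.801, 107.960), c(5.166, 21.232), c(NA, NA),
    c(0.017, 0.417), c(0.036, 1.542), c(0.126, 1.746),
    c(3.252, 9.250), c(0.339, 2.382), c(NA, NA),
    c(0.012, 1.034), c(0.215, 2.111), c(0.105, 1.696),
    c(2.702, 11.000), c(0.299, 1.886), c(NA, NA),
    c(0.017, 1.160), c(0.112, 1.591), c(0.148, 1.210),
    c(2.686, 8.473), c(0.428, 1.277), c(NA, NA),
    c(0.024, 0.966), c(0.119, 4.143), c(0.254, 1.212),
    c(3.043, 7.661), c(0.313, 1.197), c(NA, NA),
    c(0.021, 0.691), c(0.078, 1.258), c(0.127, 1.448),
    c(2.659, 8.777), c(0.326, 1.186), c(NA, NA)
  )
  r2 <- rbind(
    c(7.192, 12.516), c(3.097, 7.122), c(18.375, 27.350),
    c(23.801, 107.960), c(5.166, 21.232), c(NA, NA),
    c(0.017, 0.336), c(0.040, 1.394), c(0.126, 1.746),
    c(3.530, 9.208), c(0.414, 1.164), c(NA, NA),
    c(0.012, 0.590), c(0.249, 2.111), c(0.134, 1.592),
    c(2.702, 7.418), c(0.302, 1.208), c(NA, NA),
    c(0.017, 1.160), c(0.112, 1.591), c(0.148, 1.210),
    c(2.686, 8.231), c(0.428, 1.266), c(NA, NA),
    c(0.024, 0.735), c(0.119, 2.828), c(0.254, 1.212),
    c(3.043, 7.095), c(0.477, 1.197), c(NA, NA),
    c(0.021, 0.691), c(0.155, 1.258), c(0.249, 1.114),
    c(2.659, 8.777), c(0.391, 1.186), c(NA, NA)
  )
  data.frame(
    type = rep(c("plant", "soil"), c(6, 30)),
    variable = vars,
    A = m[, 1], B = m[, 2], C = m[, 3], D = m[, 4],
    r_squared = m[, 5], cutoff = m[, 6],
    range1_low = r1[, 1], range1_high = r1[, 2],
    range2_low = r2[, 1], range2_high = r2[, 2],
    stringsAsFactors = FALSE
  )
}

#' Verification-trial quality table (model-guided season)
#'
#' Quality traits and TOPSIS scores of the 18-treatment verification
#' season: the 16 original orthogonal treatments plus two plans (T17,
#' T18) derived from the precision fertilization model. Used to check
#' min-max FQI normalization and the high-FQI membership of the
#' model-guided treatments.
#'
#' @return A data.frame with columns `treatment`, `SFW`, `TSS`, `FF`,
#'   `FQI`, `ranking`, `fqi_norm`.
#' @export
verification_quality <- function() {
  data.frame(
    treatment = paste0("T", 1:18),
    SFW = c(3.3, 3.3, 3.8, 3.3, 3.3, 3.9, 3.2, 3.6, 3.2, 3.6,
            2.8, 3.6, 3.3, 3.4, 3.2, 3.6, 3.7, 3.6),
    TSS = c(17.8, 17.7, 17.1, 17.1, 16.1, 17.7, 16.8, 16.1, 17.7, 17.0,
            16.7, 15.2, 16.5, 17.4, 18.4, 17.4, 18.5, 17.9),
    FF = c(493.5, 507.3, 488.2, 505.6, 482.3, 503.9, 500.3, 536.4, 527.7,
           606.4, 447.2, 541.4, 562.9, 507.9, 512.0, 478.3, 572.0, 586.0),
    FQI = c(0.4718, 0.5080, 0.4087, 0.4434, 0.2527, 0.5182, 0.3882, 0.4737,
            0.5784, 0.7611, 0.2317, 0.4245, 0.5923, 0.4860, 0.5728, 0.4015,
            0.8322, 0.8434),
    ranking = c(11, 8, 14, 12, 17, 7, 16, 10, 5, 3, 18, 13, 4, 9, 6, 15,
                2, 1),
    fqi_norm = c(0.3925, 0.4517, 0.2894, 0.3461, 0.0343, 0.4684, 0.2558,
                 0.3956, 0.5668, 0.8655, 0.0000, 0.3152, 0.5895, 0.4157,
                 0.5576, 0.2776, 0.9817, 1.0000),
    stringsAsFactors = FALSE
  )
}

#' TOPSIS criterion weights for the fruit quality index
#'
#' The exogenous weights for SFW, TSS and FF. They are used as given
#' (sum 0.4337, not renormalized): the TOPSIS closeness coefficient is
#' invariant to a common scaling of the weights.
#'
#' @return Named numeric vector `c(SFW=, TSS=, FF=)`.
#' @export
fqi_weights <- function() {
  c(SFW = 0.0470, TSS = 0.2089, FF = 0.1778)
}

#' Measured stage-wise nutrient demand proportions
#'
#' Per-element proportion (%) of annual whole-plant uptake falling in each
#' of the five between-stage intervals, measured from the destructive
#' harvest series (three seasons). Each element's proportions sum to 100.
#'
#' @return A data.frame with columns `interval`, `element`, `proportion`,
#'   `proportion_sd`.
#' @export
demand_proportions <- function() {
  intervals <- c("GS-IFS", "IFS-EBS", "EBS-VS", "VS-MS", "MS-DS")
  data.frame(
    interval = rep(intervals, times = 5),
    element = rep(c("N", "P", "K", "Ca", "Mg"), each = 5),
    proportion = c(21.8, 20.1, 31.6, 8.8, 17.7,
                   18.2, 8.3, 27.1, 21.6, 24.8,
                   21.9, 6.7, 48.4, 7.1, 15.9,
                   19.7, 2.9, 10.3, 46.7, 20.4,
                   25.2, 17.7, 15.7, 3.8, 37.6),
    proportion_sd = c(2.4, 2.2, 5.7, 3.7, 3.4,
                      0.4, 2.0, 7.8, 2.3, 0.7,
                      0.8, 1.3, 6.0, 4.1, 2.6,
                      3.1, 1.3, 2.1, 3.2, 2.9,
                      1.6, 3.3, 4.2, 2.3, 1.4),
    stringsAsFactors = FALSE
  )
}

#' Field-scheme stage demand ratios (literature values)
#'
#' The stage demand ratios used to split annual fertilizer doses in the
#' '5416' field scheme (from earlier literature, not the harvest series
#' measured here; both constant sets are shipped, labelled by origin).
#'
#' @return A data.frame with columns `interval`, `element`, `ratio`.
#' @export
field_demand_ratios <- function() {
  intervals <- c("GS-IFS", "IFS-EBS", "EBS-VS", "VS-MS", "MS-DS")
  data.frame(
    interval = rep(intervals, times = 5),
    element = rep(c("N", "P", "K", "Ca", "Mg"), each = 5),
    ratio = c(14, 18, 52, 7, 9,
              4, 7, 54, 17, 18,
              13, 9, 60, 11, 7,
              7, 7, 64, 8, 14,
              8, 6, 64, 16, 6),
    stringsAsFactors = FALSE
  )
}

#' Reference whole-plant and fruit nutrient uptake per 1000 kg fruit
#'
#' Season-averaged uptake constants: total and fruit-only uptake (kg per
#' 1000 kg fruit produced) and the fruit-to-whole-plant uptake ratio FR
#' used by the precision fertilization model.
#'
#' @return A data.frame with columns `element`, `total_per_1000kg`,
#'   `fruit_per_1000kg`, `fruit_ratio`.
#' @export
uptake_reference <- function() {
  data.frame(
    element = c("N", "P", "K", "Ca", "Mg"),
    total_per_1000kg = c(4.37, 1.78, 4.84, 7.15, 1.04),
    fruit_per_1000kg = c(1.11, 0.32, 2.16, 1.17, 0.19),
    fruit_ratio = c(0.2531, 0.1775, 0.4465, 0.1640, 0.1795),
    stringsAsFactors = FALSE
  )
}

#' Stage-wise precision fertilization models
#'
#' The linear soil-test response models `y = a x + b` for each interval x
#' element (oxide basis), with the soil-test gate `x_max` attached: the
#' upper bound of optimum range 2 for the interval's start-stage soil
#' variable. `x` is the soil test (mg/g) at the start stage; `y` is the
#' fertilizer amount (kg, on the 1500 kg expected-yield basis).
#'
#' @return A data.frame with columns `interval`, `element` (oxide),
#'   `soil_element`, `start_stage`, `a`, `b`, `x_max`.
#' @export
fertilization_models <- function() {
  intervals <- c("GS-IFS", "IFS-EBS", "EBS-VS", "VS-MS", "MS-DS")
  ab <- rbind(
    c(-10.5800, 3.5549), c(-9.0830, 5.3590), c(-5.9055, 6.8504),
    c(-27.426, 20.158), c(-3.9179, 2.7073),
    c(-1.8744, 2.6130), c(-0.3029, 0.6394), c(-0.6673, 1.0617),
    c(-2.8106, 7.9485), c(-2.1732, 2.7338),
    c(-1.4583, 2.5463), c(-3.0093, 4.7907), c(-2.8602, 3.4608),
    c(-21.138, 25.619), c(-4.2919, 4.7812),
    c(-0.8322, 7.6625), c(-0.5010, 3.7161), c(-0.4261, 3.5069),
    c(-5.3307, 37.821), c(-0.4413, 3.8735),
    c(-1.1280, 1.3130), c(-1.2450, 1.5040), c(-1.0095, 1.2781),
    c(-12.533, 15.002), c(-2.8377, 3.3656)
  )
  out <- data.frame(
    interval = rep(intervals, times = 5),
    element = rep(.factors, each = 5),
    soil_element = rep(c("N", "P", "K", "Ca", "Mg"), each = 5),
    start_stage = rep(c("GS", "IFS", "EBS", "VS", "MS"), times = 5),
    a = ab[, 1], b = ab[, 2],
    stringsAsFactors = FALSE
  )
  ref <- cnd_reference_table()
  ref <- ref[ref$type == "soil" & !grepl("_R$", ref$variable), ]
  key <- paste(out$start_stage, out$soil_element, sep = "_")
  out$x_max <- ref$range2_high[match(key, ref$variable)]
  stopifnot(!anyNA(out$x_max))
  out
}

#' Fertilizer product catalog
#'
#' Nutrient mass fractions (oxide basis for P, K, Ca, Mg) of the physical
#' fertilizers used in the trial.
#'
#' @return A data.frame with one row per product and columns `product`,
#'   `N`, `P2O5`, `K2O`, `CaO`, `MgO`.
#' @export
fertilizer_catalog <- function() {
  data.frame(
    product = c("calcium nitrate", "potassium nitrate", "urea",
                "potassium dihydrogen phosphate", "magnesium sulfate",
                "calcium acetate", "potassium sulfate",
                "ammonium dihydrogen phosphate"),
    N = c(0.1186, 0.1386, 0.4667, 0, 0, 0, 0, 0.1217),
    P2O5 = c(0, 0, 0, 0.5221, 0, 0, 0, 0.6174),
    K2O = c(0, 0.4653, 0, 0.3456, 0, 0, 0.5402, 0),
    CaO = c(0.2373, 0, 0, 0, 0, 0.3179, 0, 0),
    MgO = c(0, 0, 0, 0, 0.3333, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Convert elemental amounts to oxide basis and back
#'
#' Standard stoichiometric conversion factors: P2O5 = 2.2914 P,
#' K2O = 1.2046 K, CaO = 1.3992 Ca, MgO = 1.6583 Mg; N is unchanged.
#'
#' @param x Numeric vector of amounts.
#' @param element Character vector (recycled) in `N, P, K, Ca, Mg` for
#'   `element_to_oxide()` or `N, P2O5, K2O, CaO, MgO` for
#'   `oxide_to_element()`.
#' @return Numeric vector of converted amounts.
#' @export
element_to_oxide <- function(x, element) {
  f <- c(N = 1, P = 2.2914, K = 1.2046, Ca = 1.3992, Mg = 1.6583)
  bad <- setdiff(unique(element), names(f))
  if (length(bad)) stop("unknown element: ", paste(bad, collapse = ", "))
  x * unname(f[element])
}

#' @rdname element_to_oxide
#' @export
oxide_to_element <- function(x, element) {
  f <- c(N = 1, P2O5 = 2.2914, K2O = 1.2046, CaO = 1.3992, MgO = 1.6583)
  bad <- setdiff(unique(element), names(f))
  if (length(bad)) stop("unknown oxide: ", paste(bad, collapse = ", "))
  x / unname(f[element])
}
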