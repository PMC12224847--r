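# Default synthetic-cohort parameterization.
#
# The default generator emulates a 2,306-subject multimorbid cohort with four
# planted subgroups. Group weights are the exact subgroup sizes
# 471/127/1463/245 over 2306; per-group means/SDs of the continuous features,
# per-group level probabilities of the categoricals, and per-group disease
# prevalences are the published marginal summaries this generator is designed
# to reproduce. Values are stated once here and are not tuning knobs.

.cmm_diseases <- c("hypertension", "dyslipidemia", "diabetes", "ckd",
                   "hyperuricemia")

.marital_levels <- c("Married", "Widowed", "Divorced", "Separated",
                     "Never married", "Living with partner")
.education_levels <- c("Less than 9th grade", "9-11th grade",
                       "High school graduate/GED or equivalent",
                       "Some college or AA degree",
                       "College graduate or above")

# mean/sd per group (columns = groups I..IV)
.default_continuous <- function() {
  spec <- list(
    age             = list(m = c(53.909, 48.307, 50.758, 46.192),
                           s = c(16.472, 17.066, 17.781, 17.050)),
    family_pir      = list(m = c(3.156, 2.399, 2.391, 2.196),
                           s = c(1.594, 1.531, 1.579, 1.486)),
    bmi             = list(m = c(31.044, 29.598, 29.130, 29.312),
                           s = c(7.841, 6.802, 7.107, 7.189)),
    wbc             = list(m = c(6.473, 6.771, 6.841, 7.209),
                           s = c(1.764, 1.964, 2.018, 2.188)),
    lymphocyte_pct  = list(m = c(33.292, 35.725, 31.323, 28.535),
                           s = c(8.656, 9.906, 8.787, 8.225)),
    rbc             = list(m = c(4.840, 4.936, 4.790, 4.738),
                           s = c(0.497, 0.530, 0.523, 0.548)),
    rdw             = list(m = c(13.621, 13.791, 13.855, 13.938),
                           s = c(1.127, 1.216, 1.414, 1.540)),
    crp             = list(m = c(3.354, 2.934, 4.120, 4.253),
                           s = c(5.812, 4.382, 8.717, 6.877)),
    fasting_glucose = list(m = c(111.017, 112.968, 111.896, 109.282),
                           s = c(39.077, 47.280, 36.553, 31.795)),
    alk_phos        = list(m = c(79.554, 78.850, 87.532, 83.037),
                           s = c(35.667, 38.296, 55.262, 44.595)),
    hematocrit      = list(m = c(42.525, 41.200, 41.416, 41.531),
                           s = c(3.682, 4.651, 4.154, 3.887)),
    act_vig_work    = list(m = c(157.113, 1616.921, 97.946, 374.571),
                           s = c(410.032, 1397.569, 302.866, 763.235)),
    act_mod_work    = list(m = c(399.781, 1164.685, 282.013, 469.306),
                           s = c(2358.913, 1074.212, 583.865, 799.639)),
    act_walk_bicycle = list(m = c(55.881, 107.559, 64.515, 92.612),
                           s = c(214.567, 296.766, 273.906, 393.905)),
    act_vig_rec     = list(m = c(63.457, 154.724, 41.636, 80.229),
                           s = c(143.852, 388.062, 116.055, 148.127)),
    act_mod_rec     = list(m = c(91.306, 194.803, 72.826, 123.674),
                           s = c(151.082, 379.348, 170.063, 251.381)),
    act_sedentary   = list(m = c(401.391, 266.378, 342.239, 340.653),
                           s = c(491.188, 181.333, 200.361, 182.587)),
    protein         = list(m = c(100.721, 61.721, 63.382, 130.382),
                           s = c(25.212, 26.146, 22.168, 45.261)),
    carbohydrate    = list(m = c(275.290, 201.988, 209.545, 375.904),
                           s = c(88.015, 101.539, 81.757, 151.098)),
    dietary_fiber   = list(m = c(20.998, 13.416, 14.016, 26.205),
                           s = c(9.225, 8.946, 7.283, 13.740)),
    sat_fat         = list(m = c(36.030, 20.232, 20.822, 42.885),
                           s = c(13.238, 10.038, 9.542, 19.642)),
    mono_fat        = list(m = c(39.623, 21.828, 22.464, 44.745),
                           s = c(13.804, 11.603, 9.380, 19.276)),
    poly_fat        = list(m = c(26.192, 14.012, 15.645, 29.443),
                           s = c(11.084, 7.952, 7.534, 14.586)),
    cholesterol     = list(m = c(467.902, 213.732, 228.522, 488.849),
                           s = c(200.961, 159.362, 127.902, 308.896)),
    vitamin_e       = list(m = c(11.729, 5.946, 6.789, 14.052),
                           s = c(5.621, 3.221, 3.534, 7.454)),
    retinol         = list(m = c(475.121, 221.047, 292.743, 827.102),
                           s = c(231.611, 166.408, 203.996, 603.779)),
    vitamin_a       = list(m = c(721.091, 364.181, 472.139, 1107.604),
                           s = c(371.743, 263.716, 349.309, 673.942)),
    vitamin_b1      = list(m = c(1.764, 1.186, 1.291, 2.807),
                           s = c(0.547, 0.560, 0.542, 1.070)),
    vitamin_b2      = list(m = c(2.426, 1.717, 1.531, 3.588),
                           s = c(0.746, 1.090, 0.631, 1.415)),
    niacin          = list(m = c(28.150, 21.106, 19.990, 45.233),
                           s = c(9.267, 12.314, 8.350, 17.739)),
    vitamin_b6      = list(m = c(2.279, 1.711, 1.569, 4.013),
                           s = c(0.735, 1.404, 0.769, 2.270)),
    folate          = list(m = c(421.431, 268.898, 311.854, 707.551),
                           s = c(143.556, 131.559, 146.824, 321.959)),
    choline         = list(m = c(466.792, 250.007, 252.747, 532.872),
                           s = c(131.847, 123.028, 99.883, 221.019)),
    vitamin_b12     = list(m = c(5.092, 3.636, 3.214, 10.362),
                           s = c(2.564, 3.419, 2.158, 9.103)),
    vitamin_c       = list(m = c(97.096, 67.350, 64.189, 123.535),
                           s = c(77.475, 75.682, 58.090, 111.315)),
    vitamin_d       = list(m = c(5.266, 2.865, 3.142, 10.206),
                           s = c(4.179, 2.880, 2.792, 8.110)),
    vitamin_k       = list(m = c(149.644, 83.160, 102.400, 155.814),
                           s = c(134.980, 96.272, 120.535, 151.289)),
    calcium         = list(m = c(1074.030, 683.284, 732.256, 1572.600),
                           s = c(382.539, 327.870, 340.822, 620.635)),
    phosphorus      = list(m = c(1691.055, 1022.347, 1056.046, 2227.816),
                           s = c(390.797, 392.880, 355.769, 711.208)),
    magnesium       = list(m = c(367.259, 246.764, 236.857, 467.706),
                           s = c(110.817, 107.479, 87.308, 172.313)),
    iron            = list(m = c(15.601, 10.243, 11.277, 25.696),
                           s = c(4.505, 5.386, 4.978, 10.212)),
    zinc            = list(m = c(13.008, 8.291, 8.259, 20.093),
                           s = c(3.811, 5.408, 3.438, 16.979)),
    copper          = list(m = c(1.484, 0.968, 0.941, 1.908),
                           s = c(0.546, 0.552, 0.367, 1.439)),
    sodium          = list(m = c(4215.527, 2632.803, 2801.813, 5269.396),
                           s = c(1293.447, 1151.671, 1044.642, 1953.755)),
    potassium       = list(m = c(3243.682, 2203.102, 2070.932, 4012.510),
                           s = c(825.286, 941.963, 733.943, 1302.872)),
    selenium        = list(m = c(142.409, 86.656, 90.351, 187.164),
                           s = c(44.964, 41.239, 35.262, 81.941)),
    caffeine        = list(m = c(182.076, 251.126, 116.212, 153.192),
                           s = c(188.950, 458.150, 138.925, 156.449)),
    theobromine     = list(m = c(55.200, 29.850, 25.052, 42.082),
                           s = c(84.219, 63.391, 41.983, 68.169)),
    alcohol         = list(m = c(12.491, 6.909, 6.408, 9.766),
                           s = c(32.238, 15.277, 18.449, 22.986))
  )
  spec
}

# lower clipping bounds for Gaussian draws (physiologic floors; upper bounds
# only where a hard ceiling is physiologic)
.continuous_bounds <- function() {
  b <- list(
    age = c(20, 80), family_pir = c(0, 10), bmi = c(14, 70),
    wbc = c(1.5, Inf), lymphocyte_pct = c(2, 95), rbc = c(2.5, 8),
    rdw = c(10, Inf), crp = c(0.05, Inf), fasting_glucose = c(45, Inf),
    alk_phos = c(15, Inf), hematocrit = c(20, 65)
  )
  b
}

.default_categorical <- function() {
  norm <- function(m) sweep(m, 2, colSums(m), "/")
  list(
    gender = list(
      levels = c("Female", "Male"),
      prob = norm(rbind(c(0.406, 0.378, 0.595, 0.257),
                        c(0.594, 0.622, 0.405, 0.743)))),
    marital_status = list(
      levels = .marital_levels,
      prob = norm(rbind(c(0.631, 0.559, 0.488, 0.486),
                        c(0.074, 0.039, 0.075, 0.024),
                        c(0.087, 0.087, 0.116, 0.131),
                        c(0.025, 0.071, 0.042, 0.016),
                        c(0.127, 0.142, 0.174, 0.200),
                        c(0.055, 0.102, 0.105, 0.143)))),
    education = list(
      levels = .education_levels,
      prob = norm(rbind(c(0.057, 0.071, 0.086, 0.049),
                        c(0.093, 0.134, 0.113, 0.159),
                        c(0.172, 0.236, 0.257, 0.245),
                        c(0.363, 0.441, 0.293, 0.343),
                        c(0.315, 0.118, 0.250, 0.204))))
  )
}

.default_smoking <- c(0.463, 0.575, 0.409, 0.490)

# rows = groups I..IV, cols = the five diseases
.default_disease_prev <- function() {
  m <- rbind(c(0.520, 0.701, 0.318, 0.310, 0.200),
             c(0.362, 0.693, 0.252, 0.307, 0.220),
             c(0.450, 0.660, 0.283, 0.305, 0.228),
             c(0.359, 0.612, 0.261, 0.208, 0.139))
  colnames(m) <- .cmm_diseases
  m
}

#' Synthetic-cohort configuration
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' defaults describe a four-subgroup multimorbid cohort whose group weights,
#' per-group feature means/SDs, categorical level frequencies and disease
#' prevalences match the published cohort marginals (2,306 subjects split
#' 471/127/1463/245). Any component can be overridden for planted-structure
#' experiments.
#'
#' @param n_patients number of records to generate.
#' @param n_groups number of planted subgroups.
#' @param group_weights mixture weights, must sum to 1 (tolerance 1e-9).
#' @param disease_prev `n_groups x 5` matrix of per-group disease
#'   prevalences (columns: hypertension, dyslipidemia, diabetes, ckd,
#'   hyperuricemia).
#' @param continuous named list of `list(m = means, s = sds)` per feature,
#'   each of length `n_groups`.
#' @param categorical named list of `list(levels=, prob=)`, `prob` a
#'   levels-by-groups column-stochastic matrix.
#' @param smoking_prob per-group probability of the lifetime-smoking flag.
#' @param separation multiplier applied to each group mean's deviation from
#'   the weight-averaged grand mean; `1` keeps the published marginals,
#'   larger values plant stronger subgroup structure for recovery
#'   experiments.
#' @param seed RNG seed; identical seeds yield identical cohorts.
#' @return a `cmm_synth_config` list.
#' @export
synth_config <- function(n_patients = 2306L,
                         n_groups = 4L,
                         group_weights = c(471, 127, 1463, 245) / 2306,
                         disease_prev = .default_disease_prev(),
                         continuous = .default_continuous(),
                         categorical = .default_categorical(),
                         smoking_prob = .default_smoking,
                         separation = 1,
                         seed = 0L) {
  if (n_groups < 1) stop("n_groups must be at least 1", call. = FALSE)
  if (length(group_weights) != n_groups)
    stop("group_weights must have length n_groups", call. = FALSE)
  if (abs(sum(group_weights) - 1) > 1e-9)
    stop("group_weights must sum to 1", call. = FALSE)
  if (any(group_weights < 0)) stop("group_weights must be nonnegative", call. = FALSE)
  disease_prev <- as.matrix(disease_prev)
  if (nrow(disease_prev) != n_groups || ncol(disease_prev) != 5)
    stop("disease_prev must be n_groups x 5", call. = FALSE)
  if (any(disease_prev < 0 | disease_prev > 1))
    stop("disease prevalences must lie in [0, 1]", call. = FALSE)
  for (nm in names(continuous)) {
    cc <- continuous[[nm]]
    if (length(cc$m) != n_groups || length(cc$s) != n_groups)
      stop("continuous feature '", nm, "' needs ", n_groups, " means and sds",
           call. = FALSE)
    if (any(cc$s <= 0))
      stop("continuous feature '", nm, "' has non-positive sd", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_groups = as.integer(n_groups),
                 group_weights = group_weights,
                 disease_prev = disease_prev,
                 continuous = continuous,
                 categorical = categorical,
                 smoking_prob = smoking_prob,
                 separation = separation,
                 seed = as.integer(seed)),
            class = "cmm_synth_config")
}
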