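# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

# direct graph constructor (bypasses similarity thresholding)
make_graph <- function(edges, n = max(edges$i, edges$j)) {
  edges$weight <- if (is.null(edges$weight)) 1 else edges$weight
  cmmnet:::.graph(as.character(seq_len(n)), edges, NA_real_)
}

# two triangles joined by a single bridge edge (m = 7)
bridge_graph <- function() {
  make_graph(data.frame(i = c(1, 1, 2, 4, 4, 5, 3),
                        j = c(2, 3, 3, 5, 6, 6, 4),
                        weight = 1))
}

# two disjoint cliques
two_cliques_graph <- function(a = 4, b = 4) {
  cl <- function(off, k) {
    pr <- t(combn(k, 2)) + off
    data.frame(i = pr[, 1], j = pr[, 2], weight = 1)
  }
  make_graph(rbind(cl(0, a), cl(a, b)), n = a + b)
}

# Erdos-Renyi G(n, p); resampled until it has at least one edge
random_gnp_graph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(pr)) < p
    if (any(keep)) break
  }
  make_graph(data.frame(i = pr[keep, 1], j = pr[keep, 2], weight = 1), n = n)
}

# strong-separation planted world used by the recovery experiments: four
# equal subgroups, group-mean deviations amplified 6x (see the methods
# vignette for why this is the regime where exact recovery is expected)
recovery_config <- function(n = 800, seed = 7) {
  synth_config(n_patients = n, group_weights = rep(0.25, 4),
               separation = 6, seed = seed)
}

# a raw-measurements row with every value strictly inside normal range
normal_measurements <- function(sex = "Male") {
  data.frame(sex = sex, sbp = 120, dbp = 75, dx_hypertension = FALSE,
             total_cholesterol = 4.5, triglycerides = 1.2, ldl_c = 2.5,
             hdl_c = 1.4, fasting_glucose_mmol = 5.2, ogtt_2h_glucose = 6.5,
             dx_diabetes = FALSE, acr = 10, egfr = 95,
             kidney_damage_over_3mo = FALSE, egfr_low_over_3mo = TRUE,
             serum_uric_acid = if (sex == "Male") 300 else 250)
}

# published pattern sizes and Table 1-3 contingency rows (counts only);
# used by the characterization tests and the acceptance criteria
published_sizes <- c(471, 127, 1463, 245)
published_disease_counts <- list(
  hypertension = c(245, 46, 658, 88),
  dyslipidemia = c(330, 88, 966, 150),
  diabetes = c(150, 32, 414, 64),
  ckd = c(146, 39, 446, 51),
  hyperuricemia = c(94, 28, 334, 34))
published_gender <- rbind(c(191, 48, 870, 63), c(280, 79, 593, 182))
published_marital <- rbind(c(297, 71, 714, 119), c(35, 5, 110, 6),
                           c(41, 11, 170, 32), c(12, 9, 61, 4),
                           c(60, 18, 254, 49), c(26, 13, 154, 35))
published_education <- rbind(c(27, 9, 126, 12), c(44, 17, 166, 39),
                             c(81, 30, 376, 60), c(171, 56, 429, 84),
                             c(148, 15, 366, 50))
published_smoking <- rbind(c(218, 73, 598, 120),
                           published_sizes - c(218, 73, 598, 120))
published_bmi <- data.frame(n = published_sizes,
                            mean = c(31.044, 29.598, 29.130, 29.312),
                            sd = c(7.841, 6.802, 7.107, 7.189))
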