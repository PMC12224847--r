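# synthetic cohort: disease flagging, inclusion filter, generator

test_that("flag_diseases matches a hand-coded boundary truth table", {
  # for each disease, every side-of-cutoff combination of its criteria,
  # with values epsilon-close to the printed cutoffs; the expected flag is
  # computed by an independent rule written out case by case
  base <- normal_measurements()

  # hypertension: SBP > 140, DBP > 90, or diagnosis (2^3 combos)
  grid <- expand.grid(sbp_hi = c(TRUE, FALSE), dbp_hi = c(TRUE, FALSE),
                      dx = c(TRUE, FALSE))
  m <- base[rep(1, nrow(grid)), ]
  m$sbp <- ifelse(grid$sbp_hi, 140.5, 140)   # 140 itself must NOT flag
  m$dbp <- ifelse(grid$dbp_hi, 90.5, 90)
  m$dx_hypertension <- grid$dx
  expect_equal(flag_diseases(m)$hypertension,
               grid$sbp_hi | grid$dbp_hi | grid$dx)

  # dyslipidemia: TC >= 5.18, TG >= 1.70, LDL >= 3.37 (inclusive), HDL <
  # 1.04 (strict) (2^4 combos at the exact cutpoints)
  grid <- expand.grid(tc = c(TRUE, FALSE), tg = c(TRUE, FALSE),
                      ldl = c(TRUE, FALSE), hdl = c(TRUE, FALSE))
  m <- base[rep(1, nrow(grid)), ]
  m$total_cholesterol <- ifelse(grid$tc, 5.18, 5.1799)
  m$triglycerides <- ifelse(grid$tg, 1.70, 1.6999)
  m$ldl_c <- ifelse(grid$ldl, 3.37, 3.3699)
  m$hdl_c <- ifelse(grid$hdl, 1.0399, 1.04)
  expect_equal(flag_diseases(m)$dyslipidemia,
               grid$tc | grid$tg | grid$ldl | grid$hdl)

  # diabetes: fasting >= 7.0, 2h >= 11.1, or diagnosis
  grid <- expand.grid(fpg = c(TRUE, FALSE), ogtt = c(TRUE, FALSE),
                      dx = c(TRUE, FALSE))
  m <- base[rep(1, nrow(grid)), ]
  m$fasting_glucose_mmol <- ifelse(grid$fpg, 7.0, 6.9999)
  m$ogtt_2h_glucose <- ifelse(grid$ogtt, 11.1, 11.0999)
  m$dx_diabetes <- grid$dx
  expect_equal(flag_diseases(m)$diabetes, grid$fpg | grid$ogtt | grid$dx)

  # CKD: persistent damage, ACR >= 30, or persistently low eGFR (< 60)
  grid <- expand.grid(dam = c(TRUE, FALSE), acr = c(TRUE, FALSE),
                      egfr = c(TRUE, FALSE))
  m <- base[rep(1, nrow(grid)), ]
  m$kidney_damage_over_3mo <- grid$dam
  m$acr <- ifelse(grid$acr, 30, 29.9999)
  m$egfr <- ifelse(grid$egfr, 59.9999, 60)
  expect_equal(flag_diseases(m)$ckd, grid$dam | grid$acr | grid$egfr)

  # hyperuricemia: sex-specific strict > cutoffs
  grid <- expand.grid(sex = c("Male", "Female"), hi = c(TRUE, FALSE))
  m <- base[rep(1, nrow(grid)), ]
  m$sex <- as.character(grid$sex)
  cut <- ifelse(grid$sex == "Male", 420, 357)
  m$serum_uric_acid <- ifelse(grid$hi, cut + 0.5, cut) # cutoff itself no flag
  expect_equal(flag_diseases(m)$hyperuricemia, grid$hi)
})

test_that("flag_diseases handles the spec's worked examples and errors", {
  m <- normal_measurements("Male")
  m$serum_uric_acid <- 430
  fl <- flag_diseases(m)
  expect_true(fl$hyperuricemia)
  expect_false(any(unlist(fl[c("hypertension", "dyslipidemia", "diabetes",
                               "ckd")])))

  expect_false(any(unlist(flag_diseases(normal_measurements()))))

  f <- normal_measurements("Female")
  f$total_cholesterol <- 5.18
  f$hdl_c <- 1.04
  fl <- flag_diseases(f)
  expect_true(fl$dyslipidemia)   # TC inclusive; HDL at cutoff alone would not

  bad <- normal_measurements()
  bad$sex <- "unknown"
  expect_error(flag_diseases(bad), "sex must be known")
  bad <- normal_measurements()
  bad$acr <- -1
  expect_error(flag_diseases(bad), "negative concentration")
  bad <- normal_measurements()
  bad$sbp <- 0
  expect_error(flag_diseases(bad), "blood pressures")
  expect_error(flag_diseases(normal_measurements()[, -2]), "missing")
})

test_that("flag_diseases is deterministic and idempotent", {
  m <- normal_measurements()[rep(1, 5), ]
  m$serum_uric_acid <- c(300, 430, 420, 250, 360)
  expect_identical(flag_diseases(m), flag_diseases(m))
})

test_that("filter_cmm keeps exactly the records with >= 2 flags", {
  set.seed(42)
  n <- 100
  flags <- as.data.frame(matrix(runif(n * 5) < 0.45, n, 5))
  names(flags) <- c("hypertension", "dyslipidemia", "diabetes", "ckd",
                    "hyperuricemia")
  flags$id <- seq_len(n)
  kept <- filter_cmm(flags)
  # brute-force count by enumerating per record
  expected_ids <- flags$id[apply(flags[, 1:5], 1, function(r) sum(r) >= 2)]
  expect_identical(kept$id, expected_ids)        # order preserved
  one <- flags[1, ]; one[1, 1:5] <- c(TRUE, rep(FALSE, 4))
  expect_equal(nrow(filter_cmm(one)), 0)
  expect_equal(nrow(filter_cmm(flags[0, ])), 0)
})

test_that("generate_cohort is seed-deterministic and internally consistent", {
  cfg <- synth_config(n_patients = 300, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  attr(a, "synth_config") <- attr(b, "synth_config") <- NULL
  expect_identical(a, b)

  # every record's stored flags are reproduced from its own raw columns
  fl <- flag_diseases(raw_measurements(a))
  for (d in c("hypertension", "dyslipidemia", "diabetes", "ckd",
              "hyperuricemia"))
    expect_identical(as.logical(fl[[d]]), a[[d]])

  expect_equal(nrow(generate_cohort(synth_config(n_patients = 0))), 0)
  expect_error(synth_config(group_weights = c(0.6, 0.5)), "length")
  expect_error(synth_config(n_groups = 2, group_weights = c(0.6, 0.5)),
               "sum to 1")
})

test_that("generated marginals match the configuration (Monte Carlo)", {
  cfg <- synth_config(n_patients = 10000, seed = 123)
  co <- generate_cohort(cfg)
  shares <- as.numeric(table(co$planted_group)) / nrow(co)
  expect_true(all(abs(shares - cfg$group_weights) < 0.02))
  for (g in 1:4) {
    sel <- co$planted_group == g
    prev <- colMeans(co[sel, c("hypertension", "dyslipidemia", "diabetes",
                               "ckd", "hyperuricemia")])
    expect_true(all(abs(prev - cfg$disease_prev[g, ]) < 0.03))
  }
  # overall mean age tracks the weighted mixture of the published groups
  expect_equal(mean(co$age), 50.781, tolerance = 0.02)
})

test_that("cohort CSV round trip preserves values and types", {
  co <- generate_cohort(synth_config(n_patients = 50, seed = 3))
  path <- file.path(tempdir(), "cohort_roundtrip.csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(levels(back$gender), levels(co$gender))
  expect_identical(back$hypertension, co$hypertension)
  expect_equal(back$choline, co$choline, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$synth_config$seed, 3)
  unlink(c(path, paste0(path, ".json")))
})
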