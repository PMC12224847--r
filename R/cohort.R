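# Synthetic cohort generation.
#
# Records are complete-case by construction (mirroring listwise deletion in
# the emulated survey extract). Disease flags are drawn per-group Bernoulli
# and then made consistent by back-filling raw diagnostic measurements that
# reproduce each flag under flag_diseases(); the biomarker panel is drawn
# from its own per-group Gaussians and is intentionally NOT coupled to the
# diagnostic raw measurements (marginal realism, not joint physiology).

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# raw diagnostic measurements consistent with a flag matrix; uniform draws
# on documented ranges strictly inside / outside each cutoff
.backfill_raw <- function(flags, sex) {
  n <- nrow(flags)
  pick <- function(k) sample.int(k, n, replace = TRUE)
  U <- function(lo, hi) runif(n, lo, hi)

  # hypertension: measured BP (70%) or physician diagnosis (30%)
  mech <- ifelse(flags$hypertension, ifelse(runif(n) < 0.7, 1L, 2L), 0L)
  sbp <- ifelse(mech == 1L, U(142, 190), U(95, 139))
  dbp <- U(55, 88)
  dx_htn <- mech == 2L

  # dyslipidemia: one of four lipid criteria chosen uniformly
  mech <- ifelse(flags$dyslipidemia, pick(4L), 0L)
  tc  <- ifelse(mech == 1L, U(5.18, 8.5), U(3.1, 5.17))
  tg  <- ifelse(mech == 2L, U(1.70, 5.0), U(0.5, 1.69))
  ldl <- ifelse(mech == 3L, U(3.37, 5.5), U(1.2, 3.36))
  hdl <- ifelse(mech == 4L, U(0.55, 1.03), U(1.05, 2.4))

  # diabetes: fasting, post-load, or diagnosis
  mech <- ifelse(flags$diabetes, pick(3L), 0L)
  fpg  <- ifelse(mech == 1L, U(7.0, 12.0), U(4.2, 6.9))
  ogtt <- ifelse(mech == 2L, U(11.1, 18.0), U(5.0, 10.9))
  dx_dm <- mech == 3L

  # CKD: persistent damage, albuminuria, or persistently low eGFR
  mech <- ifelse(flags$ckd, pick(3L), 0L)
  damage <- mech == 1L
  acr  <- ifelse(mech == 2L, U(30, 300), U(3, 29))
  egfr <- ifelse(mech == 3L, U(20, 59), U(65, 115))

  male <- sex == "Male"
  ua <- ifelse(flags$hyperuricemia,
               ifelse(male, U(421, 600), U(358, 550)),
               ifelse(male, U(150, 419), U(150, 356)))

  data.frame(sex = sex, sbp = sbp, dbp = dbp, dx_hypertension = dx_htn,
             total_cholesterol = tc, triglycerides = tg, ldl_c = ldl,
             hdl_c = hdl, fasting_glucose_mmol = fpg, ogtt_2h_glucose = ogtt,
             dx_diabetes = dx_dm, acr = acr, egfr = egfr,
             kidney_damage_over_3mo = damage, egfr_low_over_3mo = TRUE,
             serum_uric_acid = ua)
}

#' Generate a synthetic multimorbid cohort with planted subgroups
#'
#' Draws `cfg$n_patients` records: a planted group per record from the
#' mixture weights, continuous features from per-group Gaussians (clipped at
#' physiologic floors), categorical levels and the smoking flag from
#' per-group frequencies, disease flags from per-group Bernoulli rates, and
#' raw diagnostic measurements back-filled so that [flag_diseases()] applied
#' to a record's raw columns reproduces its stored flags exactly. The same
#' seed yields an identical cohort.
#'
#' Note the flags are marginal draws: apply [filter_cmm()] to obtain the
#' multimorbid (>= 2 diseases) analysis cohort, whose within-group
#' prevalences are then the Bernoulli rates conditioned on that event.
#'
#' @param cfg a [synth_config()] object.
#' @return data.frame, one row per patient; the planted group is kept in
#'   `planted_group`, raw measurement columns are prefixed `raw_`. The
#'   configuration is attached as attribute `synth_config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cmm_synth_config"))
  n <- cfg$n_patients
  if (n == 0) {
    out <- data.frame()
    attr(out, "synth_config") <- cfg
    return(out)
  }
  .with_seed(cfg$seed, {
    group <- sample.int(cfg$n_groups, n, replace = TRUE,
                        prob = cfg$group_weights)

    cat_draw <- function(sp) {
      lv <- sp$levels
      x <- character(n)
      for (g in seq_len(cfg$n_groups)) {
        sel <- group == g
        if (any(sel))
          x[sel] <- sample(lv, sum(sel), replace = TRUE, prob = sp$prob[, g])
      }
      factor(x, levels = lv)
    }
    cats <- lapply(cfg$categorical, cat_draw)

    bounds <- .continuous_bounds()
    grand <- function(cc) sum(cfg$group_weights * cc$m)
    cont <- lapply(names(cfg$continuous), function(nm) {
      cc <- cfg$continuous[[nm]]
      gm <- grand(cc)
      mu <- gm + cfg$separation * (cc$m - gm)
      x <- rnorm(n, mean = mu[group], sd = cc$s[group])
      b <- bounds[[nm]]
      if (is.null(b)) b <- c(0, Inf)
      pmin(pmax(x, b[1]), b[2])
    })
    names(cont) <- names(cfg$continuous)

    smoking_100 <- runif(n) < cfg$smoking_prob[group]

    flags <- as.data.frame(lapply(seq_len(5), function(d) {
      runif(n) < cfg$disease_prev[group, d]
    }))
    names(flags) <- .cmm_diseases

    sex <- if (!is.null(cats$gender)) {
      ifelse(cats$gender == "Male", "Male", "Female")
    } else {
      sample(c("Male", "Female"), n, replace = TRUE)
    }
    raw <- .backfill_raw(flags, sex)

    out <- data.frame(id = sprintf("P%05d", seq_len(n)),
                      planted_group = group)
    for (nm in names(cats)) out[[nm]] <- cats[[nm]]
    out$smoking_100 <- smoking_100
    for (nm in names(cont)) out[[nm]] <- cont[[nm]]
    for (nm in .cmm_diseases) out[[nm]] <- flags[[nm]]
    raw2 <- raw[setdiff(names(raw), "sex")]
    names(raw2) <- paste0("raw_", names(raw2))
    out <- cbind(out, raw2)
    attr(out, "synth_config") <- cfg
    out
  })
}

#' Extract the raw measurement columns of a cohort
#'
#' Returns the `raw_`-prefixed columns in the layout [flag_diseases()]
#' expects, deriving `sex` from the `gender` column.
#'
#' @param cohort a cohort data.frame from [generate_cohort()] or
#'   [read_cohort()].
#' @return data.frame of raw measurements.
#' @export
raw_measurements <- function(cohort) {
  rawcols <- grep("^raw_", names(cohort), value = TRUE)
  out <- cohort[rawcols]
  names(out) <- sub("^raw_", "", names(out))
  out$sex <- ifelse(cohort$gender == "Male", "Male", "Female")
  out
}

#' Write / read a cohort as CSV with a JSON sidecar
#'
#' Booleans are serialized as 0/1 and categorical levels as strings; the
#' sidecar (`<path>.json`) records column classes, factor levels and, when
#' present, the generating [synth_config()] (seed included) so a round trip
#' restores types exactly.
#'
#' @param cohort cohort data.frame.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  meta <- list(
    columns = lapply(df, function(x) {
      if (is.factor(x)) list(class = "factor", levels = levels(x))
      else list(class = class(x)[1])
    }),
    synth_config = if (!is.null(attr(cohort, "synth_config")))
      unclass(attr(cohort, "synth_config"))
  )
  for (nm in names(df)) {
    if (is.logical(df[[nm]])) df[[nm]] <- as.integer(df[[nm]])
    if (is.factor(df[[nm]])) df[[nm]] <- as.character(df[[nm]])
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    for (nm in names(meta$columns)) {
      cl <- meta$columns[[nm]]$class
      if (is.null(df[[nm]])) next
      if (cl == "factor") {
        df[[nm]] <- factor(df[[nm]], levels = unlist(meta$columns[[nm]]$levels))
      } else if (cl == "logical") {
        df[[nm]] <- as.logical(df[[nm]])
      }
    }
  }
  df
}
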