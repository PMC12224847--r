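# Pattern characterization: prevalence tables, Pearson chi-square, one-way
# ANOVA (raw-data and summary-statistics entry points), Bonferroni post-hoc
# pairwise t tests, and rule-based pattern naming.

.partition_labels <- function(partition, n) {
  lab <- if (inherits(partition, "cmm_partition")) partition$membership
         else partition
  if (length(lab) != n)
    stop("partition must assign every record", call. = FALSE)
  factor(lab)
}

#' Disease prevalence by pattern
#'
#' Counts and within-pattern percentages of each of the five diseases per
#' community, plus pattern sizes and cohort shares. Empty patterns are
#' retained in the listing with n = 0 (they are excluded from tests
#' downstream).
#'
#' @param cohort cohort data.frame with the five disease flag columns.
#' @param partition a `cmm_partition` or a label vector aligned to rows.
#' @return a `cmm_prevalence`: list with `counts` (diseases x patterns),
#'   `prevalence`, `pattern_sizes`, `shares`.
#' @export
prevalence_table <- function(cohort, partition) {
  lab <- .partition_labels(partition, nrow(cohort))
  sizes <- table(lab)
  counts <- sapply(levels(lab), function(l) {
    sel <- lab == l
    vapply(.cmm_diseases, function(d) sum(as.logical(cohort[[d]][sel])),
           numeric(1))
  })
  counts <- matrix(counts, nrow = length(.cmm_diseases),
                   dimnames = list(.cmm_diseases, levels(lab)))
  prev <- sweep(counts, 2, pmax(as.numeric(sizes), 1), "/")
  prev[, sizes == 0] <- NA_real_
  structure(list(counts = counts, prevalence = prev,
                 pattern_sizes = as.numeric(sizes),
                 pattern_labels = levels(lab),
                 shares = as.numeric(sizes) / nrow(cohort)),
            class = "cmm_prevalence")
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` with `E = row * col /
#' total`, `df = (r - 1)(c - 1)`, upper-tail p. No continuity correction.
#'
#' @param tab integer matrix of counts, at least 2 x 2.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least a 2 x 2 table", call. = FALSE)
  if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: zero row or column margin", call. = FALSE)
  E <- outer(rs, cs) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' One-way ANOVA, from raw data or from group summaries
#'
#' The summary-statistics entry point reconstructs the between-group sum of
#' squares `SSB = sum n_i (m_i - m_bar)^2` and the within-group sum
#' `SSW = sum (n_i - 1) s_i^2`, with `s_i` the sample (n-1) standard
#' deviation — the convention under which published Mean (SD) tables
#' reproduce their printed F statistics.
#'
#' @param values numeric vector of raw observations (with `groups`), or
#'   `NULL` when using `summaries`.
#' @param groups group labels aligned to `values`.
#' @param summaries data.frame with columns `n`, `mean`, `sd`, one row per
#'   group.
#' @return list with `F`, `df1`, `df2`, `p_value`.
#' @export
anova_oneway <- function(values = NULL, groups = NULL, summaries = NULL) {
  if (is.null(summaries)) {
    g <- factor(groups)
    summaries <- data.frame(
      n = as.numeric(table(g)),
      mean = as.numeric(tapply(values, g, mean)),
      sd = as.numeric(tapply(values, g, stats::sd)))
  }
  if (nrow(summaries) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(summaries$n < 2)) stop("each group needs n >= 2", call. = FALSE)
  N <- sum(summaries$n); k <- nrow(summaries)
  gm <- sum(summaries$n * summaries$mean) / N
  ssb <- sum(summaries$n * (summaries$mean - gm)^2)
  ssw <- sum((summaries$n - 1) * summaries$sd^2)
  if (ssw == 0) {
    if (ssb == 0)
      stop("F is undefined: zero within-group variance and equal means",
           call. = FALSE)
    return(list(F = Inf, df1 = k - 1, df2 = N - k, p_value = 0))
  }
  Fv <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fv, df1 = k - 1, df2 = N - k,
       p_value = stats::pf(Fv, k - 1, N - k, lower.tail = FALSE))
}

#' Bonferroni-adjusted pairwise t tests
#'
#' All pairwise pooled-variance two-sample t tests between groups, with
#' each p multiplied by the number of pairs and capped at 1. Groups with
#' fewer than 2 observations are excluded with a warning.
#'
#' @param values numeric vector.
#' @param groups group labels aligned to `values`.
#' @return symmetric matrix of adjusted p-values (`NA` diagonal); raw
#'   p-values as attribute `raw`.
#' @export
bonferroni_pairwise <- function(values, groups) {
  g <- factor(groups)
  ns <- table(g)
  small <- names(ns)[ns < 2]
  if (length(small)) {
    warning("excluding group(s) with n < 2: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(g %in% small)
    values <- values[keep]
    g <- droplevels(g[keep])
  }
  lv <- levels(g)
  k <- length(lv)
  if (k < 2) stop("need at least 2 usable groups", call. = FALSE)
  m <- k * (k - 1) / 2
  raw <- adj <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
    xa <- values[g == lv[a]]; xb <- values[g == lv[b]]
    na <- length(xa); nb <- length(xb)
    sp2 <- ((na - 1) * stats::var(xa) + (nb - 1) * stats::var(xb)) /
      (na + nb - 2)
    tstat <- (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(abs(tstat), na + nb - 2, lower.tail = FALSE)
    raw[a, b] <- raw[b, a] <- p
    adj[a, b] <- adj[b, a] <- min(1, m * p)
  }
  attr(adj, "raw") <- raw
  attr(adj, "n_comparisons") <- m
  adj
}

#' Rule-based pattern naming
#'
#' Deterministic rules mirroring the published reasoning: the pattern with
#' the highest hypertension prevalence is the Hypertension Predominant
#' Group (HPG); the pattern with the lowest CKD prevalence is the Kidney
#' Disease Low Group (KDLG); of the remainder, the larger is the Multiple
#' Diseases High Group (MDHG) and the last is the Uric Acid and
#' Dyslipidemia Coexistence Group (UADCG). When the rules collide (ties, a
#' pattern winning two rules, or a pattern count other than 4) every
#' pattern falls back to a generic `Pattern-k` name with a logged note.
#'
#' @param prev a `cmm_prevalence` from [prevalence_table()].
#' @return named character vector, one name per pattern label.
#' @export
name_patterns <- function(prev) {
  stopifnot(inherits(prev, "cmm_prevalence"))
  labs <- prev$pattern_labels
  fallback <- function(why) {
    message("pattern naming fell back to generic labels: ", why)
    stats::setNames(paste0("Pattern-", seq_along(labs)), labs)
  }
  if (length(labs) != 4) return(fallback("expected 4 patterns"))
  hyp <- prev$prevalence["hypertension", ]
  ckd <- prev$prevalence["ckd", ]
  if (anyNA(hyp) || anyNA(ckd)) return(fallback("empty pattern"))
  if (sum(hyp == max(hyp)) != 1 || sum(ckd == min(ckd)) != 1)
    return(fallback("tied prevalences"))
  hpg <- which.max(hyp)
  kdlg <- which.min(ckd)
  if (hpg == kdlg) return(fallback("one pattern wins two rules"))
  rest <- setdiff(seq_along(labs), c(hpg, kdlg))
  sz <- prev$pattern_sizes[rest]
  if (sz[1] == sz[2]) return(fallback("tied sizes"))
  mdhg <- rest[which.max(sz)]
  uadcg <- rest[which.min(sz)]
  out <- character(4)
  out[hpg] <- "HPG"; out[kdlg] <- "KDLG"; out[mdhg] <- "MDHG"
  out[uadcg] <- "UADCG"
  stats::setNames(out, labs)
}

#' Full epidemiological profile of detected patterns
#'
#' Assembles pattern sizes and shares, the disease prevalence table with
#' per-disease chi-square tests, chi-square tests for categorical
#' variables, one-way ANOVA with Bonferroni post-hoc matrices for
#' continuous variables, and rule-based names.
#'
#' @param cohort cohort data.frame.
#' @param partition a `cmm_partition` or label vector.
#' @param continuous character vector of continuous variable names to test
#'   (default: every numeric feature in [default_features()]).
#' @param categorical character vector of categorical variable names
#'   (default: the factor/logical features).
#' @return a `cmm_profile` list.
#' @export
pattern_profile <- function(cohort, partition, continuous = NULL,
                            categorical = NULL) {
  lab <- .partition_labels(partition, nrow(cohort))
  feats <- default_features(cohort)
  if (is.null(continuous))
    continuous <- feats[vapply(cohort[feats], is.numeric, logical(1))]
  if (is.null(categorical))
    categorical <- setdiff(feats, continuous)

  prev <- prevalence_table(cohort, partition)
  nonempty <- prev$pattern_sizes > 0
  disease_tests <- lapply(.cmm_diseases, function(d) {
    yes <- prev$counts[d, nonempty]
    tab <- rbind(yes, prev$pattern_sizes[nonempty] - yes)
    tryCatch(chi_square_test(tab), error = function(e) NULL)
  })
  names(disease_tests) <- .cmm_diseases

  cat_tests <- lapply(categorical, function(v) {
    tab <- table(cohort[[v]], lab)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    tryCatch(chi_square_test(tab), error = function(e) NULL)
  })
  names(cat_tests) <- categorical

  cont_tests <- lapply(continuous, function(v) {
    a <- tryCatch(anova_oneway(cohort[[v]], lab), error = function(e) NULL)
    ph <- tryCatch(suppressWarnings(bonferroni_pairwise(cohort[[v]], lab)),
                   error = function(e) NULL)
    list(anova = a, posthoc = ph)
  })
  names(cont_tests) <- continuous

  structure(list(prevalence = prev,
                 disease_tests = disease_tests,
                 categorical_tests = cat_tests,
                 continuous_tests = cont_tests,
                 names = name_patterns(prev)),
            class = "cmm_profile")
}

#' Export a pattern profile as JSON and Markdown tables
#'
#' @param profile a `cmm_profile`.
#' @param path output stem; writes `<path>.json` and `<path>.md`.
#' @return `path`, invisibly.
#' @export
report_profile <- function(profile, path) {
  prev <- profile$prevalence
  jsonlite::write_json(
    list(pattern_labels = prev$pattern_labels,
         pattern_sizes = prev$pattern_sizes,
         shares = prev$shares,
         names = as.list(profile$names),
         prevalence = as.data.frame(t(prev$prevalence)),
         disease_tests = profile$disease_tests,
         categorical_tests = profile$categorical_tests,
         continuous_anova = lapply(profile$continuous_tests,
                                   function(x) x$anova)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")

  md <- c("# CMM pattern profile", "",
          paste0("| pattern | name | n | share |"),
          "|---|---|---|---|",
          sprintf("| %s | %s | %d | %.1f%% |", prev$pattern_labels,
                  profile$names, as.integer(prev$pattern_sizes),
                  100 * prev$shares),
          "", "## Disease prevalence (count, % of pattern)", "",
          paste0("| disease | ", paste(prev$pattern_labels, collapse = " | "),
                 " | chi-sq | p |"),
          paste0("|", paste(rep("---", length(prev$pattern_labels) + 3),
                            collapse = "|"), "|"))
  for (d in .cmm_diseases) {
    cells <- sprintf("%d (%.1f%%)", prev$counts[d, ],
                     100 * prev$prevalence[d, ])
    tst <- profile$disease_tests[[d]]
    md <- c(md, paste0("| ", d, " | ", paste(cells, collapse = " | "),
                       " | ",
                       if (is.null(tst)) "-" else sprintf("%.3f", tst$statistic),
                       " | ",
                       if (is.null(tst)) "-" else format.pval(tst$p_value, digits = 3),
                       " |"))
  }
  writeLines(md, paste0(path, ".md"))
  invisible(path)
}
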