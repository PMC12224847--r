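#' Default feature selection for a cohort
#'
#' All demographic, lifestyle and biochemical columns of a cohort — i.e.
#' everything except identifiers, the planted group, the disease flags and
#' the raw diagnostic measurements.
#'
#' @param cohort cohort data.frame.
#' @return character vector of column names.
#' @export
default_features <- function(cohort) {
  drop <- c("id", "planted_group", .cmm_diseases,
            grep("^raw_", names(cohort), value = TRUE))
  setdiff(names(cohort), drop)
}

#' Assemble the standardized numeric feature matrix
#'
#' Continuous (numeric and logical) columns are z-scored with the cohort's
#' own mean and standard deviation; categorical columns are one-hot encoded
#' over all levels (each row block sums to 1). Column order is
#' deterministic: the selection order, with categorical levels in level
#' order. Zero-variance continuous columns are dropped with a warning. The
#' scaling and encoding are stored so held-out rows can be projected with
#' training-set parameters via [project_features()].
#'
#' @param cohort cohort data.frame.
#' @param features character vector of columns to use; defaults to
#'   [default_features()].
#' @param include_diseases if `TRUE`, the five disease flags are appended as
#'   0/1 z-scored features (the default for graph construction); keep
#'   `FALSE` for classifiers to avoid label leakage.
#' @param sd_type `"population"` (divide by n, the default) or `"sample"`.
#' @return a `cmm_feature_matrix`: list with `values`, `feature_names`,
#'   `scaling`, `encoding_map`, `row_ids` and the builder arguments.
#' @export
build_feature_matrix <- function(cohort, features = NULL,
                                 include_diseases = TRUE,
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) < 2) stop("need at least 2 records", call. = FALSE)
  if (is.null(features)) features <- default_features(cohort)
  miss <- setdiff(features, names(cohort))
  if (length(miss))
    stop("features absent from cohort: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (include_diseases) features <- c(features, .cmm_diseases)

  n <- nrow(cohort)
  cols <- list()
  scaling <- list()
  encoding <- list()
  for (f in features) {
    x <- cohort[[f]]
    if (is.factor(x) || is.character(x)) {
      x <- if (is.factor(x)) x else factor(x)
      lv <- levels(x)
      block <- matrix(0, n, length(lv),
                      dimnames = list(NULL, paste0(f, "=", lv)))
      block[cbind(seq_len(n), as.integer(x))] <- 1
      cols[[f]] <- block
      encoding[[f]] <- colnames(block)
    } else {
      x <- as.numeric(x)
      mu <- mean(x)
      sdv <- if (sd_type == "population") sqrt(mean((x - mu)^2)) else sd(x)
      if (!is.finite(sdv) || sdv == 0) {
        warning("dropping zero-variance feature '", f, "'", call. = FALSE)
        next
      }
      cols[[f]] <- matrix((x - mu) / sdv, ncol = 1,
                          dimnames = list(NULL, f))
      scaling[[f]] <- c(mean = mu, sd = sdv)
    }
  }
  values <- do.call(cbind, unname(cols))
  structure(list(values = values,
                 feature_names = colnames(values),
                 scaling = scaling,
                 encoding_map = encoding,
                 row_ids = if (!is.null(cohort$id)) as.character(cohort$id)
                           else as.character(seq_len(n)),
                 features = features,
                 include_diseases = include_diseases,
                 sd_type = sd_type),
            class = "cmm_feature_matrix")
}

#' Project new rows through stored scaling and encoding
#'
#' Applies a fitted [build_feature_matrix()] transform (training-set means,
#' SDs and one-hot layout) to new records, so test rows never contribute to
#' the scaling.
#'
#' @param fm a `cmm_feature_matrix`.
#' @param cohort data.frame of new records with the same columns.
#' @return numeric matrix with columns `fm$feature_names`.
#' @export
project_features <- function(fm, cohort) {
  cohort <- as.data.frame(cohort)
  n <- nrow(cohort)
  out <- matrix(0, n, length(fm$feature_names),
                dimnames = list(NULL, fm$feature_names))
  for (f in names(fm$scaling)) {
    p <- fm$scaling[[f]]
    out[, f] <- (as.numeric(cohort[[f]]) - p["mean"]) / p["sd"]
  }
  for (f in names(fm$encoding_map)) {
    lv <- sub(paste0("^", f, "="), "", fm$encoding_map[[f]])
    x <- as.character(cohort[[f]])
    unknown <- !(x %in% lv)
    if (any(unknown))
      stop("unknown level(s) for '", f, "': ",
           paste(unique(x[unknown]), collapse = ", "), call. = FALSE)
    out[cbind(seq_len(n),
              match(paste0(f, "=", x), fm$feature_names))] <- 1
  }
  out
}

#' Export a feature matrix as TSV plus a JSON transform sidecar
#'
#' @param fm a `cmm_feature_matrix`.
#' @param path TSV path; the transform is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm$values)
  df <- cbind(id = fm$row_ids, df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(scaling = fm$scaling,
                            encoding_map = fm$encoding_map,
                            sd_type = fm$sd_type,
                            include_diseases = fm$include_diseases),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
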