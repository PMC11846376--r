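#' Participant-level trial data container
#'
#' Bundles the outcome, treatment indicator, covariate table and per-column
#' metadata for a two-arm randomised trial. All modelling functions in the
#' package consume and return this container.
#'
#' @param Y binary outcome vector (1 = alive at day 28), values in \{0, 1\}.
#' @param W binary treatment indicator, values in \{0, 1\}.
#' @param X data frame of baseline covariates; columns may be numeric
#'   (continuous or 0/1 binary) or factor (categorical).
#' @param meta optional data frame of per-column metadata with columns
#'   `name`, `kind` (`"continuous"`, `"binary"` or `"categorical"`),
#'   `center`, `scale` (NA until standardised), `missing_frac`,
#'   `derived_score` (logical; used as a tie-break when dropping correlated
#'   columns). Rebuilt from `X` when omitted.
#' @param weights optional strictly positive per-row weights (default 1);
#'   populated by the inverse-probability-weighting missing-data strategy.
#'
#' @return An object of class `trial_data`: a list with elements `Y`, `W`,
#'   `X`, `meta`, `weights`.
#' @export
trial_data <- function(Y, W, X, meta = NULL, weights = NULL) {
  Y <- as.numeric(Y)
  W <- as.numeric(W)
  if (!all(stats::na.omit(Y) %in% c(0, 1))) {
    stop("outcome Y must be binary 0/1; offending values: ",
         paste(utils::head(setdiff(unique(Y), c(0, 1, NA))), collapse = ", "))
  }
  if (!all(stats::na.omit(W) %in% c(0, 1))) {
    stop("treatment W must be binary 0/1; offending values: ",
         paste(utils::head(setdiff(unique(W), c(0, 1, NA))), collapse = ", "))
  }
  X <- as.data.frame(X, stringsAsFactors = FALSE)
  if (length(Y) != length(W) || (ncol(X) > 0 && nrow(X) != length(Y))) {
    stop("Y, W and X must describe the same participants")
  }
  if (is.null(weights)) weights <- rep(1, length(Y))
  if (any(weights <= 0)) stop("weights must be strictly positive")
  if (is.null(meta)) meta <- infer_meta(X)
  stopifnot(identical(meta$name, names(X)))
  structure(list(Y = Y, W = W, X = X, meta = meta, weights = weights),
            class = "trial_data")
}

infer_meta <- function(X) {
  kinds <- vapply(X, function(col) {
    if (is.factor(col) || is.character(col)) return("categorical")
    v <- stats::na.omit(col)
    if (all(v %in% c(0, 1))) "binary" else "continuous"
  }, character(1))
  data.frame(
    name = if (ncol(X)) names(X) else character(0),
    kind = unname(kinds),
    center = NA_real_,
    scale = NA_real_,
    missing_frac = vapply(X, function(col) mean(is.na(col)), numeric(1),
                          USE.NAMES = FALSE),
    derived_score = FALSE,
    stringsAsFactors = FALSE
  )
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("trial_data: %d participants, %d covariates\n",
              length(x$Y), ncol(x$X)))
  cat(sprintf("  treated %d / control %d; outcome prevalence %.3f\n",
              sum(x$W == 1), sum(x$W == 0), mean(x$Y)))
  mf <- x$meta$missing_frac
  if (any(mf > 0)) {
    cat(sprintf("  %d covariate(s) with missing entries (max %.1f%%)\n",
                sum(mf > 0), 100 * max(mf)))
  }
  if (!all(x$weights == 1)) cat("  row weights present (IPW pathway)\n")
  invisible(x)
}

#' @export
dim.trial_data <- function(x) c(length(x$Y), ncol(x$X))

#' Number of participants
#' @param data a [trial_data] object.
#' @return integer row count.
#' @export
n_participants <- function(data) length(data$Y)

#' Write / read a trial dataset as CSV with a JSON metadata sidecar
#'
#' The CSV holds columns `Y`, `W`, the covariates and (when not all 1) a
#' `.weight` column; missing entries are empty cells. The sidecar
#' (`<path>.meta.json`) carries the per-column metadata and, when present,
#' the generating configuration, so a round trip reproduces the container
#' exactly.
#'
#' @param data a [trial_data] object.
#' @param path CSV file path; the sidecar is written next to it.
#' @param config optional generating configuration (e.g. a [dgp_config]) to
#'   freeze alongside the data.
#' @return `write_trial_csv()` returns `path` invisibly; `read_trial_csv()`
#'   returns a [trial_data].
#' @export
write_trial_csv <- function(data, path, config = NULL) {
  df <- data.frame(Y = data$Y, W = data$W, check.names = FALSE)
  if (ncol(data$X)) df <- cbind(df, data$X)
  if (!all(data$weights == 1)) df$.weight <- data$weights
  utils::write.csv(df, path, row.names = FALSE, na = "")
  side <- list(meta = data$meta,
               has_weights = !all(data$weights == 1))
  if (!is.null(config)) side$config <- unclass(config)
  jsonlite::write_json(side, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trial_csv
#' @param na_sentinels character values (besides empty cells) read as missing.
#' @param schema optional named list mapping roles to column names, e.g.
#'   `list(outcome = "Y", treatment = "W")`; defaults to columns `Y` and `W`.
#' @export
read_trial_csv <- function(path, schema = list(outcome = "Y", treatment = "W"),
                           na_sentinels = c("", "NA")) {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = na_sentinels,
                        stringsAsFactors = FALSE)
  ycol <- schema$outcome %||% "Y"
  wcol <- schema$treatment %||% "W"
  if (!all(c(ycol, wcol) %in% names(df))) {
    stop("outcome/treatment columns not found: ", ycol, ", ", wcol)
  }
  weights <- NULL
  if (".weight" %in% names(df)) {
    weights <- df$.weight
    df$.weight <- NULL
  }
  meta <- NULL
  sidecar <- paste0(path, ".meta.json")
  Xdf <- df[setdiff(names(df), c(ycol, wcol))]
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    meta <- as.data.frame(side$meta, stringsAsFactors = FALSE)
    for (j in seq_len(nrow(meta))) {
      if (meta$kind[j] == "categorical" && meta$name[j] %in% names(Xdf)) {
        Xdf[[meta$name[j]]] <- factor(Xdf[[meta$name[j]]])
      }
    }
  } else {
    Xdf[] <- lapply(Xdf, function(col) if (is.character(col)) factor(col) else col)
  }
  trial_data(df[[ycol]], df[[wcol]], Xdf, meta = meta, weights = weights)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
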