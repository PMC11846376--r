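#' Preprocessing report
#'
#' Record of what the screening and missing-data steps did: which covariates
#' were removed and why, which imputation method ran and, for the iterative
#' random-forest imputer, its convergence trace.
#'
#' @param removed_for_missingness data frame `(name, fraction)`.
#' @param removed_for_correlation data frame `(kept, dropped, r)`.
#' @param imputation_method one of `"missforest"`, `"mean"`,
#'   `"complete_case"`, `"ipw"`, `"none"`.
#' @param iterations_run integer.
#' @param convergence_trace numeric per-iteration discrepancies (iterative
#'   imputer only).
#' @param notes character vector of warnings recorded along the way.
#' @return an object of class `preprocess_report`.
#' @export
preprocess_report <- function(removed_for_missingness = empty_removed("fraction"),
                              removed_for_correlation = empty_removed_corr(),
                              imputation_method = "none",
                              iterations_run = 0L,
                              convergence_trace = numeric(0),
                              notes = character(0)) {
  structure(list(removed_for_missingness = removed_for_missingness,
                 removed_for_correlation = removed_for_correlation,
                 imputation_method = imputation_method,
                 iterations_run = iterations_run,
                 convergence_trace = convergence_trace,
                 notes = notes),
            class = "preprocess_report")
}

empty_removed <- function(valcol) {
  df <- data.frame(name = character(0), x = numeric(0), stringsAsFactors = FALSE)
  names(df)[2] <- valcol
  df
}
empty_removed_corr <- function() {
  data.frame(kept = character(0), dropped = character(0), r = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("preprocess_report\n")
  cat(sprintf("  removed for missingness: %d\n", nrow(x$removed_for_missingness)))
  cat(sprintf("  removed for correlation: %d\n", nrow(x$removed_for_correlation)))
  cat(sprintf("  imputation: %s (%d iteration(s))\n",
              x$imputation_method, x$iterations_run))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

drop_columns <- function(data, drop) {
  keep <- setdiff(names(data$X), drop)
  data$X <- data$X[keep]
  data$meta <- data$meta[match(keep, data$meta$name), , drop = FALSE]
  rownames(data$meta) <- NULL
  data
}

#' Drop covariates with high missingness
#'
#' Keeps only baseline covariates with missingness strictly below
#' `max_fraction` (default 30\%): a column missing exactly at the cut is
#' dropped. Outcome and treatment are never touched.
#'
#' @param data a [trial_data].
#' @param max_fraction missingness cut in (0, 1).
#' @return list `(data, report)`.
#' @export
filter_high_missingness <- function(data, max_fraction = 0.3) {
  stopifnot(inherits(data, "trial_data"),
            max_fraction > 0, max_fraction < 1)
  frac <- vapply(data$X, function(col) mean(is.na(col)), numeric(1))
  bad <- names(data$X)[frac >= max_fraction]
  if (length(bad) == ncol(data$X) && ncol(data$X) > 0) {
    stop("no covariates remain after the missingness filter")
  }
  removed <- data.frame(name = bad, fraction = unname(frac[bad]),
                        stringsAsFactors = FALSE)
  data$meta$missing_frac <- unname(frac)
  data <- drop_columns(data, bad)
  list(data = data, report = preprocess_report(removed_for_missingness = removed))
}

#' Drop one of each highly correlated covariate pair
#'
#' Computes pairwise-complete Pearson correlations between numeric covariate
#' columns; for each pair with `|r| > r_max` (strict), the member carrying
#' less information is dropped: higher missingness first, then a declared
#' derived-score flag, then the later column. Pairs are visited greedily in
#' decreasing `|r|`; pairs whose members were already removed are skipped.
#'
#' @param data a [trial_data].
#' @param r_max correlation cut in (0, 1), default 0.7.
#' @return list `(data, report)`.
#' @export
filter_correlated <- function(data, r_max = 0.7) {
  stopifnot(inherits(data, "trial_data"), r_max > 0, r_max < 1)
  num <- names(data$X)[!vapply(data$X, is.factor, logical(1))]
  removed <- empty_removed_corr()
  if (length(num) >= 2) {
    M <- as.matrix(data$X[num])
    cm <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
    cm[is.na(cm)] <- 0
    pairs <- which(upper.tri(cm) & abs(cm) > r_max, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(-abs(cm[pairs]))
      pairs <- pairs[ord, , drop = FALSE]
      miss <- vapply(data$X[num], function(col) mean(is.na(col)), numeric(1))
      score <- data$meta$derived_score[match(num, data$meta$name)]
      dropped <- character(0)
      for (k in seq_len(nrow(pairs))) {
        a <- num[pairs[k, 1]]; b <- num[pairs[k, 2]]
        if (a %in% dropped || b %in% dropped) next
        drop <- pick_less_informative(a, b, miss, score, num)
        keep <- setdiff(c(a, b), drop)
        dropped <- c(dropped, drop)
        removed <- rbind(removed, data.frame(
          kept = keep, dropped = drop, r = cm[pairs[k, 1], pairs[k, 2]],
          stringsAsFactors = FALSE))
      }
      data <- drop_columns(data, dropped)
    }
  }
  list(data = data, report = preprocess_report(removed_for_correlation = removed))
}

pick_less_informative <- function(a, b, miss, score, order_ref) {
  if (miss[a] != miss[b]) return(if (miss[a] > miss[b]) a else b)
  sa <- score[match(a, order_ref)]; sb <- score[match(b, order_ref)]
  if (isTRUE(sa) != isTRUE(sb)) return(if (isTRUE(sa)) a else b)
  if (match(a, order_ref) > match(b, order_ref)) a else b
}

#' One-hot encode categoricals and standardise continuous covariates
#'
#' Each categorical column is replaced by one indicator per level (no
#' reference level is dropped: downstream consumers are penalised or
#' tree-based; the unpenalised univariable screen re-encodes with a
#' reference level itself). Continuous columns are centred and scaled to
#' mean 0, SD 1 using the sample SD (`denominator n-1`) over non-missing
#' values; the original mean and SD are stored in the metadata so
#' thresholds learned on the standardised scale can be mapped back to raw
#' units. Zero-variance continuous columns are dropped with a note.
#'
#' @param data a [trial_data].
#' @return list `(data, report)`.
#' @export
encode_and_scale <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  notes <- character(0)
  out <- list(); meta_rows <- list()
  for (j in seq_along(data$X)) {
    nm <- names(data$X)[j]
    kind <- data$meta$kind[j]
    col <- data$X[[j]]
    if (kind == "categorical") {
      lv <- levels(factor(col))
      for (l in lv) {
        cn <- paste0(nm, ".", l)
        v <- as.numeric(col == l)
        v[is.na(col)] <- NA
        out[[cn]] <- v
        meta_rows[[cn]] <- data.frame(
          name = cn, kind = "binary", center = NA_real_, scale = NA_real_,
          missing_frac = mean(is.na(v)), derived_score = data$meta$derived_score[j],
          stringsAsFactors = FALSE)
      }
    } else if (kind == "continuous") {
      mu <- mean(col, na.rm = TRUE)
      sdv <- stats::sd(col, na.rm = TRUE)
      if (!is.finite(sdv) || sdv == 0) {
        notes <- c(notes, paste0("dropped zero-variance column ", nm))
        next
      }
      out[[nm]] <- (col - mu) / sdv
      meta_rows[[nm]] <- data.frame(
        name = nm, kind = "continuous", center = mu, scale = sdv,
        missing_frac = mean(is.na(col)), derived_score = data$meta$derived_score[j],
        stringsAsFactors = FALSE)
    } else {
      out[[nm]] <- as.numeric(col)
      meta_rows[[nm]] <- data$meta[j, , drop = FALSE]
    }
  }
  data$X <- as.data.frame(out, check.names = FALSE)
  data$meta <- do.call(rbind, c(meta_rows, list(make.row.names = FALSE)))
  list(data = data,
       report = preprocess_report(notes = notes))
}

#' Map a threshold on a standardised covariate back to raw units
#'
#' @param meta the metadata table of an encoded [trial_data].
#' @param name covariate name.
#' @param value threshold on the standardised scale.
#' @return threshold in the covariate's original units (unchanged when the
#'   column was never standardised).
#' @export
unscale_threshold <- function(meta, name, value) {
  i <- match(name, meta$name)
  if (is.na(i) || is.na(meta$center[i])) return(value)
  meta$center[i] + value * meta$scale[i]
}

#' Handle missing covariate entries
#'
#' Four strategies:
#' \describe{
#'   \item{missforest}{iterative random-forest imputation: variables are
#'     visited in order of increasing missingness; each incomplete variable
#'     is regressed on all other covariates with a random forest (regression
#'     for continuous, classification for binary/categorical) and its
#'     missing part predicted; iteration stops the first time the summed
#'     normalised discrepancy between successive imputations increases, and
#'     the previous iterate is returned.}
#'   \item{mean}{column means (modes for categorical).}
#'   \item{complete_case}{rows with any missing covariate removed.}
#'   \item{ipw}{complete cases kept, weighted by the inverse of the
#'     probability of being complete, from a logistic model of the
#'     completeness indicator on treatment, outcome and the fully observed
#'     covariates; estimated probabilities below 0.01 trigger a
#'     weight-explosion note and truncation at the 1st percentile.}
#' }
#' Observed entries are never altered.
#'
#' @param data a [trial_data].
#' @param method `"missforest"`, `"mean"`, `"complete_case"` or `"ipw"`.
#' @param max_iter cap on imputation iterations (missforest).
#' @param n_trees trees per random forest (missforest), default 100.
#' @param seed integer seed for the forests.
#' @return list `(data, report)`.
#' @export
impute <- function(data, method = c("missforest", "mean", "complete_case", "ipw"),
                   max_iter = 10L, n_trees = 100L, seed = 1L) {
  stopifnot(inherits(data, "trial_data"))
  method <- match.arg(method)
  any_missing <- any(vapply(data$X, function(col) anyNA(col), logical(1)))
  if (!any_missing) {
    return(list(data = data,
                report = preprocess_report(imputation_method = method)))
  }
  switch(method,
         missforest = impute_missforest(data, max_iter, n_trees, seed),
         mean = impute_mean(data),
         complete_case = impute_complete_case(data),
         ipw = impute_ipw(data))
}

impute_mean <- function(data) {
  for (j in seq_along(data$X)) {
    col <- data$X[[j]]
    if (!anyNA(col)) next
    if (is.factor(col)) {
      tab <- table(col)
      col[is.na(col)] <- names(tab)[which.max(tab)]
    } else {
      col[is.na(col)] <- mean(col, na.rm = TRUE)
    }
    data$X[[j]] <- col
  }
  list(data = data, report = preprocess_report(imputation_method = "mean"))
}

impute_complete_case <- function(data) {
  keep <- stats::complete.cases(data$X)
  data$Y <- data$Y[keep]; data$W <- data$W[keep]
  data$X <- data$X[keep, , drop = FALSE]
  rownames(data$X) <- NULL
  data$weights <- data$weights[keep]
  data$meta$missing_frac <- 0
  list(data = data,
       report = preprocess_report(imputation_method = "complete_case"))
}

impute_ipw <- function(data) {
  complete <- stats::complete.cases(data$X)
  full_cols <- names(data$X)[!vapply(data$X, anyNA, logical(1))]
  df <- data.frame(.complete = as.numeric(complete), Y = data$Y, W = data$W,
                   data$X[full_cols], check.names = FALSE)
  fit <- stats::glm(.complete ~ ., data = df, family = stats::binomial())
  p <- stats::fitted(fit)
  notes <- character(0)
  if (any(p[complete] < 0.01)) {
    notes <- "estimated completeness probabilities below 0.01; truncated at the 1st percentile"
    p <- pmax(p, stats::quantile(p, 0.01))
  }
  w <- 1 / p
  data$weights <- data$weights * w
  res <- impute_complete_case(data)
  res$report$imputation_method <- "ipw"
  res$report$notes <- notes
  res
}

impute_missforest <- function(data, max_iter, n_trees, seed) {
  X <- data$X
  nav <- lapply(X, is.na)
  miss_n <- vapply(nav, sum, integer(1))
  targets <- names(X)[miss_n > 0]
  targets <- targets[order(miss_n[targets])]  # least missing first
  ## initial fill: mean / mode
  prev <- impute_mean(data)$data$X
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cur <- prev
    for (v in targets) {
      mis <- nav[[v]]
      train <- cur[!mis, setdiff(names(cur), v), drop = FALSE]
      test <- cur[mis, setdiff(names(cur), v), drop = FALSE]
      yv <- cur[[v]][!mis]
      fac <- is.factor(X[[v]])
      if (!fac && length(unique(yv)) <= 2) {
        ## binary numeric: classify then map back to 0/1
        yv <- factor(yv)
        fac2 <- TRUE
      } else fac2 <- fac
      fit <- ranger::ranger(x = train, y = if (fac2) factor(yv) else yv,
                            num.trees = n_trees, seed = seed + iter,
                            mtry = ceiling(sqrt(ncol(train))),
                            num.threads = 1, verbose = FALSE)
      pred <- stats::predict(fit, data = test, num.threads = 1)$predictions
      if (fac2 && !fac) pred <- as.numeric(as.character(pred))
      cur[[v]][mis] <- pred
    }
    ## summed normalised discrepancy between successive imputations
    d_cont <- 0; d_cat <- 0; any_cont <- FALSE; any_cat <- FALSE
    for (v in targets) {
      if (is.factor(X[[v]])) {
        any_cat <- TRUE
        d_cat <- d_cat + sum(cur[[v]][nav[[v]]] != prev[[v]][nav[[v]]]) /
          max(1L, sum(nav[[v]]))
      } else {
        any_cont <- TRUE
        denom <- sum(cur[[v]]^2)
        d_cont <- d_cont + sum((cur[[v]] - prev[[v]])^2) / max(denom, 1e-12)
      }
    }
    disc <- (if (any_cont) d_cont else 0) + (if (any_cat) d_cat else 0)
    trace <- c(trace, disc)
    if (iter > 1 && disc >= trace[iter - 1]) {
      ## discrepancy increased: return the previous iterate
      cur <- prev
      iter <- iter - 1L
      break
    }
    prev <- cur
    if (iter >= max_iter) break
  }
  data$X <- prev
  list(data = data,
       report = preprocess_report(imputation_method = "missforest",
                                  iterations_run = iter,
                                  convergence_trace = trace))
}
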