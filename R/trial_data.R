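# Patient-level trial data: container, validation, CSV I/O, and the
# within-replicate imputation hook used inside the sampling engines.

CANONICAL_COLS <- c("patient_id", "arm", "cost", "qaly", "events", "followup")

#' Patient-level trial data
#'
#' A `trial_data` object is a data frame with one row per patient and the
#' canonical columns `patient_id`, `arm`, `cost` (currency units, >= 0),
#' `qaly` (effectiveness in QALYs), `events` (non-negative integer count,
#' e.g. exacerbations) and `followup` (positive, weeks). `cost`, `qaly` and
#' `events` may be `NA` (missing); `followup` may not. The ordered set of
#' arm labels is kept in the `"arms"` attribute. At least two arms, each
#' with at least two patients, are required.
#'
#' @param records data frame holding the canonical columns. `patient_id` is
#'   optional (sequential ids are generated) as is `followup` (filled with
#'   `default_followup`).
#' @param arms optional character vector fixing the arm order; defaults to
#'   order of first appearance.
#' @param default_followup follow-up, in weeks, used when the `followup`
#'   column is absent. The default (52) is a one-year outcome window.
#' @return a validated `trial_data` object.
#' @examples
#' d <- trial_data(data.frame(
#'   arm = rep(c("A", "B"), each = 3),
#'   cost = c(10, 20, 30, 40, 50, 60),
#'   qaly = c(.7, .8, .9, .6, .7, .8),
#'   events = c(0, 1, 2, 1, 1, 3)))
#' arms(d)
#' @export
trial_data <- function(records, arms = NULL, default_followup = 52) {
  if (!is.data.frame(records) || nrow(records) == 0)
    .stop_mod("trial_io", "records must be a non-empty data frame")
  df <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(df$patient_id))
    df$patient_id <- sprintf("p%04d", seq_len(nrow(df)))
  if (is.null(df$followup))
    df$followup <- default_followup
  missing_cols <- setdiff(CANONICAL_COLS, names(df))
  if (length(missing_cols))
    .stop_mod("trial_io", "missing column(s): %s",
              paste(missing_cols, collapse = ", "))
  df <- df[CANONICAL_COLS]
  df$patient_id <- as.character(df$patient_id)
  df$arm <- as.character(df$arm)
  for (col in c("cost", "qaly", "events", "followup"))
    df[[col]] <- .coerce_numeric(df[[col]], col)
  .validate_trial(df, arms)
}

.coerce_numeric <- function(x, name) {
  if (is.numeric(x)) return(as.numeric(x))
  raw <- as.character(x)
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & raw != "" & raw != "NA" & is.na(num))
  if (length(bad))
    .stop_mod("trial_io", "column '%s': non-numeric value '%s' at row %d",
              name, raw[bad[1]], bad[1])
  num
}

.validate_trial <- function(df, arms = NULL) {
  bad <- which(is.na(df$arm) | df$arm == "")
  if (length(bad))
    .stop_mod("trial_io", "empty arm label at row %d", bad[1])
  bad <- which(!is.na(df$cost) & df$cost < 0)
  if (length(bad))
    .stop_mod("trial_io", "negative cost at row %d", bad[1])
  bad <- which(!is.na(df$events) &
                 (df$events < 0 | abs(df$events - round(df$events)) > 1e-8))
  if (length(bad))
    .stop_mod("trial_io", "events must be a non-negative integer (row %d)",
              bad[1])
  bad <- which(is.na(df$followup) | df$followup <= 0)
  if (length(bad))
    .stop_mod("trial_io", "followup must be present and positive (row %d)",
              bad[1])
  seen <- unique(df$arm)
  if (is.null(arms)) arms <- seen
  if (!setequal(arms, seen))
    .stop_mod("trial_io", "arm labels in data (%s) do not match 'arms' (%s)",
              paste(seen, collapse = ","), paste(arms, collapse = ","))
  if (length(arms) < 2)
    .stop_mod("trial_io", "a trial needs at least 2 arms, found %d",
              length(arms))
  sizes <- table(df$arm)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    .stop_mod("trial_io", "arm '%s' has fewer than 2 patients", small[1])
  structure(df, arms = as.character(arms),
            class = c("trial_data", "data.frame"))
}

#' @rdname trial_data
#' @param x a `trial_data` object.
#' @export
arms <- function(x) attr(x, "arms")

#' @export
print.trial_data <- function(x, ...) {
  a <- arms(x)
  sizes <- vapply(a, function(g) sum(x$arm == g), 1L)
  cat(sprintf("trial_data: %d patients, %d arms (%s)\n", nrow(x), length(a),
              paste(sprintf("%s: n=%d", a, sizes), collapse = ", ")))
  nmiss <- vapply(c("cost", "qaly", "events"), function(c) sum(is.na(x[[c]])), 1L)
  if (any(nmiss > 0))
    cat(sprintf("missing values: cost=%d qaly=%d events=%d\n",
                nmiss[1], nmiss[2], nmiss[3]))
  invisible(x)
}

#' Read / write patient-level trial data
#'
#' CSV with a header row; missing cells are an empty string or `"NA"` on
#' read and written back as `"NA"`, so a write/read round trip preserves
#' missingness flags exactly.
#'
#' @param path file path.
#' @param dialect optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(qaly = "utility_total", events = "n_exac")`.
#' @param default_followup follow-up (weeks) when the file has no followup
#'   column.
#' @return `read_trial` returns a validated [trial_data()];
#'   `write_trial` invisibly returns `path`.
#' @export
read_trial <- function(path, dialect = NULL, default_followup = 52) {
  if (!file.exists(path))
    .stop_mod("trial_io", "file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(df))
        .stop_mod("trial_io", "mapped column '%s' not present in %s", src, path)
      names(df)[names(df) == src] <- canon
    }
  }
  trial_data(df, default_followup = default_followup)
}

#' @rdname read_trial
#' @param data a `trial_data` object.
#' @export
write_trial <- function(data, path) {
  data <- .validate_trial(as.data.frame(data), arms(data))
  write.csv(as.data.frame(data), path, row.names = FALSE, na = "NA")
  invisible(path)
}

# impute one numeric vector within an arm given that arm's bootstrap weights;
# consumes RNG only for hot_deck with >=1 missing value
.impute_vec <- function(x, w, method, integer_valued = FALSE) {
  na <- which(is.na(x))
  if (!length(na)) return(x)
  obs <- which(!is.na(x))
  if (!length(obs))
    .stop_mod("trial_io", "cannot impute: no observed values in arm")
  wo <- w[obs]
  if (sum(wo) <= 0) wo <- rep(1, length(obs))  # all bootstrap mass on missing rows
  if (method == "weighted_arm_mean") {
    m <- sum(x[obs] * wo) / sum(wo)
    if (integer_valued) m <- round(m)
    x[na] <- m
  } else { # hot_deck
    donors <- obs[sample.int(length(obs), length(na), replace = TRUE,
                             prob = wo / sum(wo))]
    x[na] <- x[donors]
  }
  x
}

#' Within-replicate imputation of missing values
#'
#' Completes missing `cost`, `qaly` and `events` cells of a trial using one
#' replicate's bootstrap weights, so that imputation uncertainty propagates
#' through the resampling run (the hook runs inside each replicate of the
#' sampling engines, between weight generation and parameter computation).
#' Observed values are never altered.
#'
#' `weighted_arm_mean` replaces a missing cell by the bootstrap-weighted
#' mean of the observed same-arm values of that field (events rounded to
#' the nearest integer); `hot_deck` draws a same-arm observed donor with
#' probability proportional to its bootstrap weight (seed the RNG for
#' reproducibility).
#'
#' @param data a [trial_data()] object, possibly with missing values.
#' @param weights a [bootstrap_weights] object conforming to `data`'s arms.
#' @param method `"weighted_arm_mean"` (default) or `"hot_deck"`.
#' @return a completed `trial_data` copy (no missing flags remain).
#' @export
impute_within_replicate <- function(data, weights,
                                    method = c("weighted_arm_mean", "hot_deck")) {
  method <- match.arg(method)
  stopifnot(inherits(data, "trial_data"), inherits(weights, "bootstrap_weights"))
  a <- arms(data)
  if (!identical(sort(a), sort(names(weights))))
    .stop_mod("trial_io", "weights do not conform to the trial's arms")
  out <- data
  for (g in a) {
    idx <- which(out$arm == g)
    w <- weights[[g]]
    if (length(w) != length(idx))
      .stop_mod("trial_io", "weight vector length mismatch for arm '%s'", g)
    out$cost[idx] <- .impute_vec(out$cost[idx], w, method)
    out$qaly[idx] <- .impute_vec(out$qaly[idx], w, method)
    out$events[idx] <- .impute_vec(out$events[idx], w, method, integer_valued = TRUE)
  }
  out
}
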