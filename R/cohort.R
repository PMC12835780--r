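# Data model for multi-group right-censored survival cohorts.

#' Construct a survival cohort
#'
#' A `survival_cohort` bundles follow-up times, event indicators, a
#' sensitive-attribute group label and a numeric covariate matrix, and
#' validates the joint structure. The group label is deliberately kept
#' outside the covariate matrix: it is used by the fairness objectives and
#' the evaluation suite, never as a predictor.
#'
#' @param time Positive follow-up times (any consistent unit; never rescaled).
#' @param event Event indicators, 1 = event observed, 0 = right-censored.
#' @param group Group labels: a factor, character or integer vector. Stored
#'   internally as a dense integer code `1..K` plus a `group_names` map.
#' @param covariates Numeric matrix, one row per subject (may have 0 columns).
#' @param feature_names Optional column names for `covariates`.
#' @param group_levels Optional character vector fixing the group coding
#'   order; defaults to the order of first appearance for factors/characters.
#' @return An object of class `survival_cohort` with elements `time`,
#'   `event`, `group` (integer codes), `covariates`, `feature_names`,
#'   `group_names`.
#' @examples
#' ch <- survival_cohort(time = c(5, 3, 8, 2), event = c(1, 0, 1, 1),
#'                       group = c("a", "b", "a", "b"),
#'                       covariates = matrix(rnorm(8), 4, 2))
#' ch$group_names
#' @export
survival_cohort <- function(time, event, group, covariates,
                            feature_names = NULL, group_levels = NULL) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  n <- length(time)
  if (length(event) != n || length(group) != n)
    stop("time, event and group must have equal length")
  if (anyNA(time) || any(!is.finite(time)))
    stop("non-finite follow-up time at row(s): ",
         paste(utils::head(which(!is.finite(time)), 5L), collapse = ", "))
  if (any(time <= 0))
    stop("nonpositive follow-up time at row(s): ",
         paste(utils::head(which(time <= 0), 5L), collapse = ", "))
  if (anyNA(event) || !all(event %in% c(0, 1)))
    stop("event indicator must be 0 or 1 for every subject")
  if (anyNA(group))
    stop("missing group label at row(s): ",
         paste(utils::head(which(is.na(group)), 5L), collapse = ", "))

  if (is.factor(group)) {
    group_names <- levels(group)
    gcode <- as.integer(group)
  } else if (is.character(group) || !is.null(group_levels)) {
    group_names <- if (!is.null(group_levels)) as.character(group_levels)
                   else unique(as.character(group))
    gcode <- match(as.character(group), group_names)
    if (anyNA(gcode)) stop("group label outside the supplied group_levels")
  } else {
    gcode <- as.integer(group)
    if (any(gcode < 1L)) stop("integer group codes must be >= 1")
    group_names <- as.character(seq_len(max(gcode)))
  }

  if (is.null(covariates)) covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  covariates <- as.matrix(covariates)
  storage.mode(covariates) <- "double"
  if (nrow(covariates) != n)
    stop("covariates must have one row per subject")
  if (ncol(covariates) > 0 && any(!is.finite(covariates)))
    stop("covariates contain non-finite values after preprocessing")
  if (is.null(feature_names)) {
    feature_names <- colnames(covariates)
    if (is.null(feature_names) && ncol(covariates) > 0)
      feature_names <- paste0("x", seq_len(ncol(covariates)))
  }
  if (ncol(covariates) > 0) colnames(covariates) <- feature_names

  structure(
    list(time = time, event = event, group = gcode,
         covariates = covariates,
         feature_names = as.character(feature_names %||% character(0)),
         group_names = group_names),
    class = "survival_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.survival_cohort <- function(x, ...) {
  n <- length(x$time)
  cat("<survival_cohort> ", n, " subjects, ",
      ncol(x$covariates), " covariates, ",
      length(x$group_names), " groups\n", sep = "")
  cat("  events: ", sum(x$event), " (",
      sprintf("%.1f%%", 100 * mean(x$event)), "), follow-up ",
      sprintf("%.3g-%.3g", min(x$time), max(x$time)), "\n", sep = "")
  tab <- table(factor(x$group, levels = seq_along(x$group_names),
                      labels = x$group_names))
  cat("  groups: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x A `survival_cohort`.
#' @return Integer subject count.
#' @export
n_subjects <- function(x) length(x$time)

#' Subset a cohort by row index
#'
#' @param cohort A `survival_cohort`.
#' @param idx Integer index vector (duplicates allowed, e.g. bootstrap).
#' @return A `survival_cohort` restricted to `idx`, keeping the group map.
#' @export
subset_cohort <- function(cohort, idx) {
  survival_cohort(cohort$time[idx], cohort$event[idx],
                  cohort$group[idx],
                  cohort$covariates[idx, , drop = FALSE],
                  feature_names = cohort$feature_names,
                  group_levels = NULL) -> out
  out$group_names <- cohort$group_names
  out
}

#' One-hot encode mixed covariates with a missing-as-category rule
#'
#' Categorical columns expand to one indicator column per observed level;
#' when a column contains any missing value (NA or empty string) an extra
#' `"missing"` level is added, so missingness is modelled as its own
#' category rather than imputed. Continuous columns pass through unchanged.
#' Column order is deterministic: input column order, levels sorted, the
#' missing level last.
#'
#' @param raw_table A data.frame of covariates.
#' @param categorical_cols Character vector naming the categorical columns.
#' @return A list with `matrix` (numeric, n x p) and `feature_names`.
#' @examples
#' enc <- encode_covariates(
#'   data.frame(stage = c("A", "B", NA, "A"), psa = c(4.1, 7.2, 5, 9)),
#'   categorical_cols = "stage")
#' enc$feature_names
#' @export
encode_covariates <- function(raw_table, categorical_cols = character(0)) {
  stopifnot(is.data.frame(raw_table))
  unknown <- setdiff(categorical_cols, names(raw_table))
  if (length(unknown))
    stop("categorical column(s) not present: ", paste(unknown, collapse = ", "))
  blocks <- list(); nms <- character(0)
  for (cn in names(raw_table)) {
    col <- raw_table[[cn]]
    if (cn %in% categorical_cols) {
      v <- as.character(col)
      v[!is.na(v) & trimws(v) == ""] <- NA
      levs <- sort(unique(v[!is.na(v)]))
      if (anyNA(v)) {
        levs <- c(levs, "missing")
        v[is.na(v)] <- "missing"
      }
      ind <- matrix(0, length(v), length(levs))
      ind[cbind(seq_along(v), match(v, levs))] <- 1
      blocks[[length(blocks) + 1L]] <- ind
      nms <- c(nms, paste(cn, levs, sep = "="))
    } else {
      if (is.character(col) || is.factor(col)) {
        num <- suppressWarnings(as.numeric(as.character(col)))
        bad <- which(!is.na(as.character(col)) & is.na(num))
        if (length(bad))
          stop("continuous column '", cn, "' contains non-numeric token at row ",
               bad[1L])
        col <- num
      }
      if (anyNA(col))
        stop("continuous column '", cn,
             "' has missing values; only categorical columns use the ",
             "missing-as-category rule")
      blocks[[length(blocks) + 1L]] <- matrix(as.numeric(col), ncol = 1)
      nms <- c(nms, cn)
    }
  }
  m <- if (length(blocks)) do.call(cbind, blocks)
       else matrix(numeric(0), nrow(raw_table), 0)
  colnames(m) <- nms
  list(matrix = m, feature_names = nms)
}

#' Read a survival cohort from CSV
#'
#' Expects a header row naming the time, event and group columns; all other
#' columns are treated as covariates. Categorical covariates are one-hot
#' encoded via [encode_covariates()] (missing values become a distinct
#' category). Rows with missing time, event or group are dropped with a
#' warning; a nonpositive time is an error naming the offending row.
#'
#' @param path CSV file path (comma-separated, UTF-8, "." decimal; missing
#'   marker is an empty cell or `NA`).
#' @param schema A list with elements `time`, `event`, `group` (column
#'   names; defaults `"time"`, `"event"`, `"group"`), optional
#'   `categorical` (character vector of categorical covariate columns) and
#'   optional `group_levels` fixing the group coding order.
#' @return A `survival_cohort`.
#' @export
read_cohort <- function(path, schema = list()) {
  schema <- utils::modifyList(
    list(time = "time", event = "event", group = "group",
         categorical = character(0), group_levels = NULL), schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""), check.names = FALSE)
  need <- c(schema$time, schema$event, schema$group)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  key_na <- is.na(df[[schema$time]]) | is.na(df[[schema$event]]) |
            is.na(df[[schema$group]])
  if (any(key_na)) {
    warning(sum(key_na), " row(s) with missing time/event/group dropped")
    df <- df[!key_na, , drop = FALSE]
  }
  tm <- as.numeric(df[[schema$time]])
  if (any(!is.finite(tm) | tm <= 0))
    stop("validation error: nonpositive or non-finite time at row ",
         which(!is.finite(tm) | tm <= 0)[1L])
  cov_cols <- setdiff(names(df), need)
  enc <- encode_covariates(df[cov_cols], intersect(schema$categorical, cov_cols))
  survival_cohort(tm, as.numeric(df[[schema$event]]), df[[schema$group]],
                  enc$matrix, feature_names = enc$feature_names,
                  group_levels = schema$group_levels)
}

#' Write a survival cohort to CSV
#'
#' Inverse of [read_cohort()] for already-encoded cohorts: writes `time`,
#' `event`, `group` (as the group name) and the numeric covariate columns.
#' Reading the file back with the matching `group_levels` reproduces the
#' cohort exactly (to printed precision).
#'
#' @param cohort A `survival_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(time = cohort$time, event = cohort$event,
                   group = cohort$group_names[cohort$group],
                   check.names = FALSE)
  if (ncol(cohort$covariates) > 0)
    df <- cbind(df, as.data.frame(cohort$covariates, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Event-stratified train/validation split
#'
#' Partitions a cohort into training and validation subsets, sampling
#' events and censored subjects separately so both partitions carry an
#' event rate close to the cohort's. Reproducible under `seed`.
#'
#' @param cohort A `survival_cohort` with at least 2 events and 2 censored
#'   subjects.
#' @param train_fraction Fraction of subjects assigned to training
#'   (default 0.8).
#' @param seed Integer RNG seed.
#' @param stratify_on_event If `FALSE`, a simple random split.
#' @return A list with `train`, `valid` (both `survival_cohort`s) and the
#'   index vectors `train_idx`, `valid_idx`.
#' @export
split_cohort <- function(cohort, train_fraction = 0.8, seed = 1L,
                         stratify_on_event = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- n_subjects(cohort)
  ev <- which(cohort$event == 1)
  cs <- which(cohort$event == 0)
  if (stratify_on_event && (length(ev) < 2L || length(cs) < 2L))
    stop("cohort too small to stratify: need >= 2 events and >= 2 censored")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (stratify_on_event) {
    n_ev_tr <- round(train_fraction * length(ev))
    n_cs_tr <- round(train_fraction * length(cs))
    # keep both partitions non-empty with >= 1 event each
    n_ev_tr <- min(max(n_ev_tr, 1L), length(ev) - 1L)
    n_cs_tr <- min(max(n_cs_tr, 1L), length(cs) - 1L)
    tr <- sort(c(sample(ev, n_ev_tr), sample(cs, n_cs_tr)))
  } else {
    n_tr <- min(max(round(train_fraction * n), 1L), n - 1L)
    tr <- sort(sample.int(n, n_tr))
  }
  va <- setdiff(seq_len(n), tr)
  list(train = subset_cohort(cohort, tr),
       valid = subset_cohort(cohort, va),
       train_idx = tr, valid_idx = va)
}

#' Z-score continuous covariates using training-split statistics
#'
#' Standardises every covariate column of the training cohort and applies
#' the training means/SDs to the validation cohort, avoiding information
#' leakage. Indicator (0/1) columns are left unscaled. Columns with zero
#' variance are centred only.
#'
#' @param train,valid `survival_cohort`s with identical covariate layout
#'   (`valid` may be `NULL`).
#' @return A list with `train`, `valid`, and the applied `center`, `scale`
#'   vectors (named by feature).
#' @export
standardize_covariates <- function(train, valid = NULL) {
  X <- train$covariates
  p <- ncol(X)
  center <- rep(0, p); scale <- rep(1, p)
  if (p > 0) {
    is_ind <- apply(X, 2, function(v) all(v %in% c(0, 1)))
    center[!is_ind] <- colMeans(X[, !is_ind, drop = FALSE])
    s <- apply(X[, !is_ind, drop = FALSE], 2, stats::sd)
    s[!is.finite(s) | s == 0] <- 1
    scale[!is_ind] <- s
    names(center) <- names(scale) <- colnames(X)
    train$covariates <- sweep(sweep(X, 2, center), 2, scale, "/")
    if (!is.null(valid))
      valid$covariates <-
        sweep(sweep(valid$covariates, 2, center), 2, scale, "/")
  }
  list(train = train, valid = valid, center = center, scale = scale)
}
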