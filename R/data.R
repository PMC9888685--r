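#' Assemble a survival-moderation dataset
#'
#' Builds the modelling container used by [prism()] and the downstream
#' estimators from a flat per-patient table.  Observed times (in days) are
#' transformed to natural-log scale at construction; all modelling is done on
#' the log scale.
#'
#' @param data data frame, one row per patient.
#' @param time name of the column holding observed time in days (> 0).
#' @param event name of the 0/1 event column (1 = event, 0 = censored).
#' @param focus name of the binary 0/1 focus column (e.g. race, NHB = 1,
#'   NHW = 0); the focus effect is the quantity whose moderation the tree
#'   models.
#' @param tract name of the area (census-tract) identifier column.
#' @param covariates character vector of individual-level covariate columns
#'   (the splitting variables z).
#' @param contextual character vector of area-level contextual columns (e.g.
#'   tract median income); each must be constant within tract.  May be
#'   `NULL` for PRISM-only use.
#' @param scales optional named character vector overriding the inferred
#'   measurement scale of covariates; values among `"continuous"`,
#'   `"ordinal"`, `"nominal"`.  By default numeric columns are continuous,
#'   ordered factors ordinal, and character/factor columns nominal.
#'
#' @return An object of class `"prism_data"`: a list with components `y`
#'   (log days), `delta`, `x`, `tract` (factor), `Z` (covariate data frame),
#'   `W` (contextual data frame keyed like the rows, or `NULL`), `specs`
#'   (variable metadata), `n`, `M` (number of distinct tracts), `n_m`
#'   (per-tract counts) and `row_id`.
#'
#' Rows with missing values in any used column are rejected with an error
#' naming them; there is no surrogate-split mechanism.
#' @seealso [read_prism_data()], [validate_prism_data()]
#' @export
prism_data <- function(data, time = "time_days", event = "event", focus = "race",
                       tract = "tract_id", covariates, contextual = NULL,
                       scales = NULL) {
  stopifnot(is.data.frame(data))
  need <- c(time, event, focus, tract, covariates, contextual)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s) in data: ", paste(miss, collapse = ", "))

  used <- data[need]
  bad <- which(!complete.cases(used))
  if (length(bad))
    stop("missing values in row(s) ", paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "",
         "; records with missing values are rejected")

  tvals <- as.numeric(data[[time]])
  nonpos <- which(!is.finite(tvals) | tvals <= 0)
  if (length(nonpos))
    stop("nonpositive or nonfinite time in row(s) ",
         paste(head(nonpos, 10L), collapse = ", "),
         ": times must be > 0 days before the log transform")

  dl <- data[[event]]
  if (!all(dl %in% c(0, 1)))
    stop("event column '", event, "' must be coded 0/1")
  xv <- data[[focus]]
  if (!all(xv %in% c(0, 1)))
    stop("focus column '", focus, "' must be binary 0/1")

  tr <- factor(as.character(data[[tract]]))

  Z <- data[covariates]
  zscale <- vapply(covariates, function(v) {
    if (!is.null(scales) && v %in% names(scales)) return(scales[[v]])
    col <- Z[[v]]
    if (is.ordered(col)) "ordinal"
    else if (is.numeric(col)) "continuous"
    else "nominal"
  }, character(1))
  bad_sc <- setdiff(zscale, c("continuous", "ordinal", "nominal"))
  if (length(bad_sc)) stop("unknown scale(s): ", paste(bad_sc, collapse = ", "))
  for (v in covariates) {
    if (zscale[[v]] == "nominal" && !is.factor(Z[[v]]))
      Z[[v]] <- factor(Z[[v]])
    if (zscale[[v]] == "ordinal" && !is.ordered(Z[[v]]))
      Z[[v]] <- factor(Z[[v]], ordered = TRUE)
    if (zscale[[v]] == "continuous" && !is.numeric(Z[[v]]))
      stop("covariate '", v, "' declared continuous but is not numeric")
  }

  W <- NULL
  if (length(contextual)) {
    W <- data[contextual]
    for (v in contextual) {
      if (!is.numeric(W[[v]]))
        stop("contextual variable '", v, "' must be numeric")
      spread <- tapply(W[[v]], tr, function(u) diff(range(u)))
      if (any(spread > 1e-8, na.rm = TRUE))
        stop("contextual variable '", v, "' is not constant within tract")
    }
  }

  specs <- data.frame(
    name = c(time, event, focus, tract, covariates, contextual),
    role = c("time", "event", "focus", "tract",
             rep("individual", length(covariates)),
             rep("contextual", length(contextual))),
    scale = c("continuous", "nominal", "nominal", "nominal",
              unname(zscale), rep("continuous", length(contextual))),
    stringsAsFactors = FALSE)

  n_m <- table(tr)
  structure(list(
    y = log(tvals),
    delta = as.integer(dl),
    x = as.integer(xv),
    tract = tr,
    Z = Z,
    W = W,
    specs = specs,
    n = nrow(data),
    M = nlevels(tr),
    n_m = n_m,
    row_id = seq_len(nrow(data))
  ), class = "prism_data")
}

#' Read a dataset from CSV with a schema
#'
#' @param path CSV file with one row per patient.
#' @param schema a list describing the variables: either the result of
#'   [prism_schema()], or a list with elements `time`, `event`, `focus`,
#'   `tract`, `covariates`, `contextual`, `scales` as accepted by
#'   [prism_data()], or the path of a YAML file with a top-level
#'   `variables:` list of `{name, role, scale, levels}` entries.
#' @param levels optional named list of level vectors for nominal/ordinal
#'   covariates; values found in the file outside the declared levels raise
#'   an error.
#' @return A [prism_data()] object.
#' @export
read_prism_data <- function(path, schema, levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(schema) && length(schema) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML schema requires the 'yaml' package")
    schema <- prism_schema(yaml::yaml.load_file(schema)$variables)
  } else if (!is.null(schema$variables)) {
    schema <- prism_schema(schema$variables)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  lv <- levels %||% schema$levels
  if (length(lv)) {
    for (v in names(lv)) {
      if (!v %in% names(df)) next
      unknown <- setdiff(unique(as.character(df[[v]])), lv[[v]])
      if (length(unknown))
        stop("unknown level(s) for '", v, "': ",
             paste(unknown, collapse = ", "))
      df[[v]] <- factor(df[[v]], levels = lv[[v]],
                        ordered = isTRUE(schema$scales[[v]] == "ordinal"))
    }
  }
  prism_data(df,
             time = schema$time, event = schema$event, focus = schema$focus,
             tract = schema$tract, covariates = schema$covariates,
             contextual = schema$contextual,
             scales = unlist(schema$scales) %||% NULL)
}

#' Build a schema from a variables list
#'
#' Converts a `variables:` style list (entries with `name`, `role`, `scale`
#' and optionally `levels`) into the argument set of [prism_data()].  Exactly
#' one variable must have role `focus`.
#' @param variables list of variable descriptions.
#' @return list with elements `time`, `event`, `focus`, `tract`,
#'   `covariates`, `contextual`, `scales`, `levels`.
#' @export
prism_schema <- function(variables) {
  role <- vapply(variables, function(v) v$role, character(1))
  name <- vapply(variables, function(v) v$name, character(1))
  pick1 <- function(r) {
    i <- which(role == r)
    if (length(i) != 1L) stop("schema must name exactly one '", r, "' variable")
    name[i]
  }
  lv <- list(); sc <- list()
  for (v in variables) {
    if (!is.null(v$scale)) sc[[v$name]] <- v$scale
    if (!is.null(v$levels)) {
      if (length(v$levels) < 2L)
        stop("variable '", v$name, "' lists fewer than 2 levels")
      lv[[v$name]] <- as.character(v$levels)
    }
  }
  list(time = pick1("time"), event = pick1("event"), focus = pick1("focus"),
       tract = pick1("tract"),
       covariates = name[role == "individual"],
       contextual = if (any(role == "contextual")) name[role == "contextual"] else NULL,
       scales = sc, levels = lv)
}

#' @export
as.data.frame.prism_data <- function(x, ...) {
  df <- data.frame(time_days = exp(x$y), event = x$delta, check.names = FALSE)
  sp <- x$specs
  names(df) <- c(sp$name[sp$role == "time"], sp$name[sp$role == "event"])
  df[[sp$name[sp$role == "focus"]]] <- x$x
  df[[sp$name[sp$role == "tract"]]] <- as.character(x$tract)
  for (v in names(x$Z)) df[[v]] <- x$Z[[v]]
  if (!is.null(x$W)) for (v in names(x$W)) df[[v]] <- x$W[[v]]
  df
}

#' Write a dataset back to CSV
#'
#' Numeric columns are written with 17 significant digits so a write/read
#' cycle reproduces them to full double precision.
#' @param ds a [prism_data()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_prism_data <- function(ds, path) {
  stopifnot(inherits(ds, "prism_data"))
  df <- as.data.frame(ds)
  for (v in names(df))
    if (is.double(df[[v]])) df[[v]] <- sprintf("%.17g", df[[v]])
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Row subset preserving structure (factor levels kept).
prism_data_subset <- function(ds, idx) {
  out <- ds
  out$y <- ds$y[idx]
  out$delta <- ds$delta[idx]
  out$x <- ds$x[idx]
  out$tract <- factor(ds$tract[idx])
  out$Z <- ds$Z[idx, , drop = FALSE]
  if (!is.null(ds$W)) out$W <- ds$W[idx, , drop = FALSE]
  out$n <- length(idx)
  out$M <- nlevels(out$tract)
  out$n_m <- table(out$tract)
  out$row_id <- ds$row_id[idx]
  out
}

#' Validate a dataset for model fitting
#'
#' Reports conditions that make the root model unfittable (fatal) and
#' features worth knowing about before fitting (notes): focus-group sizes,
#' the censoring fraction, tracts with a single record, and constant
#' covariates.
#'
#' @param ds a [prism_data()] object.
#' @return An object of class `"prism_validation"`: list with `fatal`
#'   (character vector, empty when fitting can proceed), `notes`, and a
#'   `summary` list.
#' @export
validate_prism_data <- function(ds) {
  stopifnot(inherits(ds, "prism_data"))
  fatal <- character(0)
  notes <- character(0)

  n_events <- sum(ds$delta == 1)
  if (n_events == 0) fatal <- c(fatal, "no events: all records censored")
  grp <- table(factor(ds$x, levels = 0:1))
  if (any(grp == 0))
    fatal <- c(fatal, "focus variable constant: only one focus group present")
  ev_grp <- table(factor(ds$x[ds$delta == 1], levels = 0:1))
  if (n_events > 0 && all(grp > 0) && any(ev_grp == 0))
    fatal <- c(fatal, "a focus group has no uncensored records: focus effect not estimable")
  if (ds$n < 4 || n_events < 2)
    fatal <- c(fatal, "too few records/events: root model underdetermined")

  single <- names(ds$n_m)[ds$n_m == 1]
  if (length(single))
    notes <- c(notes, paste0(length(single), " tract(s) with a single record"))
  const <- names(ds$Z)[vapply(ds$Z, function(z) length(unique(z)) < 2L, logical(1))]
  if (length(const))
    notes <- c(notes, paste0("constant covariate(s): ", paste(const, collapse = ", ")))

  structure(list(
    fatal = fatal, notes = notes,
    summary = list(
      n = ds$n, M = ds$M,
      focus_group_sizes = as.vector(grp),
      censoring_fraction = mean(ds$delta == 0),
      single_record_tracts = single,
      constant_covariates = const)
  ), class = "prism_validation")
}

#' @export
print.prism_validation <- function(x, ...) {
  s <- x$summary
  cat("Dataset check: n =", s$n, ", tracts =", s$M,
      sprintf(", censoring %.1f%%", 100 * s$censoring_fraction), "\n")
  cat("Focus groups (0/1):", paste(s$focus_group_sizes, collapse = " / "), "\n")
  if (length(x$fatal)) cat("FATAL:\n", paste(" -", x$fatal, collapse = "\n"), "\n")
  else cat("No fatal conditions.\n")
  if (length(x$notes)) cat("Notes:\n", paste(" -", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.prism_data <- function(x, ...) {
  cat("prism_data: ", x$n, " records, ", x$M, " tracts, ",
      sum(x$delta), " events (", sprintf("%.1f%%", 100 * mean(x$delta == 0)),
      " censored)\n", sep = "")
  cat("covariates: ", paste(names(x$Z), collapse = ", "), "\n", sep = "")
  if (!is.null(x$W))
    cat("contextual: ", paste(names(x$W), collapse = ", "), "\n", sep = "")
  invisible(x)
}
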