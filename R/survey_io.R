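#' Read a delimited survey file
#'
#' Reads point survey records (one gillnet set per row) from a CSV or TSV
#' file. The delimiter is autodetected from the header line. Rows whose
#' mandatory fields fail numeric coercion are not dropped silently: they
#' are collected into a rejects table with the name of the first offending
#' column as the reason.
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named character vector mapping canonical field names
#'   to the file's column names, e.g.
#'   `c(longitude = "LON", temperature = "Temp")`. Unmapped canonical
#'   names are looked up verbatim. Canonical names: `longitude`,
#'   `latitude` (or `x`, `y` for already-projected data), `year`,
#'   `temperature`, `depth`, `transparency`, `dissolved_oxygen`, plus any
#'   presence or per-age catch columns present in the file.
#' @param required canonical columns that must be present; defaults to the
#'   four environmental covariates plus coordinates and year.
#' @return list with `records` (data.frame of coerced rows), `rejects`
#'   (data.frame with `row` and `reason`).
#' @export
read_survey <- function(path, column_map = character(),
                        required = c("year", "temperature", "depth",
                                     "transparency", "dissolved_oxygen")) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(";", header)) ";" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (nrow(raw) == 0L) stop("no data rows in ", path)

  has_xy <- all(resolve_col(c("x", "y"), column_map) %in% names(raw))
  coord_cols <- if (has_xy) c("x", "y") else c("longitude", "latitude")
  wanted <- unique(c(coord_cols, required))
  src <- resolve_col(wanted, column_map)
  missing_cols <- wanted[!(src %in% names(raw))]
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         " (check the column mapping)")

  # carry along any presence/catch columns untouched by the mapping,
  # coerced to their natural types
  extra <- setdiff(names(raw), src)
  rec <- stats::setNames(raw[src], wanted)
  if (length(extra))
    rec <- cbind(rec, lapply(raw[extra], utils::type.convert, as.is = TRUE))

  num_fields <- wanted
  reject_reason <- rep(NA_character_, nrow(rec))
  for (f in num_fields) {
    v <- suppressWarnings(as.numeric(rec[[f]]))
    bad <- is.na(v) & !is.na(rec[[f]]) & nzchar(trimws(rec[[f]]))
    reject_reason[bad & is.na(reject_reason)] <- f
    rec[[f]] <- v
  }
  keep <- is.na(reject_reason)
  list(records = rec[keep, , drop = FALSE],
       rejects = data.frame(row = which(!keep),
                            reason = reject_reason[!keep],
                            stringsAsFactors = FALSE))
}

resolve_col <- function(canonical, column_map) {
  ifelse(canonical %in% names(column_map), column_map[canonical], canonical)
}

#' Clean survey records and derive presence/absence by life stage
#'
#' Removes rows with missing or physically impossible values in the catch
#' or environmental fields and codes presence/absence for juveniles
#' (age < `age_cut`) and adults (age >= `age_cut`). Presence flags already
#' present in the input are respected; otherwise they are derived from
#' per-age catch columns named like `catch_age0`, `catch_age1`, ...
#' (catch in number; the 0/1 simplification makes number vs weight
#' equivalent).
#'
#' The operational definition of "erroneous" is: any NA in a mandatory
#' field, temperature outside `temp_range`, depth <= 0, transparency < 0,
#' or dissolved oxygen < 0. Cleaning is idempotent.
#'
#' @param records data.frame as returned by [read_survey()]`$records`.
#' @param age_cut recruitment age separating juveniles from adults
#'   (default 2).
#' @param temp_range plausible water temperature range in deg C.
#' @return list with `data` (cleaned data.frame including
#'   `presence_juvenile` / `presence_adult` where derivable), `removed`
#'   (number of rows dropped) and `reasons` (per dropped row).
#' @export
clean_survey <- function(records, age_cut = 2L, temp_range = c(0, 35)) {
  stopifnot(is.data.frame(records))
  env_fields <- intersect(c("temperature", "depth", "transparency",
                            "dissolved_oxygen"), names(records))
  catch_cols <- grep("^catch_age[0-9]+$", names(records), value = TRUE)

  d <- records
  if (length(catch_cols)) {
    ages <- as.integer(sub("^catch_age", "", catch_cols))
    juv <- catch_cols[ages < age_cut]
    adu <- catch_cols[ages >= age_cut]
    catch_ok <- !Reduce(`|`, lapply(d[catch_cols], is.na))
    if (length(juv))
      d$presence_juvenile <-
        as.integer(rowSums(as.matrix(d[, juv, drop = FALSE]) > 0) > 0)
    if (length(adu))
      d$presence_adult <-
        as.integer(rowSums(as.matrix(d[, adu, drop = FALSE]) > 0) > 0)
  } else {
    catch_ok <- rep(TRUE, nrow(d))
  }

  reason <- rep(NA_character_, nrow(d))
  mark <- function(bad, why) reason[bad & is.na(reason)] <<- why
  for (f in env_fields) mark(is.na(d[[f]]), f)
  mark(!catch_ok, "catch")
  pres_cols <- intersect(c("presence_juvenile", "presence_adult"), names(d))
  for (f in pres_cols) mark(is.na(d[[f]]) | !(d[[f]] %in% c(0, 1)), f)
  if ("temperature" %in% env_fields)
    mark(d$temperature < temp_range[1] | d$temperature > temp_range[2],
         "temperature")
  if ("depth" %in% env_fields) mark(d$depth <= 0, "depth")
  if ("transparency" %in% env_fields) mark(d$transparency < 0, "transparency")
  if ("dissolved_oxygen" %in% env_fields)
    mark(d$dissolved_oxygen < 0, "dissolved_oxygen")

  keep <- is.na(reason)
  if (!any(keep)) stop("all rows removed during cleaning")
  list(data = d[keep, , drop = FALSE],
       removed = sum(!keep),
       reasons = reason[!keep])
}

#' Variance inflation factors for a covariate table
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from the least-squares regression
#' of column j on the remaining columns (with intercept). Columns that are
#' perfectly collinear are reported with infinite VIF rather than raising
#' an error. The default exclusion threshold of 3 follows common practice
#' for multicollinearity screening of environmental covariates.
#'
#' @param covariates numeric matrix or data.frame, n rows > p >= 2 columns.
#' @param threshold exclusion threshold (default 3).
#' @return data.frame with columns `variable`, `vif`, `excluded`.
#' @export
compute_vif <- function(covariates, threshold = 3) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  stopifnot(p >= 2, nrow(X) > p)
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant column in covariates")
  vif <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(variable = colnames(X), vif = vif,
             excluded = vif > threshold, stringsAsFactors = FALSE)
}
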