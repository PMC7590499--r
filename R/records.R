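# Container for a cohort of death records: per-death metadata plus the
# indicator response matrix (three-valued: "Y", "N", "." = missing).

indicator_names <- function(I) sprintf("i_%04d", seq_len(I))

#' Construct a cohort of death records
#'
#' @param data data.frame with columns `id` (unique strings), `group`
#'   (study group codes, see [va_groups()]), `cda_cause` (gold-standard cause
#'   code), optionally `cda_likelihood` (must be 1; the gold standard assigns
#'   a single certain cause) and `infection_cause` (infection-level
#'   subcategory for deaths whose broad cause is infectious, `NA` otherwise).
#' @param indicators character matrix, one row per record (rownames = ids),
#'   entries in `"Y"`, `"N"`, `"."`.
#' @param dictionary a [cause_dictionary()] used for validation.
#' @return An object of class `va_records`: a list with elements `data` and
#'   `indicators`.
#' @export
va_records <- function(data, indicators, dictionary = default_cause_dictionary()) {
  stopifnot(is.data.frame(data), is.matrix(indicators))
  need <- c("id", "group", "cda_cause")
  if (!all(need %in% names(data))) {
    stop("records need columns: ", paste(need, collapse = ", "))
  }
  data$id <- as.character(data$id)
  if (is.null(data$cda_likelihood)) data$cda_likelihood <- 1
  if (anyDuplicated(data$id)) stop("duplicate record ids")
  if (nrow(data) != nrow(indicators)) stop("indicator matrix rows != number of records")
  rownames(indicators) <- data$id
  colnames(indicators) <- indicator_names(ncol(indicators))
  x <- structure(list(data = data, indicators = indicators), class = "va_records")
  validate_records(x, dictionary)
  x
}

#' Validate a cohort against a dictionary
#'
#' Checks group codes, gold-standard causes (membership and group scope),
#' gold likelihoods (fixed at 1), and the indicator alphabet. Errors name the
#' offending record id.
#'
#' @param records a [va_records()] object.
#' @param dictionary a [cause_dictionary()].
#' @return `records`, invisibly.
#' @export
validate_records <- function(records, dictionary = default_cause_dictionary()) {
  stopifnot(inherits(records, "va_records"))
  d <- records$data
  bad <- !(d$group %in% va_groups())
  if (any(bad)) stop("unknown study group for record(s): ", paste(d$id[bad], collapse = ", "))
  if (any(d$cda_likelihood != 1)) {
    stop("gold-standard likelihood must be 1 for record(s): ",
         paste(d$id[d$cda_likelihood != 1], collapse = ", "))
  }
  for (g in unique(d$group)) {
    scope <- group_causes(dictionary, g)
    off <- d$group == g & !(d$cda_cause %in% scope)
    if (any(off)) {
      stop("gold cause not in dictionary scope of group '", g, "' for record(s): ",
           paste(d$id[off], collapse = ", "))
    }
  }
  ind <- records$indicators
  if (nrow(ind) > 0 && !all(ind %in% c("Y", "N", "."))) {
    bad_rows <- unique(rownames(ind)[which(!(ind %in% c("Y", "N", "."))) %% nrow(ind) + 1L])
    stop("indicator entries must be Y, N or '.'; offending record(s): ",
         paste(utils::head(bad_rows, 5), collapse = ", "))
  }
  invisible(records)
}

#' Number of records / indicators in a cohort
#' @param records a [va_records()] object.
#' @return Integer.
#' @export
n_records <- function(records) nrow(records$data)

#' @rdname n_records
#' @export
n_indicators <- function(records) ncol(records$indicators)

#' Subset a cohort by record index
#' @param x a [va_records()] object.
#' @param i integer or logical index (records may repeat, as in resampling).
#' @param ... unused.
#' @export
`[.va_records` <- function(x, i, ...) {
  d <- x$data[i, , drop = FALSE]
  ind <- x$indicators[i, , drop = FALSE]
  # resampling duplicates records; keep ids unique in the copy
  d$id <- make.unique(as.character(d$id))
  rownames(d) <- NULL
  rownames(ind) <- d$id
  structure(list(data = d, indicators = ind), class = "va_records")
}

#' @export
print.va_records <- function(x, ...) {
  cat("<va_records> ", n_records(x), " deaths, ", n_indicators(x),
      " indicators\n", sep = "")
  print(table(x$data$group))
  invisible(x)
}

#' Load death records from CSV
#'
#' Expected header: `id, group, cda_cause, i_0001, ..., i_NNNN` (optionally
#' `infection_cause` before the indicator block). Indicator cells are `Y`,
#' `N` or `.` (missing). The per-group tally is reported via [message()].
#'
#' @param path file path.
#' @param dictionary a [cause_dictionary()].
#' @return A [va_records()] object.
#' @export
load_records <- function(path, dictionary = default_cause_dictionary()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                       check.names = FALSE)
  meta_cols <- intersect(c("id", "group", "cda_cause", "infection_cause"), names(d))
  ind_cols <- grep("^i_[0-9]+$", names(d), value = TRUE)
  if (length(ind_cols) == 0L) stop("no indicator columns (i_0001...) found in ", path)
  other <- setdiff(names(d), c(meta_cols, ind_cols))
  if (length(other)) stop("unrecognized columns: ", paste(other, collapse = ", "))
  meta <- d[meta_cols]
  if ("infection_cause" %in% names(meta)) {
    meta$infection_cause[meta$infection_cause == ""] <- NA_character_
  }
  ind <- as.matrix(d[ind_cols])
  if (anyNA(ind)) stop("ragged indicator columns in ", path)
  x <- va_records(meta, ind, dictionary)
  tally <- table(factor(x$data$group, va_groups()))
  message("loaded ", n_records(x), " records (",
          paste(names(tally), tally, sep = "=", collapse = ", "), ")")
  x
}

#' Write death records to CSV
#'
#' Inverse of [load_records()]: `load_records(write_records(x, p))` restores
#' `x` field for field.
#'
#' @param records a [va_records()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(inherits(records, "va_records"))
  d <- records$data
  keep <- intersect(c("id", "group", "cda_cause", "infection_cause"), names(d))
  out <- cbind(d[keep], as.data.frame(records$indicators, stringsAsFactors = FALSE))
  names(out) <- c(keep, indicator_names(n_indicators(records)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# ---- model outputs ---------------------------------------------------------

#' Construct a table of coder outputs
#'
#' One row per death: up to three (cause, likelihood) pairs in non-increasing
#' likelihood order plus the residual non-conclusive mass; per row the
#' likelihoods and the residual sum to 1 (tolerance 1e-9). An empty report
#' (all causes `NA`, residual 1) is valid and denotes a non-conclusive
#' diagnosis.
#'
#' @param data data.frame with columns `id`, `cause1`, `lik1`, `cause2`,
#'   `lik2`, `cause3`, `lik3`, `nonconclusive` (cause columns `NA` when
#'   unused, their likelihoods 0 or `NA`), optionally `infection_cause1`.
#' @return The validated data.frame with class `va_outputs`.
#' @export
va_outputs <- function(data) {
  need <- c("id", "cause1", "lik1", "cause2", "lik2", "cause3", "lik3",
            "nonconclusive")
  if (!all(need %in% names(data))) {
    stop("outputs need columns: ", paste(need, collapse = ", "))
  }
  data$id <- as.character(data$id)
  for (k in 1:3) {
    lk <- paste0("lik", k)
    ck <- paste0("cause", k)
    data[[lk]] <- as.numeric(data[[lk]])
    data[[lk]][is.na(data[[lk]])] <- 0
    data[[ck]][!is.na(data[[ck]]) & data[[ck]] == ""] <- NA_character_
    if (any(is.na(data[[ck]]) & data[[lk]] > 0)) {
      stop("likelihood without a cause in column ", ck)
    }
  }
  data$nonconclusive <- as.numeric(data$nonconclusive)
  liks <- as.matrix(data[c("lik1", "lik2", "lik3")])
  if (any(liks < -1e-12 | liks > 1 + 1e-12)) stop("likelihoods must lie in [0, 1]")
  dec <- liks[, 1] + 1e-12 >= liks[, 2] & liks[, 2] + 1e-12 >= liks[, 3]
  if (!all(dec)) {
    stop("likelihoods must be non-increasing; offending id(s): ",
         paste(utils::head(data$id[!dec], 5), collapse = ", "))
  }
  tot <- rowSums(liks) + data$nonconclusive
  if (any(abs(tot - 1) > 1e-9)) {
    stop("likelihoods + nonconclusive must sum to 1; offending id(s): ",
         paste(utils::head(data$id[abs(tot - 1) > 1e-9], 5), collapse = ", "))
  }
  class(data) <- c("va_outputs", "data.frame")
  data
}

#' Write / read coder outputs as CSV
#'
#' Likelihoods are written with 12 significant digits, so a round trip
#' reproduces the table to that precision.
#'
#' @param outputs a [va_outputs()] table.
#' @param path file path.
#' @return `write_va_outputs()` returns `path` invisibly;
#'   `load_va_outputs()` returns a [va_outputs()] table.
#' @export
write_va_outputs <- function(outputs, path) {
  outputs <- va_outputs(as.data.frame(outputs))
  out <- as.data.frame(outputs)
  for (col in c("lik1", "lik2", "lik3", "nonconclusive")) {
    v <- sprintf("%.12g", out[[col]])
    v[out[[col]] == 0 & col != "nonconclusive"] <- ""
    out[[col]] <- v
  }
  for (col in c("cause1", "cause2", "cause3")) out[[col]][is.na(out[[col]])] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_va_outputs
#' @export
load_va_outputs <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", check.names = FALSE)
  for (col in c("lik1", "lik2", "lik3", "nonconclusive")) {
    d[[col]][d[[col]] == ""] <- "0"
    d[[col]] <- as.numeric(d[[col]])
  }
  for (col in c("cause1", "cause2", "cause3")) d[[col]][d[[col]] == ""] <- NA_character_
  va_outputs(d)
}
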