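#' Construct a foci table
#'
#' A foci table links behavioral sub-domains to stereotaxic activation
#' coordinates: one row per reported focus per sub-domain (a coordinate
#' reported for an experiment carrying several behavior codes appears once
#' per code). Exact-duplicate rows are retained and counted multiply
#' downstream, since focus tallies count reports, not unique locations.
#'
#' @param records data.frame with columns \code{experiment} (character),
#'   \code{subdomain_id} (integer 1--51), \code{x}, \code{y}, \code{z}
#'   (numeric, mm).
#' @param space \code{"TAL"} or \code{"MNI"}.
#' @return An object of class \code{foci_table}.
#' @export
foci_table <- function(records = data.frame(experiment = character(),
                                            subdomain_id = integer(),
                                            x = numeric(), y = numeric(),
                                            z = numeric()),
                       space = c("TAL", "MNI")) {
  space <- match.arg(space)
  stopifnot(all(c("experiment", "subdomain_id", "x", "y", "z") %in%
                  names(records)))
  records$subdomain_id <- normalize_subdomain_id(records$subdomain_id)
  coords <- as.matrix(records[, c("x", "y", "z")])
  if (nrow(records) && !all(is.finite(coords)))
    stopf("non-finite coordinate at row(s): %s",
          paste(utils::head(which(!stats::complete.cases(coords) |
                                    rowSums(!is.finite(coords)) > 0), 5L),
                collapse = ", "))
  rownames(records) <- NULL
  structure(list(records = records, space = space), class = "foci_table")
}

#' @export
print.foci_table <- function(x, ...) {
  cat(sprintf("<foci_table> %d foci, %d sub-domains, space %s\n",
              nrow(x$records), length(unique(x$records$subdomain_id)),
              x$space))
  invisible(x)
}

#' Number of focus records
#' @param table a \code{foci_table}.
#' @return integer count.
#' @export
n_foci <- function(table) nrow(table$records)

#' Per-sub-domain coordinate index
#'
#' Groups the records of a foci table by sub-domain, preserving row order
#' within each group.
#'
#' @param table a \code{foci_table}.
#' @param taxonomy a \code{behavior_taxonomy}.
#' @return Named list of length 51 (names = sub-domain ids); each element a
#'   numeric matrix with columns x, y, z (0 rows when the sub-domain has no
#'   foci).
#' @export
foci_index <- function(table, taxonomy = behavior_taxonomy()) {
  ids <- taxonomy$id
  r <- table$records
  out <- vector("list", length(ids))
  names(out) <- as.character(ids)
  empty <- matrix(numeric(), ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
  grp <- split(seq_len(nrow(r)), factor(r$subdomain_id, levels = ids))
  for (i in seq_along(ids)) {
    rows <- grp[[i]]
    out[[i]] <- if (length(rows))
      as.matrix(r[rows, c("x", "y", "z"), drop = FALSE]) else empty
    rownames(out[[i]]) <- NULL
  }
  out
}

#' Read a foci table from delimited text
#'
#' Accepts comma- or tab-delimited files with a header row naming the
#' experiment, sub-domain and x/y/z columns. The sub-domain column may hold
#' integer ids or \code{"Domain:Name"} strings; both are normalized to ids.
#' An optional \code{space} column (or the \code{space} argument) declares
#' the stereotaxic space.
#'
#' @param path input file.
#' @param space fallback space tag when the file has no \code{space} column.
#' @param taxonomy a \code{behavior_taxonomy}.
#' @return a \code{foci_table}.
#' @export
read_foci_table <- function(path, space = c("TAL", "MNI"),
                            taxonomy = behavior_taxonomy()) {
  space <- match.arg(space)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  names(df) <- tolower(names(df))
  cmap <- c(experiment = "experiment", experiment_id = "experiment",
            exp = "experiment",
            subdomain = "subdomain_id", subdomain_id = "subdomain_id",
            behavior = "subdomain_id", behavior_id = "subdomain_id",
            x = "x", y = "y", z = "z", space = "space")
  known <- names(df) %in% names(cmap)
  names(df)[known] <- cmap[names(df)[known]]
  missing <- setdiff(c("experiment", "subdomain_id", "x", "y", "z"),
                     names(df))
  if (length(missing))
    stopf("foci file %s lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  if (nrow(df) == 0L)
    return(foci_table(space = space))
  for (cc in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v))
      stopf("non-numeric %s coordinate at data row(s): %s", cc,
            paste(utils::head(which(is.na(v)), 5L), collapse = ", "))
    df[[cc]] <- v
  }
  ids <- rep(NA_integer_, nrow(df))
  for (i in seq_len(nrow(df))) {
    ids[i] <- tryCatch(normalize_subdomain_id(df$subdomain_id[i], taxonomy),
                       error = function(e)
                         stopf("data row %d of %s: %s", i, path,
                               conditionMessage(e)))
  }
  if ("space" %in% names(df) && nrow(df)) {
    tags <- unique(toupper(df$space))
    if (length(tags) > 1L)
      stopf("mixed space tags in %s: %s", path, paste(tags, collapse = ", "))
    space <- match.arg(tags, c("TAL", "MNI"))
  }
  foci_table(data.frame(experiment = df$experiment, subdomain_id = ids,
                        x = df$x, y = df$y, z = df$z,
                        stringsAsFactors = FALSE),
             space = space)
}

#' Write a foci table as CSV
#'
#' Writes header + one row per record, including a \code{space} column, so
#' that \code{read_foci_table()} round-trips the table record-for-record.
#'
#' @param table a \code{foci_table}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_foci_table <- function(table, path) {
  df <- table$records
  df$space <- rep(table$space, length.out = nrow(df))
  if (nrow(df) == 0L)
    df <- df[, c("experiment", "subdomain_id", "x", "y", "z", "space")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
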