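#' Read trip records from CSV
#'
#' Expects a header `origin,destination,month,count` with months as
#' `"YYYY-MM"`. Self-loop rows (origin equal to destination) are dropped with
#' a warning. Counts must be positive integers.
#'
#' @param path CSV file path.
#' @param islands Optional island metadata; when supplied, rows naming
#'   unknown islands trigger a warning flagging them.
#' @return A tibble of validated trip records.
#' @export
read_trip_records <- function(path, islands = NULL) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("origin", "destination", "month", "count")
  absent <- setdiff(required, names(df))
  if (length(absent) > 0) {
    stop("trip file is missing column(s): ", paste(absent, collapse = ", "))
  }
  if (!is.numeric(df$count)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$count))))
    stop("non-numeric trip count at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  neg <- which(df$count < 1)
  if (length(neg) > 0) {
    stop("trip count < 1 at row(s): ", paste(utils::head(neg, 5), collapse = ", "))
  }
  loops <- df$origin == df$destination
  if (any(loops)) {
    warning(sum(loops), " self-loop record(s) dropped")
    df <- df[!loops, , drop = FALSE]
  }
  if (!is.null(islands)) {
    unknown <- setdiff(union(df$origin, df$destination), islands$island)
    if (length(unknown) > 0) {
      warning("trip records reference island(s) absent from metadata: ",
              paste(unknown, collapse = ", "))
    }
  }
  tibble::as_tibble(df[, required])
}

#' Read island metadata from CSV
#'
#' Expects a header `island,lat,lon,harris_zone`. Island names must be
#' unique and zones in 1..5.
#'
#' @param path CSV file path.
#' @return A tibble with one row per island.
#' @export
read_islands <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("island", "lat", "lon", "harris_zone")
  absent <- setdiff(required, names(df))
  if (length(absent) > 0) {
    stop("island file is missing column(s): ", paste(absent, collapse = ", "))
  }
  if (anyDuplicated(df$island)) stop("duplicate island names in metadata")
  if (!all(df$harris_zone %in% 1:5)) stop("harris_zone must be in 1..5")
  tibble::as_tibble(df[, required])
}

#' Read monthly island sea-surface temperatures from CSV
#'
#' Expects a header `island,month,sst_c` (months `"YYYY-MM"`, SST in degrees
#' Celsius). Duplicate (island, month) rows are an error; islands missing a
#' month are allowed and their pairs are excluded from that month downstream.
#'
#' @param path CSV file path.
#' @return A tibble with columns `island`, `month`, `sst_c`.
#' @export
read_sst <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("island", "month", "sst_c")
  absent <- setdiff(required, names(df))
  if (length(absent) > 0) {
    stop("SST file is missing column(s): ", paste(absent, collapse = ", "))
  }
  if (!is.numeric(df$sst_c) || any(!is.finite(df$sst_c))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$sst_c))))
    stop("non-numeric SST at row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (anyDuplicated(df[, c("island", "month")])) {
    stop("duplicate (island, month) rows in SST file")
  }
  tibble::as_tibble(df[, required])
}
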