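#' Read a proxy-state compilation table
#'
#' Expects CSV columns `record_id,region,lat,lon,bin_start_yrBP,state`, the
#' state being a subjective hydroclimate classification at 500-year
#' intervals: one of `"wet"`, `"moderate"`, `"dry"`.
#'
#' @param x CSV path or data frame.
#' @param bin Expected bin spacing in years (default 500); each record's
#'   bins must lie on a uniform grid of this spacing.
#' @return Validated data frame of class `proxy_states`.
#' @export
read_proxy_states <- function(x, bin = 500) {
  if (is.character(x) && length(x) == 1L) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  need <- c("record_id", "bin_start_yrBP", "state")
  if (!all(need %in% names(x))) {
    stop("proxy table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(x$state), c("wet", "moderate", "dry"))
  if (length(bad) > 0L) {
    stop("unknown state value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (id in unique(x$record_id)) {
    b <- sort(x$bin_start_yrBP[x$record_id == id])
    if (any(b %% bin != 0) || (length(b) > 1L && any(diff(b) %% bin != 0))) {
      stop(sprintf("record '%s' bins are not on a uniform %d-yr grid", id, bin), call. = FALSE)
    }
    if (anyDuplicated(b)) stop(sprintf("record '%s' has duplicate bins", id), call. = FALSE)
  }
  class(x) <- c("proxy_states", "data.frame")
  x
}

#' Date the humid-period collapse of one proxy record
#'
#' The collapse is dated as the first time at which humid conditions are no
#' longer present: scanning forward in time from the record's earliest wet
#' bin, the first bin whose state is not humid gives the collapse date (its
#' bin start).  By default only `"wet"` counts as humid; `"moderate"` does
#' not.
#'
#' @param states Character vector of states, ordered oldest to youngest.
#' @param bin_start Years BP of each bin (same order, strictly decreasing).
#' @param humid_states States counted as humid (default `"wet"`).
#' @return Collapse date in years BP, or `NA` (with a warning) if the record
#'   has no humid bin, or `NA` silently if humid conditions persist to the
#'   end of the record.
#' @export
date_collapse <- function(states, bin_start, humid_states = "wet") {
  if (length(states) != length(bin_start)) stop("states and bin_start lengths differ", call. = FALSE)
  ord <- order(bin_start, decreasing = TRUE)
  states <- states[ord]
  bin_start <- bin_start[ord]
  humid <- states %in% humid_states
  first_wet <- which(humid)[1]
  if (is.na(first_wet)) {
    warning("record has no humid bin; collapse undefined")
    return(NA_real_)
  }
  drop_idx <- which(!humid & seq_along(states) >= first_wet)[1]
  if (is.na(drop_idx)) return(NA_real_)
  bin_start[drop_idx]
}

#' Histogram of proxy collapse dates
#'
#' Applies [date_collapse()] to every record of a proxy-state table and
#' counts collapse dates per bin, optionally filtering by region or
#' excluding records south of a latitude cut (the compilation's southern
#' limit for the associated population reconstructions is 13.42 deg N).
#'
#' @param table A `proxy_states` table (see [read_proxy_states()]).
#' @param bin Bin width in years (default 500).
#' @param regions Optional character vector of regions to keep.
#' @param min_lat Optional latitude cut; records with `lat < min_lat` are
#'   excluded (requires a `lat` column).
#' @param humid_states Passed to [date_collapse()].
#' @return Data frame `bin_start_yrBP,n_collapses` covering the range of
#'   observed collapse dates; total count equals the number of records with
#'   a defined collapse date.
#' @export
collapse_histogram <- function(table, bin = 500, regions = NULL, min_lat = NULL,
                               humid_states = "wet") {
  x <- table
  if (!is.null(regions)) x <- x[x$region %in% regions, , drop = FALSE]
  if (!is.null(min_lat)) {
    if (!"lat" %in% names(x)) stop("latitude filter requires a 'lat' column", call. = FALSE)
    x <- x[x$lat >= min_lat, , drop = FALSE]
  }
  ids <- unique(x$record_id)
  dates <- vapply(ids, function(id) {
    rec <- x[x$record_id == id, , drop = FALSE]
    suppressWarnings(date_collapse(rec$state, rec$bin_start_yrBP, humid_states))
  }, numeric(1))
  dates <- dates[!is.na(dates)]
  if (length(dates) == 0L) {
    return(data.frame(bin_start_yrBP = numeric(0), n_collapses = integer(0)))
  }
  lv <- seq(max(dates), min(dates), by = -bin)
  counts <- table(factor(dates, levels = lv))
  data.frame(bin_start_yrBP = lv, n_collapses = as.integer(counts))
}
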