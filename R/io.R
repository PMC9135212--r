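#' Column dialect for administrative inquiry CSV exports
#'
#' Maps the package's canonical record fields to the column names of a
#' particular export. 311-style exports vary in header naming and date
#' formats; `date_formats` is tried in order per row.
#'
#' @param created_date,descriptor,complaint_type,agency,area_id column
#'   names in the source file (`agency` and `area_id` optional:
#'   set to NA to skip).
#' @param date_formats character vector of `strptime` formats tried in
#'   order.
#' @return named list of class `inquiry_dialect`.
#' @export
inquiry_dialect <- function(created_date = "created_date",
                            descriptor = "descriptor",
                            complaint_type = "complaint_type",
                            agency = NA_character_,
                            area_id = NA_character_,
                            date_formats = c("%Y-%m-%d", "%m/%d/%Y",
                                             "%Y-%m-%dT%H:%M:%S",
                                             "%m/%d/%Y %I:%M:%S %p")) {
  structure(list(created_date = created_date, descriptor = descriptor,
                 complaint_type = complaint_type, agency = agency,
                 area_id = area_id, date_formats = date_formats),
            class = "inquiry_dialect")
}

parse_dates <- function(x, formats) {
  out <- as.Date(rep(NA, length(x)))
  left <- seq_along(x)
  for (f in formats) {
    if (!length(left)) break
    d <- as.Date(x[left], format = f)
    hit <- !is.na(d)
    out[left[hit]] <- d[hit]
    left <- left[!hit]
  }
  out
}

#' Read inquiry records from a CSV export
#'
#' Chunked, bounded-memory parse of a headered CSV. Rows whose date does
#' not parse under any declared format are counted, logged via a message
#' and dropped (never fatal); row order is preserved. Missing mapped
#' columns abort with the full list of what is absent.
#'
#' @param path CSV file path.
#' @param dialect an [inquiry_dialect()].
#' @param chunk_size rows per parsing chunk.
#' @return data.frame with columns `created_date` (Date), `descriptor`,
#'   `complaint_type`, and `agency` / `area_id` when mapped; attribute
#'   `n_rejected` counts dropped rows.
#' @export
read_inquiries <- function(path, dialect = inquiry_dialect(),
                           chunk_size = 10000L) {
  con <- file(path, "r")
  on.exit(close(con))
  header <- utils::read.csv(con, nrows = 1, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE, colClasses = "character")
  cols <- names(header)
  mapped <- unlist(dialect[c("created_date", "descriptor", "complaint_type",
                             "agency", "area_id")])
  need <- mapped[!is.na(mapped)]
  missing_cols <- setdiff(need, cols)
  if (length(missing_cols))
    stop("missing mapped column(s): ", paste(missing_cols, collapse = ", "))

  grab <- function(df) {
    out <- data.frame(created_date = df[[dialect$created_date]],
                      descriptor = df[[dialect$descriptor]],
                      complaint_type = df[[dialect$complaint_type]],
                      stringsAsFactors = FALSE)
    if (!is.na(dialect$agency)) out$agency <- df[[dialect$agency]]
    if (!is.na(dialect$area_id)) out$area_id <- df[[dialect$area_id]]
    out
  }
  chunks <- list(grab(header))
  repeat {
    chunk <- tryCatch(
      utils::read.csv(con, nrows = chunk_size, header = FALSE,
                      col.names = cols, check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character"),
      error = function(e) NULL)
    if (is.null(chunk) || nrow(chunk) == 0) break
    names(chunk) <- cols
    chunks[[length(chunks) + 1L]] <- grab(chunk)
  }
  rec <- do.call(rbind, chunks)
  rec$created_date <- parse_dates(rec$created_date, dialect$date_formats)
  bad <- is.na(rec$created_date)
  if (any(bad))
    message("rejected ", sum(bad), " record(s) with unparseable dates")
  out <- rec[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Extract pest-specific records by keyword search
#'
#' Case-insensitive substring match of each keyword against the
#' descriptor and complaint-type fields. The matched keyword and field
#' are recorded per retained record so the filter is auditable.
#'
#' @param records data.frame as returned by [read_inquiries()].
#' @param keywords non-empty character vector; default targets bed-bug
#'   phrasings.
#' @return the matching records with `matched_keyword` and
#'   `matched_field` columns added.
#' @export
filter_bedbug <- function(records,
                          keywords = c("bed bug", "bedbug", "bed bugs")) {
  if (!length(keywords)) stop("'keywords' must be non-empty")
  desc <- tolower(records$descriptor)
  ctype <- tolower(records$complaint_type)
  matched_keyword <- rep(NA_character_, nrow(records))
  matched_field <- rep(NA_character_, nrow(records))
  for (kw in keywords) {
    k <- tolower(kw)
    hit_d <- is.na(matched_keyword) & grepl(k, desc, fixed = TRUE)
    matched_keyword[hit_d] <- kw
    matched_field[hit_d] <- "descriptor"
    hit_c <- is.na(matched_keyword) & grepl(k, ctype, fixed = TRUE)
    matched_keyword[hit_c] <- kw
    matched_field[hit_c] <- "complaint_type"
  }
  keep <- !is.na(matched_keyword)
  out <- records[keep, , drop = FALSE]
  out$matched_keyword <- matched_keyword[keep]
  out$matched_field <- matched_field[keep]
  rownames(out) <- NULL
  out
}

#' Aggregate inquiry records to a monthly series or an area-year panel
#'
#' Monthly mode bins records by calendar month (the record's printed
#' local date, truncated to the month) and zero-fills months with no
#' records between the first and last observed month. Panel mode counts
#' records per (area, year), zero-fills all observed areas and years, and
#' joins populations keyed by (area, year); a per-100k rate column is
#' added when populations are supplied. Records without an area id are
#' excluded from panel mode with their count logged.
#'
#' @param records data.frame with `created_date` (Date) and, for panel
#'   mode, `area_id`.
#' @param by "month" or "year_area".
#' @param populations for panel mode, data.frame with `area_id`, `year`,
#'   `population`. Years absent from the table use the nearest available
#'   year's estimate (no interpolation), logged.
#' @return monthly mode: a [monthly_series()] (with a `year_month`
#'   column); panel mode: a panel data.frame (`area_id`, `year`,
#'   `population`, `y`, `rate_per_100k`).
#' @export
aggregate_inquiries <- function(records, by = c("month", "year_area"),
                                populations = NULL) {
  by <- match.arg(by)
  if (!inherits(records$created_date, "Date"))
    stop("'records$created_date' must be a Date column")
  if (by == "month") {
    ym <- format(records$created_date, "%Y-%m")
    first <- min(records$created_date)
    last <- max(records$created_date)
    months <- format(seq(as.Date(format(first, "%Y-%m-01")),
                         as.Date(format(last, "%Y-%m-01")), by = "month"),
                     "%Y-%m")
    counts <- table(factor(ym, levels = months))
    s <- monthly_series(t = seq_along(months) - 1, y = as.integer(counts),
                        label = "aggregated")
    s$year_month <- months
    return(s)
  }

  if (is.null(records$area_id))
    stop("panel aggregation needs an 'area_id' column")
  no_area <- is.na(records$area_id) | records$area_id == ""
  if (any(no_area))
    message("excluding ", sum(no_area),
            " record(s) without an area id from areal aggregation")
  rec <- records[!no_area, , drop = FALSE]
  year <- as.integer(format(rec$created_date, "%Y"))
  areas <- sort(unique(rec$area_id))
  years <- seq(min(year), max(year))
  if (!is.null(populations)) {
    orphans <- setdiff(areas, unique(populations$area_id))
    if (length(orphans))
      stop("area(s) absent from population table: ",
           paste(orphans, collapse = ", "))
  }
  counts <- table(factor(rec$area_id, levels = areas),
                  factor(year, levels = years))
  panel <- data.frame(area_id = rep(areas, times = length(years)),
                      year = rep(years, each = length(areas)),
                      y = as.vector(counts), stringsAsFactors = FALSE)
  if (!is.null(populations)) {
    pop_years <- sort(unique(populations$year))
    panel$population <- mapply(function(a, yr) {
      nearest <- pop_years[which.min(abs(pop_years - yr))]
      populations$population[populations$area_id == a &
                               populations$year == nearest][1]
    }, panel$area_id, panel$year)
    if (!all(years %in% pop_years))
      message("population for year(s) ",
              paste(setdiff(years, pop_years), collapse = ", "),
              " taken from the nearest available estimate year")
    panel <- rate_per_100k(panel)
  }
  panel
}

#' Queen-contiguity lattice from GeoJSON polygons
#'
#' Parses a GeoJSON FeatureCollection of Polygon/MultiPolygon features
#' and declares two areas adjacent when they share at least one boundary
#' vertex (coordinates compared after rounding to `digits` decimal
#' places). This matches queen contiguity on topologically clean
#' administrative geographies where neighbouring polygons share their
#' boundary vertices; contact along an edge interior without a shared
#' vertex is not detected.
#'
#' @param geo_path GeoJSON file path.
#' @param id_property feature property holding the area id.
#' @param population_property optional feature property with the area
#'   population.
#' @param digits coordinate rounding used for vertex matching.
#' @return an `area_lattice` (components identified from the graph).
#' @export
adjacency_from_polygons <- function(geo_path, id_property = "area_id",
                                    population_property = NULL,
                                    digits = 8) {
  gj <- jsonlite::fromJSON(geo_path, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats) || !length(feats)) stop("no features in ", geo_path)
  ids <- character(length(feats))
  verts <- vector("list", length(feats))
  pops <- rep(NA_real_, length(feats))
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature ", k, " lacks property '", id_property, "'")
    ids[k] <- as.character(id)
    if (!is.null(population_property) &&
        !is.null(f$properties[[population_property]]))
      pops[k] <- as.numeric(f$properties[[population_property]])
    g <- f$geometry
    if (is.null(g$type) || !g$type %in% c("Polygon", "MultiPolygon"))
      stop("invalid or unsupported geometry in feature '", ids[k], "'")
    rings <- if (g$type == "Polygon") g$coordinates else
      unlist(g$coordinates, recursive = FALSE)
    pts <- unlist(rings, recursive = FALSE)
    if (!length(pts)) stop("empty geometry in feature '", ids[k], "'")
    verts[[k]] <- unique(vapply(pts, function(p)
      paste(round(as.numeric(p[[1]]), digits),
            round(as.numeric(p[[2]]), digits)), ""))
  }
  if (anyDuplicated(ids)) stop("duplicate area ids in ", geo_path)
  n <- length(ids)
  adj <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (any(verts[[a]] %in% verts[[b]])) {
        adj[a, b] <- 1L
        adj[b, a] <- 1L
      }
    }
  }
  lattice_from_adjacency(adj,
                         population = if (!is.null(population_property)) pops)
}
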