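#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Column contracts for the three record schemas plus the taxonomy table.
.schema_columns <- list(
  visits   = c("plant", "insect", "date", "count"),
  pollen   = c("individual", "insect", "date", "plant_genus", "grains"),
  svd      = c("genus", "family", "grains", "is_control"),
  taxonomy = c("raw", "canonical", "rank", "family")
)

.set_schema <- function(x, schema) {
  attr(x, "pollinet_schema") <- schema
  x
}

#' Schema of a record table
#'
#' Record tables read by [read_records()] (or emitted by
#' [simulate_community()]) carry their schema (`"visits"`, `"pollen"`,
#' `"svd"`, or `"taxonomy"`) as an attribute so that downstream verbs can
#' dispatch on it.
#'
#' @param x A record table.
#' @return A single string, or `NA` if `x` carries no schema.
#' @export
record_schema <- function(x) {
  s <- attr(x, "pollinet_schema", exact = TRUE)
  if (is.null(s)) NA_character_ else s
}

#' Parse report of a record table
#'
#' @param x A table returned by [read_records()].
#' @return A list with elements `n_read`, `n_kept`, `n_rejected` and a
#'   tibble `rejected` (`row`, `reason`) describing every dropped row.
#' @export
parse_report <- function(x) attr(x, "parse_report", exact = TRUE)

#' Read a table of interaction, pollen-load, or deposition records
#'
#' Reads one of the four delimited-text table types used throughout the
#' package and validates every row against the schema's invariants. Rows
#' that violate an invariant (non-positive visit counts, negative grain
#' counts, unparseable or missing dates, duplicated pollen rows for one
#' individual x plant pair) are rejected, not silently fixed; the rejects
#' are listed in the attached parse report. Records without a definite
#' date are rejected because the whole analysis is anchored on the week
#' of observation.
#'
#' Expected headers:
#' \describe{
#'   \item{visits}{`plant, insect, date, count` — one dated observation of
#'     an insect taxon visiting a plant taxon, `count` >= 1 visit events.}
#'   \item{pollen}{`individual, insect, date, plant_genus, grains` — pollen
#'     load of one captured individual, grains of one plant genus.}
#'   \item{svd}{`genus, family, grains, is_control` — conspecific grains
#'     deposited on a virgin stigma during a single visit; control rows
#'     (unvisited flowers) have both taxon fields empty.}
#'   \item{taxonomy}{`raw, canonical, rank, family` — name harmonization
#'     map; `rank` one of species/genus/family.}
#' }
#'
#' @param path Path to a UTF-8 delimited text file.
#' @param schema One of `"visits"`, `"pollen"`, `"svd"`, `"taxonomy"`.
#' @param delim Field delimiter; comma by default, tab accepted.
#' @return A tibble of validated records in file order, with the schema
#'   and a parse report attached (see [record_schema()], [parse_report()]).
#' @export
read_records <- function(path, schema = c("visits", "pollen", "svd", "taxonomy"),
                         delim = ",") {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(paste0("File does not exist: ", path), class = "pollinet_io_error")
  }
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    warn(paste0("Empty ", schema, " file: ", path))
    out <- as_tibble(stats::setNames(
      rep(list(character()), length(.schema_columns[[schema]])),
      .schema_columns[[schema]]
    ))
    return(validate_records(out, schema))
  }
  missing <- setdiff(.schema_columns[[schema]], names(raw))
  if (length(missing) > 0) {
    abort(
      paste0("Schema '", schema, "' is missing column(s): ",
             paste(missing, collapse = ", ")),
      class = "pollinet_schema_error"
    )
  }
  validate_records(raw[.schema_columns[[schema]]], schema)
}

#' Write a record table back to delimited text
#'
#' Inverse of [read_records()]: writes the schema's columns so that
#' reading the file back reproduces the table.
#'
#' @param records A record table.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, delim = ",") {
  readr::write_delim(records, path, delim = delim, progress = FALSE)
  invisible(path)
}

# Coerce raw character columns to their types, enforcing row invariants.
# Returns the kept rows with a parse report attached.
validate_records <- function(raw, schema) {
  n <- nrow(raw)
  reasons <- rep(NA_character_, n)
  note <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reasons[bad & is.na(reasons)] <<- why
  }
  out <- raw
  if (schema == "visits") {
    out$date <- .parse_date(raw$date)
    out$count <- suppressWarnings(as.integer(raw$count))
    note(is.na(out$date), "missing or unparseable date")
    note(is.na(out$count), "unparseable count")
    note(out$count < 1, "count < 1")
    note(is.na(raw$plant) | raw$plant == "", "missing plant name")
    note(is.na(raw$insect) | raw$insect == "", "missing insect name")
  } else if (schema == "pollen") {
    out$date <- .parse_date(raw$date)
    out$grains <- suppressWarnings(as.integer(raw$grains))
    note(is.na(out$date), "missing or unparseable date")
    note(is.na(out$grains), "unparseable grains")
    note(out$grains < 0, "grains < 0")
    note(is.na(raw$individual) | raw$individual == "", "missing individual id")
    note(is.na(raw$insect) | raw$insect == "", "missing insect name")
    note(is.na(raw$plant_genus) | raw$plant_genus == "", "missing plant genus")
    dup <- duplicated(raw[c("individual", "plant_genus")]) |
      duplicated(raw[c("individual", "plant_genus")], fromLast = TRUE)
    if (any(dup & is.na(reasons))) {
      abort(
        paste0(
          "Duplicated pollen rows for (individual, plant_genus) pair(s): ",
          paste(unique(paste0(raw$individual[dup], " x ", raw$plant_genus[dup])),
                collapse = "; "),
          " — likely data corruption, refusing to merge."
        ),
        class = "pollinet_duplicate_error"
      )
    }
  } else if (schema == "svd") {
    out$grains <- suppressWarnings(as.integer(raw$grains))
    out$is_control <- .parse_logical(raw$is_control)
    out$genus <- dplyr::na_if(dplyr::coalesce(raw$genus, ""), "")
    out$family <- dplyr::na_if(dplyr::coalesce(raw$family, ""), "")
    note(is.na(out$grains), "unparseable grains")
    note(out$grains < 0, "grains < 0")
    note(is.na(out$is_control), "unparseable is_control flag")
    note(!out$is_control %in% TRUE & is.na(out$family), "missing family on trial row")
    note(out$is_control %in% TRUE & (!is.na(out$genus) | !is.na(out$family)),
         "control row carries a taxon name")
  } else if (schema == "taxonomy") {
    note(is.na(raw$raw) | raw$raw == "", "missing raw name")
    note(is.na(raw$canonical) | raw$canonical == "", "missing canonical name")
    note(!raw$rank %in% c("species", "genus", "family"), "invalid rank")
  }
  keep <- is.na(reasons)
  rejected <- tibble(row = which(!keep), reason = reasons[!keep])
  out <- out[keep, , drop = FALSE]
  attr(out, "parse_report") <- list(
    n_read = n, n_kept = sum(keep), n_rejected = sum(!keep), rejected = rejected
  )
  if (n > 0 && sum(!keep) > 0) {
    inform(paste0(sum(!keep), "/", n, " ", schema, " row(s) rejected; see parse_report()."))
  }
  .set_schema(out, schema)
}

.parse_date <- function(x) {
  d <- suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
  d
}

.parse_logical <- function(x) {
  lo <- tolower(trimws(dplyr::coalesce(x, "")))
  out <- rep(NA, length(x))
  out[lo %in% c("true", "t", "1", "yes")] <- TRUE
  out[lo %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Build a taxonomy-harmonization map
#'
#' @param raw,canonical Character vectors of equal length: observed name and
#'   the name it harmonizes to.
#' @param rank Taxonomic rank of the canonical name.
#' @param family Family of the canonical taxon (`NA` for plants if unused).
#' @return A `taxonomy`-schema tibble. Canonical names that never appear in
#'   `raw` are added as self-mapping rows, so the map is total on its own
#'   canonical vocabulary.
#' @export
taxonomy_map <- function(raw, canonical, rank = "species", family = NA_character_) {
  map <- tibble(raw = raw, canonical = canonical,
                rank = rank, family = family)
  selfless <- setdiff(map$canonical, map$raw)
  if (length(selfless) > 0) {
    extra <- map[match(selfless, map$canonical), ]
    extra$raw <- selfless
    map <- dplyr::bind_rows(map, extra)
  }
  .set_schema(map, "taxonomy")
}

.lookup_canonical <- function(names, map, what) {
  idx <- match(names, map$raw)
  if (anyNA(idx)) {
    missing <- sort(unique(names[is.na(idx)]))
    abort(
      paste0("Unmapped ", what, " name(s): ", paste(missing, collapse = ", ")),
      class = "pollinet_taxonomy_error"
    )
  }
  map$canonical[idx]
}

#' Harmonize taxon names and merge duplicate records
#'
#' Replaces every raw name by its canonical form. Names absent from the
#' map are an error (no silent pass-through), and taxa on the exclusion
#' list (e.g. spiders and mites caught by the visitation protocol but not
#' recorded in earlier sampling) are dropped. Visit records that become
#' identical after renaming — same plant, insect, date — are merged by
#' summing their counts, so no observation is lost or double-counted.
#' Pollen-load rows are renamed only; a collision of two individuals'
#' rows cannot occur because individual ids are untouched, but a renaming
#' that makes two loads of the same individual collide (two raw genera
#' mapping to one canonical genus) merges them by summing grains.
#'
#' @param records A `visits` or `pollen` record table.
#' @param map A `taxonomy`-schema tibble (see [taxonomy_map()]).
#' @param exclude Character vector of canonical names to drop (non-insect
#'   flower visitors).
#' @return The harmonized table, same schema as the input.
#' @export
harmonize <- function(records, map, exclude = character()) {
  schema <- record_schema(records)
  if (!schema %in% c("visits", "pollen")) {
    abort("harmonize() expects a 'visits' or 'pollen' record table.")
  }
  if (nrow(records) == 0) return(records)
  if (schema == "visits") {
    records$plant <- .lookup_canonical(records$plant, map, "plant")
    records$insect <- .lookup_canonical(records$insect, map, "insect")
    records <- records[!(records$insect %in% exclude | records$plant %in% exclude), ]
    grouping <- intersect(c("plant", "insect", "date", "year", "week", "evidence"),
                          names(records))
    out <- records |>
      dplyr::summarise(count = sum(.data$count),
                       .by = dplyr::all_of(grouping))
    out <- out[names(records)]
  } else {
    records$insect <- .lookup_canonical(records$insect, map, "insect")
    records$plant_genus <- .lookup_canonical(records$plant_genus, map, "plant genus")
    records <- records[!(records$insect %in% exclude), ]
    grouping <- intersect(c("individual", "insect", "date", "year", "week", "plant_genus"),
                          names(records))
    out <- records |>
      dplyr::summarise(grains = sum(.data$grains),
                       .by = dplyr::all_of(grouping))
    out <- out[names(records)]
  }
  .set_schema(as_tibble(out), schema)
}

#' Season-week index of a calendar date
#'
#' Weeks are 7-day bins counted from a fixed season origin:
#' `floor((date - origin) / 7)`. The same origin (by default June 1 of
#' each year, roughly the onset of the snow-free season in the high
#' Arctic) is used for every year of a study, so week indices align
#' across years by calendar date and "the same week" is comparable from
#' year to year.
#'
#' @param date A `Date` vector.
#' @param season_origin A single `Date`: week 0 starts on this day.
#' @return Integer week indices (may be negative for dates before the
#'   origin).
#' @export
assign_week <- function(date, season_origin) {
  stopifnot(inherits(date, "Date"), inherits(season_origin, "Date"),
            length(season_origin) == 1)
  as.integer(floor(as.numeric(date - season_origin) / 7))
}

#' Add year and season-week columns to a dated record table
#'
#' Applies [assign_week()] with the study's season origin anchored at the
#' same month and day (default June 1) of each record's own year.
#'
#' @param records A `visits` or `pollen` record table with a `date` column.
#' @param origin_month_day Month-day anchor of week 0, as `"MM-DD"`.
#' @return The table with integer `year` and `week` columns added (and,
#'   for visit records, an `evidence = "visit"` column).
#' @export
add_season_weeks <- function(records, origin_month_day = "06-01") {
  schema <- record_schema(records)
  records$year <- as.integer(format(records$date, "%Y"))
  origins <- as.Date(paste0(records$year, "-", origin_month_day))
  records$week <- as.integer(floor(as.numeric(records$date - origins) / 7))
  if (identical(schema, "visits") && !"evidence" %in% names(records)) {
    records$evidence <- "visit"
  }
  .set_schema(records, schema)
}
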