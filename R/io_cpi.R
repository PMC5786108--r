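# Reading, validation and canonicalization of CPI packet streams,
# rosters and recording-gap schedules.
#
# File conventions:
#   * CPI file: delimited text, one 30-s packet per row, columns
#     t,id_a,id_b (a whitespace "t i j" contact-list dialect is
#     supported through the `dialect` map);
#   * roster: CSV with id,status,category,ward,age,gender,reason,
#     present_from,present_to[,pvs], ISO-8601 dates;
#   * gap schedule: CSV with start_date,end_date (closed intervals).

#' Canonicalize a CPI packet table
#'
#' Orders each pair lexicographically (smaller id first), floors
#' off-grid timestamps to the 30-s grid, collapses duplicate reports of
#' the same `(pair, t)` packet — including mirrored reports where both
#' sensors logged the interaction — and sorts by time. Self-loop rows
#' (`id_a == id_b`) are dropped and counted.
#'
#' @param records A `data.frame`/`data.table` with columns `t`, `id_a`,
#'   `id_b`.
#' @return A `data.table` of canonical records (columns `t`, `id_a`,
#'   `id_b`), sorted by `t`, with a `"report"` attribute listing
#'   `n_input`, `n_self_loops`, `n_off_grid`, `n_duplicates`,
#'   `n_output`.
#' @export
canonicalize_records <- function(records) {
  dt <- as.data.table(records)[, .(t = as.numeric(t),
                                   id_a = as.character(id_a),
                                   id_b = as.character(id_b))]
  n_input <- nrow(dt)
  if (n_input && anyNA(dt$t)) stop("non-numeric timestamp in CPI records")
  if (n_input && any(dt$t < 0)) stop("negative timestamp in CPI records")
  self <- dt$id_a == dt$id_b
  dt <- dt[!self]
  off_grid <- sum(dt$t %% PACKET_S != 0)
  dt[, t := (t %/% PACKET_S) * PACKET_S]
  cp <- canonical_pair(dt$id_a, dt$id_b)
  dt[, `:=`(id_a = cp$id_a, id_b = cp$id_b)]
  n_before <- nrow(dt)
  dt <- unique(dt, by = c("t", "id_a", "id_b"))
  setkey(dt, t, id_a, id_b)
  setattr(dt, "report", list(
    n_input = n_input,
    n_self_loops = sum(self),
    n_off_grid = off_grid,
    n_duplicates = n_before - nrow(dt),
    n_output = nrow(dt)))
  dt[]
}

#' Read a CPI packet file
#'
#' Reads a delimited file of 30-second proximity packets and returns the
#' canonical record set (see [canonicalize_records()]). The delimiter is
#' auto-detected from the extension (`.csv` comma, `.tsv` tab, anything
#' else whitespace).
#'
#' @param path Path to the packet file.
#' @param dialect Named character vector mapping the canonical column
#'   names `t`, `id_a`, `id_b` to the column names (or, for header-less
#'   whitespace files, the column positions `"1"`, `"2"`, `"3"`) found
#'   in the file. The default matches both the package's own writer and
#'   the common `t i j` contact-list layout.
#' @return Canonical `data.table` of records with a `"report"`
#'   attribute; see [canonicalize_records()].
#' @export
read_cpi_records <- function(path,
                             dialect = c(t = "t", id_a = "id_a", id_b = "id_b")) {
  if (!file.exists(path)) stop("CPI file not found: ", path)
  sep <- cpi_sep(path)
  dt <- tryCatch(
    fread(path, sep = sep, header = "auto"),
    error = function(e) stop("malformed CPI file ", path, ": ",
                             conditionMessage(e)))
  nm <- names(dt)
  want <- c("t", "id_a", "id_b")
  cols <- character(3)
  for (i in seq_along(want)) {
    target <- if (want[i] %in% names(dialect)) dialect[[want[i]]] else want[i]
    if (target %in% nm) {
      cols[i] <- target
    } else if (grepl("^[0-9]+$", target) && as.integer(target) <= ncol(dt)) {
      cols[i] <- nm[as.integer(target)]
    } else {
      stop("cannot resolve column '", want[i], "' (looked for '", target,
           "') in ", path)
    }
  }
  dt <- dt[, cols, with = FALSE]
  setnames(dt, want)
  bad <- which(is.na(suppressWarnings(as.numeric(dt$t))))
  if (length(bad)) {
    stop("malformed CPI row(s) at line(s) ",
         paste(head(bad + 1L, 5L), collapse = ", "),
         ": non-numeric timestamp")
  }
  canonicalize_records(dt)
}

cpi_sep <- function(path) {
  switch(tolower(tools::file_ext(path)), csv = ",", tsv = "\t", " ")
}

#' Write a CPI packet file
#'
#' @param records Canonical record table.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_cpi_records <- function(records, path) {
  fwrite(as.data.table(records)[, .(t, id_a, id_b)], path,
         sep = if (cpi_sep(path) == "\t") "\t" else ",")
  invisible(path)
}

#' Read a roster file
#'
#' Reads the individual roster: one row per participant with status
#' (patient/staff), category, administrative ward attachment, patient
#' covariates, and the closed presence interval. Patients must carry
#' age, gender and a reason for hospitalization; staff rows leave those
#' blank. An optional logical `pvs` column flags patients in a
#' persistent vegetative state (excluded from the risk models).
#'
#' @param path Path to the roster CSV.
#' @return A `data.table` with columns `id`, `status`, `category`,
#'   `ward`, `age`, `gender`, `reason`, `present_from`, `present_to`,
#'   `pvs`.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("roster file not found: ", path)
  dt <- fread(path, colClasses = list(character = c("id")))
  req <- c("id", "status", "category", "ward", "present_from", "present_to")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("roster missing column(s): ", paste(miss, collapse = ", "))
  for (opt in c("age", "gender", "reason")) {
    if (!opt %in% names(dt)) dt[[opt]] <- NA
  }
  if (!"pvs" %in% names(dt)) dt[["pvs"]] <- FALSE
  dt <- dt[, .(id = as.character(id), status = as.character(status),
               category = as.character(category), ward = as.character(ward),
               age = suppressWarnings(as.integer(age)),
               gender = as.character(gender), reason = as.character(reason),
               present_from = as.Date(present_from),
               present_to = as.Date(present_to),
               pvs = as.logical(pvs))]
  dt[is.na(pvs), pvs := FALSE]
  dt[gender == "", gender := NA_character_]
  dt[reason == "", reason := NA_character_]
  validate_roster(dt)
  setkey(dt, id)
  dt[]
}

validate_roster <- function(dt) {
  if (anyDuplicated(dt$id)) stop("duplicate ids in roster")
  bad_cat <- setdiff(unique(dt$category), c(CPI_CATEGORIES, CPI_EXTRA_CATEGORIES))
  if (length(bad_cat)) stop("unknown category label(s): ",
                            paste(bad_cat, collapse = ", "))
  bad_ward <- setdiff(unique(dt$ward), CPI_WARDS)
  if (length(bad_ward)) stop("unknown ward label(s): ",
                             paste(bad_ward, collapse = ", "))
  bad_status <- setdiff(unique(dt$status), c("patient", "staff"))
  if (length(bad_status)) stop("unknown status label(s): ",
                               paste(bad_status, collapse = ", "))
  if (any((dt$status == "patient") != (dt$category == "patient")))
    stop("category must be 'patient' iff status is 'patient'")
  pat <- dt[status == "patient"]
  if (anyNA(pat$age) || anyNA(pat$gender) || anyNA(pat$reason))
    stop("patient row(s) missing age, gender or reason: ",
         paste(head(pat[is.na(age) | is.na(gender) | is.na(reason), id], 5L),
               collapse = ", "))
  bad_reason <- setdiff(unique(pat$reason), CPI_REASONS)
  if (length(bad_reason)) stop("unknown reason label(s): ",
                               paste(bad_reason, collapse = ", "))
  bad_gender <- setdiff(stats::na.omit(unique(dt$gender)), c("F", "M"))
  if (length(bad_gender)) stop("unknown gender label(s): ",
                               paste(bad_gender, collapse = ", "))
  if (any(dt$present_from > dt$present_to))
    stop("present_from after present_to for id(s): ",
         paste(head(dt[present_from > present_to, id], 5L), collapse = ", "))
  invisible(dt)
}

#' @rdname read_roster
#' @param roster Roster table to write.
#' @export
write_roster <- function(roster, path) {
  fwrite(as.data.table(roster), path)
  invisible(path)
}

#' Recording-gap schedules
#'
#' A gap schedule lists the closed date intervals during which sensor
#' recording was invalid (battery changes and similar outages). Packets
#' and person-days falling on those dates are excluded from analyses.
#'
#' @param start_date,end_date Vectors of interval bounds (`Date` or
#'   ISO-8601 strings); intervals are closed and must not overlap.
#' @return A `data.table` with `start_date`, `end_date`, sorted.
#' @export
gap_schedule <- function(start_date = as.Date(character()),
                         end_date = as.Date(character())) {
  dt <- data.table(start_date = as.Date(start_date),
                   end_date = as.Date(end_date))
  if (any(dt$start_date > dt$end_date)) stop("gap interval ends before it starts")
  setkey(dt, start_date)
  if (nrow(dt) > 1L &&
      any(dt$start_date[-1L] <= dt$end_date[-nrow(dt)]))
    stop("gap intervals overlap")
  dt[]
}

#' @rdname gap_schedule
#' @param path Path to a gap CSV (`start_date,end_date`).
#' @export
read_gaps <- function(path) {
  if (!file.exists(path)) stop("gap file not found: ", path)
  dt <- fread(path)
  if (!all(c("start_date", "end_date") %in% names(dt)))
    stop("gap file must have columns start_date,end_date")
  gap_schedule(dt$start_date, dt$end_date)
}

#' @rdname gap_schedule
#' @param gaps Gap schedule to write.
#' @export
write_gaps <- function(gaps, path) {
  fwrite(as.data.table(gaps), path)
  invisible(path)
}

# TRUE for dates inside any gap interval
in_gap <- function(date, gaps) {
  if (is.null(gaps) || nrow(gaps) == 0L) return(rep(FALSE, length(date)))
  d <- as.Date(date)
  res <- rep(FALSE, length(d))
  for (i in seq_len(nrow(gaps))) {
    res <- res | (d >= gaps$start_date[i] & d <= gaps$end_date[i])
  }
  res
}

#' Cross-check a CPI dataset
#'
#' Report-only consistency check of a record stream against a roster and
#' gap schedule: counts records whose ids are absent from the roster,
#' records dated outside either party's presence interval, records dated
#' inside a gap interval, and the number of records involving each
#' category (a record involving two categories counts once for each).
#'
#' @param records Canonical record table.
#' @param roster Roster table.
#' @param gaps Gap schedule (may be `NULL` or empty).
#' @param origin Calendar date of day 0 of the timestamp scale.
#' @return A list with components `n_records`, `unknown_id`,
#'   `outside_presence`, `in_gap` and `involvement` (named integer
#'   vector per category).
#' @export
validate_dataset <- function(records, roster, gaps = NULL,
                             origin = as.Date("2009-07-01")) {
  rec <- as.data.table(records)
  ros <- as.data.table(roster)
  rec[, date := cpi_date(t, origin)]
  known <- rec$id_a %chin% ros$id & rec$id_b %chin% ros$id
  # presence check (only for known ids)
  pres <- ros[, .(id, present_from, present_to)]
  ka <- pres[rec, on = c(id = "id_a")]
  kb <- pres[rec, on = c(id = "id_b")]
  out_a <- !is.na(ka$present_from) &
    (ka$date < ka$present_from | ka$date > ka$present_to)
  out_b <- !is.na(kb$present_from) &
    (kb$date < kb$present_from | kb$date > kb$present_to)
  gap_hit <- in_gap(rec$date, gaps)
  inv <- involvement_from_records(rec, ros)
  rec[, date := NULL]
  list(n_records = nrow(rec),
       unknown_id = sum(!known),
       outside_presence = sum(out_a | out_b),
       in_gap = sum(gap_hit),
       involvement = inv)
}

#' Category involvement counts of a record stream
#'
#' Counts, per category, how many records involve at least one member of
#' the category. A record whose two members belong to different
#' categories contributes to both counts, so the counts sum to more than
#' the number of records.
#'
#' @inheritParams validate_dataset
#' @return Named integer vector over the categories present.
#' @export
involvement_from_records <- function(records, roster) {
  rec <- as.data.table(records)
  ros <- as.data.table(roster)
  cat_of <- setNames(ros$category, ros$id)
  ca <- cat_of[rec$id_a]
  cb <- cat_of[rec$id_b]
  cats <- sort(unique(c(ca, cb)))
  cats <- cats[!is.na(cats)]
  out <- setNames(integer(length(cats)), cats)
  for (cc in cats) {
    out[cc] <- sum(ca == cc | cb == cc, na.rm = TRUE)
  }
  out
}
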