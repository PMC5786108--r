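# Ward-conditioned category mixing matrices.
#
# For a ward w, the contact matrix has one row per category with members
# administratively attached to w and one column per category
# hospital-wide; cell (r, c) is the mean, over the person-days of the
# (w, r) group, of the number of distinct category-c partners met that
# day (partners can be anywhere in the hospital). The duration matrix
# is the pair-day analogue: the mean daily cumulative duration between
# a (w, r) member and a category-c member anywhere.

#' Ward-specific contact (distinct-frequency) matrix
#'
#' @param records Canonical record table.
#' @param roster Roster table (defines ward attachment and presence).
#' @param ward One of `W1..W5`, `W6_transversal`.
#' @param gaps Gap schedule.
#' @param origin Calendar date of day 0.
#' @param averaging `"person_day"` (pool all person-days of the group,
#'   the default) or `"individual"` (average within individuals first).
#' @return A `category_matrix` object: list with `ward`, `kind`,
#'   `values` (rows = categories attached to the ward, cols = all
#'   categories), and `support` (averaged units per cell).
#' @export
contact_matrix <- function(records, roster, ward,
                           gaps = NULL, origin = as.Date("2009-07-01"),
                           averaging = c("person_day", "individual")) {
  averaging <- match.arg(averaging)
  ros <- as.data.table(roster)
  w <- ward
  members <- ros[ward == w]
  all_cats <- CPI_CATEGORIES
  row_cats <- intersect(CPI_CATEGORIES, unique(members$category))
  if (nrow(members) == 0L) {
    message("ward ", w, " has no attached individuals; empty matrix")
    return(new_category_matrix(w, "distinct_frequency",
                               matrix(numeric(), 0, length(all_cats),
                                      dimnames = list(NULL, all_cats)),
                               matrix(integer(), 0, length(all_cats),
                                      dimnames = list(NULL, all_cats))))
  }
  # distinct partners per (person-day, partner category)
  rec <- as.data.table(records)[, .(t, id_a, id_b)]
  rec[, date := cpi_date(t, origin)]
  rec <- rec[!in_gap(date, gaps)]
  long <- rbindlist(list(rec[, .(id = id_a, partner = id_b, date)],
                         rec[, .(id = id_b, partner = id_a, date)]))
  long[ros, on = c(partner = "id"), partner_cat := i.category]
  long <- long[!is.na(partner_cat) & id %chin% members$id]
  counts <- long[, .(value = uniqueN(partner)), by = .(id, date, partner_cat)]
  # full person-day grid of the group's members (zeros matter)
  grid <- members[, .(date = seq(present_from, present_to, by = "day")),
                  by = .(id, category)]
  grid <- grid[!in_gap(date, gaps)]
  vals <- matrix(NA_real_, length(row_cats), length(all_cats),
                 dimnames = list(row_cats, all_cats))
  supp <- matrix(0L, length(row_cats), length(all_cats),
                 dimnames = list(row_cats, all_cats))
  for (r in row_cats) {
    g <- grid[category == r]
    if (nrow(g) == 0L) next
    for (cc in all_cats) {
      x <- counts[partner_cat == cc][g, on = c("id", "date")]
      x[is.na(value), value := 0]
      if (averaging == "individual") {
        x <- x[, .(value = mean(value)), by = id]
      }
      vals[r, cc] <- mean(x$value)
      supp[r, cc] <- nrow(x)
    }
  }
  new_category_matrix(w, "distinct_frequency", vals, supp)
}

#' Ward-specific duration matrix
#'
#' Cell (r, c): mean daily cumulative contact duration (minutes/day)
#' over pair-days whose one member is attached to the ward with category
#' r and whose other member has category c (any ward). Each pair-day is
#' viewed from both members' perspectives, so a same-ward pair-day
#' contributes to both (r, c) and (c, r). Cells with no pair-days are
#' missing with support 0.
#'
#' @param pdays Output of [pair_days()].
#' @inheritParams contact_matrix
#' @return A `category_matrix` with `kind = "cumulative_duration"`.
#' @export
duration_matrix <- function(pdays, roster, ward) {
  ros <- as.data.table(roster)
  w <- ward
  members <- ros[ward == w]
  all_cats <- CPI_CATEGORIES
  row_cats <- intersect(CPI_CATEGORIES, unique(members$category))
  x <- copy(as.data.table(pdays))
  x[ros, on = c(id_a = "id"), `:=`(cat_a = i.category, ward_a = i.ward)]
  x[ros, on = c(id_b = "id"), `:=`(cat_b = i.category, ward_b = i.ward)]
  # both directed views of every pair-day
  directed <- rbindlist(list(
    x[, .(ward_r = ward_a, cat_row = cat_a, cat_col = cat_b,
          minutes = cum_duration_s / 60)],
    x[, .(ward_r = ward_b, cat_row = cat_b, cat_col = cat_a,
          minutes = cum_duration_s / 60)]))
  directed <- directed[ward_r == w & !is.na(cat_row) & !is.na(cat_col)]
  agg <- directed[, .(value = mean(minutes), support = .N),
                  by = .(cat_row, cat_col)]
  vals <- matrix(NA_real_, length(row_cats), length(all_cats),
                 dimnames = list(row_cats, all_cats))
  supp <- matrix(0L, length(row_cats), length(all_cats),
                 dimnames = list(row_cats, all_cats))
  for (i in seq_len(nrow(agg))) {
    r <- agg$cat_row[i]; cc <- agg$cat_col[i]
    if (r %in% row_cats && cc %in% all_cats) {
      vals[r, cc] <- agg$value[i]
      supp[r, cc] <- agg$support[i]
    }
  }
  new_category_matrix(w, "cumulative_duration", vals, supp)
}

new_category_matrix <- function(ward, kind, values, support) {
  structure(list(ward = ward, kind = kind, values = values,
                 support = support),
            class = "category_matrix")
}

#' @export
print.category_matrix <- function(x, ...) {
  cat(sprintf("<category_matrix> ward %s, kind %s (%d x %d)\n",
              x$ward, x$kind, nrow(x$values), ncol(x$values)))
  print(round(x$values, 2))
  invisible(x)
}

#' Long-format view of a category matrix
#'
#' @param x A `category_matrix`.
#' @return `data.table(ward, kind, cat_row, cat_col, value, support)`,
#'   the layout used for CSV export.
#' @export
as_long.category_matrix <- function(x) {
  if (nrow(x$values) == 0L) {
    return(data.table(ward = character(), kind = character(),
                      cat_row = character(), cat_col = character(),
                      value = numeric(), support = integer()))
  }
  dt <- CJ(cat_row = rownames(x$values), cat_col = colnames(x$values),
           sorted = FALSE)
  dt[, `:=`(ward = x$ward, kind = x$kind,
            value = x$values[cbind(cat_row, cat_col)],
            support = x$support[cbind(cat_row, cat_col)])]
  setcolorder(dt, c("ward", "kind", "cat_row", "cat_col", "value", "support"))
  dt[]
}

#' @rdname as_long.category_matrix
#' @export
as_long <- function(x) UseMethod("as_long")
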