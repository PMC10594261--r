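#' Canonical CAI weight table
#'
#' The Cumulative Adversity Index is built from 15 questionnaire items
#' grouped into nine exposure types. Each item (or, for the COVID-19 course
#' item, each response level) carries a severity weight in points. Items that
#' are mutually dependent (e.g. COVID-19 symptoms vs. diagnosis vs. course)
#' form a dependency group of which only the highest endorsed weight counts.
#' Some items were only fielded in a subset of subperiods; the availability
#' mask records this. Under this table the subperiod maxima are 15 / 16 / 16
#' points and the theoretical cumulative maximum at period 3 is 47.
#'
#' The table is data, not code: alternative weighting schemes can be supplied
#' to every scoring function as a data frame with the same columns, or loaded
#' from CSV with [read_weight_table()].
#'
#' @return data frame with one row per (item, response level):
#'   `item` (1..15), `label`, `type` (one of nine exposure-type names),
#'   `group` (dependency group id), `level` (integer response level, >= 1),
#'   `points` (non-negative weight), `sp1`, `sp2`, `sp3` (logical
#'   availability per subperiod).
#' @export
canonical_weight_table <- function() {
  w <- data.frame(
    item = c(1L, 2L, 3L, 3L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L, 15L),
    label = c(
      "own COVID-19 symptoms without diagnosis",
      "own COVID-19 diagnosis",
      "own COVID-19 course: mild",
      "own COVID-19 course: severe",
      "own COVID-19 course: hospitalised",
      "lives alone",
      "household member COVID-19 symptoms",
      "household member COVID-19 diagnosis",
      "household member severe course/hospitalised",
      "close contact died of COVID-19",
      "quarantine",
      "daily activities changed",
      "inside for prolonged periods",
      "no outdoor space at home",
      "income decreased",
      "lost job",
      "serious financial problems"
    ),
    type = c(
      rep("own_infection", 5L), "living_alone",
      rep("household_infection", 3L), "bereavement", "quarantine",
      "activity_change", "confinement", "no_outdoor_space",
      rep("financial", 3L)
    ),
    group = c(
      rep(1L, 5L), 2L, rep(3L, 3L), 4L, 5L, 6L, 7L, 8L, rep(9L, 3L)
    ),
    level = c(1L, 1L, 1L, 2L, 3L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),
    points = c(1, 3, 3, 4, 5, 1, 1, 2, 2, 3, 1, 1, 1, 1, 1, 2, 2),
    sp1 = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
            TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    sp2 = c(rep(TRUE, 10L), TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    sp3 = c(rep(TRUE, 10L), TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  validate_weight_table(w)
  w
}

#' Names of the nine exposure types, in canonical order
#' @export
exposure_types <- function() {
  c("own_infection", "living_alone", "household_infection", "quarantine",
    "bereavement", "activity_change", "confinement", "no_outdoor_space",
    "financial")
}

#' Validate a CAI weight table
#'
#' Checks the structural invariants: exactly 15 items and 9 exposure types,
#' every item in exactly one type and one dependency group, non-negative
#' weights, consecutive response levels starting at 1, and availability in at
#' least one subperiod per item.
#'
#' @param w a weight table data frame (see [canonical_weight_table()]).
#' @return `w`, invisibly, if valid; otherwise an error.
#' @export
validate_weight_table <- function(w) {
  need <- c("item", "type", "group", "level", "points", "sp1", "sp2", "sp3")
  miss <- setdiff(need, names(w))
  if (length(miss)) {
    stop("weight table is missing columns: ", paste(miss, collapse = ", "))
  }
  items <- sort(unique(w$item))
  if (!identical(items, 1:15)) {
    stop("weight table must cover exactly items 1..15")
  }
  if (length(unique(w$type)) != 9L) {
    stop("weight table must define exactly 9 exposure types, found ",
         length(unique(w$type)))
  }
  if (any(w$points < 0)) stop("weight table points must be non-negative")
  for (it in items) {
    rows <- w[w$item == it, ]
    if (length(unique(rows$type)) != 1L || length(unique(rows$group)) != 1L) {
      stop("item ", it, " maps to more than one type or dependency group")
    }
    if (!identical(sort(rows$level), seq_len(nrow(rows)))) {
      stop("item ", it, " levels must be consecutive integers starting at 1")
    }
    if (!any(rows$sp1 | rows$sp2 | rows$sp3)) {
      stop("item ", it, " is unavailable in every subperiod")
    }
    # a dependency group never spans exposure types
    grp <- w[w$group == rows$group[1], ]
    if (length(unique(grp$type)) != 1L) {
      stop("dependency group ", rows$group[1], " spans multiple exposure types")
    }
  }
  invisible(w)
}

#' Read / write a weight table as CSV
#'
#' @param path file path. The canonical table ships with the package at
#'   `system.file("extdata", "cai_weight_table.csv", package = "caindex")`.
#' @return [read_weight_table()] returns a validated weight table.
#' @export
read_weight_table <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("sp1", "sp2", "sp3")) w[[col]] <- as.logical(w[[col]])
  validate_weight_table(w)
  w
}

#' @rdname read_weight_table
#' @param w a weight table.
#' @export
write_weight_table <- function(w, path) {
  validate_weight_table(w)
  utils::write.csv(w, path, row.names = FALSE)
  invisible(path)
}

#' Maximum attainable cumulative CAI score
#'
#' Exhaustive enumeration over the weight table: for each subperiod, each
#' exposure type contributes at most the highest weight among its items
#' available in that subperiod (dependency groups take a maximum, and maxima
#' across waves cannot exceed the best single response); the subperiod
#' maximum is the sum over the nine types, and the period-`through_period`
#' maximum is the running sum of subperiod maxima. Under the canonical table
#' this is 15 + 16 + 16 = 47.
#'
#' @param w weight table.
#' @param through_period last subperiod included in the cumulative sum.
#' @return maximum cumulative score (scalar).
#' @export
max_possible_score <- function(w = canonical_weight_table(),
                               through_period = 3L) {
  validate_weight_table(w)
  stopifnot(through_period %in% 1:3)
  sum(vapply(seq_len(through_period), function(p) {
    avail <- w[w[[paste0("sp", p)]], , drop = FALSE]
    if (!nrow(avail)) return(0)
    sum(tapply(avail$points, avail$type, max))
  }, numeric(1)))
}
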