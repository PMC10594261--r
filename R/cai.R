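#' Score one dependency group at a single wave
#'
#' Maps each endorsed item response to its weight and resolves mutual
#' dependency by taking the highest weight in the group (e.g. a COVID-19
#' diagnosis, 3 points, supersedes symptoms without diagnosis, 1 point).
#' Returns 0 when nothing is endorsed.
#'
#' @param responses named numeric vector: names are item ids of one
#'   dependency group, values are response levels (0 = not endorsed,
#'   `k >= 1` = endorsed at level `k`; NA = item not asked).
#' @param subperiod subperiod index in 1..3 of the wave.
#' @param w weight table.
#' @return the group (= exposure type) score in points.
#' @examples
#' w <- canonical_weight_table()
#' score_exposure_type(c(`1` = 1, `2` = 0), 1, w)  # symptoms only: 1 point
#' score_exposure_type(c(`1` = 1, `2` = 1), 1, w)  # diagnosis wins: 3 points
#' @export
score_exposure_type <- function(responses, subperiod, w = canonical_weight_table()) {
  items <- as.integer(names(responses))
  if (anyNA(items)) stop("responses must be named by item id")
  grp <- unique(w$group[match(items, w$item)])
  if (length(grp) != 1L) {
    stop("responses span more than one dependency group: ",
         paste(grp, collapse = ", "))
  }
  best <- 0
  for (i in seq_along(items)) {
    r <- responses[[i]]
    if (is.na(r) || r == 0) next
    rows <- w[w$item == items[i], , drop = FALSE]
    if (!rows[[paste0("sp", subperiod)]][1]) {
      stop(sprintf("item %d is not available in subperiod %d", items[i], subperiod))
    }
    if (r > nrow(rows) || r != round(r) || r < 0) {
      stop(sprintf("item %d: response level %s out of range 0..%d",
                   items[i], format(r), nrow(rows)))
    }
    best <- max(best, rows$points[rows$level == r])
  }
  best
}

#' Per-wave exposure-type scores for a long wave table
#'
#' Vectorised scoring of every wave row: each item response is mapped to its
#' weight, dependency groups are resolved by maximum within the wave, and one
#' column per exposure type is returned. Endorsements of items not fielded in
#' the wave's subperiod raise an availability error; NA responses mean "not
#' asked" and contribute nothing.
#'
#' @param waves data frame with columns `participant_id`, `date` (or
#'   `subperiod`), and `item_1` .. `item_15` response levels.
#' @param w weight table.
#' @return data frame: `participant_id`, `subperiod`, plus one numeric score
#'   column per exposure type (canonical order, names as in
#'   [exposure_types()]).
#' @export
wave_type_scores <- function(waves, w = canonical_weight_table()) {
  validate_weight_table(w)
  if (!"subperiod" %in% names(waves)) {
    waves$subperiod <- assign_subperiod(waves$date)
  }
  n <- nrow(waves)
  types <- exposure_types()
  out <- matrix(0, nrow = n, ncol = length(types),
                dimnames = list(NULL, types))
  for (it in 1:15) {
    col <- paste0("item_", it)
    if (!col %in% names(waves)) {
      stop("wave table is missing column ", col)
    }
    r <- waves[[col]]
    rows <- w[w$item == it, , drop = FALSE]
    n_lev <- nrow(rows)
    bad <- !is.na(r) & (r < 0 | r > n_lev | r != round(r))
    if (any(bad)) {
      stop(sprintf("item %d: response level %s out of range 0..%d",
                   it, format(r[bad][1]), n_lev))
    }
    avail <- c(rows$sp1[1], rows$sp2[1], rows$sp3[1])[waves$subperiod]
    if (any(!is.na(r) & r > 0 & !avail)) {
      p_bad <- waves$subperiod[which(!is.na(r) & r > 0 & !avail)[1]]
      stop(sprintf("item %d endorsed in subperiod %d where it is not available",
                   it, p_bad))
    }
    pts <- c(0, rows$points[order(rows$level)])[ifelse(is.na(r), 0, r) + 1L]
    ty <- rows$type[1]
    out[, ty] <- pmax(out[, ty], pts)
  }
  cbind(waves[, "participant_id", drop = FALSE],
        subperiod = waves$subperiod, as.data.frame(out))
}

#' Aggregate one participant-subperiod to its SubperiodScore
#'
#' Across the waves a participant completed within a subperiod, each exposure
#' type keeps its highest observed score; the subperiod total is the sum over
#' the nine types. With zero observed waves the total is returned as a
#' missing-subperiod marker (NA), not an error.
#'
#' @param wave_scores data frame of per-wave type scores for one participant
#'   and one subperiod (the type-score columns of [wave_type_scores()]).
#' @return list with `per_type` (named 9-vector), `total`, `n_waves_observed`.
#' @export
aggregate_subperiod <- function(wave_scores) {
  types <- exposure_types()
  if (NROW(wave_scores) == 0L) {
    return(list(per_type = stats::setNames(rep(NA_real_, 9L), types),
                total = NA_real_, n_waves_observed = 0L))
  }
  per_type <- vapply(types, function(ty) max(wave_scores[[ty]]), numeric(1))
  list(per_type = per_type, total = sum(per_type),
       n_waves_observed = NROW(wave_scores))
}

#' Running cumulative CAI across the three periods
#'
#' Period 1 is the subperiod-1 total; period 2 adds subperiod 2; period 3
#' adds subperiod 3. A missing subperiod contributes 0 to later cumulative
#' sums and yields no row for its own period. Participants are eligible only
#' if at least two subperiod scores are computable.
#'
#' @param totals numeric vector of length 3 of subperiod totals, NA marking a
#'   missing subperiod.
#' @return data frame with one row per computable period: `period`,
#'   `subperiod_total`, `cai` (cumulative score), `eligible`.
#' @examples
#' cumulate(c(15, 16, 16))   # cumulative 15, 31, 47
#' cumulate(c(5, NA, 4))     # periods 1 and 3: 5 and 9, still eligible
#' @export
cumulate <- function(totals) {
  stopifnot(length(totals) == 3L)
  observed <- !is.na(totals)
  eligible <- sum(observed) >= 2L
  cum <- cumsum(ifelse(observed, totals, 0))
  data.frame(
    period = which(observed),
    subperiod_total = totals[observed],
    cai = cum[observed],
    eligible = eligible
  )
}

#' Compute cumulative CAI scores for a cohort of wave records
#'
#' Full index construction: assign subperiods, score waves (weights +
#' dependency maxima), take per-type maxima across waves within each
#' subperiod, sum types to subperiod totals, and accumulate across periods.
#'
#' @param waves long wave table (see [wave_type_scores()]).
#' @param w weight table.
#' @param type_weights optional named 9-vector of per-type multipliers (in
#'   canonical type order or named by type); used for the perceived-impact
#'   alternative weighting, where each type's score is rescaled by its
#'   empirical weight before summation. `NULL` keeps the table weights as-is.
#' @return data frame with one row per participant x computable period:
#'   `participant_id`, `period`, `subperiod_total`, `cai`, `n_waves`,
#'   `eligible`. The per-subperiod exposure-type scores are attached as
#'   attribute `"type_scores"`.
#' @export
compute_cai <- function(waves, w = canonical_weight_table(), type_weights = NULL) {
  ws <- wave_type_scores(waves, w)
  types <- exposure_types()
  if (!is.null(type_weights)) {
    if (!is.null(names(type_weights))) {
      if (!setequal(names(type_weights), types)) {
        stop("type_weights must be named by the nine exposure types")
      }
      type_weights <- type_weights[types]
    } else if (length(type_weights) != 9L) {
      stop("type_weights must have length 9")
    }
  }

  key <- interaction(ws$participant_id, ws$subperiod, drop = TRUE)
  agg <- data.frame(
    participant_id = tapply(ws$participant_id, key, `[`, 1L),
    subperiod = as.integer(tapply(ws$subperiod, key, `[`, 1L)),
    n_waves = as.integer(tapply(ws$subperiod, key, length))
  )
  for (ty in types) agg[[ty]] <- as.numeric(tapply(ws[[ty]], key, max))
  tm <- as.matrix(agg[, types, drop = FALSE])
  agg$subperiod_total <- if (is.null(type_weights)) rowSums(tm)
                         else as.numeric(tm %*% as.numeric(type_weights))

  out <- do.call(rbind, lapply(split(agg, agg$participant_id), function(d) {
    totals <- rep(NA_real_, 3L)
    nw <- integer(3L)
    totals[d$subperiod] <- d$subperiod_total
    nw[d$subperiod] <- d$n_waves
    res <- cumulate(totals)
    res$participant_id <- d$participant_id[1]
    res$n_waves <- nw[res$period]
    res
  }))
  rownames(out) <- NULL
  out <- out[, c("participant_id", "period", "subperiod_total", "cai",
                 "n_waves", "eligible")]
  out <- out[order(out$participant_id, out$period), ]
  rownames(out) <- NULL
  attr(out, "type_scores") <- agg[, c("participant_id", "subperiod", types)]
  out
}

#' Restrict CAI scores to eligible participants
#'
#' Keeps participants whose CAI is computable in at least two subperiods and
#' reports how many were excluded.
#'
#' @param cai_scores output of [compute_cai()].
#' @return the eligible subset, with attributes `"n_excluded"` and
#'   `"excluded_ids"`.
#' @export
filter_eligible <- function(cai_scores) {
  ids <- unique(cai_scores$participant_id)
  keep <- cai_scores$eligible
  out <- cai_scores[keep, , drop = FALSE]
  rownames(out) <- NULL
  excluded <- setdiff(ids, unique(out$participant_id))
  attr(out, "n_excluded") <- length(excluded)
  attr(out, "excluded_ids") <- excluded
  ts <- attr(cai_scores, "type_scores")
  if (!is.null(ts)) {
    attr(out, "type_scores") <- ts[!ts$participant_id %in% excluded, , drop = FALSE]
  }
  out
}
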