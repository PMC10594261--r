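#' QIDS depression severity score (0--27)
#'
#' Scores the 16-item Quick Inventory of Depressive Symptomatology into nine
#' symptom domains. Sleep (items 1--4), appetite/weight (items 6--9) and
#' psychomotor change (items 15--16) are each scored as the maximum of their
#' items; mood (5), concentration (10), self-view (11), suicidal ideation
#' (12), interest (13) and fatigue (14) enter singly. The total is the sum of
#' the nine domain scores, an integer in 0..27. Item values must lie in
#' 0..3; any missing item yields a missing total (carrying a
#' `"missing_reason"` attribute) rather than a silently imputed score.
#'
#' @param items numeric vector of length 16, or a matrix/data frame with 16
#'   columns (one row per respondent).
#' @return integer vector of total scores (NA where items were missing).
#' @examples
#' score_qids(rep(3, 16))          # 27
#' score_qids(c(3, rep(0, 15)))    # 3: sleep domain max
#' @export
score_qids <- function(items) {
  m <- as_item_matrix(items, 16L, "QIDS")
  check_item_range(m, 0L, 3L, "QIDS")
  dom <- qids_domains()
  per_dom <- vapply(dom, function(ix) {
    if (length(ix) == 1L) m[, ix] else apply(m[, ix, drop = FALSE], 1L, max)
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) per_dom <- matrix(per_dom, nrow = 1L)
  out <- as.integer(rowSums(per_dom))
  flag_missing(out, m)
}

#' @describeIn score_qids the item-to-domain mapping (standard QIDS-SR16
#'   layout).
#' @export
qids_domains <- function() {
  list(
    sleep = 1:4, mood = 5L, appetite_weight = 6:9, concentration = 10L,
    self_view = 11L, suicidal_ideation = 12L, interest = 13L,
    fatigue = 14L, psychomotor = 15:16
  )
}

#' BAI anxiety severity score (0--63)
#'
#' Sum of the 21 Beck Anxiety Inventory items, each rated 0 (not at all)
#' to 3 (severely).
#'
#' @param items numeric vector of length 21, or a matrix with 21 columns.
#' @return integer vector of totals (NA where items were missing).
#' @export
score_bai <- function(items) {
  m <- as_item_matrix(items, 21L, "BAI")
  check_item_range(m, 0L, 3L, "BAI")
  flag_missing(as.integer(rowSums(m)), m)
}

#' De Jong Gierveld loneliness score (0--6)
#'
#' Six-item abbreviated scale. On negatively worded items, "yes" and
#' "more_or_less" both score 1 and "no" scores 0; on positively worded items
#' the mapping is reversed ("no" and "more_or_less" score 1, "yes" scores 0),
#' so "more_or_less" always scores 1. The default polarity follows the
#' standard short form (three negative items then three positive); marking
#' all items negative recovers an unreversed variant.
#'
#' @param responses character vector of length 6 with values in
#'   `c("yes", "more_or_less", "no")`, or a matrix with 6 columns.
#' @param polarity logical vector of length 6; `TRUE` = negatively worded.
#' @return integer vector of totals (NA where responses were missing).
#' @export
score_loneliness <- function(responses,
                             polarity = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)) {
  if (is.null(dim(responses))) {
    responses <- matrix(as.character(responses), nrow = 1L)
  } else {
    responses <- as.matrix(responses)
  }
  if (ncol(responses) != 6L) {
    stop("loneliness responses must have exactly 6 items, got ", ncol(responses))
  }
  stopifnot(is.logical(polarity), length(polarity) == 6L, !anyNA(polarity))
  known <- c("yes", "more_or_less", "no")
  bad <- !is.na(responses) & !(responses %in% known)
  if (any(bad)) {
    stop("unknown loneliness response category: ",
         paste(unique(responses[bad]), collapse = ", "))
  }
  pts <- matrix(NA_integer_, nrow(responses), 6L)
  for (j in 1:6) {
    r <- responses[, j]
    pts[, j] <- ifelse(is.na(r), NA_integer_,
                       ifelse(r == "more_or_less", 1L,
                              if (polarity[j]) ifelse(r == "yes", 1L, 0L)
                              else ifelse(r == "no", 1L, 0L)))
  }
  flag_missing(as.integer(rowSums(pts)), pts)
}

#' Perceived mental health impact score
#'
#' Mean of the nine perceived-impact items, each rated 1 (completely
#' disagree) to 5 (completely agree).
#'
#' @param items numeric vector of length 9 or matrix with 9 columns.
#' @return numeric vector of means in 1..5 (NA where items were missing).
#' @export
score_perceived_impact <- function(items) {
  m <- as_item_matrix(items, 9L, "perceived impact")
  check_item_range(m, 1L, 5L, "perceived impact")
  flag_missing(rowMeans(m), m)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_T^2)} for `k` items, where
#' \eqn{s_i^2} are item variances and \eqn{s_T^2} the variance of the total
#' score (sample variances, denominator n-1).
#'
#' @param item_matrix numeric matrix or data frame, respondents x items,
#'   no missing entries.
#' @return alpha (scalar, at most 1; can be negative).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (anyNA(m)) stop("cronbach_alpha: item matrix contains missing entries")
  k <- ncol(m)
  if (k < 2L) stop("cronbach_alpha: need at least 2 items")
  if (nrow(m) < 3L) stop("cronbach_alpha: need at least 3 respondents")
  tot_var <- stats::var(rowSums(m))
  if (tot_var <= .Machine$double.eps) {
    stop("cronbach_alpha: total-score variance is zero; alpha undefined")
  }
  k / (k - 1) * (1 - sum(apply(m, 2L, stats::var)) / tot_var)
}

# ---- internal helpers -------------------------------------------------------

as_item_matrix <- function(items, k, what) {
  m <- if (is.null(dim(items))) matrix(as.numeric(items), nrow = 1L)
       else as.matrix(items)
  if (ncol(m) != k) {
    stop(what, " responses must have exactly ", k, " items, got ", ncol(m))
  }
  storage.mode(m) <- "double"
  m
}

check_item_range <- function(m, lo, hi, what) {
  v <- m[!is.na(m)]
  if (any(v < lo | v > hi | v != round(v))) {
    stop(what, " item values must be integers in ", lo, "..", hi)
  }
  invisible(m)
}

# NA out rows with any missing item and attach which rows (and why)
flag_missing <- function(scores, m) {
  miss <- apply(m, 1L, anyNA)
  if (any(miss)) {
    scores[miss] <- NA
    attr(scores, "missing_reason") <-
      sprintf("row %d: %d missing item(s)", which(miss),
              rowSums(is.na(m))[miss])
  }
  scores
}
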