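#' Disorders contributing to the pre-pandemic chronicity measure
#'
#' Major depressive disorder, dysthymia, generalised anxiety disorder, panic
#' disorder, social phobia, agoraphobia and obsessive-compulsive disorder.
#' The generator and the chronicity functions use the column prefix `dx_`
#' (current 6-month diagnosis at a wave) and `lifetime_` (ever diagnosed).
#'
#' @export
disorder_names <- function() {
  c("mdd", "dysthymia", "gad", "panic", "social_phobia", "agoraphobia", "ocd")
}

#' Pre-pandemic chronicity of mental health disorders
#'
#' For each participant: across the pre-pandemic diagnostic waves attended
#' from 2006 onwards, a wave counts as a disorder wave when any of the seven
#' disorders was currently (6-month recency) diagnosed. Chronicity is the
#' percentage of attended waves that were disorder waves; the denominator is
#' attended waves, so participants with missed waves still get a defined
#' percentage. Participants with zero attended waves receive a missing
#' profile (NA percentage, NA group).
#'
#' @param diagnosis_waves long data frame, one row per participant x attended
#'   pre-pandemic wave, with columns `participant_id`, `year`, and one
#'   `dx_<disorder>` indicator (0/1 or logical) per disorder in
#'   [disorder_names()]. Waves before 2006 are dropped.
#' @param lifetime data frame with `participant_id` and either a logical
#'   `lifetime_any` column or per-disorder `lifetime_<disorder>` columns
#'   (ORed together). Participants absent from `diagnosis_waves` but present
#'   here get a missing profile row.
#' @return data frame (one row per participant): `participant_id`,
#'   `n_waves_attended`, `n_waves_with_disorder`, `chronicity_pct`,
#'   `lifetime_any`, `group`.
#' @export
compute_chronicity <- function(diagnosis_waves, lifetime) {
  dxcols <- paste0("dx_", disorder_names())
  miss <- setdiff(dxcols, names(diagnosis_waves))
  if (length(miss)) {
    stop("diagnosis_waves is missing indicator columns: ",
         paste(miss, collapse = ", "))
  }
  dw <- diagnosis_waves[diagnosis_waves$year >= 2006, , drop = FALSE]
  dxm <- as.matrix(dw[, dxcols, drop = FALSE])
  storage.mode(dxm) <- "numeric"
  any_dx <- rowSums(dxm) > 0

  if ("lifetime_any" %in% names(lifetime)) {
    lt <- data.frame(participant_id = lifetime$participant_id,
                     lifetime_any = as.logical(lifetime$lifetime_any))
  } else {
    ltcols <- paste0("lifetime_", disorder_names())
    miss <- setdiff(ltcols, names(lifetime))
    if (length(miss)) {
      stop("lifetime table needs lifetime_any or per-disorder columns; missing: ",
           paste(miss, collapse = ", "))
    }
    ltm <- as.matrix(lifetime[, ltcols, drop = FALSE])
    storage.mode(ltm) <- "numeric"
    lt <- data.frame(
      participant_id = lifetime$participant_id,
      lifetime_any = rowSums(ltm) > 0
    )
  }

  ids <- unique(c(dw$participant_id, lt$participant_id))
  att <- table(factor(dw$participant_id, levels = ids))
  ndx <- tapply(any_dx, factor(dw$participant_id, levels = ids), sum)
  ndx[is.na(ndx)] <- 0

  prof <- data.frame(
    participant_id = ids,
    n_waves_attended = as.integer(att),
    n_waves_with_disorder = as.integer(ndx),
    stringsAsFactors = FALSE
  )
  prof$chronicity_pct <- ifelse(prof$n_waves_attended > 0,
                                100 * prof$n_waves_with_disorder / prof$n_waves_attended,
                                NA_real_)
  prof$lifetime_any <- lt$lifetime_any[match(prof$participant_id, lt$participant_id)]
  # a current diagnosis at any wave implies a lifetime diagnosis
  prof$lifetime_any <- prof$lifetime_any | (prof$n_waves_with_disorder > 0)
  prof$lifetime_any[is.na(prof$lifetime_any)] <- prof$n_waves_with_disorder[is.na(prof$lifetime_any)] > 0
  prof$group <- classify_group(prof$chronicity_pct, prof$lifetime_any)
  prof[order(prof$participant_id), , drop = FALSE]
}

#' Four-level chronicity group classification
#'
#' `none`: no lifetime diagnosis (0% chronicity); `remitted`: a lifetime
#' diagnosis but 0% chronicity across pre-pandemic waves; `low_medium`:
#' chronicity in (0, 50]; `high`: chronicity in (50, 100]. The half-open
#' boundaries make non-integer percentages (arising from missed waves)
#' classifiable while agreeing with the printed integer ranges 1--50% and
#' 51--100% when all six waves were attended.
#'
#' @param chronicity_pct numeric vector of percentages in 0..100 (NA allowed).
#' @param lifetime_any logical vector.
#' @return factor with levels `none`, `remitted`, `low_medium`, `high`.
#' @export
classify_group <- function(chronicity_pct, lifetime_any) {
  stopifnot(length(chronicity_pct) == length(lifetime_any))
  bad <- !is.na(chronicity_pct) & chronicity_pct > 0 & !lifetime_any
  if (any(bad)) {
    stop("inconsistent profile: chronicity ", chronicity_pct[bad][1],
         "% > 0 with lifetime_any = FALSE")
  }
  out <- rep(NA_character_, length(chronicity_pct))
  ok <- !is.na(chronicity_pct)
  out[ok & chronicity_pct == 0 & !lifetime_any] <- "none"
  out[ok & chronicity_pct == 0 & lifetime_any] <- "remitted"
  out[ok & chronicity_pct > 0 & chronicity_pct <= 50] <- "low_medium"
  out[ok & chronicity_pct > 50] <- "high"
  factor(out, levels = chronicity_levels())
}

#' @describeIn classify_group the ordered group labels.
#' @export
chronicity_levels <- function() c("none", "remitted", "low_medium", "high")
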