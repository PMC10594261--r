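#' Analytic expected subperiod CAI under a generator configuration
#'
#' Closed-form expectation of the subperiod total score for one chronicity
#' stratum, used by [calibrate_exposure_multiplier()] so that calibration is
#' free of Monte-Carlo noise. For a participant attending `k` of the `W`
#' waves of the subperiod, an item endorsed per wave with probability
#' \eqn{p'} is ever endorsed with probability \eqn{1-(1-p')^k}; the expected
#' dependency-group maximum follows from
#' \eqn{E[\max] = \sum_j (v_j - v_{j-1}) P(\max \ge v_j)} over the group's
#' distinct point values, and the expectation is averaged over the binomial
#' attendance distribution conditional on at least one attended wave (the
#' condition under which a subperiod score exists).
#'
#' @param config a [generator_config()].
#' @param stratum one of [chronicity_levels()].
#' @param scalar global odds scalar (defaults to the config's).
#' @param subperiod subperiod index.
#' @param w weight table.
#' @return expected subperiod total (CAI points).
#' @export
expected_subperiod_cai <- function(config, stratum,
                                   scalar = config$exposure_odds_scalar,
                                   subperiod = 1L,
                                   w = canonical_weight_table()) {
  stopifnot(stratum %in% chronicity_levels())
  mult <- config$chronicity_odds_multipliers[[stratum]] * scalar
  dates <- as.Date(config$pandemic_wave_dates)
  W <- sum(assign_subperiod(dates) == subperiod)
  if (W == 0L) return(0)
  r <- config$wave_response_probability
  spcol <- paste0("sp", subperiod)

  # per-(item, level): per-wave probability of a response worth >= points
  avail <- w[w[[spcol]], , drop = FALSE]
  p_base <- config$item_base_probabilities
  groups <- split(avail, avail$group)

  e_given_k <- function(k) {
    sum(vapply(groups, function(grp) {
      vals <- sort(unique(grp$points[grp$points > 0]))
      if (!length(vals)) return(0)
      prev <- 0
      total <- 0
      for (v in vals) {
        # P(group max >= v) over k waves, items independent
        p_none <- 1
        for (it in unique(grp$item)) {
          rows <- grp[grp$item == it, , drop = FALSE]
          p_endorse <- scale_odds(p_base[[paste0("item_", it)]], mult)
          lev_ge <- rows$level[rows$points >= v]
          if (!length(lev_ge)) next
          # multi-level items: response level drawn iid given endorsement
          p_hit <- if (nrow(rows) > 1L && it == 3L) {
            p_endorse * sum(config$item3_level_probs[min(lev_ge):length(config$item3_level_probs)])
          } else if (nrow(rows) > 1L) {
            stop("analytic expectation supports levels only for item 3")
          } else {
            p_endorse
          }
          p_none <- p_none * (1 - p_hit)^k
        }
        total <- total + (v - prev) * (1 - p_none)
        prev <- v
      }
      total
    }, numeric(1)))
  }

  pk <- stats::dbinom(1:W, W, r)
  sum(pk * vapply(1:W, e_given_k, numeric(1))) / (1 - stats::dbinom(0, W, r))
}

#' Calibrate the global exposure-odds multiplier to target stratum means
#'
#' Finds a single scalar multiplier on all adversity-item odds such that the
#' analytic expected period-1 CAI of each named stratum matches its target.
#' The expected mean is continuous and non-decreasing in the scalar, so each
#' stratum target is solved by monotone bisection; with several targets the
#' scalar minimising the maximum absolute deviation is returned. If that
#' minimum exceeds `tolerance` (e.g. a target above the attainable
#' subperiod-1 maximum), calibration fails with an error.
#'
#' @param config a [generator_config()].
#' @param target_means named numeric vector of period-1 mean CAI targets;
#'   names are chronicity strata.
#' @param tolerance maximum acceptable absolute deviation (CAI points).
#' @param w weight table.
#' @return the config with `exposure_odds_scalar` set; attributes
#'   `"achieved"` (analytic means at the solution) and `"max_deviation"`.
#' @export
calibrate_exposure_multiplier <- function(config, target_means,
                                          tolerance = 0.15,
                                          w = canonical_weight_table()) {
  validate_generator_config(config)
  if (is.null(names(target_means)) ||
      !all(names(target_means) %in% chronicity_levels())) {
    stop("target_means must be named by chronicity strata")
  }
  if (any(!is.finite(target_means)) || any(target_means < 0)) {
    stop("target_means must be finite and non-negative")
  }

  mean_at <- function(s, stratum) {
    expected_subperiod_cai(config, stratum, scalar = s, subperiod = 1L, w = w)
  }

  # attainable supremum: every item with positive probability endorsed a.s.
  sup_of <- function(stratum) mean_at(1e9, stratum)

  roots <- vapply(names(target_means), function(st) {
    tgt <- target_means[[st]]
    if (tgt == 0) return(0)
    if (tgt > sup_of(st) - 1e-9) {
      stop(sprintf(
        "calibration error: target %.3g for stratum '%s' exceeds the attainable subperiod-1 maximum %.3g",
        tgt, st, sup_of(st)))
    }
    hi <- 1
    while (mean_at(hi, st) < tgt) hi <- hi * 2
    stats::uniroot(function(s) mean_at(s, st) - tgt, c(0, hi),
                   tol = 1e-8)$root
  }, numeric(1))

  objective <- function(s) {
    max(abs(vapply(names(target_means),
                   function(st) mean_at(s, st) - target_means[[st]],
                   numeric(1))))
  }
  s_star <- if (length(roots) == 1L || diff(range(roots)) < 1e-10) {
    unname(roots[1])
  } else {
    stats::optimize(objective, range(roots), tol = 1e-8)$minimum
  }
  dev <- objective(s_star)
  if (dev > tolerance) {
    stop(sprintf(
      "calibration error: no single odds scalar reaches all targets within %.3g (best max deviation %.3g)",
      tolerance, dev))
  }
  config$exposure_odds_scalar <- s_star
  attr(config, "achieved") <- vapply(names(target_means),
                                     function(st) mean_at(s_star, st),
                                     numeric(1))
  attr(config, "max_deviation") <- dev
  config
}
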