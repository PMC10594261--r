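#' Derive empirical exposure-type weights from perceived mental health impact
#'
#' Fits one multiple linear regression of the perceived-impact score (mean of
#' its nine items) on the nine exposure-type scores simultaneously and
#' returns the standardized coefficients
#' \eqn{b_t \, \mathrm{sd}(x_t)/\mathrm{sd}(y)} as alternative per-type
#' weights. Signs are retained (negative weights are not floored). The
#' returned vector can be passed to [compute_cai()] as `type_weights`.
#'
#' @param exposure_type_scores data frame or matrix, participants x 9
#'   exposure types (columns named as in [exposure_types()]); typically each
#'   participant's type scores summed over their observed subperiods.
#' @param impact numeric vector of perceived-impact scores, one per
#'   participant (see [score_perceived_impact()]).
#' @return named numeric vector of 9 standardized weights.
#' @export
derive_impact_weights <- function(exposure_type_scores, impact) {
  x <- as.data.frame(exposure_type_scores)[, exposure_types(), drop = FALSE]
  if (nrow(x) != length(impact)) {
    stop("impact must have one score per row of exposure_type_scores")
  }
  ok <- stats::complete.cases(x) & !is.na(impact)
  x <- x[ok, , drop = FALSE]
  impact <- impact[ok]
  if (nrow(x) < 50L) {
    stop("derive_impact_weights: need at least 50 complete participants, have ",
         nrow(x))
  }
  xm <- cbind(1, as.matrix(x))
  qrx <- qr(xm)
  if (qrx$rank < ncol(xm)) {
    aliased <- colnames(xm)[-1][!(seq_len(ncol(xm))[-1] %in% qrx$pivot[seq_len(qrx$rank)])]
    stop("derive_impact_weights: collinear exposure-type scores: ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::lm(impact ~ ., data = cbind(impact = impact, x))
  b <- stats::coef(fit)[-1]
  sds <- apply(as.matrix(x), 2L, stats::sd)
  sy <- stats::sd(impact)
  if (sy <= .Machine$double.eps) {
    stop("derive_impact_weights: perceived-impact score has zero variance")
  }
  w <- b * sds / sy
  names(w) <- exposure_types()
  w
}
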