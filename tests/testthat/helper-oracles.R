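# Independent brute-force oracles and small fixture builders.
# The oracles re-derive scores directly from the weight-table data with plain
# loops, sharing no code path with the package implementations they check.

# One-pass cumulative CAI: enumerate every item of every wave, map responses
# to points, resolve dependency groups by max within a wave, take per-group
# maxima across waves, sum groups per subperiod, and accumulate.
brute_cai <- function(waves, w = canonical_weight_table()) {
  totals <- rep(NA_real_, 3)
  for (p in 1:3) {
    rows_p <- waves[waves$subperiod == p, , drop = FALSE]
    if (!nrow(rows_p)) next
    tot <- 0
    for (g in unique(w$group)) {
      best <- 0
      for (r in seq_len(nrow(rows_p))) {
        for (it in unique(w$item[w$group == g])) {
          resp <- rows_p[[paste0("item_", it)]][r]
          if (!is.na(resp) && resp > 0) {
            best <- max(best, w$points[w$item == it & w$level == resp])
          }
        }
      }
      tot <- tot + best
    }
    totals[p] <- tot
  }
  obs <- which(!is.na(totals))
  cum <- cumsum(ifelse(is.na(totals), 0, totals))
  list(totals = totals, cumulative = cum[obs], periods = obs,
       eligible = length(obs) >= 2)
}

# Random wave records for one participant, respecting availability masks.
random_participant_waves <- function(id, w = canonical_weight_table(),
                                     endorse_p = 0.35) {
  waves <- NULL
  for (p in 1:3) {
    for (k in seq_len(sample(0:3, 1))) {
      row <- data.frame(participant_id = id, subperiod = p)
      for (it in 1:15) {
        rows <- w[w$item == it, , drop = FALSE]
        avail <- rows[[paste0("sp", p)]][1]
        row[[paste0("item_", it)]] <- if (!avail) NA_integer_
          else if (stats::runif(1) < endorse_p) sample(seq_len(nrow(rows)), 1)
          else 0L
      }
      waves <- rbind(waves, row)
    }
  }
  waves
}

# Explicit nine-domain QIDS scorer (independent of score_qids internals).
brute_qids <- function(x) {
  max(x[1], x[2], x[3], x[4]) + x[5] + max(x[6], x[7], x[8], x[9]) +
    x[10] + x[11] + x[12] + x[13] + x[14] + max(x[15], x[16])
}

# Exhaustive per-subperiod maximum over the weight table: every combination
# of item response levels, scored with brute_cai on a single wave.
brute_max_subperiod <- function(p, w = canonical_weight_table()) {
  items <- 1:15
  levels_of <- lapply(items, function(it) {
    rows <- w[w$item == it, , drop = FALSE]
    if (rows[[paste0("sp", p)]][1]) 0:nrow(rows) else NA_integer_
  })
  # independence across groups: enumerate each dependency group exhaustively
  total <- 0
  for (g in unique(w$group)) {
    g_items <- unique(w$item[w$group == g])
    combos <- expand.grid(lapply(g_items, function(it) {
      lv <- levels_of[[it]]
      if (all(is.na(lv))) 0L else lv
    }))
    best <- 0
    for (r in seq_len(nrow(combos))) {
      sc <- 0
      for (j in seq_along(g_items)) {
        resp <- combos[r, j]
        if (resp > 0) {
          sc <- max(sc, w$points[w$item == g_items[j] & w$level == resp])
        }
      }
      best <- max(best, sc)
    }
    total <- total + best
  }
  total
}

# Minimal hand-built cohort for arithmetic checks on build_long_table().
make_mini_cohort <- function() {
  dis <- disorder_names()
  participants <- data.frame(
    participant_id = 1:2, age = c(50, 60), gender = c("female", "male"),
    education = c("high", "low"), partner = c("yes", "no"),
    stringsAsFactors = FALSE
  )
  for (d in dis) participants[[paste0("lifetime_", d)]] <- c(FALSE, TRUE)
  pre <- data.frame(
    participant_id = rep(1:2, each = 2), year = rep(c(2008, 2012), 2)
  )
  for (d in dis) pre[[paste0("dx_", d)]] <- 0L
  pre$dx_mdd <- c(0L, 0L, 1L, 0L)
  pre$qids_total <- c(4, 6, 10, 12)
  pre$bai_total <- c(3, 5, 12, 14)
  pre$lonely_total <- c(1, 1, 3, 3)
  pw <- data.frame(
    participant_id = c(1, 1, 1, 2, 2),
    wave_index = c(1, 2, 6, 1, 10),
    date = as.Date(c("2020-04-15", "2020-05-20", "2020-09-20",
                     "2020-04-15", "2021-01-15")),
    subperiod = c(1, 1, 2, 1, 3)
  )
  for (it in 1:15) pw[[paste0("item_", it)]] <- 0L
  pw$item_3 <- c(NA, NA, 0L, NA, 0L)
  pw$item_7 <- c(NA, NA, 0L, NA, 0L)
  pw$item_15 <- c(NA, NA, 0L, NA, 0L)
  pw$item_11 <- c(0L, 0L, NA, 0L, NA)
  pw$item_4 <- c(1L, 0L, 1L, 0L, 0L)
  pw$qids_total <- c(10, 14, 9, 5, 7)
  pw$bai_total <- c(20, 22, 18, 6, 8)
  pw$lonely_total <- c(2, 4, 3, 1, 2)
  structure(list(participants = participants, prepandemic_waves = pre,
                 pandemic_waves = pw, cai = NULL),
            class = "synthetic_cohort")
}
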