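#' Direct under-5 mortality from complete birth histories
#'
#' Synthetic-cohort life-table estimator of 5q0 for a calendar period:
#' within each age segment the weighted deaths and the weighted risk set
#' of children exposed to the segment during the period are counted, the
#' ratio gives the segment death probability `q_a`, and the period
#' estimate is `1 - prod_a (1 - q_a)` — the probability that a synthetic
#' child experiencing the period's age-specific risks dies before 60
#' months.
#'
#' A child enters segment `a`'s risk set when it reaches the segment's
#' starting age during the period while alive and under observation, and
#' must be observable through the segment (to its death or the segment
#' end); children censored mid-segment are excluded from that segment.
#' The standard error is a leave-one-mother-out jackknife, which
#' respects the within-mother correlation of sibling outcomes.
#'
#' If any age segment has an empty risk set the observation is flagged
#' missing (`estimate = NA`, `missing = TRUE`) rather than raising an
#' error.
#'
#' @param births Birth-record tibble as produced by
#'   [simulate_birth_histories()] (columns `region`, `mother_id`,
#'   `birth_date`, `weight`, `died`, `death_age_months`,
#'   `censor_age_months`).
#' @param region_id Region to estimate (default: all pooled).
#' @param period Two-element numeric `[start, end)` in decimal years.
#' @param age_segments Segment boundaries in months
#'   (see [default_age_segments()]).
#' @return One-row tibble: `region`, `year` (period midpoint), `q5`,
#'   `se`, `n_children`, `n_deaths`, `missing`.
#' @export
#' @examples
#' g <- make_region_graph(2, "line")
#' tr <- simulate_true_coverage(g, 2000:2005,
#'   trend_params = data.frame(floor = 0.08, ceiling = 0.2,
#'                             midpoint = 2002, steepness = -0.3)[c(1, 1), ],
#'   scale_tag = "mortality")
#' bh <- simulate_birth_histories(tr, n_mothers = 400, seed = 2)
#' direct_5q0(bh, region_id = 1, period = c(2000, 2006))
direct_5q0 <- function(births, region_id = NULL, period,
                       age_segments = default_age_segments()) {
  births <- tibble::as_tibble(births)
  assert_df_has(births, c("mother_id", "birth_date", "weight", "died",
                          "death_age_months", "censor_age_months"), "births")
  if (!is.null(region_id)) births <- dplyr::filter(births, .data$region %in% region_id)
  stopifnot(length(period) == 2, period[1] < period[2])

  tab <- segment_counts(births, period, age_segments)
  mid <- mean(period)
  reg <- if (!is.null(region_id) && length(region_id) == 1) region_id else NA
  q5 <- if (nrow(births) == 0) NA_real_ else
    q5_from_counts(tab$D_total, tab$N_total)
  if (is.na(q5)) {
    return(tibble::tibble(region = reg, year = mid, q5 = NA_real_, se = NA_real_,
                          n_children = nrow(births),
                          n_deaths = if (nrow(births)) sum(births$died) else 0L,
                          missing = TRUE))
  }

  # mother-level jackknife: remove each mother's segment contributions
  mothers <- sort(unique(tab$by_mother$mother_id))
  M <- length(mothers)
  se <- NA_real_
  if (M > 1) {
    Dm <- matrix(0, M, length(tab$D_total))
    Nm <- matrix(0, M, length(tab$N_total))
    mi <- match(tab$by_mother$mother_id, mothers)
    for (k in seq_len(nrow(tab$by_mother))) {
      a <- tab$by_mother$segment[k]
      Dm[mi[k], a] <- Dm[mi[k], a] + tab$by_mother$D[k]
      Nm[mi[k], a] <- Nm[mi[k], a] + tab$by_mother$N[k]
    }
    reps <- vapply(seq_len(M), function(m) {
      q5_from_counts(tab$D_total - Dm[m, ], tab$N_total - Nm[m, ])
    }, numeric(1))
    reps <- reps[is.finite(reps)]
    if (length(reps) > 1) {
      se <- sqrt((length(reps) - 1) / length(reps) *
                   sum((reps - mean(reps))^2))
    }
  }
  tibble::tibble(region = reg, year = mid, q5 = q5, se = se,
                 n_children = nrow(births), n_deaths = sum(births$died),
                 missing = FALSE)
}

# Chain segment probabilities into 5q0. A segment with an empty risk set
# makes the estimate unidentifiable (NA) unless the synthetic cohort is
# already extinct by that age, in which case 5q0 = 1 regardless.
q5_from_counts <- function(D, N) {
  surv <- 1
  for (a in seq_along(N)) {
    if (surv <= 0) break
    if (N[a] <= 0) return(NA_real_)
    surv <- surv * (1 - min(D[a] / N[a], 1))
  }
  1 - surv
}

# Weighted deaths D_a and risk sets N_a per age segment for a calendar
# period, plus the per-mother segment contributions used by the jackknife.
segment_counts <- function(births, period, age_segments) {
  n_seg <- length(age_segments) - 1
  D_total <- numeric(n_seg); N_total <- numeric(n_seg)
  by_mother <- list()
  end_age <- ifelse(births$died, births$death_age_months, births$censor_age_months)
  for (a in seq_len(n_seg)) {
    x0 <- age_segments[a]; x1 <- age_segments[a + 1]
    entry_time <- births$birth_date + x0 / 12
    in_period <- entry_time >= period[1] & entry_time < period[2]
    alive_at_entry <- end_age >= x0
    observable <- births$censor_age_months >= x1 |
      (births$died & births$death_age_months < x1)
    at_risk <- in_period & alive_at_entry & observable
    died_in <- at_risk & births$died &
      births$death_age_months >= x0 & births$death_age_months < x1
    D_total[a] <- sum(births$weight[died_in])
    N_total[a] <- sum(births$weight[at_risk])
    if (any(at_risk)) {
      contrib <- tibble::tibble(
        mother_id = births$mother_id[at_risk],
        segment = a,
        D = births$weight[at_risk] * died_in[at_risk],
        N = births$weight[at_risk]
      )
      by_mother[[length(by_mother) + 1]] <- contrib
    }
  }
  bm <- if (length(by_mother) > 0) dplyr::bind_rows(by_mother) else
    tibble::tibble(mother_id = integer(), segment = integer(),
                   D = numeric(), N = numeric())
  bm <- bm |>
    dplyr::group_by(.data$mother_id, .data$segment) |>
    dplyr::summarise(D = sum(.data$D), N = sum(.data$N), .groups = "drop")
  list(D_total = D_total, N_total = N_total, by_mother = bm)
}
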