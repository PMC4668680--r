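# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so failures are reproducible.

# The survey schedule used by recovery experiments: four DHS-style rounds
# and a non-DHS household-survey family interleaved, six survey-years per
# region per indicator, effective n ~ 1000.
recovery_schedule <- function(shift = 0.15, n_eff = 1000) {
  survey_schedule(tibble::tibble(
    source_id = c("DHS", "NHS"),
    is_dhs = c(TRUE, FALSE),
    years = list(c(1995L, 2000L, 2006L, 2011L), c(1992L, 2005L)),
    n_eff = c(n_eff, n_eff),
    shift = c(0, shift)
  ))
}

# A fully-observed three-source mortality schedule (one DHS, two shifted).
mortality_schedule <- function(years) {
  survey_schedule(tibble::tibble(
    source_id = c("DHS", "AIS", "CEN"),
    is_dhs = c(TRUE, FALSE, FALSE),
    years = list(years, years, years),
    n_eff = rep(1000, 3),
    shift = c(0, 0.3, 0.3)
  ))
}

# Small clustered microdata fixture with known truth.
small_microdata <- function(p = 0.6, clusters = 20, per_cluster = 15,
                            icc = 0.1, wdisp = 0.4, seed = 7) {
  g <- make_region_graph(2, "line")
  tp <- data.frame(floor = p - 0.01, ceiling = p + 0.01,
                   midpoint = 2000, steepness = 0)[c(1, 1), ]
  tr <- simulate_true_coverage(g, 1999:2001, tp)
  simulate_microdata(tr, 2000, clusters_per_region = clusters,
                     children_per_cluster = per_cluster, icc = icc,
                     weight_dispersion = wdisp, seed = seed)
}
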