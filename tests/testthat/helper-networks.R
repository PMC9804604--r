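# small networks built in code for the unit tests

make_net <- function(m, plants = NULL, polls = NULL, site = "S1",
                     treatment = "restored", period = "2012-09", ...) {
  m <- as.matrix(m)
  if (is.null(plants)) plants <- sprintf("p%d", seq_len(nrow(m)))
  if (is.null(polls)) polls <- sprintf("a%d", seq_len(ncol(m)))
  interaction_network(m, plant_ids = plants, pollinator_ids = polls,
                      site_id = site, treatment = treatment,
                      period = period, ...)
}

# random connected count matrix (retries until no empty margins)
random_count_matrix <- function(nr, nc, max_count = 6) {
  repeat {
    m <- matrix(rpois(nr * nc, 1.2), nr, nc)
    m[runif(nr * nc) < 0.4] <- 0
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# a small design for fast end-to-end tests
small_design <- function(seed = 1, n_sites_per_treatment = 1,
                         months = c("2012-09", "2012-10", "2012-11",
                                    "2012-12", "2013-01", "2013-02",
                                    "2013-03", "2013-04"), ...) {
  synthetic_design(n_sites_per_treatment = n_sites_per_treatment,
                   months = months,
                   n_plants = c(5, 7), n_pollinators = c(8, 10),
                   connectance = 0.45, plant_season_decline = 0.8,
                   seed = seed, ...)
}
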