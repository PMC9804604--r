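#' Design of a synthetic restoration study
#'
#' Describes the data-generating context the package emulates: eight
#' inselberg sites split equally between a restored treatment (invasive
#' plants removed before the season) and an unrestored control, sampled
#' monthly over one September-April flowering season (64 monthly networks,
#' poolable to 16 seasonal ones). Interaction frequencies are right-skewed;
#' unrestored sites additionally contain one dominant invasive generalist
#' plant whose long flowering season makes it the main late-season resource.
#'
#' @param n_sites_per_treatment Sites per treatment (default 4).
#' @param months Month labels (`"YYYY-MM"`), default September 2012 to
#'   April 2013.
#' @param n_plants,n_pollinators Integer ranges (length 2) for per-network
#'   native richness in each guild.
#' @param connectance Target fraction of realised plant-pollinator links.
#' @param nestedness_strength Exponent of the rank-abundance skew used to
#'   build the topology; larger values give more skewed degrees and higher
#'   NODF.
#' @param module_count Number of blocks overlaid on the topology to induce
#'   modularity (0 = none).
#' @param invasive_generalism Fraction of the pollinators present in a month
#'   that the invasive plant links to, at full flowering intensity.
#' @param invasive_weight_share Fraction of a network's total visits routed
#'   through the invasive plant, at full flowering intensity.
#' @param invasive_phenology Relative flowering intensity of the invasive
#'   plant in the early months (September-December); late months are at
#'   full intensity 1.
#' @param invasive_monopoly At full intensity, the probability that a
#'   pollinator visiting the invasive plant abandons each of its links to
#'   native plants (competition for pollination).
#' @param restoration_release Relative increase in native link density at
#'   restored sites: removing the invasive releases native plants from
#'   competition for pollination, raising their visitation rates.
#' @param plant_season_decline Multiplier on native plant richness in the
#'   late months, emulating late-season floral resource scarcity.
#' @param late_season_turnover Fraction of the native community resampled
#'   between the early and late season.
#' @param count_dispersion Negative-binomial size parameter of the per-link
#'   visit counts; smaller values give more skew.
#' @param mean_count Mean extra visits per realised link (counts are
#'   1 + negative binomial).
#' @param vertebrate_fraction Fraction of pollinators tagged as vertebrates
#'   (default 0; used to exercise the guild filter).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the design.
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(n_sites_per_treatment = 4,
                             months = c(sprintf("2012-%02d", 9:12),
                                        sprintf("2013-%02d", 1:4)),
                             n_plants = c(10, 16),
                             n_pollinators = c(22, 32),
                             connectance = 0.25,
                             nestedness_strength = 1,
                             module_count = 0,
                             invasive_generalism = 0.85,
                             invasive_weight_share = 0.45,
                             invasive_phenology = 0.25,
                             invasive_monopoly = 0.75,
                             restoration_release = 0,
                             plant_season_decline = 0.4,
                             late_season_turnover = 0.3,
                             count_dispersion = 0.7,
                             mean_count = 4,
                             vertebrate_fraction = 0,
                             seed = 1L) {
  design <- as.list(environment())
  fr <- c("connectance", "invasive_generalism", "invasive_weight_share",
          "invasive_phenology", "invasive_monopoly", "restoration_release",
          "plant_season_decline", "late_season_turnover",
          "vertebrate_fraction")
  for (nm in fr) {
    if (design[[nm]] < 0 || design[[nm]] > 1) {
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  stopifnot(min(n_plants) >= 2, min(n_pollinators) >= 2,
            n_sites_per_treatment >= 1, length(months) >= 1)
  class(design) <- "synthetic_design"
  design
}

# per-site uniforms deciding which native links an invasive-visiting
# pollinator abandons; drawn once per site so the decision is shared by
# every month (phenology only moves the threshold)
monopoly_uniforms <- function(design, site, pool_p, pool_a) {
  state <- .Random.seed
  on.exit(assign(".Random.seed", state, envir = globalenv()))
  set.seed(derive_seed(design$seed, paste0(site, ":monopoly"), 1L))
  matrix(stats::runif(pool_p * pool_a), pool_p, pool_a)
}

# per-site vertebrate flags over the pollinator pool, constant across months
taxon_flags <- function(design, site, pool_a) {
  if (design$vertebrate_fraction <= 0) return(rep(FALSE, pool_a))
  state <- .Random.seed
  on.exit(assign(".Random.seed", state, envir = globalenv()))
  set.seed(derive_seed(design$seed, paste0(site, ":taxa"), 1L))
  stats::runif(pool_a) < design$vertebrate_fraction
}

# heavy-tailed rank-abundance weights (Zipf-like), normalised to mean 1
rank_weights <- function(n, s) {
  w <- seq_len(n)^(-s)
  w / mean(w)
}

#' Generate one synthetic monthly network
#'
#' Builds a binary topology by linking plant-pollinator pairs with
#' probability proportional to the product of heavy-tailed species
#' abundance weights (calibrated to the target connectance; the skew of the
#' weights, `nestedness_strength`, controls NODF), optionally overlaid with
#' block structure for modularity, then draws visit counts from a shifted
#' negative binomial on the realised links. In unrestored sites an invasive
#' generalist plant is added, linked to a phenology-scaled fraction of the
#' pollinators and carrying a phenology-scaled share of the total visits;
#' pollinators that visit it abandon some of their native links.
#'
#' @param design A [synthetic_design()].
#' @param site Site label.
#' @param treatment `"restored"` or `"unrestored"`.
#' @param month `"YYYY-MM"` month label.
#' @param seed Integer seed; defaults to a deterministic function of the
#'   design seed, site and month.
#' @return An `interaction_network`.
#' @export
generate_site_network <- function(design, site, treatment, month,
                                  seed = NULL) {
  stopifnot(inherits(design, "synthetic_design"))
  if (is.null(seed)) {
    seed <- derive_seed(design$seed, paste(site, treatment, month), 1L)
  }
  set.seed(seed)
  mn <- month_num(month)
  late <- mn %in% 1:4
  phen <- if (late) 1 else design$invasive_phenology

  # site species pools (deterministic per site, shared across months)
  pool_p <- 2 * max(design$n_plants)
  pool_a <- 2 * max(design$n_pollinators)
  plant_pool <- sprintf("%s_P%02d", site, seq_len(pool_p))
  poll_pool <- sprintf("%s_A%02d", site, seq_len(pool_a))
  w_pool_p <- rank_weights(pool_p, design$nestedness_strength)
  w_pool_a <- rank_weights(pool_a, design$nestedness_strength)

  # month richness: native plants decline late in the season
  n_p <- sample(design$n_plants[1]:design$n_plants[2], 1)
  if (late) n_p <- max(2, round(n_p * design$plant_season_decline))
  n_a <- sample(design$n_pollinators[1]:design$n_pollinators[2], 1)

  # abundant species are present more often; late-season turnover resamples
  # part of the community from the lower ranks of the pool
  pick <- function(pool, w, n) {
    idx <- sample(seq_along(pool), n, prob = w)
    if (late && design$late_season_turnover > 0) {
      swap <- which(stats::runif(n) < design$late_season_turnover)
      if (length(swap) > 0) {
        repl <- sample(setdiff(seq_along(pool), idx), length(swap))
        idx[swap] <- repl
      }
    }
    sort(idx)
  }
  ip <- pick(plant_pool, w_pool_p, n_p)
  ia <- pick(poll_pool, w_pool_a, n_a)
  plants <- plant_pool[ip]
  polls <- poll_pool[ia]
  w_p <- w_pool_p[ip]
  w_a <- w_pool_a[ia]

  # link probabilities: weight products scaled to the target connectance
  pw <- outer(w_p, w_a)
  if (design$module_count > 0) {
    bp <- (ip %% design$module_count) + 1
    ba <- (ia %% design$module_count) + 1
    same <- outer(bp, ba, "==")
    pw <- pw * ifelse(same, 3, 1 / 3)
  }
  target_links <- design$connectance * n_p * n_a
  # competition release: invasive removal raises native visitation rates,
  # so restored sites realise a denser native network
  if (treatment == "restored") {
    target_links <- target_links * (1 + design$restoration_release)
  }
  if (target_links < max(n_p, n_a)) {
    stop("target connectance too low to link every species", call. = FALSE)
  }
  prob <- pmin(1, pw * target_links / sum(pw))
  m <- matrix(as.integer(stats::runif(n_p * n_a) < prob), n_p, n_a)
  # guarantee every species at least one link (to its best partner)
  for (i in which(rowSums(m) == 0)) m[i, which.max(w_a)] <- 1L
  for (j in which(colSums(m) == 0)) m[which.max(w_p), j] <- 1L

  # visit counts: shifted negative binomial, skewed by abundance products
  mu <- design$mean_count * pw / mean(pw)
  counts <- matrix(0L, n_p, n_a, dimnames = list(plants, polls))
  on <- m == 1
  counts[on] <- 1L + rnbinom(sum(on), size = design$count_dispersion,
                             mu = mu[on])

  meta_extra <- NULL
  if (treatment == "unrestored") {
    inv_id <- paste0(site, "_INV")
    n_inv_links <- max(1, round(phen * design$invasive_generalism * n_a))
    inv_targets <- order(w_a, decreasing = TRUE)[seq_len(n_inv_links)]
    # pollinators drawn to the invasive abandon native links, dropping
    # minor (low-abundance) native resources first while keeping the major
    # ones — optimal foraging under a mass-flowering alternative. The
    # abandonment is a persistent behavioural shift: the same
    # (plant, pollinator) pair is dropped in every month of the season.
    p_drop <- design$invasive_monopoly * phen *
      (1 - w_p / max(c(w_p, 1e-12)))
    u_site <- monopoly_uniforms(design, site, pool_p, pool_a)
    for (j in inv_targets) {
      drop <- which(counts[, j] > 0 & u_site[ip, ia[j]] < p_drop)
      counts[drop, j] <- 0L
    }
    # orphaned natives fall back to scarce pollinators: the abundant
    # generalists are the ones that defected to the invasive
    scarce <- which(w_a <= stats::median(w_a))
    for (i in which(rowSums(counts) == 0)) {
      counts[i, sample(scarce, 1)] <- 1L
    }
    share <- phen * design$invasive_weight_share
    native_total <- sum(counts)
    inv_total <- round(share / (1 - share) * native_total)
    inv_counts <- integer(n_a)
    if (inv_total > 0) {
      alloc <- inv_total * w_a[inv_targets] / sum(w_a[inv_targets])
      inv_counts[inv_targets] <- pmax(1L, round(alloc))
    } else {
      inv_counts[inv_targets] <- 1L
    }
    counts <- rbind(counts, inv_counts)
    rownames(counts) <- c(plants, inv_id)
    plants <- c(plants, inv_id)
    meta_extra <- tibble::tibble(
      species_id = inv_id, guild = "plant",
      taxon_group = "invasive_plant", is_vertebrate = FALSE,
      is_invasive = TRUE)
  }

  # taxonomy is a property of the site pool, constant across months
  vert_pool <- taxon_flags(design, site, pool_a)
  vert <- vert_pool[ia]
  meta <- dplyr::bind_rows(
    tibble::tibble(species_id = setdiff(plants, paste0(site, "_INV")),
                   guild = "plant", taxon_group = "Angiospermae",
                   is_vertebrate = FALSE, is_invasive = FALSE),
    meta_extra,
    tibble::tibble(species_id = polls, guild = "pollinator",
                   taxon_group = ifelse(vert, "Gekkonidae", "Insecta"),
                   is_vertebrate = vert, is_invasive = FALSE))

  # drop species that ended up with no interactions
  keep_p <- rowSums(counts) > 0
  keep_a <- colSums(counts) > 0
  interaction_network(counts[keep_p, keep_a, drop = FALSE],
                      site_id = site, treatment = treatment, period = month,
                      species_meta = meta[meta$species_id %in%
                                            c(plants[keep_p], polls[keep_a]), ])
}

#' Generate a full synthetic month-level dataset
#'
#' Produces one network per site and month under the study design: with the
#' defaults, 8 sites (4 restored, 4 unrestored) by 8 months = 64 networks.
#' Deterministic for a given design (including its seed).
#'
#' @param design A [synthetic_design()].
#' @return A month-level `study_dataset`.
#' @export
generate_dataset <- function(design = synthetic_design()) {
  stopifnot(inherits(design, "synthetic_design"))
  sites <- c(sprintf("R%d", seq_len(design$n_sites_per_treatment)),
             sprintf("U%d", seq_len(design$n_sites_per_treatment)))
  treatments <- rep(c("restored", "unrestored"),
                    each = design$n_sites_per_treatment)
  nets <- list()
  for (k in seq_along(sites)) {
    for (month in design$months) {
      nets[[length(nets) + 1]] <-
        generate_site_network(design, sites[k], treatments[k], month)
    }
  }
  study_dataset(nets, level = "month")
}
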