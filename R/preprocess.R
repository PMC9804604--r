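#' Restrict the pollinator guild to invertebrates
#'
#' Vertebrate flower visitors (birds, geckos, skinks) differ from insects by
#' an order of magnitude in longevity and are not obligately dependent on
#' floral resources, so the dynamic model's assumptions do not apply to
#' them. This filter drops vertebrate pollinator columns and any plants left
#' without interactions; the order of the remaining species is preserved.
#'
#' @param net An `interaction_network`.
#' @param exclude_vertebrates If `FALSE` the network is returned unchanged.
#' @return A filtered `interaction_network`.
#' @export
filter_guild <- function(net, exclude_vertebrates = TRUE) {
  validate_network(net)
  if (!exclude_vertebrates) return(net)
  meta <- net$species_meta
  pm <- meta[match(net$pollinator_ids, meta$species_id), ]
  if (anyNA(pm$species_id) || anyNA(pm$is_vertebrate)) {
    stop("missing taxon metadata for pollinators; cannot filter vertebrates",
         call. = FALSE)
  }
  keep_a <- !pm$is_vertebrate
  if (!any(keep_a)) {
    stop("no invertebrate pollinators remain after filtering", call. = FALSE)
  }
  m <- net$counts[, keep_a, drop = FALSE]
  keep_p <- rowSums(m) > 0
  if (!any(keep_p)) {
    stop("no plants with interactions remain after filtering", call. = FALSE)
  }
  m <- m[keep_p, , drop = FALSE]
  subset_network(net, net$plant_ids[keep_p], net$pollinator_ids[keep_a])
}

subset_network <- function(net, plants, pollinators) {
  interaction_network(
    net$counts[plants, pollinators, drop = FALSE],
    plant_ids = plants, pollinator_ids = pollinators,
    site_id = net$site_id, treatment = net$treatment, period = net$period,
    species_meta = net$species_meta[
      net$species_meta$species_id %in% c(plants, pollinators), ]
  )
}

#' Restrict a network to its largest connected component
#'
#' Compartmentalised networks are reduced to the connected component with
#' the most species before any metric or dynamic analysis, so that structure
#' and persistence describe a single interacting community. Ties on species
#' count are broken by larger total interaction count, then by the
#' lexicographically smallest species identifier.
#'
#' @param net An `interaction_network`.
#' @return The induced sub-network; identical to `net` when already
#'   connected. Idempotent.
#' @export
largest_component <- function(net) {
  validate_network(net)
  g <- as_igraph(net)
  comp <- igraph::components(g)
  if (comp$no == 1) return(net)
  names_all <- igraph::V(g)$name
  scores <- lapply(seq_len(comp$no), function(k) {
    members <- names_all[comp$membership == k]
    sub_p <- intersect(net$plant_ids, members)
    sub_a <- intersect(net$pollinator_ids, members)
    list(members = members,
         n = length(members),
         total = sum(net$counts[sub_p, sub_a, drop = FALSE]),
         min_id = min(members))
  })
  ord <- order(-vapply(scores, `[[`, numeric(1), "n"),
               -vapply(scores, `[[`, numeric(1), "total"),
               vapply(scores, `[[`, character(1), "min_id"))
  keep <- scores[[ord[1]]]$members
  subset_network(net,
                 net$plant_ids[net$plant_ids %in% keep],
                 net$pollinator_ids[net$pollinator_ids %in% keep])
}

#' Standard preprocessing: guild filter then largest component
#'
#' The fixed preprocessing order applied throughout the package before
#' computing metrics or running dynamics.
#'
#' @param net An `interaction_network`.
#' @param exclude_vertebrates Passed to [filter_guild()].
#' @return A preprocessed `interaction_network`.
#' @export
preprocess_network <- function(net, exclude_vertebrates = TRUE) {
  net |>
    filter_guild(exclude_vertebrates = exclude_vertebrates) |>
    largest_component()
}

month_num <- function(period) {
  if (!all(grepl("^\\d{4}-\\d{2}$", period))) {
    stop("month labels must be 'YYYY-MM', got: ",
         paste(period, collapse = ", "), call. = FALSE)
  }
  as.integer(substr(period, 6, 7))
}

#' Pool monthly networks into early- and late-season networks
#'
#' Monthly networks from one site are aggregated by element-wise summation
#' of counts on the union of their species: early season is September to
#' December, late season January to April. Species that interact in no
#' pooled month are excluded from that season's network.
#'
#' @param nets List of monthly `interaction_network` objects from a single
#'   site (period labels `"YYYY-MM"` spanning September-April).
#' @return A named list with elements `early` and `late`.
#' @export
pool_season <- function(nets) {
  stopifnot(length(nets) > 0)
  sites <- unique(vapply(nets, `[[`, character(1), "site_id"))
  treats <- unique(vapply(nets, `[[`, character(1), "treatment"))
  if (length(sites) > 1 || length(treats) > 1) {
    stop("pool_season expects networks from a single site and treatment",
         call. = FALSE)
  }
  months <- vapply(nets, `[[`, character(1), "period")
  mn <- month_num(months)
  if (any(!mn %in% c(9:12, 1:4))) {
    stop("months outside the September-April flowering season: ",
         paste(months[!mn %in% c(9:12, 1:4)], collapse = ", "), call. = FALSE)
  }
  season <- ifelse(mn >= 9, "early", "late")
  if (length(unique(mn[season == "early"])) < 4 ||
      length(unique(mn[season == "late"])) < 4) {
    warning("missing months for site ", sites,
            "; pooling the networks that exist", call. = FALSE)
  }
  pool_one <- function(members, label) {
    if (length(members) == 0) {
      stop("no networks to pool for ", label, " season", call. = FALSE)
    }
    plants <- unique(unlist(lapply(members, `[[`, "plant_ids")))
    polls <- unique(unlist(lapply(members, `[[`, "pollinator_ids")))
    m <- matrix(0, length(plants), length(polls),
                dimnames = list(plants, polls))
    for (net in members) {
      m[net$plant_ids, net$pollinator_ids] <-
        m[net$plant_ids, net$pollinator_ids] + net$counts
    }
    keep_p <- rowSums(m) > 0
    keep_a <- colSums(m) > 0
    meta <- dplyr::distinct(
      dplyr::bind_rows(lapply(members, `[[`, "species_meta")))
    interaction_network(m[keep_p, keep_a, drop = FALSE],
                        site_id = sites, treatment = treats, period = label,
                        species_meta = meta)
  }
  list(early = pool_one(nets[season == "early"], "early"),
       late = pool_one(nets[season == "late"], "late"))
}

#' Pool a whole monthly dataset to the season level
#'
#' @param dataset A month-level `study_dataset`.
#' @return A season-level `study_dataset` with two networks per site.
#' @export
pool_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (dataset$level != "month") {
    stop("pool_dataset expects a month-level dataset", call. = FALSE)
  }
  sites <- vapply(dataset$networks, `[[`, character(1), "site_id")
  pooled <- unlist(lapply(split(dataset$networks, sites), pool_season),
                   recursive = FALSE)
  study_dataset(unname(pooled), level = "season")
}

# bipartite network as an undirected igraph with count weights
as_igraph <- function(net) {
  edges <- tidy(net)
  g <- igraph::graph_from_data_frame(
    edges[, c("plant", "pollinator", "count")],
    directed = FALSE,
    vertices = data.frame(name = c(net$plant_ids, net$pollinator_ids)))
  igraph::E(g)$weight <- edges$count
  g
}
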