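#' Run the full persistence study over a dataset
#'
#' For each network: preprocess (guild filter, then largest component),
#' compute network structure (NODF, spin-glass modularity) and species
#' centrality (weighted closeness, specialisation d'), run the replicate
#' persistence simulations, and join everything into tidy analysis tables.
#' Networks that fail are logged and excluded, never fatal for the rest of
#' the run.
#'
#' @param dataset A `study_dataset`.
#' @param cfg A [dynamics_config()]; its seed drives all randomness.
#' @param exclude_vertebrates Drop vertebrate pollinators before analysis.
#' @param compute_metrics Set `FALSE` to skip structure/centrality metrics
#'   (persistence only).
#' @return A `persistence_study` object with `networks` (one row per
#'   network: structure metrics, sizes, mean persistence per guild),
#'   `species` (one row per surviving species: persistence, centrality),
#'   and `exclusions` (tibble of failed networks, possibly empty).
#' @export
run_study <- function(dataset, cfg = dynamics_config(),
                      exclude_vertebrates = TRUE, compute_metrics = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"))
  net_rows <- list()
  sp_rows <- list()
  excl <- list()
  for (net in dataset$networks) {
    id <- network_id(net)
    res <- tryCatch({
      pre <- preprocess_network(net, exclude_vertebrates = exclude_vertebrates)
      pers <- run_persistence(pre, cfg)
      size <- glance(pre)
      if (compute_metrics) {
        struct <- find_modules(pre, seed = derive_seed(cfg$seed, id, 0L))
        spm <- species_metrics(pre)
        nrow_tbl <- dplyr::bind_cols(
          pers$network,
          tibble::tibble(nodf = struct$nodf,
                         modularity_q = struct$modularity_q,
                         n_modules = struct$n_modules),
          size[, c("n_plants", "n_pollinators", "n_species",
                   "n_links", "total_count", "connectance")])
        srow <- dplyr::left_join(pers$species, spm,
                                 by = c("species_id", "guild"))
      } else {
        nrow_tbl <- dplyr::bind_cols(
          pers$network,
          size[, c("n_plants", "n_pollinators", "n_species",
                   "n_links", "total_count", "connectance")])
        srow <- pers$species
      }
      list(network = nrow_tbl, species = srow)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1]] <-
        tibble::tibble(network_id = id, reason = conditionMessage(res))
      next
    }
    net_rows[[length(net_rows) + 1]] <- res$network
    sp_rows[[length(sp_rows) + 1]] <- res$species
  }
  if (length(net_rows) == 0) stop("every network failed", call. = FALSE)
  structure(list(
    networks = dplyr::bind_rows(net_rows),
    species = dplyr::bind_rows(sp_rows),
    exclusions = if (length(excl)) dplyr::bind_rows(excl) else
      tibble::tibble(network_id = character(), reason = character()),
    cfg = cfg,
    level = dataset$level
  ), class = "persistence_study")
}

#' @export
print.persistence_study <- function(x, ...) {
  cat(sprintf("<persistence_study> %d networks (%s level), %d species rows, %d excluded\n",
              nrow(x$networks), x$level, nrow(x$species), nrow(x$exclusions)))
  invisible(x)
}

#' @export
tidy.persistence_study <- function(x, ...) x$species

#' @export
glance.persistence_study <- function(x, ...) x$networks

#' Descriptive persistence and structure contrasts
#'
#' Per-group mean, SD and n of plant and pollinator persistence, and of the
#' structure metrics when present — the descriptive companion to the
#' treatment/season comparisons.
#'
#' @param study A `persistence_study` (or its `networks` tibble).
#' @param group_by Character vector of grouping columns, a subset of
#'   `c("treatment", "period", "site")`.
#' @return A tibble with one row per group.
#' @export
summarize_contrast <- function(study, group_by = c("treatment", "period")) {
  tbl <- if (inherits(study, "persistence_study")) study$networks else
    tibble::as_tibble(study)
  if (!all(group_by %in% names(tbl))) {
    stop("unknown grouping key(s): ",
         paste(setdiff(group_by, names(tbl)), collapse = ", "), call. = FALSE)
  }
  num_cols <- intersect(
    c("persistence_plants", "persistence_pollinators", "persistence_all",
      "nodf", "modularity_q"), names(tbl))
  tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(num_cols),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~sd(.x, na.rm = TRUE))),
      .groups = "drop")
}

#' Export analysis-ready model tables
#'
#' Writes the network-level and species-level CSVs consumed by downstream
#' beta-error mixed models: the species table gains a per-network
#' max-scaled closeness column (`weighted_closeness_scaled`, maximum 1
#' within each network) and the network table a squared species-richness
#' covariate (`n_species_sq`).
#'
#' @param study A `persistence_study`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the two file paths.
#' @export
export_model_table <- function(study, dir, prefix = "pollinet") {
  stopifnot(inherits(study, "persistence_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  net_tbl <- study$networks |>
    dplyr::mutate(n_species_sq = .data$n_species^2)
  sp_tbl <- study$species
  if ("weighted_closeness" %in% names(sp_tbl)) {
    sp_tbl <- sp_tbl |>
      dplyr::group_by(.data$network_id) |>
      dplyr::mutate(weighted_closeness_scaled =
                      .data$weighted_closeness /
                      max(.data$weighted_closeness)) |>
      dplyr::ungroup()
  }
  net_path <- file.path(dir, paste0(prefix, "_networks.csv"))
  sp_path <- file.path(dir, paste0(prefix, "_species.csv"))
  readr::write_csv(net_tbl, net_path)
  readr::write_csv(sp_tbl, sp_path)
  invisible(c(networks = net_path, species = sp_path))
}

#' Plot a persistence study
#'
#' `type = "persistence"` draws the treatment-by-period box plots of mean
#' plant and pollinator persistence; `type = "structure"` plots persistence
#' against NODF and modularity; `type = "centrality"` plots species
#' persistence against max-scaled weighted closeness.
#'
#' @param object A `persistence_study`.
#' @param type One of `"persistence"`, `"structure"`, `"centrality"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.persistence_study <- function(object,
                                       type = c("persistence", "structure",
                                                "centrality"), ...) {
  type <- match.arg(type)
  if (type == "persistence") {
    long <- object$networks |>
      tidyr::pivot_longer(c("persistence_plants", "persistence_pollinators"),
                          names_to = "guild", values_to = "persistence") |>
      dplyr::mutate(guild = ifelse(.data$guild == "persistence_plants",
                                   "plants", "pollinators"))
    ggplot2::ggplot(long, ggplot2::aes(x = .data$period,
                                       y = .data$persistence,
                                       fill = .data$treatment)) +
      ggplot2::geom_boxplot() +
      ggplot2::facet_wrap(~guild) +
      ggplot2::labs(x = NULL, y = "mean persistence") +
      ggplot2::theme_minimal()
  } else if (type == "structure") {
    long <- object$networks |>
      tidyr::pivot_longer(c("nodf", "modularity_q"),
                          names_to = "metric", values_to = "value")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                       y = .data$persistence_pollinators,
                                       colour = .data$treatment)) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
      ggplot2::facet_wrap(~metric, scales = "free_x") +
      ggplot2::labs(y = "mean pollinator persistence") +
      ggplot2::theme_minimal()
  } else {
    sp <- object$species |>
      dplyr::group_by(.data$network_id) |>
      dplyr::mutate(closeness_scaled = .data$weighted_closeness /
                      max(.data$weighted_closeness)) |>
      dplyr::ungroup()
    ggplot2::ggplot(sp, ggplot2::aes(x = .data$closeness_scaled,
                                     y = .data$persistence,
                                     colour = .data$treatment)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_smooth(method = "glm", formula = y ~ x,
                           method.args = list(family = "quasibinomial")) +
      ggplot2::facet_wrap(~guild) +
      ggplot2::labs(x = "weighted closeness (scaled)",
                    y = "species persistence") +
      ggplot2::theme_minimal()
  }
}
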