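#' Construct a bipartite interaction network
#'
#' The central data structure of the package: a weighted bipartite network
#' recording the number of visits observed between each plant and each
#' pollinator at one site in one sampling period, together with the species
#' metadata needed for guild filtering.
#'
#' @param counts Non-negative integer matrix, plants in rows and pollinators
#'   in columns. Dimnames, if present, must agree with `plant_ids` /
#'   `pollinator_ids`.
#' @param plant_ids,pollinator_ids Character vectors of unique species
#'   identifiers. Default to the dimnames of `counts`.
#' @param site_id Site label.
#' @param treatment `"restored"` (invasive plants removed) or `"unrestored"`.
#' @param period Sampling period: a month label (`"YYYY-MM"`) or a season
#'   label (`"early"`, `"late"`).
#' @param species_meta Optional tibble with columns `species_id`, `guild`
#'   (`"plant"`/`"pollinator"`), `taxon_group`, `is_vertebrate`. Generated
#'   from the guilds (all invertebrate) when omitted.
#'
#' @return An object of class `interaction_network`.
#' @export
#' @examples
#' m <- matrix(c(3, 1, 0, 2), 2, 2,
#'             dimnames = list(c("p1", "p2"), c("a1", "a2")))
#' net <- interaction_network(m, site_id = "S1", treatment = "restored",
#'                            period = "2012-09")
#' net
interaction_network <- function(counts,
                                plant_ids = rownames(counts),
                                pollinator_ids = colnames(counts),
                                site_id = NA_character_,
                                treatment = NA_character_,
                                period = NA_character_,
                                species_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(plant_ids)) plant_ids <- paste0("plant_", seq_len(nrow(counts)))
  if (is.null(pollinator_ids)) pollinator_ids <- paste0("poll_", seq_len(ncol(counts)))
  plant_ids <- as.character(plant_ids)
  pollinator_ids <- as.character(pollinator_ids)
  dimnames(counts) <- list(plant_ids, pollinator_ids)
  if (is.null(species_meta)) {
    species_meta <- default_species_meta(plant_ids, pollinator_ids)
  }
  net <- structure(
    list(
      plant_ids = plant_ids,
      pollinator_ids = pollinator_ids,
      counts = counts,
      site_id = as.character(site_id),
      treatment = as.character(treatment),
      period = as.character(period),
      species_meta = tibble::as_tibble(species_meta)
    ),
    class = "interaction_network"
  )
  validate_network(net)
  net
}

default_species_meta <- function(plant_ids, pollinator_ids) {
  tibble::tibble(
    species_id = c(plant_ids, pollinator_ids),
    guild = c(rep("plant", length(plant_ids)),
              rep("pollinator", length(pollinator_ids))),
    taxon_group = NA_character_,
    is_vertebrate = FALSE
  )
}

#' Validate an interaction network
#'
#' Checks the structural invariants: non-negative integral counts, unique
#' identifiers consistent with the matrix dimensions, and a valid treatment
#' label. Invisibly returns the network so it can be used in pipes.
#'
#' @param net An `interaction_network`.
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  counts <- net$counts
  if (!is.numeric(counts)) {
    stop("interaction counts must be numeric", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("interaction counts must be non-negative and non-missing", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("interaction counts must be integral (visit counts)", call. = FALSE)
  }
  if (nrow(counts) != length(net$plant_ids) ||
      ncol(counts) != length(net$pollinator_ids)) {
    stop("counts dimensions do not match id lists", call. = FALSE)
  }
  ids <- c(net$plant_ids, net$pollinator_ids)
  if (anyDuplicated(ids)) {
    stop("duplicated species identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (!is.na(net$treatment) &&
      !net$treatment %in% c("restored", "unrestored")) {
    stop("treatment must be 'restored' or 'unrestored'", call. = FALSE)
  }
  invisible(net)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "<interaction_network> %d plants x %d pollinators, %d links, %d visits\n",
    length(x$plant_ids), length(x$pollinator_ids),
    sum(x$counts > 0), sum(x$counts)))
  cat(sprintf("  site: %s | treatment: %s | period: %s\n",
              x$site_id, x$treatment, x$period))
  invisible(x)
}

#' Tidy an interaction network into an edge-list tibble
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return A tibble with one row per realised link: `plant`, `pollinator`,
#'   `count`, plus the network metadata columns.
#' @export
tidy.interaction_network <- function(x, ...) {
  idx <- which(x$counts > 0, arr.ind = TRUE)
  tibble::tibble(
    site = x$site_id,
    treatment = x$treatment,
    period = x$period,
    plant = x$plant_ids[idx[, 1]],
    pollinator = x$pollinator_ids[idx[, 2]],
    count = x$counts[idx]
  ) |>
    dplyr::arrange(.data$plant, .data$pollinator)
}

#' @rdname tidy.interaction_network
#' @return For `glance()`: a one-row tibble of network-level summaries.
#' @export
glance.interaction_network <- function(x, ...) {
  tibble::tibble(
    site = x$site_id,
    treatment = x$treatment,
    period = x$period,
    n_plants = length(x$plant_ids),
    n_pollinators = length(x$pollinator_ids),
    n_species = length(x$plant_ids) + length(x$pollinator_ids),
    n_links = sum(x$counts > 0),
    total_count = sum(x$counts),
    connectance = sum(x$counts > 0) /
      (length(x$plant_ids) * length(x$pollinator_ids))
  )
}

#' Read an interaction network from disk
#'
#' Two CSV dialects are supported. `matrix_csv` stores the full count matrix
#' with plant identifiers in the first column and pollinator identifiers as
#' the header row. `edge_list_csv` stores one realised link per row with
#' columns `plant`, `pollinator`, `count`; pairs absent from the file have
#' count 0.
#'
#' @param path Path to the CSV file.
#' @param format `"matrix_csv"` or `"edge_list_csv"`.
#' @param ... Network metadata (`site_id`, `treatment`, `period`,
#'   `species_meta`) passed on to [interaction_network()].
#' @return An `interaction_network`.
#' @export
read_network <- function(path, format = c("matrix_csv", "edge_list_csv"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "matrix_csv") {
    df <- suppressMessages(
      readr::read_csv(path, show_col_types = FALSE, name_repair = "minimal"))
    df <- as.data.frame(df, check.names = FALSE)
    plant_ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric counts in ", path, call. = FALSE)
    rownames(m) <- plant_ids
    interaction_network(m, ...)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            plant = readr::col_character(),
                            pollinator = readr::col_character(),
                            count = readr::col_double()))
    if (!all(c("plant", "pollinator", "count") %in% names(df))) {
      stop("edge list must have columns plant, pollinator, count", call. = FALSE)
    }
    if (anyNA(df$count) || any(df$count < 0)) {
      stop("negative or non-numeric counts in ", path, call. = FALSE)
    }
    plants <- unique(df$plant)
    polls <- unique(df$pollinator)
    m <- matrix(0, length(plants), length(polls),
                dimnames = list(plants, polls))
    m[cbind(df$plant, df$pollinator)] <- df$count
    interaction_network(m, ...)
  }
}

#' Write an interaction network to disk
#'
#' Inverse of [read_network()]; a written network reads back identically.
#'
#' @param net An `interaction_network`.
#' @param path Output CSV path.
#' @param format `"matrix_csv"` or `"edge_list_csv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("matrix_csv", "edge_list_csv")) {
  format <- match.arg(format)
  if (format == "matrix_csv") {
    df <- data.frame(net$plant_ids, net$counts, check.names = FALSE)
    names(df) <- c("", net$pollinator_ids)
    readr::write_csv(df, path)
  } else {
    readr::write_csv(tidy(net)[, c("plant", "pollinator", "count")], path)
  }
  invisible(path)
}

#' Read a study dataset from a manifest file
#'
#' The manifest (YAML or JSON by file extension) lists one entry per network
#' with fields `path`, `site`, `treatment`, `month`, and optionally `format`
#' (default `"matrix_csv"`). Paths are resolved relative to the manifest's
#' directory. An optional top-level `species_meta` field names a CSV with
#' columns `species_id`, `guild`, `taxon_group`, `is_vertebrate` applied to
#' every network.
#'
#' @param path Path to the manifest file (`.yaml`/`.yml` or `.json`).
#' @return A month-level `study_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  manifest <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  entries <- if (!is.null(manifest$networks)) manifest$networks else manifest
  base <- dirname(path)
  meta <- NULL
  if (!is.null(manifest$species_meta)) {
    meta <- readr::read_csv(file.path(base, manifest$species_meta),
                            show_col_types = FALSE)
  }
  nets <- lapply(entries, function(e) {
    stopifnot(!is.null(e$path), !is.null(e$site), !is.null(e$treatment),
              !is.null(e$month))
    read_network(file.path(base, e$path),
                 format = if (is.null(e$format)) "matrix_csv" else e$format,
                 site_id = e$site, treatment = e$treatment,
                 period = e$month,
                 species_meta = meta)
  })
  study_dataset(nets, level = "month")
}

#' Bundle networks into a study dataset
#'
#' A `study_dataset` is a list of networks observed at one temporal level
#' (monthly or pooled seasonal), the unit the simulation pipeline consumes.
#'
#' @param networks List of `interaction_network` objects.
#' @param level `"month"` or `"season"`.
#' @return A `study_dataset`.
#' @export
study_dataset <- function(networks, level = c("month", "season")) {
  level <- match.arg(level)
  stopifnot(length(networks) > 0,
            all(vapply(networks, inherits, logical(1), "interaction_network")))
  # treatment must be consistent within a site
  meta <- purrr::map_dfr(networks, glance)
  bad <- meta |>
    dplyr::distinct(.data$site, .data$treatment) |>
    dplyr::count(.data$site) |>
    dplyr::filter(.data$n > 1)
  if (nrow(bad) > 0) {
    stop("inconsistent treatment within site(s): ",
         paste(bad$site, collapse = ", "), call. = FALSE)
  }
  structure(list(networks = networks, level = level), class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d networks at %s level\n",
              length(x$networks), x$level))
  invisible(x)
}

#' @export
glance.study_dataset <- function(x, ...) {
  purrr::imap_dfr(x$networks, function(net, i) {
    dplyr::bind_cols(tibble::tibble(network_id = network_id(net)), glance(net))
  })
}

#' Canonical network identifier (site x period)
#' @param net An `interaction_network`.
#' @return A single string.
#' @export
network_id <- function(net) {
  paste(net$site_id, net$period, sep = ":")
}
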