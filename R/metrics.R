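#' NODF nestedness of a bipartite network
#'
#' Nestedness by overlap and decreasing fill on the presence/absence matrix:
#' for every ordered pair of rows (and of columns) where the first has
#' strictly larger fill, the paired term is the share of the sparser
#' species' partners also used by the more generalist species; pairs with
#' equal fill contribute 0. NODF is 100 times the mean paired term over all
#' row pairs and column pairs. Computed via `vegan::nestednodf()` on the
#' binary incidence matrix.
#'
#' @param net An `interaction_network` with at least 2 plants and 2
#'   pollinators and no all-zero row or column.
#' @return NODF in \[0, 100\].
#' @export
nodf <- function(net) {
  m <- (net$counts > 0) * 1
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("NODF needs at least a 2 x 2 matrix", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("all-zero row/column; preprocess the network first", call. = FALSE)
  }
  unname(vegan::nestednodf(m)$statistic["NODF"])
}

#' Weighted Newman-Girvan modularity of a given partition
#'
#' Evaluates Q for the bipartite network viewed as a unipartite weighted
#' graph with the visit counts as edge weights:
#' `Q = (1/2m) * sum_ij (w_ij - k_i k_j / 2m) delta(c_i, c_j)`.
#'
#' @param net An `interaction_network`.
#' @param partition Named vector or list mapping every species id to a
#'   module label.
#' @return The modularity Q (at most 1).
#' @export
modularity_q <- function(net, partition) {
  g <- as_igraph(net)
  ids <- igraph::V(g)$name
  partition <- unlist(partition)
  if (!all(ids %in% names(partition))) {
    stop("partition must cover every species in the network", call. = FALSE)
  }
  if (!all(names(partition) %in% ids)) {
    stop("partition labels unknown species: ",
         paste(setdiff(names(partition), ids), collapse = ", "), call. = FALSE)
  }
  memb <- as.integer(factor(partition[ids]))
  igraph::modularity(g, memb, weights = igraph::E(g)$weight)
}

#' Detect modules by spin-glass simulated annealing
#'
#' Maximises the spin-glass community objective (at resolution 1, where it
#' coincides with weighted Newman-Girvan modularity) by simulated annealing,
#' via `igraph::cluster_spinglass()`. Disconnected networks are handled by
#' annealing each connected component separately and merging the module
#' labels, so each component contributes its own modules.
#'
#' @param net An `interaction_network`.
#' @param seed Integer seed; the same seed always returns the same
#'   partition.
#' @param spins Maximum number of modules per component.
#' @param n_restarts Independent annealing restarts per component; the
#'   partition with the highest Q is kept. Restarts guard against the
#'   annealer freezing in a local optimum on small graphs.
#' @return A `structure_metrics` list: `nodf`, `modularity_q`, `partition`
#'   (named integer vector over all species), `n_modules`.
#' @export
find_modules <- function(net, seed = 1L, spins = 25, n_restarts = 10) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  labels <- integer(igraph::vcount(g))
  names(labels) <- igraph::V(g)$name
  m_total <- sum(igraph::E(g)$weight)
  offset <- 0L
  for (k in seq_len(comp$no)) {
    vk <- which(comp$membership == k)
    if (length(vk) == 1) {
      labels[vk] <- offset + 1L
      offset <- offset + 1L
      next
    }
    sub <- igraph::induced_subgraph(g, vk)
    # global Q scales the component's null model by its weight share, so
    # each component is optimised at the matching resolution
    res_k <- sum(igraph::E(sub)$weight) / m_total
    if (igraph::vcount(sub) <= 4) {
      # annealing is degenerate on tiny components; solve them exactly
      memb <- exhaustive_modules(sub, resolution = res_k)
    } else {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        set.seed(derive_seed(seed, paste0("spinglass:", k), r))
        cl <- igraph::cluster_spinglass(
          sub, weights = igraph::E(sub)$weight,
          spins = min(spins, igraph::vcount(sub)),
          update.rule = "config", gamma = res_k)
        q <- igraph::modularity(sub, igraph::membership(cl),
                                weights = igraph::E(sub)$weight,
                                resolution = res_k)
        if (is.null(best) || q > best$q) best <- list(q = q, cl = cl)
      }
      memb <- igraph::membership(best$cl)
    }
    labels[names(memb)] <- offset + as.integer(factor(as.integer(memb)))
    offset <- max(labels)
  }
  structure(list(
    nodf = tryCatch(nodf(net), error = function(e) NA_real_),
    modularity_q = modularity_q(net, labels),
    partition = labels,
    n_modules = length(unique(labels))
  ), class = "structure_metrics")
}

# exact modularity optimum over all set partitions of a tiny graph,
# enumerated as restricted growth strings
exhaustive_modules <- function(g, resolution = 1) {
  n <- igraph::vcount(g)
  w <- igraph::E(g)$weight
  a <- rep(1L, n)
  best_q <- -Inf
  best <- a
  repeat {
    q <- igraph::modularity(g, a, weights = w, resolution = resolution)
    if (q > best_q) { best_q <- q; best <- a }
    i <- n
    while (i > 1) {
      if (a[i] <= max(a[seq_len(i - 1)])) break
      i <- i - 1
    }
    if (i == 1) break
    a[i] <- a[i] + 1L
    if (i < n) a[(i + 1):n] <- 1L
  }
  stats::setNames(best, igraph::V(g)$name)
}

#' @export
print.structure_metrics <- function(x, ...) {
  cat(sprintf("<structure_metrics> NODF %.2f | Q %.3f in %d modules\n",
              x$nodf, x$modularity_q, x$n_modules))
  invisible(x)
}

#' Weighted closeness centrality of every species
#'
#' Shortest-path closeness on the bipartite graph with edge length
#' `1/count`, so stronger interactions are shorter:
#' `C(i) = (n - 1) / sum_j dist(i, j)` over the `n` species of i's
#' connected component. Species isolated in their own component get 0.
#' Values are returned unscaled; the analysis pipeline rescales them to a
#' per-network maximum of 1 before model export.
#'
#' @param net An `interaction_network`.
#' @return A tibble: `species_id`, `guild`, `weighted_closeness`.
#' @export
weighted_closeness <- function(net) {
  g <- as_igraph(net)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  comp <- igraph::components(g)
  cl <- vapply(seq_len(nrow(d)), function(i) {
    same <- comp$membership == comp$membership[i]
    n <- sum(same)
    if (n < 2) return(0)
    (n - 1) / sum(d[i, same & seq_along(same) != i])
  }, numeric(1))
  tibble::tibble(
    species_id = igraph::V(g)$name,
    guild = ifelse(igraph::V(g)$name %in% net$plant_ids,
                   "plant", "pollinator"),
    weighted_closeness = cl
  )
}

# Kullback-Leibler specialisation d for one margin of the count matrix;
# rows of `m` are the focal species, columns their potential partners.
dprime_margin <- function(m) {
  a_i <- rowSums(m)
  a_j <- colSums(m)
  total <- sum(m)
  if (any(a_i == 0)) stop("species with zero interaction total", call. = FALSE)
  q <- a_j / total
  vapply(seq_len(nrow(m)), function(i) {
    p <- m[i, ] / a_i[i]
    pos <- p > 0
    d <- sum(p[pos] * log(p[pos] / q[pos]))
    d_max <- log(total / a_i[i])
    d_min <- dmin_greedy(a_i[i], q)
    if (d_max - d_min < .Machine$double.eps) return(0)
    min(1, max(0, (d - d_min) / (d_max - d_min)))
  }, numeric(1))
}

# Most generalised achievable integer allocation of n events across
# partners proportional to availability q (largest-remainder rounding),
# and its KL divergence from q.
dmin_greedy <- function(n, q) {
  ideal <- n * q
  alloc <- floor(ideal)
  rem <- n - sum(alloc)
  if (rem > 0) {
    frac <- ideal - alloc
    take <- order(frac, decreasing = TRUE)[seq_len(rem)]
    alloc[take] <- alloc[take] + 1
  }
  p <- alloc / n
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Standardised specialisation d' of every species
#'
#' Kullback-Leibler divergence between a species' observed partner-use
#' distribution and partner availability (marginal totals of the count
#' matrix), standardised to \[0, 1\] between the most generalised
#' achievable integer allocation (d_min, largest-remainder allocation
#' proportional to availability) and the theoretical maximum
#' `d_max = ln(m / A_i)`. 0 means partner use exactly proportional to
#' availability; 1 means maximal specialisation on rare partners.
#'
#' @param net An `interaction_network` with positive total count.
#' @return A tibble: `species_id`, `guild`, `d_prime`.
#' @export
specialisation_dprime <- function(net) {
  if (sum(net$counts) == 0) stop("empty count matrix", call. = FALSE)
  tibble::tibble(
    species_id = c(net$plant_ids, net$pollinator_ids),
    guild = c(rep("plant", length(net$plant_ids)),
              rep("pollinator", length(net$pollinator_ids))),
    d_prime = c(dprime_margin(net$counts), dprime_margin(t(net$counts)))
  )
}

#' All species-level metrics of a network
#'
#' @param net An `interaction_network`.
#' @return A tibble joining [weighted_closeness()] and
#'   [specialisation_dprime()] on `species_id`.
#' @export
species_metrics <- function(net) {
  dplyr::left_join(weighted_closeness(net), specialisation_dprime(net),
                   by = c("species_id", "guild"))
}
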