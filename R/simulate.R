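#' Simulate a birth-death phylogeny
#'
#' Thin, seed-controlled wrapper around [ape::rphylo()] producing a rooted
#' bifurcating tree with positive branch lengths — a stand-in species pool
#' for gradient community simulations.
#'
#' @param n_species Number of tips (default 200).
#' @param birth,death Speciation and extinction rates (default 1 and 0,
#'   i.e. a Yule tree).
#' @param seed Optional integer seed; identical seeds give identical trees.
#' @param tip_prefix Tip label prefix (labels are `sp001`, `sp002`, ...).
#' @return A rooted [ape::phylo].
#' @export
sim_tree <- function(n_species = 200, birth = 1, death = 0, seed = NULL,
                     tip_prefix = "sp") {
  if (n_species < 2L) abort("need at least 2 species", class = "phylograd_domain_error")
  if (birth <= 0 || death < 0) abort("rates must be positive", class = "phylograd_domain_error")
  gen <- function() ape::rphylo(n_species, birth = birth, death = death, fossils = FALSE)
  tree <- if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
  tree$tip.label <- sprintf("%s%03d", tip_prefix, seq_len(n_species))
  validate_phylogeny(tree)
}

# Default per-site richness: unimodal in site order, peaking mid-gradient
# (the canonical montane pattern), scaled to the pool size.
default_richness <- function(n_species, n_sites) {
  pos <- seq(0, 1, length.out = n_sites)
  shape <- 0.5 - 0.9 * (pos - 0.4)^2 # peak ~40% up the gradient
  pmax(2L, round(shape * n_species))
}

#' Simulate gradient community matrices with known assembly structure
#'
#' Generates a binary sites x species matrix over ordered elevational sites
#' under one of five assembly regimes:
#' \describe{
#'   \item{random}{each site draws its richness uniformly from the pool —
#'     the null-model calibration case.}
#'   \item{filtered}{sites at or above `filter_elevation` draw a fraction
#'     `filter_strength` of their members from one designated clade
#'     (environmental filtering; produces phylogenetic clustering).}
#'   \item{overdispersed}{greedy max-min phylogenetic distance selection
#'     (limiting-similarity caricature).}
#'   \item{nested-attrition}{each site is a random subset of the site below
#'     it — pure nestedness, no turnover.}
#'   \item{range-turnover}{each species occupies a contiguous window of
#'     sites centred on a random elevation midpoint — pure range turnover.}
#' }
#' Species never recorded anywhere are dropped from the returned matrix (the
#' pool in `tree` is unaffected and remains the null-model reference).
#'
#' @param tree Species pool phylogeny ([ape::phylo]).
#' @param elevations Site elevations in metres (default eight sites, 200 to
#'   3700 m in 500 m steps).
#' @param mode Assembly regime (see above).
#' @param richness Per-site richness targets; default unimodal with a
#'   mid-gradient peak (for `nested-attrition` made non-increasing).
#' @param filter_strength Fraction of a filtered community drawn from the
#'   designated clade (default 0.8).
#' @param filter_elevation Sites at or above this elevation are filtered
#'   (default 2200 m).
#' @param filter_clade Tip labels of the filtering clade; by default the
#'   smallest clade containing at least 10% of the pool.
#' @param range_breadth_sites Mean range breadth (in number of sites) for
#'   `range-turnover` mode (default 3).
#' @param seed Optional integer seed.
#' @return A community tibble (`site`, `elevation`, species 0/1 columns).
#' @export
sim_communities <- function(tree,
                            elevations = seq(200, 3700, by = 500),
                            mode = c("random", "filtered", "overdispersed",
                                     "nested-attrition", "range-turnover"),
                            richness = NULL,
                            filter_strength = 0.8,
                            filter_elevation = 2200,
                            filter_clade = NULL,
                            range_breadth_sites = 3,
                            seed = NULL) {
  mode <- match.arg(mode)
  validate_phylogeny(tree)
  pool <- tree$tip.label
  n_pool <- length(pool)
  n_sites <- length(elevations)
  if (is.null(richness)) {
    richness <- default_richness(n_pool, n_sites)
    if (mode == "nested-attrition") richness <- rev(sort(richness))
  }
  if (length(richness) != n_sites) {
    abort("`richness` must have one value per site", class = "phylograd_validation_error")
  }
  if (any(richness > n_pool) || any(richness < 1)) {
    abort("infeasible richness targets", class = "phylograd_domain_error")
  }
  if (mode == "nested-attrition" && is.unsorted(rev(richness))) {
    abort("nested-attrition requires non-increasing richness",
      class = "phylograd_domain_error")
  }
  if (filter_strength < 0 || filter_strength > 1) {
    abort("`filter_strength` must be in [0, 1]", class = "phylograd_domain_error")
  }

  gen <- function() {
    X <- matrix(0, n_sites, n_pool, dimnames = list(NULL, pool))
    if (mode == "random") {
      for (s in seq_len(n_sites)) X[s, sample(n_pool, richness[s])] <- 1
    } else if (mode == "filtered") {
      clade <- filter_clade %||% pick_clade(tree, min_frac = 0.1)
      out_clade <- setdiff(pool, clade)
      for (s in seq_len(n_sites)) {
        k <- richness[s]
        if (elevations[s] >= filter_elevation) {
          k_in <- min(round(filter_strength * k), length(clade))
          chosen <- c(sample(clade, k_in),
            if (k - k_in > 0) sample(out_clade, k - k_in))
        } else {
          chosen <- sample(pool, k)
        }
        X[s, chosen] <- 1
      }
    } else if (mode == "overdispersed") {
      d <- cophenetic_distances(tree)
      for (s in seq_len(n_sites)) {
        k <- richness[s]
        start <- which(d == max(d), arr.ind = TRUE)[1L, ]
        sel <- as.integer(start)
        while (length(sel) < k) {
          cand <- setdiff(seq_len(n_pool), sel)
          mind <- apply(d[cand, sel, drop = FALSE], 1L, min)
          sel <- c(sel, cand[which.max(mind)])
        }
        X[s, sel[seq_len(k)]] <- 1
      }
    } else if (mode == "nested-attrition") {
      current <- sample(pool, richness[1L])
      X[1L, current] <- 1
      for (s in seq_len(n_sites)[-1L]) {
        current <- sample(current, richness[s])
        X[s, current] <- 1
      }
    } else if (mode == "range-turnover") {
      idx <- seq_len(n_sites)
      for (j in seq_len(n_pool)) {
        breadth <- max(1L, stats::rpois(1L, range_breadth_sites - 1L) + 1L)
        mid <- sample(idx, 1L)
        lo <- max(1L, mid - (breadth - 1L) %/% 2L)
        hi <- min(n_sites, lo + breadth - 1L)
        X[lo:hi, j] <- 1
      }
    }
    X
  }
  X <- if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()

  present <- colSums(X) > 0
  X <- X[, present, drop = FALSE]
  comm <- dplyr::bind_cols(
    tibble::tibble(
      site = sprintf("S%04d", as.integer(elevations)),
      elevation = as.numeric(elevations)
    ),
    tibble::as_tibble(as.data.frame(X, check.names = FALSE))
  )
  validate_community(comm)
}

# Smallest clade holding at least `min_frac` of the tips: the designated
# "filter-tolerant" lineage for filtered assembly.
pick_clade <- function(tree, min_frac = 0.1) {
  inc <- edge_tip_incidence(tree)
  sizes <- rowSums(inc)
  target <- ceiling(min_frac * length(tree$tip.label))
  ok <- which(sizes >= target)
  e <- ok[which.min(sizes[ok])]
  tree$tip.label[inc[e, ] > 0]
}

#' Simulate site-level environmental predictors
#'
#' Temperature declines linearly with elevation from `temp_lowland` at
#' `base_elevation` at `lapse_rate` degrees C per 100 m (defaults 27.4 C at
#' 200 m and 0.54 C/100 m, typical of wet-tropical mountains); plant
#' richness is unimodal with a mid-gradient peak; predator abundance
#' declines monotonically. Both raw and z-scored columns are returned.
#'
#' @param elevations Site elevations in metres.
#' @param temp_lowland Lowland mean annual temperature, degrees C.
#' @param lapse_rate Temperature lapse rate, degrees C per 100 m.
#' @param base_elevation Elevation (m) at which `temp_lowland` applies.
#' @param temp_noise_sd Gaussian noise sd added to temperature (default 0).
#' @param plant_peak_elevation Elevation of the plant-richness maximum (m).
#' @param plant_max Plant richness at the peak.
#' @param predator_range Predator-abundance index at the lowest and highest
#'   site (linear in elevation between them).
#' @param seed Optional integer seed (used only when noise is requested).
#' @return A tibble: `site`, `elevation`, raw `temperature`,
#'   `plant_richness`, `predator_abundance`, and `*_z` columns.
#' @export
sim_predictors <- function(elevations = seq(200, 3700, by = 500),
                           temp_lowland = 27.4, lapse_rate = 0.54,
                           base_elevation = 200, temp_noise_sd = 0,
                           plant_peak_elevation = 1500, plant_max = 120,
                           predator_range = c(10, 1), seed = NULL) {
  gen <- function() {
    temp <- temp_lowland - lapse_rate * (elevations - base_elevation) / 100
    if (temp_noise_sd > 0) temp <- temp + stats::rnorm(length(elevations), 0, temp_noise_sd)
    span <- max(elevations) - min(elevations)
    plant <- plant_max * (1 - ((elevations - plant_peak_elevation) / span)^2)
    plant <- pmax(round(plant), 1)
    # exponential decay between the endpoint abundances: monotone but not
    # collinear with the linear temperature profile
    pred <- predator_range[1L] *
      (predator_range[2L] / predator_range[1L])^((elevations - min(elevations)) / span)
    tibble::tibble(
      site = sprintf("S%04d", as.integer(elevations)),
      elevation = as.numeric(elevations),
      temperature = temp,
      plant_richness = as.numeric(plant),
      predator_abundance = pred,
      temperature_z = zscore(temp),
      plant_richness_z = zscore(plant),
      predator_abundance_z = zscore(pred)
    )
  }
  if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
}

#' Simulate a full gradient dataset (tree, communities, predictors)
#'
#' Bundles [sim_tree()], [sim_communities()] and [sim_predictors()] under a
#' single seed, recording every generating parameter for recovery tests.
#'
#' @param n_species Pool size (default 200).
#' @param elevations Site elevations in metres.
#' @param mode Assembly regime (see [sim_communities()]).
#' @param seed Integer seed (mandatory: the bundle must be reproducible).
#' @param ... Further arguments passed to [sim_communities()] and
#'   [sim_predictors()] (matched by name).
#' @return A list of class `phylograd_sim`: `tree`, `community`,
#'   `predictors`, `truth` (the generating parameters).
#' @export
sim_gradient <- function(n_species = 200,
                         elevations = seq(200, 3700, by = 500),
                         mode = "random", seed, ...) {
  if (missing(seed)) abort("`seed` is mandatory", class = "phylograd_validation_error")
  dots <- list(...)
  comm_args <- dots[names(dots) %in% names(formals(sim_communities))]
  pred_args <- dots[names(dots) %in% names(formals(sim_predictors))]
  tree <- sim_tree(n_species, seed = seed)
  comm <- do.call(sim_communities, c(
    list(tree = tree, elevations = elevations, mode = mode, seed = seed + 1L),
    comm_args
  ))
  preds <- do.call(sim_predictors, c(
    list(elevations = elevations, seed = seed + 2L), pred_args
  ))
  out <- list(
    tree = tree,
    community = comm,
    predictors = preds,
    truth = c(list(n_species = n_species, elevations = elevations,
      mode = mode, seed = seed), comm_args, pred_args)
  )
  class(out) <- "phylograd_sim"
  out
}
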