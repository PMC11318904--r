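#' Run the full gradient community-phylogenetics pipeline
#'
#' Orchestrates the complete analysis: (optional) single-gap interpolation
#' of the occurrence matrix, alpha standardized effect sizes (NRI, NTI,
#' SES.PD) under the taxon-shuffling null, species and phylogenetic beta
#' diversity with turnover/nestedness decomposition, COMDIST clustering of
#' sites, AICc model ranking of each index on the site predictors, and a
#' Mantel test between the species and phylogenetic dissimilarity matrices.
#'
#' @param config A named list, or the path of a YAML/JSON file holding one,
#'   with elements:
#'   \describe{
#'     \item{tree, matrix, predictors}{input file paths (Newick/NEXUS tree,
#'       occurrence CSV, predictor CSV), or}
#'     \item{simulate}{a list of arguments for [sim_gradient()];}
#'     \item{seed}{integer, mandatory;}
#'     \item{iterations}{null iterations (default 999);}
#'     \item{include_root}{default `TRUE`;}
#'     \item{interpolation}{`"single"` (default), `"any-flanked"`, `"off"`;}
#'     \item{linkage}{dendrogram linkage, default `"average"`;}
#'     \item{out_dir}{optional output directory.}
#'   }
#' @param out_dir Output directory (overrides `config$out_dir`); when `NULL`
#'   nothing is written.
#' @return Invisibly, a list with `alpha` (the SES table), `ranking`
#'   (bound model rankings for all three indices), `beta` (pairwise
#'   decompositions), `beta_matrices`, `comdist`, `dendrogram` (hclust),
#'   `mantel`, and `settings`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) {
    abort("config must specify a seed", class = "phylograd_validation_error")
  }
  settings <- list(
    seed = as.integer(config$seed),
    iterations = config$iterations %||% 999,
    include_root = config$include_root %||% TRUE,
    interpolation = config$interpolation %||% "single",
    linkage = config$linkage %||% "average"
  )
  out_dir <- out_dir %||% config$out_dir

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) unlink(file.path(out_dir, PIPELINE_FILES), force = TRUE)
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
        class = "phylograd_pipeline_error")
    })
  }

  inputs <- stage("load", {
    if (!is.null(config$simulate)) {
      sim <- do.call(sim_gradient, c(config$simulate,
        if (is.null(config$simulate$seed)) list(seed = settings$seed)))
      list(tree = sim$tree, comm = sim$community, preds = sim$predictors)
    } else {
      preds <- if (!is.null(config$predictors)) {
        tibble::as_tibble(read.csv(config$predictors, check.names = FALSE))
      }
      list(
        tree = read_phylogeny(config$tree),
        comm = read_community(config$matrix),
        preds = preds
      )
    }
  })

  comm <- stage("interpolate",
    interpolate_single_gaps(inputs$comm, mode = settings$interpolation))

  alpha <- stage("alpha", ses_indices(comm, inputs$tree,
    n_iter = settings$iterations, seed = settings$seed,
    include_root = settings$include_root))

  beta <- stage("beta", beta_pairs(comm, inputs$tree,
    include_root = settings$include_root))
  bmat <- stage("beta", beta_matrices(comm, inputs$tree,
    include_root = settings$include_root))
  cd <- stage("comdist", comdist_matrix(comm, inputs$tree))
  hc <- stage("cluster", cluster_communities(cd, linkage = settings$linkage))

  mantel <- stage("mantel", mantel_test(bmat$species_sor, bmat$phylo_sor,
    n_perm = settings$iterations, seed = settings$seed))

  ranking <- NULL
  if (!is.null(inputs$preds)) {
    ranking <- stage("regress", {
      zcols <- grep("_z$", names(inputs$preds), value = TRUE)
      dat <- dplyr::inner_join(
        tibble::as_tibble(alpha)[, c("site", "nri", "nti", "ses_pd")],
        inputs$preds, by = "site")
      dplyr::bind_rows(lapply(c("nri", "nti", "ses_pd"), function(resp) {
        rank_models(dat, resp, zcols)
      }))
    })
  }

  result <- list(
    alpha = alpha, ranking = ranking, beta = beta, beta_matrices = bmat,
    comdist = cd, dendrogram = hc, mantel = mantel, settings = settings
  )

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write.csv(as.data.frame(tibble::as_tibble(alpha)),
        file.path(out_dir, "alpha_table.csv"), row.names = FALSE)
      if (!is.null(ranking)) {
        rk <- as.data.frame(tibble::as_tibble(ranking))
        rk$predictors <- NULL
        write.csv(rk, file.path(out_dir, "model_ranking.csv"), row.names = FALSE)
      }
      write.csv(as.data.frame(beta), file.path(out_dir, "beta_pairs.csv"),
        row.names = FALSE)
      for (nm in names(bmat)) {
        write.csv(bmat[[nm]], file.path(out_dir, paste0("beta_", nm, ".csv")))
      }
      write.csv(cd, file.path(out_dir, "comdist.csv"))
      dendrogram_newick(hc, file.path(out_dir, "dendrogram.nwk"))
      log <- c(settings,
        list(run_time = format(Sys.time(), tz = "UTC"),
          package_version = as.character(utils::packageVersion("phylograd")),
          mantel_r = mantel$r, mantel_p = mantel$p_value))
      jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
        auto_unbox = TRUE, pretty = TRUE)
    })
  }
  invisible(result)
}

PIPELINE_FILES <- c(
  "alpha_table.csv", "model_ranking.csv", "beta_pairs.csv",
  "beta_species_sor.csv", "beta_species_sim.csv", "beta_species_sne.csv",
  "beta_phylo_sor.csv", "beta_phylo_sim.csv", "beta_phylo_sne.csv",
  "comdist.csv", "dendrogram.nwk", "run_log.json"
)

#' Per-site phylogenetic indices and predictors for the Mt. Wilhelm gradient
#'
#' The study system's site table: eight rainforest sites on a complete
#' tropical elevational gradient (200-3700 m a.s.l., 500 m steps), with the
#' published NRI, NTI and SES.PD values of their geometrid moth communities
#' and the z-scored site predictors (woody plant species richness, a
#' combined insectivore predator-abundance index, and mean annual
#' temperature).
#'
#' @return A tibble with columns `site`, `elevation`, `nri`, `nti`,
#'   `ses_pd`, `plant_richness_z`, `predator_abundance_z`, `temperature_z`.
#' @examples
#' sites <- mt_wilhelm_sites()
#' rank_models(sites, "nri", c("plant_richness_z", "predator_abundance_z",
#'                             "temperature_z"))
#' @export
mt_wilhelm_sites <- function() {
  path <- system.file("extdata", "mt_wilhelm_sites.csv", package = "phylograd",
    mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
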