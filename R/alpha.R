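#' Mean pairwise phylogenetic distance of a taxon set
#'
#' Unweighted mean of the cophenetic distance over all unordered pairs of
#' taxa in the set.
#'
#' @param taxa Character vector of tip labels.
#' @param dist Cophenetic distance matrix (see [cophenetic_distances()]).
#' @return A single number, or `NA` (with a warning) when fewer than two
#'   taxa are supplied.
#' @export
mpd_community <- function(taxa, dist) {
  idx <- match_taxa(taxa, dist)
  if (length(idx) < 2L) {
    warn("MPD undefined for fewer than 2 taxa; returning NA")
    return(NA_real_)
  }
  m <- dist[idx, idx]
  sum(m) / (length(idx) * (length(idx) - 1L))
}

#' Mean nearest-taxon distance of a taxon set
#'
#' Mean over the taxa of the distance to the closest other taxon in the set.
#'
#' @inheritParams mpd_community
#' @return A single number, or `NA` (with a warning) for fewer than two taxa.
#' @export
mntd_community <- function(taxa, dist) {
  idx <- match_taxa(taxa, dist)
  if (length(idx) < 2L) {
    warn("MNTD undefined for fewer than 2 taxa; returning NA")
    return(NA_real_)
  }
  m <- dist[idx, idx]
  diag(m) <- Inf
  mean(apply(m, 1L, min))
}

match_taxa <- function(taxa, dist) {
  taxa <- unique(as.character(taxa))
  idx <- match(taxa, colnames(dist))
  if (anyNA(idx)) {
    abort(
      paste0("taxa not in distance matrix: ",
        paste(taxa[is.na(idx)], collapse = ", ")),
      class = "phylograd_lookup_error"
    )
  }
  idx
}

# Align a community tibble to the full tree pool: binary sites x n_tips
# matrix in tree tip order. The null model shuffles labels over the whole
# pool present in the tree, not just the species observed in the matrix.
align_to_tree <- function(comm, tree) {
  X <- community_matrix(comm)
  missing <- setdiff(colnames(X), tree$tip.label)
  if (length(missing)) {
    abort(
      paste0("species absent from tree: ", paste(missing, collapse = ", ")),
      class = "phylograd_lookup_error"
    )
  }
  full <- matrix(0, nrow = nrow(X), ncol = length(tree$tip.label),
    dimnames = list(rownames(X), tree$tip.label))
  full[, colnames(X)] <- X
  full
}

# All three observed metrics for every row of an aligned matrix.
alpha_metrics_sites <- function(X, dist, inc, len, include_root = TRUE) {
  k <- rowSums(X)
  mpd <- rowSums((X %*% dist) * X) / ifelse(k >= 2, k * (k - 1), NA_real_)
  mpd[k < 2] <- NA_real_
  mntd <- vapply(seq_len(nrow(X)), function(s) {
    idx <- which(X[s, ] > 0)
    if (length(idx) < 2L) return(NA_real_)
    m <- dist[idx, idx]
    diag(m) <- Inf
    mean(apply(m, 1L, min))
  }, numeric(1))
  pd <- pd_sites(X, inc, len, include_root = include_root)
  pd[k == 0] <- NA_real_
  list(mpd = as.numeric(mpd), mntd = mntd, pd = as.numeric(pd))
}

#' Taxon-label-shuffling null ensemble for one alpha metric
#'
#' Each iteration draws one uniform permutation of the tip labels of the
#' full species pool in the tree (equivalently, permutes the columns of the
#' occurrence matrix) and recomputes the metric for every site from that
#' same permutation. Site rows are untouched, so the null preserves each
#' site's richness by construction. `mode = "exhaustive"` instead enumerates
#' every distinct taxon subset of the observed richness (feasible only for
#' small pools) and is exact.
#'
#' @param comm A community tibble.
#' @param tree A rooted [ape::phylo]; its tips define the species pool.
#' @param metric `"mpd"`, `"mntd"` or `"pd"`.
#' @param n_iter Number of null iterations (default 999).
#' @param seed Integer seed; required for reproducible pipelines.
#' @param mode `"permute"` (Monte-Carlo, default) or `"exhaustive"`.
#' @param include_root Passed to the PD computation.
#' @param keep_values Keep the raw null values as a list-column?
#' @return A tibble with one row per site: `site`, `metric`, `observed`,
#'   `null_mean`, `null_sd` (sample sd, \eqn{n-1}), `n_null`, and `values`
#'   when requested.
#' @export
shuffle_null <- function(comm, tree, metric = c("mpd", "mntd", "pd"),
                         n_iter = 999, seed = NULL,
                         mode = c("permute", "exhaustive"),
                         include_root = TRUE, keep_values = FALSE) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  comm <- validate_community(comm)
  validate_phylogeny(tree)
  X <- align_to_tree(comm, tree)
  dist <- cophenetic_distances(tree)
  inc <- edge_tip_incidence(tree)
  len <- tree$edge.length
  ens <- null_ensembles(X, dist, inc, len, metric, n_iter, seed, mode, include_root)
  obs <- alpha_metrics_sites(X, dist, inc, len, include_root)[[metric]]
  out <- tibble::tibble(
    site = rownames(X),
    metric = metric,
    observed = obs,
    null_mean = ens$mean,
    null_sd = ens$sd,
    n_null = ens$n
  )
  if (keep_values) out$values <- ens$values
  out
}

# Core null-model engine shared by shuffle_null() and ses_indices().
# Returns per-site mean/sd/rank for the requested metrics, computed either
# by Monte-Carlo label permutation (one permutation per iteration, all
# sites and metrics from the same permutation) or by exhaustive subset
# enumeration.
null_ensembles <- function(X, dist, inc, len, metrics, n_iter, seed,
                           mode = "permute", include_root = TRUE,
                           observed = NULL) {
  metrics <- as.character(metrics)
  n_site <- nrow(X)
  n_pool <- ncol(X)
  if (is.null(observed)) {
    observed <- alpha_metrics_sites(X, dist, inc, len, include_root)
  }

  if (mode == "exhaustive") {
    res <- lapply(metrics, function(me) {
      vals_by_site <- lapply(seq_len(n_site), function(s) {
        k <- sum(X[s, ] > 0)
        if (k == 0) return(numeric(0))
        n_comb <- choose(n_pool, k)
        if (n_comb > 1e5) {
          abort(paste0("exhaustive null infeasible: choose(", n_pool, ", ", k,
            ") = ", n_comb, " subsets"), class = "phylograd_domain_error")
        }
        subsets <- combn(n_pool, k)
        apply(subsets, 2L, function(idx) {
          Xs <- matrix(0, 1L, n_pool)
          Xs[1L, idx] <- 1
          alpha_metrics_sites(Xs, dist, inc, len, include_root)[[me]]
        })
      })
      list(
        mean = vapply(vals_by_site, function(v) if (length(v)) mean(v) else NA_real_, 1),
        sd = vapply(vals_by_site, function(v) if (length(v) > 1) sd(v) else NA_real_, 1),
        n = vapply(vals_by_site, length, 1L),
        rank = vapply(seq_len(n_site), function(s) {
          v <- vals_by_site[[s]]
          if (!length(v) || is.na(observed[[me]][s])) return(NA_real_)
          sum(v < observed[[me]][s]) + 1
        }, 1),
        values = vals_by_site
      )
    })
    names(res) <- metrics
    return(if (length(metrics) == 1L) res[[1L]] else res)
  }

  run <- function() {
    acc <- lapply(metrics, function(me) list(
      s = numeric(n_site), s2 = numeric(n_site), below = numeric(n_site),
      values = if (n_site * n_iter <= 2e6) matrix(NA_real_, n_site, n_iter) else NULL
    ))
    names(acc) <- metrics
    for (b in seq_len(n_iter)) {
      perm <- sample.int(n_pool)
      Xp <- X[, perm, drop = FALSE]
      vals <- alpha_metrics_sites(Xp, dist, inc, len, include_root)
      for (me in metrics) {
        v <- vals[[me]]
        cmp <- v < observed[[me]]
        cmp[is.na(cmp)] <- 0
        acc[[me]]$s <- acc[[me]]$s + ifelse(is.na(v), 0, v)
        acc[[me]]$s2 <- acc[[me]]$s2 + ifelse(is.na(v), 0, v^2)
        acc[[me]]$below <- acc[[me]]$below + cmp
        if (!is.null(acc[[me]]$values)) acc[[me]]$values[, b] <- v
      }
    }
    res <- lapply(metrics, function(me) {
      m <- acc[[me]]$s / n_iter
      v <- (acc[[me]]$s2 - n_iter * m^2) / (n_iter - 1)
      # cancellation guard: variance below accumulation round-off is zero
      v[v < 1e-14 * pmax(m^2, 1)] <- 0
      m[is.na(observed[[me]])] <- NA_real_
      v[is.na(observed[[me]])] <- NA_real_
      rank <- acc[[me]]$below + 1
      rank[is.na(observed[[me]])] <- NA_real_
      list(
        mean = m, sd = sqrt(v), n = rep(n_iter, n_site),
        rank = rank,
        values = if (!is.null(acc[[me]]$values)) {
          lapply(seq_len(n_site), function(s) acc[[me]]$values[s, ])
        } else {
          rep(list(NULL), n_site)
        }
      )
    })
    names(res) <- metrics
    if (length(metrics) == 1L) res[[1L]] else res
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Standardized effect sizes of community phylogenetic structure
#'
#' Computes, per site, the observed mean pairwise distance (MPD), mean
#' nearest-taxon distance (MNTD) and Faith's PD, their null distributions
#' under taxon-label shuffling over the full tree pool, and the derived
#' indices:
#' \itemize{
#'   \item NRI (net relatedness index) \eqn{= -(\mathrm{MPD}_{obs} -
#'     \bar{\mathrm{MPD}}_{null})/\mathrm{sd}_{null}};
#'   \item NTI (nearest taxon index), the same with MNTD;
#'   \item SES.PD \eqn{= (\mathrm{PD}_{obs} -
#'     \bar{\mathrm{PD}}_{null})/\mathrm{sd}_{null}} (no sign flip).
#' }
#' Positive NRI/NTI indicate phylogenetic clustering (co-occurring taxa more
#' related than expected), negative values overdispersion; negative SES.PD
#' indicates less phylogenetic diversity than expected at the observed
#' richness. Indices with |value| >= 1.96 are flagged as significant
#' departures from the null. Sites with fewer than two taxa have undefined
#' MPD/MNTD (hence `NA` NRI/NTI) but a valid SES.PD; a degenerate null
#' (sd = 0) yields `NA`, never infinity.
#'
#' @inheritParams shuffle_null
#' @param sig_threshold Two-sided significance demarcation on the SES scale
#'   (default 1.96).
#' @return A tibble of class `phylograd_ses` with one row per site: observed
#'   metrics, null means/sds, `nri`, `nti`, `ses_pd`, significance flags,
#'   and observed ranks within the null (`*_obs_rank` out of `n_null`).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' comm <- tibble::tibble(site = "s1", A = 1, B = 1, C = 0, D = 0)
#' ses_indices(comm, tr, mode = "exhaustive") # NRI +1.291, SES.PD -1.291
#' @export
ses_indices <- function(comm, tree, n_iter = 999, seed = NULL,
                        mode = c("permute", "exhaustive"),
                        include_root = TRUE, sig_threshold = 1.96) {
  mode <- match.arg(mode)
  comm <- validate_community(comm)
  validate_phylogeny(tree)
  X <- align_to_tree(comm, tree)
  dist <- cophenetic_distances(tree)
  inc <- edge_tip_incidence(tree)
  len <- tree$edge.length
  obs <- alpha_metrics_sites(X, dist, inc, len, include_root)
  ens <- null_ensembles(X, dist, inc, len, c("mpd", "mntd", "pd"),
    n_iter, seed, mode, include_root, observed = obs)

  ses_of <- function(o, e) {
    s <- (o - e$mean) / e$sd
    degenerate <- !is.na(e$sd) & e$sd < 1e-8 * pmax(abs(e$mean), 1)
    s[degenerate] <- NA_real_
    s
  }
  ses_mpd <- ses_of(obs$mpd, ens$mpd)
  ses_mntd <- ses_of(obs$mntd, ens$mntd)
  ses_pd <- ses_of(obs$pd, ens$pd)

  out <- tibble::tibble(
    site = rownames(X),
    richness = as.integer(rowSums(X)),
    mpd = obs$mpd,
    mpd_null_mean = ens$mpd$mean,
    mpd_null_sd = ens$mpd$sd,
    mpd_obs_rank = ens$mpd$rank,
    mntd = obs$mntd,
    mntd_null_mean = ens$mntd$mean,
    mntd_null_sd = ens$mntd$sd,
    mntd_obs_rank = ens$mntd$rank,
    pd = obs$pd,
    pd_null_mean = ens$pd$mean,
    pd_null_sd = ens$pd$sd,
    pd_obs_rank = ens$pd$rank,
    nri = -ses_mpd,
    nti = -ses_mntd,
    ses_pd = ses_pd,
    nri_sig = abs(-ses_mpd) >= sig_threshold,
    nti_sig = abs(-ses_mntd) >= sig_threshold,
    ses_pd_sig = abs(ses_pd) >= sig_threshold,
    n_null = ens$pd$n
  )
  if ("elevation" %in% names(comm)) {
    out <- tibble::add_column(out,
      elevation = comm$elevation[match(out$site, comm$site)], .after = "site")
  }
  attr(out, "include_root") <- include_root
  attr(out, "seed") <- seed
  attr(out, "mode") <- mode
  attr(out, "sig_threshold") <- sig_threshold
  class(out) <- c("phylograd_ses", class(out))
  out
}
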