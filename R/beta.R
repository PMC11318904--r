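# Sorensen-family decomposition from matching components:
# a = shared, b/c = unique to each community (branch lengths or counts).
decompose_abc <- function(a, b, c) {
  tot <- 2 * a + b + c
  beta_sor <- ifelse(tot > 0, (b + c) / tot, 0)
  mn <- pmin(b, c)
  beta_sim <- ifelse(mn > 0, mn / (a + mn), 0)
  tibble::tibble(
    a = a, b = b, c = c,
    beta_sor = beta_sor,
    beta_sim = beta_sim,
    beta_sne = beta_sor - beta_sim
  )
}

#' Phylogenetic Sorensen (PhyloSor) dissimilarity between two communities
#'
#' The PhyloSor similarity of two communities is
#' \eqn{2a / (2a + b + c)} where `a` is the branch length shared between the
#' two communities' spanning subtrees and `b`, `c` the branch lengths unique
#' to each (with `a + b` equal to the PD of community 1). The complementary
#' dissimilarity `beta_sor = (b + c)/(2a + b + c)` is decomposed,
#' Baselga-style, into a true turnover component
#' `beta_sim = min(b, c)/(a + min(b, c))` and a nestedness-resultant
#' component `beta_sne = beta_sor - beta_sim`.
#'
#' @param taxa1,taxa2 Non-empty character vectors of tip labels.
#' @param tree A rooted [ape::phylo].
#' @param include_root Include root paths in the spanning subtrees
#'   (consistent with [faith_pd()]); default `TRUE`.
#' @return A one-row tibble: `a`, `b`, `c`, `beta_sor`, `beta_sim`,
#'   `beta_sne`, `phylosor` (the similarity), `variant = "phylogenetic"`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' phylosor_pair(c("A", "B"), c("A", "C"), tr) # beta_sor = 3/7
#' @export
phylosor_pair <- function(taxa1, taxa2, tree, include_root = TRUE) {
  validate_phylogeny(tree)
  if (!length(taxa1) || !length(taxa2)) {
    abort("communities must be non-empty", class = "phylograd_domain_error")
  }
  inc <- edge_tip_incidence(tree)
  len <- tree$edge.length
  e1 <- spanning_edges(tree, inc, taxa1, include_root)
  e2 <- spanning_edges(tree, inc, taxa2, include_root)
  a <- sum(len[e1 & e2])
  b <- sum(len[e1 & !e2])
  c <- sum(len[e2 & !e1])
  out <- decompose_abc(a, b, c)
  out$phylosor <- ifelse(2 * a + b + c > 0, 2 * a / (2 * a + b + c), 1)
  out$variant <- "phylogenetic"
  out
}

spanning_edges <- function(tree, inc, taxa, include_root) {
  taxa <- unique(as.character(taxa))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) {
    abort(paste0("taxa not in tree: ", paste(unknown, collapse = ", ")),
      class = "phylograd_lookup_error")
  }
  cnt <- rowSums(inc[, taxa, drop = FALSE])
  if (include_root) cnt >= 1 else (cnt >= 1 & cnt < length(taxa))
}

#' Species-level Sorensen dissimilarity between two communities
#'
#' The phylogeny-free counterpart of [phylosor_pair()]: `a` is the number of
#' shared species and `b`, `c` the numbers unique to each community, with
#' the same turnover/nestedness decomposition.
#'
#' @param taxa1,taxa2 Character vectors of species labels.
#' @return A one-row tibble as in [phylosor_pair()], `variant = "species"`.
#' @export
sorensen_pair <- function(taxa1, taxa2) {
  t1 <- unique(as.character(taxa1))
  t2 <- unique(as.character(taxa2))
  out <- decompose_abc(length(intersect(t1, t2)),
    length(setdiff(t1, t2)), length(setdiff(t2, t1)))
  out$phylosor <- NA_real_
  out$variant <- "species"
  out
}

#' All pairwise beta-diversity decompositions for a community matrix
#'
#' Computes, for every unordered pair of sites, the species Sorensen
#' decomposition and (when a tree is supplied) the PhyloSor decomposition.
#'
#' @param comm A community tibble.
#' @param tree Optional rooted [ape::phylo] for the phylogenetic variant.
#' @param include_root Root-path convention for spanning subtrees.
#' @return A tibble with columns `site1`, `site2`, `variant`, `a`, `b`, `c`,
#'   `beta_sor`, `beta_sim`, `beta_sne`.
#' @export
beta_pairs <- function(comm, tree = NULL, include_root = TRUE) {
  comm <- validate_community(comm)
  X <- community_matrix(comm)
  n <- nrow(X)
  if (n < 2L) abort("need at least 2 sites", class = "phylograd_domain_error")
  pr <- combn(n, 2L)

  shared_sp <- X %*% t(X)
  rich <- rowSums(X)
  res <- list()
  a <- shared_sp[cbind(pr[1L, ], pr[2L, ])]
  b <- rich[pr[1L, ]] - a
  c <- rich[pr[2L, ]] - a
  sp <- decompose_abc(a, b, c)
  sp$variant <- "species"
  res$species <- sp

  if (!is.null(tree)) {
    validate_phylogeny(tree)
    Xt <- align_to_tree(comm, tree)
    inc <- edge_tip_incidence(tree)
    len <- tree$edge.length
    E <- (Xt %*% t(inc)) > 0 # sites x edges: edge in spanning subtree
    if (!include_root) {
      k <- rowSums(Xt)
      E <- E & !sweep(Xt %*% t(inc), 1L, k, "==")
    }
    E <- E + 0
    sharedL <- tcrossprod(E * matrix(len, nrow(E), length(len), byrow = TRUE), E)
    pd <- drop(E %*% len)
    a <- sharedL[cbind(pr[1L, ], pr[2L, ])]
    ph <- decompose_abc(a, pd[pr[1L, ]] - a, pd[pr[2L, ]] - a)
    ph$variant <- "phylogenetic"
    res$phylogenetic <- ph
  }

  out <- dplyr::bind_rows(res)
  pairs_tbl <- tibble::tibble(
    site1 = rownames(X)[pr[1L, ]],
    site2 = rownames(X)[pr[2L, ]]
  )
  dplyr::bind_cols(
    pairs_tbl[rep(seq_len(ncol(pr)), length.out = nrow(out)), ],
    out
  )
}

#' Site x site beta-diversity matrices
#'
#' @inheritParams beta_pairs
#' @return A named list of symmetric zero-diagonal matrices:
#'   `species_sor`, `species_sim`, `species_sne` and, with a tree,
#'   `phylo_sor`, `phylo_sim`, `phylo_sne`.
#' @export
beta_matrices <- function(comm, tree = NULL, include_root = TRUE) {
  comm <- validate_community(comm)
  pairs <- beta_pairs(comm, tree, include_root)
  sites <- comm$site
  build <- function(tbl, col) {
    m <- matrix(0, length(sites), length(sites), dimnames = list(sites, sites))
    i <- match(tbl$site1, sites)
    j <- match(tbl$site2, sites)
    m[cbind(i, j)] <- tbl[[col]]
    m[cbind(j, i)] <- tbl[[col]]
    m
  }
  out <- list()
  sp <- pairs[pairs$variant == "species", ]
  out$species_sor <- build(sp, "beta_sor")
  out$species_sim <- build(sp, "beta_sim")
  out$species_sne <- build(sp, "beta_sne")
  if (!is.null(tree)) {
    ph <- pairs[pairs$variant == "phylogenetic", ]
    out$phylo_sor <- build(ph, "beta_sor")
    out$phylo_sim <- build(ph, "beta_sim")
    out$phylo_sne <- build(ph, "beta_sne")
  }
  out
}

#' Mean inter-community pairwise phylogenetic distance (COMDIST)
#'
#' Unweighted mean of the cophenetic distance over all cross-community
#' pairs; species shared by both communities contribute zero-distance
#' self-pairs, so COMDIST of identical communities is not zero in general
#' but is for single shared species.
#'
#' @param taxa1,taxa2 Non-empty character vectors of tip labels.
#' @param dist Cophenetic distance matrix.
#' @return A single non-negative number.
#' @export
comdist_pair <- function(taxa1, taxa2, dist) {
  i1 <- match_taxa(taxa1, dist)
  i2 <- match_taxa(taxa2, dist)
  mean(dist[i1, i2, drop = FALSE])
}

#' Site x site COMDIST matrix
#'
#' @param comm A community tibble.
#' @param tree A rooted [ape::phylo].
#' @return Symmetric matrix of mean inter-community phylogenetic distances
#'   with zero diagonal entries forced (self-comparisons are conventionally
#'   reported as 0 for clustering).
#' @export
comdist_matrix <- function(comm, tree) {
  comm <- validate_community(comm)
  validate_phylogeny(tree)
  X <- align_to_tree(comm, tree)
  dist <- cophenetic_distances(tree)
  k <- rowSums(X)
  num <- X %*% dist %*% t(X)
  m <- num / outer(k, k)
  diag(m) <- 0
  dimnames(m) <- list(rownames(X), rownames(X))
  m
}

#' Hierarchical clustering of communities from a distance matrix
#'
#' Standard agglomerative clustering of sites; the default average linkage
#' (UPGMA) is configurable. Merge heights are reported as raw merge
#' distances (the `stats::hclust` convention, not halved).
#'
#' @param dist A symmetric site x site distance matrix with zero diagonal.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An object of class [stats::hclust].
#' @export
cluster_communities <- function(dist, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  dist <- as.matrix(dist)
  if (nrow(dist) < 2L) abort("need at least 2 sites", class = "phylograd_domain_error")
  if (!isSymmetric(unname(dist), tol = 1e-8)) {
    abort("distance matrix must be symmetric", class = "phylograd_validation_error")
  }
  hclust(as.dist(dist), method = linkage)
}

#' Serialize a site dendrogram as Newick
#'
#' @param hc An [stats::hclust] object (see [cluster_communities()]).
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
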