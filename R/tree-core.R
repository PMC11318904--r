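#' Read a rooted phylogeny from Newick or NEXUS
#'
#' Reads a tree file and validates it for downstream community-phylogenetic
#' analysis: unique non-empty tip labels, finite non-negative branch lengths,
#' a single root. Zero-length branches are allowed (they arise when
#' constraint-induced polytomies are resolved arbitrarily); negative lengths
#' are rejected. Internal node labels are preserved but ignored by all
#' metrics.
#'
#' @param path Path to a tree file.
#' @param format One of `"auto"` (default; decided by file content/extension),
#'   `"newick"` or `"nexus"`.
#' @return A rooted [ape::phylo] object.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,(C:1,D:1):1);", tf)
#' tr <- read_phylogeny(tf)
#' sum(tr$edge.length)
#' @export
read_phylogeny <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("tree file not found: ", path), class = "phylograd_io_error")
  }
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    ext <- tolower(tools::file_ext(path))
    format <- if (startsWith(first, "#NEXUS") || ext %in% c("nex", "nexus", "nxs")) {
      "nexus"
    } else {
      "newick"
    }
  }
  tree <- tryCatch(
    switch(format,
      newick = ape::read.tree(path),
      nexus  = ape::read.nexus(path)
    ),
    error = function(e) {
      abort(
        paste0("failed to parse ", format, " file '", path, "': ", conditionMessage(e)),
        class = "phylograd_parse_error"
      )
    }
  )
  if (is.null(tree)) {
    abort(
      paste0("failed to parse ", format, " file '", path, "': no tree found"),
      class = "phylograd_parse_error"
    )
  }
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  validate_phylogeny(tree)
}

#' Write a phylogeny to Newick or NEXUS
#'
#' @param tree A [ape::phylo] object.
#' @param path Output path.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_phylogeny <- function(tree, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  switch(format,
    newick = ape::write.tree(tree, file = path),
    nexus  = ape::write.nexus(tree, file = path)
  )
  invisible(path)
}

#' Validate a phylogeny for community-phylogenetic analysis
#'
#' @param tree A [ape::phylo] object.
#' @return `tree`, invisibly classed, after validation.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) {
    abort("`tree` must be an ape 'phylo' object", class = "phylograd_validation_error")
  }
  tips <- tree$tip.label
  if (anyDuplicated(tips)) {
    dups <- unique(tips[duplicated(tips)])
    abort(
      paste0("duplicate tip labels: ", paste(dups, collapse = ", ")),
      class = "phylograd_validation_error"
    )
  }
  if (any(!nzchar(tips))) {
    abort("empty tip labels are not allowed", class = "phylograd_validation_error")
  }
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths", class = "phylograd_validation_error")
  }
  if (any(!is.finite(tree$edge.length))) {
    abort("non-finite branch lengths", class = "phylograd_validation_error")
  }
  if (any(tree$edge.length < 0)) {
    abort("negative branch lengths are not allowed", class = "phylograd_validation_error")
  }
  # NB: basal polytomies are accepted; the basal node is treated as the root
  # (ape cannot distinguish a rooted basal polytomy from an unrooted tree).
  tree
}

# Edge x tip incidence: entry (e, i) is 1 when tip i descends from edge e.
# Single postorder sweep; the workhorse behind PD, cophenetic distances and
# the shared-branch accounting of PhyloSor.
edge_tip_incidence <- function(tree) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  n_node <- n + tree$Nnode
  desc <- matrix(0, nrow = n_node, ncol = n)
  desc[cbind(seq_len(n), seq_len(n))] <- 1
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]
    chi <- po$edge[e, 2L]
    desc[par, ] <- desc[par, ] + desc[chi, ]
  }
  desc <- (desc > 0) + 0
  inc <- desc[tree$edge[, 2L], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  inc
}

#' Pairwise cophenetic (patristic) distances between tips
#'
#' Distance between two tips is the sum of branch lengths along the path
#' connecting them. Computed from the edge-tip incidence structure: an edge
#' of length \eqn{\ell} lies on the path between tips \eqn{i,j} exactly when
#' one, but not both, of them descends from it, so
#' \eqn{d(i,j) = w_i + w_j - 2\sum_e \ell_e m_{ei} m_{ej}} with \eqn{w_i}
#' the root-to-tip depth.
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @return A symmetric numeric matrix with tip labels as dimnames and zero
#'   diagonal.
#' @export
cophenetic_distances <- function(tree) {
  validate_phylogeny(tree)
  n <- length(tree$tip.label)
  if (n == 1L) {
    return(matrix(0, 1L, 1L, dimnames = list(tree$tip.label, tree$tip.label)))
  }
  inc <- edge_tip_incidence(tree)
  len <- tree$edge.length
  shared <- crossprod(inc, inc * len) # sum of edge lengths on both root paths
  depth <- diag(shared)
  d <- outer(depth, depth, "+") - 2 * shared
  d[d < 0] <- 0 # clamp tiny negative round-off
  diag(d) <- 0
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

#' Faith's phylogenetic diversity of a set of taxa
#'
#' Sum of branch lengths of the minimal subtree spanning `taxa`. With
#' `include_root = TRUE` (default, matching the common convention) the path
#' connecting that subtree to the root is included, so the PD of a single
#' taxon is its root-to-tip depth.
#'
#' @param tree A rooted [ape::phylo].
#' @param taxa Character vector of tip labels (non-empty subset of the tips).
#' @param include_root Include the path from the spanning subtree to the
#'   root? Default `TRUE`.
#' @return A single non-negative number.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' faith_pd(tr, c("A", "B")) # 3: both tip edges plus their stem
#' @export
faith_pd <- function(tree, taxa, include_root = TRUE) {
  validate_phylogeny(tree)
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) {
    abort("`taxa` must be non-empty", class = "phylograd_domain_error")
  }
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) {
    abort(
      paste0("taxa not in tree: ", paste(unknown, collapse = ", ")),
      class = "phylograd_lookup_error"
    )
  }
  inc <- edge_tip_incidence(tree)
  len <- tree$edge.length
  cnt <- rowSums(inc[, taxa, drop = FALSE])
  keep <- cnt >= 1L
  if (!include_root) keep <- keep & cnt < length(taxa)
  sum(len[keep])
}

# PD for every row of a binary sites x species matrix aligned to the tree's
# tip order; vectorised over sites (and reused per null iteration).
pd_sites <- function(X, inc, len, include_root = TRUE) {
  cnt <- X %*% t(inc) # sites x edges: community members below each edge
  pd <- (cnt > 0) %*% len
  if (!include_root) {
    k <- rowSums(X)
    on_root_path <- sweep(cnt, 1L, k, "==") & k > 0
    pd <- pd - on_root_path %*% len
  }
  drop(pd)
}
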