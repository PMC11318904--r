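# Shared fixtures and independent brute-force oracles.

toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

toy_community <- function() {
  tibble::tibble(
    site = c("low", "high"),
    elevation = c(200, 700),
    A = c(1, 0), B = c(1, 0), C = c(0, 1), D = c(0, 1)
  )
}

random_tree <- function(n, seed) {
  phylograd::sim_tree(n, seed = seed)
}

# Oracle: MPD by an explicit double loop over unordered pairs.
mpd_brute <- function(taxa, d) {
  taxa <- unique(taxa)
  tot <- 0
  np <- 0
  for (i in seq_along(taxa)) {
    for (j in seq_along(taxa)) {
      if (j > i) {
        tot <- tot + d[taxa[i], taxa[j]]
        np <- np + 1
      }
    }
  }
  tot / np
}

# Oracle: MNTD by explicit nearest-neighbour search.
mntd_brute <- function(taxa, d) {
  taxa <- unique(taxa)
  mean(vapply(taxa, function(i) {
    min(vapply(setdiff(taxa, i), function(j) d[i, j], 1))
  }, 1))
}

# Oracle: COMDIST by explicit double loop over cross pairs.
comdist_brute <- function(t1, t2, d) {
  tot <- 0
  for (i in t1) for (j in t2) tot <- tot + d[i, j]
  tot / (length(t1) * length(t2))
}

# Oracle: Faith's PD by explicit edge enumeration — an edge is in the
# spanning subtree when at least one member lies below it; excluding the
# root drops edges with every member below.
pd_brute <- function(tree, taxa, include_root = TRUE) {
  n <- length(tree$tip.label)
  tip_ids <- match(taxa, tree$tip.label)
  below <- function(node) {
    if (node <= n) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below))
  }
  tot <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips_below <- below(tree$edge[e, 2])
    k <- sum(tip_ids %in% tips_below)
    if (k >= 1 && (include_root || k < length(tip_ids))) {
      tot <- tot + tree$edge.length[e]
    }
  }
  tot
}

# Oracle: textbook agglomerative clustering (naive Lance-Williams update),
# returning merge heights in order.
agglom_brute <- function(d, linkage = "average") {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  dd <- d
  diag(dd) <- Inf
  heights <- numeric(0)
  while (length(active) > 1) {
    k <- length(active)
    best <- c(1, 2)
    bestv <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        v <- cluster_dist(active[[i]], active[[j]], d, linkage)
        if (v < bestv - 1e-12) {
          bestv <- v
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, bestv)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1]] <- merged
  }
  heights
}

cluster_dist <- function(a, b, d, linkage) {
  vals <- d[a, b, drop = FALSE]
  switch(linkage,
    average = mean(vals),
    complete = max(vals),
    single = min(vals)
  )
}

# Random symmetric zero-diagonal distance matrix (Euclidean, so metric).
random_distance_matrix <- function(n, labels = sprintf("x%02d", seq_len(n))) {
  pts <- matrix(runif(n * 2), n, 2)
  m <- as.matrix(stats::dist(pts))
  dimnames(m) <- list(labels, labels)
  m
}

write_temp_csv <- function(df, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
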