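#' Read a sites x species presence/absence matrix from CSV
#'
#' The expected layout is one row per site with the first column holding the
#' site label and the remaining columns holding 0/1 presences for each
#' species (`orientation = "sites"`). The transposed layout (species in
#' rows) is handled with `orientation = "species"`. An optional `elevation`
#' column (or a numeric vector supplied via `elevations`) attaches the site
#' elevations in metres used by gap interpolation and the plotting helpers.
#'
#' @param path CSV file path.
#' @param orientation `"sites"` (default, sites in rows) or `"species"`.
#' @param elevations Optional numeric vector of site elevations (m a.s.l.),
#'   one per site, in the file's site order. Ignored when the file already
#'   has an `elevation` column.
#' @param drop_empty_species Drop species never recorded at any site
#'   (default `TRUE`, with a message).
#' @return A community tibble: columns `site`, optionally `elevation`, then
#'   one 0/1 column per species, rows sorted by elevation when available.
#' @export
read_community <- function(path, orientation = c("sites", "species"),
                           elevations = NULL, drop_empty_species = TRUE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    abort(paste0("community file not found: ", path), class = "phylograd_io_error")
  }
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) {
    abort("community CSV needs a label column plus at least one data column",
      class = "phylograd_validation_error")
  }
  labels <- as.character(raw[[1L]])
  values <- raw[, -1L, drop = FALSE]
  if (orientation == "species") {
    m <- t(as.matrix(values))
    colnames(m) <- labels
    labels <- colnames(values)
    values <- as.data.frame(m, check.names = FALSE)
  }
  comm <- tibble::tibble(site = labels)
  elev_col <- which(tolower(names(values)) == "elevation")
  if (length(elev_col)) {
    comm$elevation <- as.numeric(values[[elev_col[1L]]])
    values <- values[, -elev_col, drop = FALSE]
  } else if (!is.null(elevations)) {
    if (length(elevations) != nrow(comm)) {
      abort("`elevations` must have one value per site",
        class = "phylograd_validation_error")
    }
    comm$elevation <- as.numeric(elevations)
  }
  comm <- dplyr::bind_cols(comm, tibble::as_tibble(values))
  validate_community(comm, drop_empty_species = drop_empty_species)
}

#' Validate (and canonicalise) a community tibble
#'
#' Checks that all species entries are 0/1, site labels are unique, and, if
#' an `elevation` column is present, sorts sites by increasing elevation.
#'
#' @param comm A community tibble (see [read_community()]).
#' @param drop_empty_species Drop all-zero species columns (default `FALSE`).
#' @return The validated tibble.
#' @export
validate_community <- function(comm, drop_empty_species = FALSE) {
  comm <- tibble::as_tibble(comm)
  if (!"site" %in% names(comm)) {
    abort("community data must have a `site` column", class = "phylograd_validation_error")
  }
  comm$site <- as.character(comm$site)
  if (anyDuplicated(comm$site)) {
    abort(
      paste0("duplicate site labels: ",
        paste(unique(comm$site[duplicated(comm$site)]), collapse = ", ")),
      class = "phylograd_validation_error"
    )
  }
  sp <- species_names(comm)
  if (anyDuplicated(sp)) {
    abort(
      paste0("duplicate species labels: ",
        paste(unique(sp[duplicated(sp)]), collapse = ", ")),
      class = "phylograd_validation_error"
    )
  }
  X <- community_matrix(comm)
  bad <- which(!(X %in% c(0, 1)) | is.na(X))
  if (length(bad)) {
    rows <- ((bad - 1L) %% nrow(X)) + 1L
    cols <- ((bad - 1L) %/% nrow(X)) + 1L
    cells <- paste0(comm$site[rows], "/", sp[cols], "=", X[bad])
    abort(
      paste0("non-binary entries in community matrix: ",
        paste(utils::head(cells, 10L), collapse = ", "),
        if (length(cells) > 10L) " ..." else ""),
      class = "phylograd_validation_error"
    )
  }
  if ("elevation" %in% names(comm)) {
    if (any(!is.finite(comm$elevation))) {
      abort("elevations must be finite", class = "phylograd_validation_error")
    }
    comm <- dplyr::arrange(comm, .data$elevation)
  }
  empty <- sp[colSums(X) == 0]
  if (length(empty)) {
    if (drop_empty_species) {
      inform(paste0("dropping ", length(empty), " species never recorded at any site"))
      comm <- comm[, setdiff(names(comm), empty)]
    } else {
      warn(paste0(length(empty), " species have no presences: ",
        paste(utils::head(empty, 5L), collapse = ", ")))
    }
  }
  comm
}

#' Species columns of a community tibble
#' @param comm A community tibble.
#' @return Character vector of species labels.
#' @export
species_names <- function(comm) {
  setdiff(names(comm), c("site", "elevation"))
}

#' Binary site x species matrix of a community tibble
#' @param comm A community tibble.
#' @return Numeric matrix with site labels as rownames.
#' @export
community_matrix <- function(comm) {
  sp <- species_names(comm)
  X <- as.matrix(comm[, sp, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- comm$site
  X
}

#' Per-site taxon sets
#' @param comm A community tibble.
#' @return Named list of character vectors, one per site.
#' @export
community_sets <- function(comm) {
  X <- community_matrix(comm)
  sp <- colnames(X)
  sets <- apply(X, 1L, function(r) sp[r > 0], simplify = FALSE)
  names(sets) <- rownames(X)
  sets
}

#' Fill single-site gaps in species elevational ranges
#'
#' A species absent at exactly one site whose immediately adjacent lower and
#' higher sites (in elevation order) both record it is treated as present
#' there: with only a handful of trapping nights per site, a one-site hole
#' inside an occupied elevational band is far more likely a sampling miss
#' than a true range disjunction. The strict default fills only internal
#' absence runs of length exactly one; `mode = "any-flanked"` fills flanked
#' runs of any length; `mode = "off"` returns the data unchanged. Terminal
#' absences are never filled, and the operation is idempotent.
#'
#' @param comm A community tibble with sites ordered by elevation (rows are
#'   re-sorted if an `elevation` column is present).
#' @param mode `"single"` (default), `"any-flanked"` or `"off"`.
#' @return The community tibble with gaps filled.
#' @examples
#' comm <- tibble::tibble(site = c("lo", "mid", "hi"),
#'                        elevation = c(200, 700, 1200),
#'                        sp1 = c(1, 0, 1), sp2 = c(0, 1, 0))
#' interpolate_single_gaps(comm) # sp1 becomes 1,1,1; sp2 untouched
#' @export
interpolate_single_gaps <- function(comm, mode = c("single", "any-flanked", "off")) {
  mode <- match.arg(mode)
  comm <- validate_community(comm)
  if (mode == "off") return(comm)
  X <- community_matrix(comm)
  n <- nrow(X)
  if (n < 3L) return(comm)
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    pres <- which(v > 0)
    if (length(pres) < 2L) next
    lo <- pres[1L]
    hi <- pres[length(pres)]
    gaps <- rle(v[lo:hi] == 0)
    pos <- lo - 1L + cumsum(c(1L, gaps$lengths))
    for (g in seq_along(gaps$lengths)) {
      if (gaps$values[g] && (mode == "any-flanked" || gaps$lengths[g] == 1L)) {
        v[pos[g]:(pos[g] + gaps$lengths[g] - 1L)] <- 1
      }
    }
    X[, j] <- v
  }
  comm[, species_names(comm)] <- tibble::as_tibble(as.data.frame(X, check.names = FALSE))
  comm
}

#' Summarise a community matrix
#'
#' @param comm A community tibble.
#' @return A list with `per_site` (tibble of site, elevation, richness),
#'   `n_sites`, `n_species`, and `n_occurrences` (grand total of presences).
#' @export
community_summary <- function(comm) {
  comm <- validate_community(comm)
  X <- community_matrix(comm)
  per_site <- tibble::tibble(site = comm$site, richness = rowSums(X))
  if ("elevation" %in% names(comm)) {
    per_site <- tibble::add_column(per_site, elevation = comm$elevation, .after = "site")
  }
  list(
    per_site = per_site,
    n_sites = nrow(X),
    n_species = ncol(X),
    n_occurrences = sum(X)
  )
}
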