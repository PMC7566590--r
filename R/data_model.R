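# Domain containers and I/O shared by every model: the site table, the
# pairwise distance matrix and the observed flow matrix. The canonical site
# order is the row order of the site table; every matrix in the package is
# indexed in that order, with dimnames equal to the site ids.

EARTH_RADIUS_KM <- 6371.0088  # IUGG mean radius

#' Construct and validate a site table
#'
#' A site table holds, for each site, the three data values used to set model
#' site parameters: the population \eqn{P_i}, the number of commuters (or
#' units of flow) departing \eqn{O_i} and arriving \eqn{I_i}, plus an
#' optional pair of coordinates in decimal degrees. Row order is the
#' canonical site order shared by all matrices derived from the table.
#'
#' @param df A data.frame with columns `site_id`, `population`, `out_flow`,
#'   `in_flow`, and optionally `lat` and `lon` (both or neither).
#' @return A validated data.frame of class `site_table`.
#' @export
site_table <- function(df) {
  required <- c("site_id", "population", "out_flow", "in_flow")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_data("site table is missing column(s): ",
              paste(missing_cols, collapse = ", "))
  }
  df$site_id <- as.character(df$site_id)
  if (anyDuplicated(df$site_id)) {
    dup <- unique(df$site_id[duplicated(df$site_id)])
    stop_data("duplicate site_id: ", paste(dup, collapse = ", "))
  }
  has_lat <- "lat" %in% names(df)
  has_lon <- "lon" %in% names(df)
  if (has_lat != has_lon) {
    stop_data("columns lat and lon must be supplied together")
  }
  if (has_lat) {
    if (anyNA(df$lat) || anyNA(df$lon)) {
      if (all(is.na(df$lat)) && all(is.na(df$lon))) {
        df$lat <- NULL
        df$lon <- NULL
        has_lat <- FALSE
      } else {
        stop_data("coordinates must be present for every site or for none")
      }
    }
  }
  for (col in c("population", "out_flow", "in_flow")) {
    v <- df[[col]]
    if (anyNA(v)) stop_data("missing values in column ", col)
    if (!is.numeric(v)) stop_data("column ", col, " must be numeric")
    if (any(v < 0)) stop_data("negative values in column ", col)
    if (any(v != floor(v))) stop_data("non-integer values in column ", col)
    df[[col]] <- as.numeric(v)
  }
  ord <- c("site_id", if (has_lat) c("lat", "lon"), "population",
           "out_flow", "in_flow")
  df <- df[, ord, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("site_table", "data.frame")
  df
}

has_coordinates <- function(sites) {
  all(c("lat", "lon") %in% names(sites))
}

#' Read a site table from CSV
#'
#' Expects a header `site_id,lat,lon,population,out_flow,in_flow`; the
#' `lat`/`lon` columns may be omitted together when an external distance
#' table is used instead. Row order in the file defines the canonical site
#' order.
#'
#' @param path Path to a CSV file.
#' @return A [site_table].
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop_usage("sites file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(site_id = "character"))
  site_table(df)
}

#' Write a site table to CSV
#'
#' Emits the same dialect [read_sites()] consumes (UTF-8, `\n` line endings,
#' no row names), so a write/read round trip reproduces the table exactly.
#'
#' @param sites A [site_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  df <- as.data.frame(sites)
  for (col in c("population", "out_flow", "in_flow")) {
    df[[col]] <- format(df[[col]], scientific = FALSE, trim = TRUE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a flow matrix from an edge list
#'
#' Aggregates an `origin,dest,flow` edge list into a dense matrix of counts
#' \eqn{F_{ij}} in canonical site order. Self-flows are dropped with a
#' warning (the models only predict flows between distinct sites), duplicate
#' edges are summed, and pairs not listed are zero.
#'
#' @param edges A data.frame with columns `origin`, `dest`, `flow`.
#' @param sites The [site_table] defining site ids and order.
#' @return A numeric matrix with zero diagonal and dimnames = site ids.
#' @export
flow_matrix <- function(edges, sites) {
  required <- c("origin", "dest", "flow")
  if (!all(required %in% names(edges))) {
    stop_data("flow edge list needs columns origin, dest, flow")
  }
  ids <- sites$site_id
  origin <- as.character(edges$origin)
  dest <- as.character(edges$dest)
  unknown <- setdiff(unique(c(origin, dest)), ids)
  if (length(unknown) > 0) {
    stop_data("unknown site id(s) in flows: ", paste(unknown, collapse = ", "))
  }
  fl <- edges$flow
  if (anyNA(fl) || !is.numeric(fl)) stop_data("flow values must be numeric")
  if (any(fl < 0)) stop_data("negative flow values")
  if (any(fl != floor(fl))) stop_data("non-integer flow values")
  self <- origin == dest
  if (any(self)) {
    warning(sum(self), " self-flow edge(s) dropped (models predict i != j only)",
            call. = FALSE)
    origin <- origin[!self]
    dest <- dest[!self]
    fl <- fl[!self]
  }
  n <- length(ids)
  F <- matrix(0, n, n, dimnames = list(ids, ids))
  if (length(fl) > 0) {
    idx <- cbind(match(origin, ids), match(dest, ids))
    # duplicate edges are summed, census-style split records lose no counts
    agg <- rowsum(fl, group = (idx[, 1] - 1) * n + idx[, 2])
    lin <- as.integer(rownames(agg))
    F[cbind((lin - 1L) %/% n + 1L, (lin - 1L) %% n + 1L)] <- agg[, 1]
  }
  F
}

#' Read an observed flow edge list from CSV
#'
#' @param path Path to a CSV with header `origin,dest,flow`.
#' @param sites The [site_table] the flows refer to.
#' @return A flow matrix (see [flow_matrix()]).
#' @export
read_flows <- function(path, sites) {
  if (!file.exists(path)) stop_usage("flows file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(origin = "character",
                                       dest = "character"))
  flow_matrix(df, sites)
}

#' Write a flow matrix as an edge list CSV
#'
#' Only nonzero flows are written, in row-major canonical order; zero pairs
#' are implicit. The written file reads back to an identical matrix.
#'
#' @param flows A flow matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flows <- function(flows, path) {
  ids <- rownames(flows)
  keep <- which(t(flows) > 0)  # transpose to enumerate row-major
  i <- (keep - 1L) %/% nrow(flows) + 1L
  j <- (keep - 1L) %% nrow(flows) + 1L
  df <- data.frame(origin = ids[i], dest = ids[j],
                   flow = format(flows[cbind(i, j)], scientific = FALSE,
                                 trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Great-circle distance matrix from site coordinates
#'
#' Haversine distances in km between all site pairs, using the IUGG mean
#' Earth radius 6371.0088 km on a spherical approximation.
#'
#' @param sites A [site_table] in which every site has coordinates.
#' @return A symmetric numeric matrix of distances in km, zero diagonal.
#' @export
haversine_distances <- function(sites) {
  if (!has_coordinates(sites)) {
    stop_data("haversine_distances requires lat/lon for every site")
  }
  pts <- cbind(sites$lon, sites$lat)
  hav <- function(a, b) {
    geosphere::distHaversine(a, b, r = EARTH_RADIUS_KM * 1000)
  }
  D <- geosphere::distm(pts, fun = hav) / 1000
  D <- (D + t(D)) / 2  # enforce exact symmetry against rounding
  diag(D) <- 0
  dimnames(D) <- list(sites$site_id, sites$site_id)
  D
}

#' Read a pairwise distance table from CSV
#'
#' Long-format `site_a,site_b,km` rows. Each unordered pair must appear at
#' least once; pairs listed in both directions must agree. The result is a
#' symmetrised matrix in canonical site order.
#'
#' @param path Path to a CSV with header `site_a,site_b,km`.
#' @param sites The [site_table] the distances refer to.
#' @return A symmetric numeric distance matrix in km.
#' @export
read_distances <- function(path, sites) {
  if (!file.exists(path)) stop_usage("distances file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(site_a = "character",
                                       site_b = "character"))
  ids <- sites$site_id
  unknown <- setdiff(unique(c(df$site_a, df$site_b)), ids)
  if (length(unknown) > 0) {
    stop_data("unknown site id(s) in distances: ",
              paste(unknown, collapse = ", "))
  }
  if (any(df$km < 0)) stop_data("negative distance")
  n <- length(ids)
  D <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  ia <- match(df$site_a, ids)
  ib <- match(df$site_b, ids)
  for (r in seq_along(ia)) {
    i <- ia[r]; j <- ib[r]
    if (i == j) next
    known <- D[i, j]
    if (!is.na(known) && abs(known - df$km[r]) > 1e-9 * max(1, known)) {
      stop_data("inconsistent distances for pair ", ids[i], ",", ids[j],
                ": ", known, " vs ", df$km[r])
    }
    D[i, j] <- df$km[r]
    D[j, i] <- df$km[r]
  }
  if (anyNA(D)) {
    miss <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    stop_data("distance table incomplete; missing pair(s) e.g. ",
              ids[miss[1, 1]], ",", ids[miss[1, 2]])
  }
  D
}

#' Write a distance matrix as a long-format CSV
#'
#' One row per unordered pair, header `site_a,site_b,km`.
#'
#' @param D A symmetric distance matrix with site-id dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distances <- function(D, path) {
  ids <- rownames(D)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  df <- data.frame(site_a = ids[ut[, 1]], site_b = ids[ut[, 2]],
                   km = D[ut])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Derive out-flow and in-flow marginals from a flow matrix
#'
#' \eqn{O_i = \sum_{j \ne i} F_{ij}} and \eqn{I_i = \sum_{j \ne i} F_{ji}};
#' both marginals sum to the total inter-site flow.
#'
#' @param flows A flow matrix.
#' @return A list with numeric vectors `out_flow` and `in_flow`.
#' @export
derive_marginals <- function(flows) {
  F <- flows
  diag(F) <- 0
  list(out_flow = rowSums(F), in_flow = colSums(F))
}
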