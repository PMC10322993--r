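# Quasi-uniform Fibonacci lattice on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (pi * (3 - sqrt(5))) * (seq_len(n) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Simulate a labeled spherical parcellation
#'
#' Builds a stand-in for the spherical registration surface of a cortical
#' parcellation: quasi-uniform vertices on the unit sphere (Fibonacci
#' lattice), partitioned into parcels as the spherical Voronoi cells of
#' randomly drawn seed directions. The right hemisphere is the mirror image
#' (x negated) of the left, with the same parcel labels. With the default
#' 34 parcels per hemisphere the labels are the Desikan-Killiany region
#' names.
#'
#' @param config A [sim_config()]; `config$sphere_spec` gives `n_vertices`
#'   (per hemisphere) and `n_parcels_per_hemisphere`.
#' @param max_retries Seed sets leaving any parcel empty are redrawn at
#'   most this many times.
#' @return A data.frame of class `sphere_parcellation` with columns
#'   `vertex_id`, `x`, `y`, `z`, `hemisphere` ("lh"/"rh"),
#'   `parcel_label`; attribute `seeds` holds the seed directions.
#' @export
simulate_sphere_parcellation <- function(config, max_retries = 25L) {
  stopifnot(inherits(config, "sim_config"))
  sph <- config$sphere_spec
  n_v <- sph$n_vertices
  n_p <- sph$n_parcels_per_hemisphere
  labels <- if (n_p == 34L) dk_regions() else sprintf("parcel_%02d", 1:n_p)
  verts <- fibonacci_sphere(n_v)
  with_seed(config$seed + 303L, {
    for (try in seq_len(max_retries)) {
      seeds <- matrix(stats::rnorm(3 * n_p), n_p, 3)
      seeds <- seeds / sqrt(rowSums(seeds^2))
      assign_idx <- max.col(verts %*% t(seeds), ties.method = "first")
      if (length(unique(assign_idx)) == n_p) break
      if (try == max_retries)
        stop("could not draw parcel seeds with all parcels non-empty")
    }
    lh <- data.frame(vertex_id = seq_len(n_v), x = verts[, 1], y = verts[, 2],
                     z = verts[, 3], hemisphere = "lh",
                     parcel_label = labels[assign_idx],
                     stringsAsFactors = FALSE)
    rh <- lh
    rh$x <- -rh$x
    rh$hemisphere <- "rh"
    rh$vertex_id <- rh$vertex_id + n_v
    out <- rbind(lh, rh)
    rownames(out) <- NULL
    attr(out, "seeds") <- seeds
    class(out) <- c("sphere_parcellation", "data.frame")
    out
  })
}

# Vertex coordinate matrix / label vector for one hemisphere.
sphere_vertices <- function(sphere, hemi) {
  s <- sphere[sphere$hemisphere == hemi, ]
  as.matrix(s[, c("x", "y", "z")])
}

sphere_labels <- function(sphere, hemi) {
  sphere$parcel_label[sphere$hemisphere == hemi]
}

#' Write / read a sphere parcellation as CSV
#'
#' @param sphere A `sphere_parcellation`.
#' @param path File path.
#' @return `read_sphere` returns the `sphere_parcellation`.
#' @export
write_sphere <- function(sphere, path) {
  utils::write.csv(as.data.frame(sphere), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sphere
#' @export
read_sphere <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("sphere_parcellation", "data.frame")
  out
}
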