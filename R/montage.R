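#' Electrode montage, scalp regions and spatial adjacency
#'
#' The analyses in this package are tied to a 61-channel equidistant-style
#' montage. Electrode identity (the integer label 1..61) is what drives the
#' statistics: scalp regions and injection targets are defined as ID sets.
#' Because the true cap coordinates of the equidistant 61-channel layout are
#' not published as part of the region definitions, [build_default_layout()]
#' generates a deterministic quasi-equidistant stand-in on the upper unit
#' hemisphere; coordinates only matter for spatial adjacency and
#' spherical-spline interpolation, both of which need plausible geometry,
#' not the literal cap.
#'
#' Coordinate convention: `x` points to the nose (anterior), `y` to the left
#' ear, `z` up; all electrodes lie on the unit sphere.
#'
#' @param n_rings number of concentric rings (including the vertex); ring
#'   `r` (0-based) carries `6 r` electrodes, so `n_rings = 5` generates
#'   exactly 1 + 6 + 12 + 18 + 24 = 61 positions.
#' @param n_keep number of electrodes retained (IDs `1..n_keep`). Rings are
#'   enumerated from the outermost inwards, each starting at the
#'   anterior-midline azimuth, so ID 1 is always an anterior-midline border
#'   electrode and the vertex is kept last.
#' @return An object of class `electrode_layout`: a data frame with columns
#'   `id`, `x`, `y`, `z`.
#' @examples
#' lay <- build_default_layout()
#' nrow(lay)            # 61
#' range(sqrt(lay$x^2 + lay$y^2 + lay$z^2))
#' @export
build_default_layout <- function(n_rings = 5L, n_keep = 61L) {
  n_rings <- as.integer(n_rings)
  if (n_rings < 2L) stopf("n_rings must be >= 2")
  counts <- c(1L, 6L * seq_len(n_rings - 1L))
  if (sum(counts) < n_keep)
    stopf("n_rings = %d yields only %d electrodes (< n_keep = %d)",
          n_rings, sum(counts), n_keep)
  theta_max <- 1.45 # rad; outer ring sits ~83 deg from the vertex
  theta <- seq(0, theta_max, length.out = n_rings)
  pos <- vector("list", n_rings)
  for (r in seq(n_rings, 1L)) { # outermost ring first
    m <- counts[r]
    phi <- 2 * pi * (seq_len(m) - 1L) / m
    pos[[n_rings - r + 1L]] <- cbind(
      x = sin(theta[r]) * cos(phi),
      y = sin(theta[r]) * sin(phi),
      z = cos(theta[r]) + numeric(m)
    )
  }
  pos <- do.call(rbind, pos)[seq_len(n_keep), , drop = FALSE]
  out <- data.frame(id = seq_len(n_keep), x = pos[, 1], y = pos[, 2],
                    z = pos[, 3])
  class(out) <- c("electrode_layout", "data.frame")
  out
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout: %d electrodes on the unit sphere>\n",
              nrow(x)))
  invisible(x)
}

layout_positions <- function(layout) {
  as.matrix(layout[, c("x", "y", "z")])
}

# Chord-distance matrix between electrodes.
layout_distances <- function(layout) {
  p <- layout_positions(layout)
  d2 <- outer(rowSums(p^2), rowSums(p^2), `+`) - 2 * tcrossprod(p)
  sqrt(pmax(d2, 0))
}

#' Nearest-neighbour distances of a layout
#'
#' @param layout an `electrode_layout`.
#' @return numeric vector, one chord distance per electrode.
#' @export
nearest_neighbor_dist <- function(layout) {
  d <- layout_distances(layout)
  diag(d) <- Inf
  apply(d, 1L, min)
}

#' Scalp region definitions for the 61-channel montage
#'
#' Returns the six-region split used throughout the analyses, as printed ID
#' lists: left/midline/right anterior and left/midline/right posterior,
#' plus the derived `anterior` (24 electrodes) and `posterior` (20
#' electrodes) unions used as component injection targets.
#'
#' The source lists place electrodes 17 and 42 in both the left-anterior
#' and the left-posterior regions. This is preserved verbatim rather than
#' silently corrected; a warning is emitted (suppress with `warn = FALSE`).
#' The `anterior`/`posterior` unions consequently overlap in those two IDs.
#'
#' @param warn emit a warning about the 17/42 overlap (default `TRUE`).
#' @return An object of class `region_map`: a named list of integer
#'   vectors with entries `left_anterior`, `anterior_midline`,
#'   `right_anterior`, `left_posterior`, `posterior_midline`,
#'   `right_posterior`, `anterior`, `posterior`, plus an `overlap` field.
#' @examples
#' rm <- build_region_map(warn = FALSE)
#' length(rm$anterior)   # 24
#' length(rm$posterior)  # 20
#' @export
build_region_map <- function(warn = TRUE) {
  rm <- list(
    left_anterior     = c(5L, 6L, 17L, 18L, 19L, 20L, 21L, 42L, 43L, 44L, 45L),
    anterior_midline  = c(1L, 7L, 33L, 34L),
    right_anterior    = c(2L, 3L, 8L, 9L, 10L, 11L, 35L, 36L, 37L),
    left_posterior    = c(15L, 16L, 17L, 28L, 41L, 42L, 56L, 55L),
    posterior_midline = c(4L, 40L, 27L, 54L),
    right_posterior   = c(12L, 13L, 14L, 26L, 38L, 39L, 52L, 53L)
  )
  rm$anterior <- sort(unique(c(rm$left_anterior, rm$anterior_midline,
                               rm$right_anterior)))
  rm$posterior <- sort(unique(c(rm$left_posterior, rm$posterior_midline,
                                rm$right_posterior)))
  rm$overlap <- intersect(rm$anterior, rm$posterior)
  if (warn && length(rm$overlap))
    warning(sprintf(
      "electrodes %s appear in both an anterior and a posterior region (kept as printed)",
      paste(rm$overlap, collapse = ", ")), call. = FALSE)
  class(rm) <- "region_map"
  rm
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map>\n")
  for (nm in setdiff(names(x), "overlap"))
    cat(sprintf("  %-17s (%2d): %s\n", nm, length(x[[nm]]),
                paste(x[[nm]], collapse = " ")))
  if (length(x$overlap))
    cat("  note: IDs", paste(x$overlap, collapse = ", "),
        "are in both anterior and posterior sets\n")
  invisible(x)
}

#' Spatial adjacency graph over a layout
#'
#' Two electrodes are neighbours iff their chord distance is below
#' `scale` times the median nearest-neighbour distance of the layout. The
#' relation is symmetric and irreflexive; on the default layout with the
#' default `scale` it is connected with a mean degree of roughly 4-8,
#' matching common EEG neighbourhood definitions.
#'
#' @param layout an `electrode_layout`.
#' @param scale multiplier (> 1) of the median nearest-neighbour distance.
#' @return An object of class `adjacency_graph`: list with `ids` and
#'   `neighbors` (a list, per electrode, of neighbouring IDs).
#' @export
build_adjacency <- function(layout, scale = 1.5) {
  if (!is.numeric(scale) || scale <= 1)
    stopf("scale must be > 1 (got %s)", format(scale))
  d <- layout_distances(layout)
  diag(d) <- Inf
  nn <- apply(d, 1L, min)
  if (!all(is.finite(nn)) || median(nn) <= 0)
    stopf("degenerate layout: electrodes are not spatially distinct")
  thr <- scale * median(nn)
  adj <- d < thr
  nbrs <- lapply(seq_len(nrow(adj)),
                 function(i) layout$id[which(adj[i, ])])
  names(nbrs) <- as.character(layout$id)
  structure(list(ids = layout$id, neighbors = nbrs, threshold = thr),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("<adjacency_graph: %d electrodes, mean degree %.2f>\n",
              length(x$ids), mean(deg)))
  invisible(x)
}

# Neighbour list re-indexed to positions within `ids` (for the C++ kernels).
adjacency_index_list <- function(adjacency, ids) {
  lapply(as.character(ids), function(id) {
    nb <- adjacency$neighbors[[id]]
    if (is.null(nb)) stopf("electrode %s missing from adjacency graph", id)
    idx <- match(intersect(nb, ids), ids)
    as.integer(idx[!is.na(idx)])
  })
}

#' Is an adjacency graph connected?
#'
#' @param adjacency an `adjacency_graph`.
#' @return logical scalar.
#' @export
adjacency_is_connected <- function(adjacency) {
  ids <- adjacency$ids
  nb <- adjacency_index_list(adjacency, ids)
  seen <- logical(length(ids))
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    i <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (j in nb[[i]]) if (!seen[j]) {
      seen[j] <- TRUE
      stack <- c(stack, j)
    }
  }
  all(seen)
}

#' Default pseudo-mastoid reference electrodes
#'
#' The generated layout has no literal mastoid channels; the two outer-ring
#' electrodes closest to the left/right retro-auricular direction stand in
#' for them when emulating a mastoid re-reference on synthetic data.
#'
#' @param layout an `electrode_layout`.
#' @return named integer vector `c(left = , right = )`.
#' @export
default_mastoids <- function(layout) {
  p <- layout_positions(layout)
  low <- which(p[, 3] <= min(p[, 3]) + 1e-9) # outermost ring
  target_l <- c(cos(115 * pi / 180) * sin(1.45),
                sin(115 * pi / 180) * sin(1.45), cos(1.45))
  target_r <- target_l * c(1, -1, 1)
  score <- function(tgt) colSums((t(p[low, , drop = FALSE]) - tgt)^2)
  c(left = layout$id[low[which.min(score(target_l))]],
    right = layout$id[low[which.min(score(target_r))]])
}

#' @importFrom stats quantile
NULL

#' Write / read a layout with region membership as TSV
#'
#' Columns: `id`, `x`, `y`, `z`, `region` (comma-separated region names the
#' electrode belongs to, `""` if none).
#'
#' @param layout an `electrode_layout`.
#' @param regions a `region_map` (or `NULL` to omit membership).
#' @param path file path.
#' @return `write_layout_tsv` returns `path` invisibly; `read_layout_tsv`
#'   returns an `electrode_layout` with a `region` column.
#' @export
write_layout_tsv <- function(layout, path, regions = NULL) {
  df <- as.data.frame(layout)
  region_names <- c("left_anterior", "anterior_midline", "right_anterior",
                    "left_posterior", "posterior_midline", "right_posterior")
  df$region <- vapply(df$id, function(id) {
    if (is.null(regions)) return("")
    paste(region_names[vapply(region_names,
                              function(r) id %in% regions[[r]], logical(1))],
          collapse = ",")
  }, character(1))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout_tsv
#' @export
read_layout_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("integer", "numeric", "numeric", "numeric",
                                  "character"))
  class(df) <- c("electrode_layout", "data.frame")
  df
}
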