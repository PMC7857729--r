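# Region-wise MRI intensity quantification and intensity biclustering.

#' Average pixel intensity per sampled disc region
#'
#' For each (level, location) rectangle in the grid mapping, the mean pixel
#' intensity is taken per stack and then averaged over stacks.
#'
#' @param images Named list (by level) of lists of grayscale matrices
#'   (0-255), as produced by [generate_toy_images()] or read from PNGs.
#' @param grid Data frame: `level`, `location`, `row0`, `row1`, `col0`,
#'   `col1` (1-based inclusive pixel rectangles).
#' @return Data frame of class `region_intensity`: `level`, `location`,
#'   `intensity` (stack mean) plus per-stack columns `stack1..k`.
#' @export
region_intensity <- function(images, grid) {
  out <- list()
  for (r in seq_len(nrow(grid))) {
    g <- grid[r, ]
    stacks <- images[[g$level]]
    if (is.null(stacks)) stop("no image stack for level ", g$level)
    if (!length(stacks)) stop("need at least one stack per level")
    per_stack <- vapply(stacks, function(img) {
      if (g$row1 > nrow(img) || g$col1 > ncol(img) ||
          g$row0 < 1 || g$col0 < 1)
        stop("grid rectangle exceeds image bounds for ",
             g$level, "/", g$location)
      mean(img[g$row0:g$row1, g$col0:g$col1])
    }, 0)
    row <- data.frame(level = g$level, location = g$location,
                      intensity = mean(per_stack),
                      stringsAsFactors = FALSE)
    for (s in seq_along(per_stack))
      row[[paste0("stack", s)]] <- per_stack[s]
    out[[r]] <- row
  }
  res <- do.call(rbind, out)
  class(res) <- c("region_intensity", class(res))
  res
}

#' Read grayscale PNG stacks for region quantification
#'
#' @param dir Directory written by [write_toy_images()]: per-level PNGs named
#'   `<level>_stack<k>.png` plus `grid.json`.
#' @return List with `images` (0-255 matrices, nested by level) and `grid`.
#' @export
read_image_stacks <- function(dir) {
  grid <- jsonlite::read_json(file.path(dir, "grid.json"),
                              simplifyVector = TRUE)
  images <- list()
  for (lev in unique(grid$level)) {
    files <- sort(list.files(dir, sprintf("^%s_stack\\d+\\.png$",
                                          gsub("/", "", lev)),
                             full.names = TRUE))
    images[[lev]] <- lapply(files, function(f) png::readPNG(f) * 255)
  }
  list(images = images, grid = grid)
}

#' Bicluster region MRI intensities by level and location
#'
#' Hierarchical clustering of rows (levels) and columns (locations) of the
#' level x location intensity matrix, with (1 - correlation) distance;
#' Euclidean distance is used for an axis with fewer than 4 items (the
#' 3-level axis), where correlation distance is ill-conditioned.
#'
#' @param region A `region_intensity` data frame (one age group).
#' @return List: `matrix` (level x location), `row_tree`, `col_tree`
#'   (`NULL` when an axis has a single item), `reordered`.
#' @export
bicluster_intensity <- function(region) {
  m <- stats::xtabs(intensity ~ level + location, data = region)
  m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  if (anyNA(m)) stop("incomplete level x location intensity matrix")
  tree_of <- function(x) {
    if (nrow(x) < 2) return(NULL)
    # correlation distance needs vectors long enough to carry a pattern;
    # with fewer than 4 entries (the 3-level axis) fall back to Euclidean
    d <- if (ncol(x) >= 4) {
      cm <- suppressWarnings(stats::cor(t(x)))
      cm[!is.finite(cm)] <- 0
      stats::as.dist(1 - cm)
    } else stats::dist(x)
    stats::hclust(d, method = "average")
  }
  row_tree <- tree_of(m)
  col_tree <- tree_of(t(m))
  if (is.null(row_tree)) warning("single level; column clustering only")
  if (is.null(col_tree)) warning("single location; row clustering only")
  ro <- if (is.null(row_tree)) seq_len(nrow(m)) else row_tree$order
  co <- if (is.null(col_tree)) seq_len(ncol(m)) else col_tree$order
  list(matrix = m, row_tree = row_tree, col_tree = col_tree,
       reordered = m[ro, co, drop = FALSE])
}
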