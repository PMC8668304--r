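#' Label connected components of a binary mask
#'
#' Labels foreground (1) pixels of a binary mask into connected components
#' under 4- or 8-connectivity. Labels are positive integers assigned in
#' raster (column-major) order of each component's first pixel; background
#' stays 0.
#'
#' @param mask binary integer matrix.
#' @param connectivity 4 or 8.
#' @return an integer matrix of component labels.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  assertBinaryMask(mask)
  if (!connectivity %in% c(4L, 8L))
    stop("'connectivity' must be 4 or 8", call. = FALSE)
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask == 1)
  out <- matrix(0L, h, w)
  if (length(fg) == 0L) return(out)
  idx <- integer(h * w); idx[fg] <- seq_along(fg)  # pixel -> vertex id
  ri <- (fg - 1L) %% h + 1L
  ci <- (fg - 1L) %/% h + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- integer(0)
  for (o in offs) {
    r2 <- ri + o[1]; c2 <- ci + o[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    hit <- idx[nb] > 0L
    edges <- c(edges, rbind(idx[fg[ok]][hit], idx[nb][hit]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber components by first occurrence in raster order
  lab <- match(memb, unique(memb))
  out[fg] <- lab
  out
}

#' Threshold a tumor probability map
#'
#' Applies a single global cutoff: mask pixel is 1 iff the tumor-class
#' probability is at least `tau`.
#'
#' @param probMap numeric matrix of probabilities in \[0, 1\].
#' @param tau cutoff in \[0, 1\].
#' @return an integer 0/1 mask matrix.
#' @export
globalThreshold <- function(probMap, tau = 0.5) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0 || tau > 1)
    stop("'tau' must be a single probability in [0, 1]", call. = FALSE)
  assertImage2D(probMap, arg = "probMap")
  if (any(probMap < 0 | probMap > 1))
    stop("'probMap' must contain probabilities in [0, 1]", call. = FALSE)
  matrix(as.integer(probMap >= tau), nrow(probMap), ncol(probMap))
}

#' Remove small connected components from a binary mask
#'
#' Deletes foreground components whose pixel area is below `minRegionPx`,
#' the connected-component cleanup that strips small spurious non-tumor
#' regions from a thresholded probability map. Never adds pixels; applying
#' it twice equals applying it once.
#'
#' @param mask binary integer matrix.
#' @param minRegionPx minimum surviving component area (>= 0).
#' @param connectivity 4 or 8.
#' @return the cleaned 0/1 integer mask.
#' @export
removeSmallRegions <- function(mask, minRegionPx = 100L, connectivity = 8L) {
  assertBinaryMask(mask)
  if (minRegionPx < 0) stop("'minRegionPx' must be >= 0", call. = FALSE)
  if (minRegionPx == 0) return(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  lab <- labelComponents(mask, connectivity)
  if (max(lab) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= minRegionPx)
  matrix(as.integer(lab %in% keep), nrow(mask), ncol(mask))
}

#' Postprocess a tumor probability map
#'
#' Global threshold followed by small-region removal on the tumor class
#' (background pixels are never touched).
#'
#' @param probMap tumor-class probability matrix.
#' @param tau probability cutoff (default 0.5).
#' @param minRegionPx minimum surviving component area (default 100).
#' @param connectivity 4 or 8 (default 8).
#' @return a cleaned 0/1 integer mask.
#' @export
postprocessMask <- function(probMap, tau = 0.5, minRegionPx = 100L,
                            connectivity = 8L) {
  removeSmallRegions(globalThreshold(probMap, tau), minRegionPx, connectivity)
}
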