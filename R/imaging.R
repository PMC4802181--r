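#' Pixel/micron threshold conversion
#'
#' At the default pixel size of 320 nm, the classifier thresholds convert
#' as 3 px = 0.96 um and 5 px = 1.6 um (and 10 px = 3.2 um).
#'
#' @param px Distance in pixels.
#' @param pixel_size_nm Pixel size in nm (default 320).
#' @return Distance in microns.
#' @export
px_to_um <- function(px, pixel_size_nm = 320) px * pixel_size_nm / 1000

#' @rdname px_to_um
#' @param um Distance in microns.
#' @export
um_to_px <- function(um, pixel_size_nm = 320) um * 1000 / pixel_size_nm

#' Maximum-intensity projection of a z-stack
#'
#' @param stack 3D array (y, x, z) or list of equally sized matrices.
#' @return Matrix: per-pixel maximum across planes.
#' @export
max_project <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  if (!is.list(stack) || length(stack) == 0)
    stop("need at least one z-plane")
  d <- dim(stack[[1]])
  for (m in stack)
    if (!identical(dim(m), d)) stop("z-planes differ in shape")
  Reduce(pmax, stack)
}

#' Segment nuclei in a projected nuclear-stain image
#'
#' Global automatic (Otsu) threshold on the normalized image, hole
#' filling, connected-component labelling, and a minimum-area filter.
#' Components touching the image border are flagged and excluded from the
#' retained set (but still reported).
#'
#' @param img Numeric matrix (maximally projected nuclear-stain channel).
#' @param min_area Minimum component area in pixels (default 50).
#' @return List: `labels` (integer matrix of component labels, 0 =
#'   background) and `nuclei` (data.frame: label, area, touches_border,
#'   retained). A blank image yields zero nuclei, not an error.
#' @export
segment_nuclei <- function(img, min_area = 50) {
  if (length(img) == 0) stop("empty image")
  rng <- range(img)
  empty <- list(labels = matrix(0L, nrow(img), ncol(img)),
                nuclei = data.frame(label = integer(0), area = integer(0),
                                    touches_border = logical(0),
                                    retained = logical(0)))
  if (diff(rng) == 0) return(empty)
  norm <- (img - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm))
  mask <- EBImage::fillHull(EBImage::Image(norm > th))
  labels <- EBImage::imageData(EBImage::bwlabel(mask))
  storage.mode(labels) <- "integer"
  n <- max(labels)
  if (n == 0) return(empty)
  area <- tabulate(labels[labels > 0], nbins = n)
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  touches <- seq_len(n) %in% border
  nuclei <- data.frame(label = seq_len(n), area = area,
                       touches_border = touches,
                       retained = !touches & area >= min_area)
  list(labels = labels, nuclei = nuclei)
}

#' Detect spots as local intensity maxima within a nucleus
#'
#' Candidate pixels inside the nucleus mask at or above `min_intensity`
#' are visited in order of decreasing intensity (ties broken by smallest
#' (y, x)); a pixel becomes a spot centre -- its brightest pixel -- unless
#' it lies within `min_separation` of an already accepted centre.
#'
#' @param img Numeric matrix (projected FISH/IF channel).
#' @param mask Logical matrix: the nucleus pixels.
#' @param min_intensity Minimum centre intensity.
#' @param min_separation Minimum Euclidean distance between centres in
#'   pixels (default 2).
#' @return data.frame: x_px, y_px (integer pixel coordinates), intensity.
#' @export
detect_spots <- function(img, mask, min_intensity, min_separation = 2) {
  stopifnot(identical(dim(img), dim(mask)))
  if (!any(mask)) stop("nucleus mask is empty")
  idx <- which(mask & img >= min_intensity, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(x_px = integer(0), y_px = integer(0),
                      intensity = numeric(0)))
  inten <- img[idx]
  o <- order(-inten, idx[, 1], idx[, 2])
  idx <- idx[o, , drop = FALSE]
  inten <- inten[o]
  keep_y <- numeric(0); keep_x <- numeric(0); keep_i <- numeric(0)
  for (i in seq_len(nrow(idx))) {
    y <- idx[i, 1]; x <- idx[i, 2]
    if (length(keep_y) == 0 ||
        min((keep_y - y)^2 + (keep_x - x)^2) >= min_separation^2) {
      keep_y <- c(keep_y, y); keep_x <- c(keep_x, x)
      keep_i <- c(keep_i, inten[i])
    }
  }
  data.frame(x_px = as.integer(keep_x), y_px = as.integer(keep_y),
             intensity = keep_i)
}

#' Per-RNU1-spot minimum pairwise distances within a cell
#'
#' For every RNU1 FISH spot: the minimum Euclidean distance to any VGOI
#' spot (`d_gene`) and to any CB (`d_cb`); `d_cb_vgoi` is the minimum
#' CB-VGOI distance of the CB that realizes `d_cb` (used for the bridging
#' flag). Distances are in pixels, computed on the (possibly continuous)
#' centre coordinates.
#'
#' @param spots data.frame for ONE cell with columns channel, x_px, y_px.
#' @param rnu1,vgoi,cb Channel labels (defaults "RNU1", "VGOI", "CB").
#' @return data.frame: rnu1_spot, d_gene, d_cb, d_cb_vgoi. An ineligible
#'   cell (a channel with no spot) yields a zero-row data.frame carrying a
#'   `reason` attribute.
#' @export
spot_distances <- function(spots, rnu1 = "RNU1", vgoi = "VGOI", cb = "CB") {
  get <- function(ch) as.matrix(spots[spots$channel == ch,
                                      c("x_px", "y_px"), drop = FALSE])
  R <- get(rnu1); V <- get(vgoi); C <- get(cb)
  if (nrow(R) == 0 || nrow(V) == 0 || nrow(C) == 0) {
    out <- data.frame(rnu1_spot = integer(0), d_gene = numeric(0),
                      d_cb = numeric(0), d_cb_vgoi = numeric(0))
    attr(out, "reason") <- paste0(
      "missing_", paste(c(rnu1, vgoi, cb)[c(nrow(R), nrow(V),
                                            nrow(C)) == 0],
                        collapse = "+"))
    return(out)
  }
  dmat <- function(A, B)
    sqrt(outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2)
  rv <- dmat(R, V)
  rc <- dmat(R, C)
  cv <- dmat(C, V)
  nearest_cb <- apply(rc, 1, which.min)
  data.frame(rnu1_spot = seq_len(nrow(R)),
             d_gene = apply(rv, 1, min),
             d_cb = apply(rc, 1, min),
             d_cb_vgoi = apply(cv, 1, min)[nearest_cb])
}

#' Classify an RNU1 spot by its distance signature
#'
#' `CB_dependent` iff `d_gene <= gene_thresh` and `d_cb <= cb_thresh`;
#' `CB_independent` iff `d_gene <= gene_thresh` and `d_cb > cb_thresh`;
#' otherwise `none`. Exactly one of the three labels applies. The
#' bridging flag is orthogonal: `d_cb <= cb_thresh` and
#' `d_cb_vgoi <= cb_thresh`, evaluated on the CB realizing the RNU1-CB
#' minimum. Inclusion bounds are `<=`, the distal condition strict `>`.
#'
#' @param d_gene,d_cb,d_cb_vgoi Distances in pixels (vectorized, >= 0).
#' @param gene_thresh RNU1-VGOI threshold in px (default 3 = 0.96 um at
#'   320 nm/px).
#' @param cb_thresh RNU1-CB (and CB-VGOI) threshold in px (default 5 =
#'   1.6 um).
#' @return data.frame: label (factor CB_dependent/CB_independent/none),
#'   bridging (logical).
#' @export
classify_rnu1_spot <- function(d_gene, d_cb, d_cb_vgoi,
                               gene_thresh = 3, cb_thresh = 5) {
  if (any(c(d_gene, d_cb, d_cb_vgoi) < 0)) stop("distances must be >= 0")
  label <- ifelse(d_gene <= gene_thresh,
                  ifelse(d_cb <= cb_thresh, "CB_dependent",
                         "CB_independent"),
                  "none")
  data.frame(label = factor(label, levels = c("CB_dependent",
                                              "CB_independent", "none")),
             bridging = d_cb <= cb_thresh & d_cb_vgoi <= cb_thresh)
}

#' Classify every eligible cell's RNU1 spots in a spot table
#'
#' Applies [spot_distances()] and [classify_rnu1_spot()] per cell. Cells
#' lacking a spot in any of the three channels are ineligible and are
#' excluded (with a reason) from all downstream frequencies.
#'
#' @param spots data.frame: cell_id, channel, x_px, y_px (multiple cells).
#' @param gene_thresh,cb_thresh Thresholds in pixels.
#' @inheritParams spot_distances
#' @return List: `events` (data.frame: cell_id, rnu1_spot, d_gene, d_cb,
#'   d_cb_vgoi, label, bridging), `eligible_cells` (integer vector),
#'   `ineligible` (data.frame: cell_id, reason).
#' @export
classify_cells <- function(spots, gene_thresh = 3, cb_thresh = 5,
                           rnu1 = "RNU1", vgoi = "VGOI", cb = "CB") {
  ids <- unique(spots$cell_id)
  ev <- list(); inel <- list()
  for (id in ids) {
    d <- spot_distances(spots[spots$cell_id == id, , drop = FALSE],
                        rnu1 = rnu1, vgoi = vgoi, cb = cb)
    if (nrow(d) == 0) {
      inel[[length(inel) + 1]] <- data.frame(cell_id = id,
                                             reason = attr(d, "reason"))
      next
    }
    cl <- classify_rnu1_spot(d$d_gene, d$d_cb, d$d_cb_vgoi,
                             gene_thresh, cb_thresh)
    ev[[length(ev) + 1]] <- cbind(cell_id = id, d, cl)
  }
  list(events = if (length(ev)) do.call(rbind, ev) else NULL,
       eligible_cells = setdiff(ids, if (length(inel))
         do.call(rbind, inel)$cell_id else integer(0)),
       ineligible = if (length(inel)) do.call(rbind, inel) else
         data.frame(cell_id = integer(0), reason = character(0)))
}

#' Interaction frequency: percentage of cells with at least one event
#'
#' Computed over eligible cells only (cells lacking a CB or FISH signal
#' never enter numerator or denominator), with the binomial standard
#' error on the percentage scale.
#'
#' @param analysis Output of [classify_cells()].
#' @param event One of "CB_dependent", "CB_independent", "any_pair"
#'   (either pair label) or "bridging".
#' @return List: percent, se_percent, n_cells, n_event_cells. With zero
#'   eligible cells the percentage is NA (undefined, reported).
#' @export
interaction_frequency <- function(analysis,
                                  event = c("CB_dependent",
                                            "CB_independent", "any_pair",
                                            "bridging")) {
  event <- match.arg(event)
  n <- length(analysis$eligible_cells)
  if (n == 0)
    return(list(percent = NA_real_, se_percent = NA_real_,
                n_cells = 0L, n_event_cells = 0L))
  ev <- analysis$events
  hit <- switch(event,
                any_pair = ev$label %in% c("CB_dependent", "CB_independent"),
                bridging = ev$bridging,
                ev$label == event)
  cells_with <- unique(ev$cell_id[hit])
  k <- sum(analysis$eligible_cells %in% cells_with)
  p <- k / n
  list(percent = 100 * p, se_percent = 100 * sqrt(p * (1 - p) / n),
       n_cells = n, n_event_cells = k)
}

#' Score a locus position relative to a territory mask
#'
#' `interior` when the spot lies inside the mask farther than
#' `edge_width` from its boundary, `periphery` when within `edge_width`
#' of the boundary (either side), `exterior` otherwise. The boundary is
#' the set of mask pixels with a 4-neighbour outside the mask (or on the
#' image edge); distance is Euclidean to the nearest boundary pixel
#' centre.
#'
#' @param x,y Spot centre in pixel coordinates (continuous allowed).
#' @param mask Logical matrix: the territory.
#' @param edge_width Edge zone half-width in pixels.
#' @return One of "interior", "periphery", "exterior".
#' @export
locus_position_class <- function(x, y, mask, edge_width) {
  if (!any(mask)) stop("territory mask is empty")
  ny <- nrow(mask); nx <- ncol(mask)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- mask
  inner <- pad[2:(ny + 1), 2:(nx + 1)]
  nb <- pad[1:ny, 2:(nx + 1)] & pad[3:(ny + 2), 2:(nx + 1)] &
    pad[2:(ny + 1), 1:nx] & pad[2:(ny + 1), 3:(nx + 2)]
  boundary <- which(inner & !nb, arr.ind = TRUE)
  d <- min(sqrt((boundary[, 1] - y)^2 + (boundary[, 2] - x)^2))
  iy <- round(y); ix <- round(x)
  inside <- iy >= 1 && iy <= ny && ix >= 1 && ix <= nx && mask[iy, ix]
  if (d <= edge_width) "periphery"
  else if (inside) "interior"
  else "exterior"
}
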