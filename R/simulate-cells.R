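#' Describe a synthetic cell population for FISH co-localization
#'
#' Parameters of the generator that emulates high-content DNA FISH/IF
#' fields: nuclei with variable radius, a small number of Cajal bodies
#' (CBs) per cell, FISH spots for the RNU1 array and a variable gene of
#' interest (VGOI), and planted CB-dependent / CB-independent gene-pairing
#' configurations at known rates.
#'
#' `p_dep` is the probability that a cell carries a planted CB-clustered
#' triplet (RNU1 within `cb_thresh` of a CB and VGOI within `gene_thresh`
#' of that RNU1 spot); `p_indep` the probability of a planted CB-distal
#' RNU1--VGOI pair. Non-planted spots are placed with exclusion margins so
#' that no accidental pair events arise: the planted rates are exact
#' binomial ground truth for the downstream classifier.
#'
#' @param n_cells Number of cells.
#' @param nucleus_radius Mean and sd of the nuclear radius in pixels.
#' @param alleles_per_gene Named probability vector over allele counts per
#'   gene (names are counts).
#' @param cbs_per_cell Named probability vector over CB counts per cell.
#' @param p_dep,p_indep Planting probabilities in [0, 1].
#' @param pixel_size Pixel size in nm (default 320).
#' @param gene_thresh,cb_thresh Classifier thresholds in pixels used to
#'   guarantee the planted configurations (defaults 3 and 5).
#' @return An object of class `cell_population_model`.
#' @export
cell_population_model <- function(n_cells = 1000,
                                  nucleus_radius = c(mean = 40, sd = 4),
                                  alleles_per_gene = c("2" = 0.25, "3" = 0.5,
                                                       "4" = 0.25),
                                  cbs_per_cell = c("1" = 0.2, "2" = 0.35,
                                                   "3" = 0.3, "4" = 0.15),
                                  p_dep = 0.3, p_indep = 0.1,
                                  pixel_size = 320,
                                  gene_thresh = 3, cb_thresh = 5) {
  stopifnot(n_cells >= 1, pixel_size > 0,
            p_dep >= 0, p_dep <= 1, p_indep >= 0, p_indep <= 1)
  for (p in list(alleles_per_gene, cbs_per_cell))
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("count distributions must be named probability vectors summing to 1")
  structure(as.list(environment()), class = "cell_population_model")
}

# uniform point in a disc of radius r around (cx, cy)
.runif_disc <- function(n, cx, cy, r) {
  th <- stats::runif(n, 0, 2 * pi)
  rr <- r * sqrt(stats::runif(n))
  cbind(x = cx + rr * cos(th), y = cy + rr * sin(th))
}

.dist2 <- function(p, q) sqrt((p[, 1] - q[1])^2 + (p[, 2] - q[2])^2)

# rejection-sample one point in the nucleus satisfying a predicate
.place <- function(cx, cy, r, ok, max_try = 2000) {
  for (i in seq_len(max_try)) {
    p <- .runif_disc(1, cx, cy, r)
    if (ok(p)) return(p)
  }
  NULL
}

#' Simulate per-cell FISH/IF spot tables with planted pairing events
#'
#' For each cell, draws a nucleus, CB spots and allele spots for RNU1 and
#' the VGOI; with probability `p_dep` plants a CB-dependent triplet and
#' with probability `p_indep` a CB-independent pair (see
#' [cell_population_model()]). Spot coordinates are continuous; rounding to
#' integer pixels happens only at rendering, so sub-pixel boundary cases
#' survive into the classifier.
#'
#' Cells whose nucleus is too small to satisfy the exclusion constraints
#' are regenerated with a fresh radius; after repeated failure the cell is
#' dropped with a logged reason (never silently mislabelled).
#'
#' @param model A [cell_population_model()].
#' @param seed Integer seed.
#' @return List with `spots` (data.frame: cell_id, channel, x_px, y_px,
#'   intensity), `cells` (data.frame of ground truth: cell_id, radius, cx,
#'   cy, n_cb, planted_dep, planted_indep) and `dropped` (data.frame:
#'   cell_id, reason).
#' @export
simulate_cell_spots <- function(model, seed = 1L) {
  stopifnot(inherits(model, "cell_population_model"))
  withr::local_seed(seed)
  gt <- model$gene_thresh
  ct <- model$cb_thresh
  margin <- 0.5

  spots <- vector("list", model$n_cells)
  cells <- vector("list", model$n_cells)
  dropped <- list()
  draw_count <- function(p) as.integer(sample(names(p), 1, prob = p))

  for (i in seq_len(model$n_cells)) {
    dep <- stats::runif(1) < model$p_dep
    indep <- stats::runif(1) < model$p_indep
    n_cb <- draw_count(model$cbs_per_cell)
    if (dep && n_cb == 0) n_cb <- 1L  # a planted CB triplet needs a CB
    n_rnu1 <- draw_count(model$alleles_per_gene)
    n_vgoi <- draw_count(model$alleles_per_gene)
    n_rnu1 <- max(n_rnu1, dep + indep)  # planted events use distinct spots

    placed <- NULL
    for (attempt in 1:5) {
      r <- max(stats::rnorm(1, model$nucleus_radius[["mean"]],
                            model$nucleus_radius[["sd"]]), 15)
      cx <- cy <- ceiling(r) + 5
      rin <- r - 1  # keep spot centres off the nuclear rim
      cb <- .runif_disc(n_cb, cx, cy, rin)
      rnu1 <- matrix(numeric(0), 0, 2)
      vgoi <- matrix(numeric(0), 0, 2)
      fail <- FALSE

      add <- function(m, p) rbind(m, p)
      mind <- function(p, m) if (nrow(m) == 0) Inf else
        min(sqrt((m[, 1] - p[1, 1])^2 + (m[, 2] - p[1, 2])^2))
      cb_dist <- function(p) if (nrow(cb) == 0) Inf else min(.dist2(cb, c(p)))

      if (dep) {
        # RNU1 near a CB, VGOI near that RNU1
        k <- sample.int(n_cb, 1)
        p1 <- .place(cx, cy, rin, function(p)
          .dist2(p, cb[k, ]) <= ct - margin)
        p2 <- if (is.null(p1)) NULL else .place(cx, cy, rin, function(p)
          .dist2(p, p1[1, ]) <= gt - margin)
        if (is.null(p1) || is.null(p2)) fail <- TRUE else {
          rnu1 <- add(rnu1, p1); vgoi <- add(vgoi, p2)
        }
      }
      if (!fail && indep) {
        # RNU1 far from every CB, VGOI near that RNU1
        p1 <- .place(cx, cy, rin, function(p) cb_dist(p) > ct + margin)
        p2 <- if (is.null(p1)) NULL else .place(cx, cy, rin, function(p)
          .dist2(p, p1[1, ]) <= gt - margin && cb_dist(p) > ct + margin)
        if (is.null(p1) || is.null(p2)) fail <- TRUE else {
          rnu1 <- add(rnu1, p1); vgoi <- add(vgoi, p2)
        }
      }
      # neutral spots: excluded from the other gene channel by > gene_thresh
      # so they never create accidental pair events
      while (!fail && nrow(rnu1) < n_rnu1) {
        p <- .place(cx, cy, rin, function(p)
          mind(p, vgoi) > gt + margin)
        if (is.null(p)) fail <- TRUE else rnu1 <- add(rnu1, p)
      }
      while (!fail && nrow(vgoi) < n_vgoi) {
        p <- .place(cx, cy, rin, function(p)
          mind(p, rnu1) > gt + margin)
        if (is.null(p)) fail <- TRUE else vgoi <- add(vgoi, p)
      }
      if (!fail) {
        placed <- list(cb = cb, rnu1 = rnu1, vgoi = vgoi, r = r,
                       cx = cx, cy = cy)
        break
      }
    }
    if (is.null(placed)) {
      dropped[[length(dropped) + 1]] <-
        data.frame(cell_id = i, reason = "nucleus_too_small")
      next
    }
    mk <- function(ch, m) if (nrow(m) == 0) NULL else
      data.frame(cell_id = i, channel = ch, x_px = m[, 1], y_px = m[, 2],
                 intensity = stats::runif(nrow(m), 0.7, 1))
    spots[[i]] <- rbind(mk("RNU1", placed$rnu1), mk("VGOI", placed$vgoi),
                        mk("CB", placed$cb))
    cells[[i]] <- data.frame(cell_id = i, radius = placed$r,
                             cx = placed$cx, cy = placed$cy, n_cb = n_cb,
                             planted_dep = dep, planted_indep = indep)
  }
  list(spots = do.call(rbind, spots),
       cells = do.call(rbind, cells),
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(cell_id = integer(0), reason = character(0)))
}

#' Render point spots into an intensity image
#'
#' Draws each spot as an isotropic 2D Gaussian (amplitude scaled by the
#' spot's intensity) on a `dim[1] x dim[2]` pixel grid, optionally with
#' Poisson shot noise. Row index is y, column index is x.
#'
#' @param coords data.frame with `x_px`, `y_px` and optionally `intensity`.
#' @param dim Image dimensions `c(ny, nx)`.
#' @param sigma Gaussian sigma in pixels.
#' @param amplitude Peak photon count of a unit-intensity spot.
#' @param background Constant background level.
#' @param poisson_noise Apply Poisson noise?
#' @param seed Seed used when `poisson_noise` is TRUE.
#' @return Numeric matrix `ny x nx`.
#' @export
render_spots <- function(coords, dim, sigma = 1.2, amplitude = 200,
                         background = 10, poisson_noise = FALSE, seed = 1L) {
  img <- matrix(background, dim[1], dim[2])
  if (!is.null(coords) && nrow(coords)) {
    inten <- if ("intensity" %in% names(coords)) coords$intensity else
      rep(1, nrow(coords))
    yy <- matrix(seq_len(dim[1]), dim[1], dim[2])
    xx <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
    for (i in seq_len(nrow(coords))) {
      img <- img + amplitude * inten[i] *
        exp(-((xx - coords$x_px[i])^2 + (yy - coords$y_px[i])^2) /
              (2 * sigma^2))
    }
  }
  if (poisson_noise) {
    withr::local_seed(seed)
    img[] <- stats::rpois(length(img), img)
  }
  img
}

#' Render disc nuclei into a nuclear-stain image
#'
#' @param nuclei data.frame with `cx`, `cy`, `radius` (pixels).
#' @param dim Image dimensions `c(ny, nx)`.
#' @param level Foreground intensity of the disc (background 0).
#' @return Numeric matrix `ny x nx`.
#' @export
render_nuclei <- function(nuclei, dim, level = 1) {
  img <- matrix(0, dim[1], dim[2])
  yy <- matrix(seq_len(dim[1]), dim[1], dim[2])
  xx <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  for (i in seq_len(nrow(nuclei))) {
    inside <- (xx - nuclei$cx[i])^2 + (yy - nuclei$cy[i])^2 <=
      nuclei$radius[i]^2
    img[inside] <- level
  }
  img
}
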