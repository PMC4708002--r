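#' Insert-length model
#'
#' Sonicated paired-end libraries have insert lengths well approximated by
#' a Gaussian N(L, sigma); the model parameterizes both the forward
#' diffusion operator and its conjugate.
#'
#' @param mean mean insert length L (bp)
#' @param sd insert-length standard deviation sigma (bp)
#' @return object of class `insert_model`
#' @export
insert_model <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "insert_model")
}

#' Robust insert-model estimate from accordant pairs
#'
#' Median and scaled MAD (1.4826 x median absolute deviation) of the
#' template lengths of proper pairs; robust against a small admixture of
#' mismapped outliers. The sd is floored at 1 bp.
#'
#' @param pairs pair table with `proper` and `tlen` columns
#' @param min_pairs minimum number of proper pairs required (default 1000)
#' @return an `insert_model`
#' @export
estimate_insert_model <- function(pairs, min_pairs = 1000L) {
  tl <- abs(pairs$tlen[pairs$proper & !is.na(pairs$tlen)])
  if (length(tl) < min_pairs)
    stop("too few proper pairs to estimate the insert model; ",
         "supply insert mean/sd in the configuration")
  m <- median(tl)
  s <- max(mad(tl), 1)
  insert_model(m, s)
}

#' Per-cluster grid over G x G
#'
#' A dense grid of discordant-pair counts around one cluster. Rows index
#' the first (x) coordinate, columns the second (y); `bin` genome bases
#' per cell. Padding of at least L + 4 sigma around the bounding box keeps
#' the diffusion operators' mass on the grid.
#'
#' @param points cluster points (`x`, `y` global coordinates)
#' @param model an `insert_model`
#' @param class orientation class of the cluster
#' @param bin bin size in bp (default 1)
#' @return object of class `cluster_grid`: `values` matrix, `origin`
#'   (global coordinates of cell \[1,1\]), `bin`, `class`
#' @export
cluster_grid <- function(points, model, class, bin = 1L) {
  stopifnot(nrow(points) >= 1)
  pad <- ceiling((model$mean + 4 * model$sd) / bin) + 2L
  x0 <- floor(min(points$x) / bin) - pad
  y0 <- floor(min(points$y) / bin) - pad
  nr <- floor(max(points$x) / bin) + pad + 1L - x0
  nc <- floor(max(points$y) / bin) + pad + 1L - y0
  v <- matrix(0, nr, nc)
  i <- floor(points$x / bin) - x0 + 1L
  j <- floor(points$y / bin) - y0 + 1L
  for (k in seq_along(i)) v[i[k], j[k]] <- v[i[k], j[k]] + 1
  structure(list(values = v, origin = c(x = x0 * bin, y = y0 * bin),
                 bin = as.integer(bin), class = class),
            class = "cluster_grid")
}

# shared parameterization of the discretized operator factors
op_params <- function(grid, model) {
  geo <- class_geometry(grid$class)
  list(h = as.integer(round(model$mean / 2 / grid$bin)),
       sigma_axis = model$sd / sqrt(2) / grid$bin,
       d = geo$d, antidiag = geo$antidiag)
}

check_mass <- function(before, after, what) {
  if (before > 0 && (before - after) / before > 1e-3)
    stop("insufficient grid padding: ", what,
         " lost ", format((before - after) / before), " of total mass")
}

#' Forward operator: breakpoint distribution to discordant-pair
#' distribution
#'
#' Applies the composition of a parallel translation by L/2 (in the
#' direction of the cluster's orientation class), a uniform diffusion of
#' length +/- L/2 along the class's diagonal, and a Gaussian diffusion of
#' scale sigma. A unit mass at a junction becomes the sampling density of
#' the discordant pairs the junction generates.
#'
#' @param grid a `cluster_grid` holding a breakpoint indicator
#' @param model an `insert_model`
#' @return a `cluster_grid` holding the transformed values
#' @export
apply_forward <- function(grid, model) {
  p <- op_params(grid, model)
  v <- grid$values
  m0 <- sum(v)
  v <- grid_translate_cpp(v, p$d[1] * p$h, p$d[2] * p$h)
  v <- grid_diag_box_cpp(v, p$h, p$antidiag)
  v <- grid_gauss_cpp(v, p$sigma_axis)
  check_mass(m0, sum(v), "forward operator")
  grid$values <- v
  grid
}

#' Conjugate operator: discordant pairs back towards their breakpoint
#'
#' The adjoint of [apply_forward()]: the Gaussian and uniform factors are
#' self-adjoint, the translation is reversed. Applied to the empirical
#' discordant-pair counts y it yields z = A* y, whose large values locate
#' the breakpoint region; for a single pair the argmax of z sits at the
#' pair displaced by L/2 against the class direction.
#'
#' @inheritParams apply_forward
#' @return a `cluster_grid` holding z = A* y
#' @export
apply_conjugate <- function(grid, model) {
  p <- op_params(grid, model)
  v <- grid$values
  m0 <- sum(v)
  v <- grid_translate_cpp(v, -p$d[1] * p$h, -p$d[2] * p$h)
  v <- grid_diag_box_cpp(v, p$h, p$antidiag)
  v <- grid_gauss_cpp(v, p$sigma_axis)
  check_mass(m0, sum(v), "conjugate operator")
  grid$values <- v
  grid
}

#' Normal operator A* A
#'
#' The composition of the forward operator and its conjugate: the two
#' translations cancel, the uniform diffusion acts twice, and the two
#' Gaussian factors compose into one of sqrt(2) times the scale — a
#' symmetric blurring with no net displacement, positive semi-definite
#' and self-adjoint.
#'
#' @inheritParams apply_forward
#' @return a `cluster_grid`
#' @export
normal_operator <- function(grid, model) {
  p <- op_params(grid, model)
  v <- grid$values
  m0 <- sum(v)
  v <- grid_diag_box_cpp(v, p$h, p$antidiag)
  v <- grid_diag_box_cpp(v, p$h, p$antidiag)
  v <- grid_gauss_cpp(v, p$sigma_axis * sqrt(2))
  check_mass(m0, sum(v), "normal operator")
  grid$values <- v
  grid
}

#' Threshold a conjugate-transformed grid into breakpoint regions
#'
#' Breakpoint regions are the connected components of the set where
#' z is significantly large, operationalized as z >= tau * max(z).
#' Each component is returned as a bounding box with its two 1-D
#' projections: region A on the first (smaller-coordinate) axis and
#' region B on the second.
#'
#' @param grid a `cluster_grid` holding z = A* y (see [apply_conjugate()])
#' @param tau relative threshold in (0, 1\] (default 0.5)
#' @return `data.table`, one row per region: projections `a_lo`, `a_hi`,
#'   `b_lo`, `b_hi` (global coordinates, inclusive), `peak` (max z),
#'   `peak_x`, `peak_y` (argmax), `class`
#' @export
predict_regions <- function(grid, tau = 0.5) {
  v <- grid$values
  mx <- max(v)
  empty <- data.table(a_lo = numeric(0), a_hi = numeric(0),
                      b_lo = numeric(0), b_hi = numeric(0),
                      peak = numeric(0), peak_x = numeric(0),
                      peak_y = numeric(0), class = character(0))
  if (mx <= 0) return(empty)
  lab <- grid_label_cpp(v >= tau * mx)
  am <- which(v == mx, arr.ind = TRUE)[1, ]
  comps <- sort(unique(lab[lab > 0]))
  out <- lapply(comps, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    pk <- max(v[lab == k])
    pkidx <- idx[which.max(v[idx]), ]
    data.table(
      a_lo = grid$origin["x"] + (min(idx[, 1]) - 1) * grid$bin,
      a_hi = grid$origin["x"] + (max(idx[, 1]) - 1) * grid$bin + grid$bin - 1,
      b_lo = grid$origin["y"] + (min(idx[, 2]) - 1) * grid$bin,
      b_hi = grid$origin["y"] + (max(idx[, 2]) - 1) * grid$bin + grid$bin - 1,
      peak = pk,
      peak_x = grid$origin["x"] + (pkidx[1] - 1) * grid$bin,
      peak_y = grid$origin["y"] + (pkidx[2] - 1) * grid$bin,
      class = grid$class)
  })
  rbindlist(out)[order(-peak)]
}

#' Predict breakpoint regions for every retained cluster
#'
#' Builds the per-cluster grid, applies the conjugate operator and
#' thresholds it, carrying the cluster's orientation class and somatic
#' label onto each region.
#'
#' @param points clustered points (see [cluster_points()])
#' @param clusters cluster summary (see [summarize_clusters()])
#' @param model an `insert_model`
#' @param tau relative threshold (default 0.5)
#' @param bin grid bin size in bp (default 1)
#' @return `data.table` of regions with `cluster`, `somatic`, `n_pairs`
#'   columns added
#' @export
predict_cluster_regions <- function(points, clusters, model, tau = 0.5,
                                    bin = 1L) {
  out <- vector("list", nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    cid <- clusters$cluster[i]
    pts <- points[cluster == cid]
    g <- cluster_grid(pts, model, clusters$class[i], bin = bin)
    z <- apply_conjugate(g, model)
    r <- predict_regions(z, tau = tau)
    if (nrow(r) > 0) {
      r[, cluster := cid]
      r[, somatic := clusters$somatic[i]]
      r[, n_pairs := clusters$n[i]]
    }
    out[[i]] <- r
  }
  rbindlist(out)
}
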