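# Stratified KDE grids for continuous-variable reconstruction.
#
# The empirical distribution of each continuous variable is estimated with
# a Gaussian kernel; its CDF is evaluated analytically on a discretised
# grid (mean of normal CDFs centred at the observations) and differenced
# into per-subinterval probability masses. Band reconstruction then runs a
# two-stage draw: pick a grid subinterval inside the band proportionally
# to its mass, then draw uniformly within it.

# mean of Gaussian CDFs, chunked to bound memory
kde_cdf_eval <- function(x_eval, data, bw, chunk = 4e6) {
  n <- length(data)
  step <- max(1L, floor(chunk / length(x_eval)))
  acc <- numeric(length(x_eval))
  for (s in seq(1, n, by = step)) {
    d <- data[s:min(s + step - 1, n)]
    acc <- acc + rowSums(stats::pnorm(outer(x_eval, d, "-") / bw))
  }
  acc / n
}

kde_bandwidth <- function(x) {
  if (length(x) < 2 || stats::sd(x) == 0) return(0)
  bw <- tryCatch(stats::bw.nrd0(x), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) bw <- stats::sd(x) * length(x)^(-0.2)
  bw
}

#' Fit a stratified marginal KDE grid
#'
#' Per stratum, a Gaussian-kernel CDF (normal-reference bandwidth) is
#' evaluated on a regular grid covering the pooled data range and
#' differenced into subinterval masses, renormalised to sum to 1. Strata
#' with fewer than `min_stratum_n` observations fall back to the pooled
#' grid and are flagged. Constant-valued input is handled as a point mass.
#'
#' @param values Numeric observations (NAs dropped).
#' @param strata_labels Optional stratum label per observation.
#' @param grid_resolution Grid step in the variable's units.
#' @param min_stratum_n Minimum stratum size before pooled fallback.
#' @param max_grid_points Cap on grid size; the resolution is coarsened to
#'   respect it.
#' @param variable Name carried for reporting.
#' @return A `kde_grid`: grid points, per-stratum interval masses (plus a
#'   pooled row), bandwidths and fallback flags.
#' @export
fit_marginal_kde <- function(values, strata_labels = NULL, grid_resolution = 1,
                             min_stratum_n = 30L, max_grid_points = 2000L,
                             variable = "x") {
  keep <- is.finite(values)
  if (!is.null(strata_labels)) {
    strata_labels <- as.character(strata_labels)[keep]
  }
  values <- values[keep]
  if (length(values) == 0) stop("no finite observations for '", variable, "'")
  rng <- range(values)
  degenerate <- rng[1] == rng[2]
  if (degenerate) {
    grid <- c(rng[1], rng[1] + grid_resolution)
  } else {
    res <- grid_resolution
    if ((rng[2] - rng[1]) / res > max_grid_points)
      res <- (rng[2] - rng[1]) / max_grid_points
    pad <- 3 * kde_bandwidth(values)
    lo <- floor((rng[1] - pad) / res) * res
    hi <- ceiling((rng[2] + pad) / res) * res
    grid <- seq(lo, hi, by = res)
    if (grid[length(grid)] < hi) grid <- c(grid, hi)
  }
  n_int <- length(grid) - 1
  mass_of <- function(x) {
    if (length(x) == 0) return(rep(0, n_int))
    bw <- kde_bandwidth(x)
    if (bw == 0) {
      idx <- pmin(pmax(findInterval(x, grid, rightmost.closed = TRUE), 1), n_int)
      tabulate(idx, n_int) / length(x)
    } else {
      cdf <- kde_cdf_eval(grid, x, bw)
      m <- pmax(diff(cdf), 0)
      if (sum(m) <= 0) rep(1 / n_int, n_int) else m / sum(m)
    }
  }
  pooled <- mass_of(values)
  strata <- character(0)
  masses <- matrix(pooled, nrow = 1,
                   dimnames = list("(pooled)", NULL))
  fallback <- character(0)
  bandwidths <- c("(pooled)" = kde_bandwidth(values))
  if (!is.null(strata_labels)) {
    strata <- sort(unique(strata_labels))
    extra <- matrix(0, length(strata), n_int)
    rownames(extra) <- strata
    for (s in strata) {
      x <- values[strata_labels == s]
      if (length(x) < min_stratum_n) {
        extra[s, ] <- pooled
        fallback <- c(fallback, s)
        bandwidths[s] <- bandwidths[["(pooled)"]]
      } else {
        extra[s, ] <- mass_of(x)
        bandwidths[s] <- kde_bandwidth(x)
      }
    }
    masses <- rbind(masses, extra)
  }
  structure(list(variable = variable, grid = grid, masses = masses,
                 strata = strata, fallback_strata = fallback,
                 bandwidths = bandwidths, degenerate = degenerate),
            class = "kde_grid")
}

#' @export
print.kde_grid <- function(x, ...) {
  cat("<kde_grid> '", x$variable, "': ", length(x$grid) - 1,
      " subintervals over [", format(x$grid[1]), ", ",
      format(x$grid[length(x$grid)]), "]", sep = "")
  if (length(x$strata) > 0)
    cat(", ", length(x$strata), " strata (",
        length(x$fallback_strata), " pooled fallbacks)", sep = "")
  cat("\n")
  invisible(x)
}

grid_masses_for <- function(kde_grid, stratum = NULL) {
  key <- if (is.null(stratum) || !stratum %in% rownames(kde_grid$masses))
    "(pooled)" else stratum
  kde_grid$masses[key, ]
}

#' Two-stage draw of values inside a band from a KDE grid
#'
#' Stage 1 picks a grid subinterval overlapping the band proportionally to
#' its KDE mass (edge subintervals prorated by overlap fraction); stage 2
#' draws uniformly inside the overlap, so every value lies inside the
#' band. A band with zero total KDE mass falls back to a uniform draw over
#' the whole band; the fallback count is returned as attribute
#' `"n_fallback"`.
#'
#' @param band Numeric `c(lo, hi)`, the (left-closed) band.
#' @param kde_grid A [fit_marginal_kde()] result.
#' @param stratum Optional stratum name.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_within_band <- function(band, kde_grid, stratum = NULL, n = 1) {
  lo <- band[1]; hi <- band[2]
  g <- kde_grid$grid
  if (hi <= g[1] || lo >= g[length(g)]) {
    out <- stats::runif(n, lo, hi)
    attr(out, "n_fallback") <- n
    return(out)
  }
  m <- grid_masses_for(kde_grid, stratum)
  g_lo <- g[-length(g)]; g_hi <- g[-1]
  ov_lo <- pmax(g_lo, lo); ov_hi <- pmin(g_hi, hi)
  frac <- pmax(ov_hi - ov_lo, 0) / (g_hi - g_lo)
  w <- m * frac
  tot <- sum(w)
  if (tot <= 0) {
    out <- stats::runif(n, lo, hi)
    attr(out, "n_fallback") <- n
    return(out)
  }
  pick <- sample.int(length(w), n, replace = TRUE, prob = w)
  out <- stats::runif(n, ov_lo[pick], ov_hi[pick])
  attr(out, "n_fallback") <- 0L
  out
}

#' Fit a joint KDE grid for a correlated pair of variables
#'
#' The joint CDF (product-Gaussian kernel, normal-reference bandwidth per
#' dimension) is evaluated on the grid and converted to per-cell masses by
#' the inclusion-exclusion principle; tiny negative numerical residues are
#' clipped to zero and the cells renormalised.
#'
#' @param x,y Paired observations (rows with any NA dropped).
#' @param grid_resolution_x,grid_resolution_y Grid steps.
#' @param max_grid_points Per-dimension cap on grid size.
#' @param variables Length-2 names carried for reporting.
#' @return A `kde_joint_grid` with the CDF grid, cell masses and the two
#'   implied marginal interval-mass vectors.
#' @export
fit_joint_kde <- function(x, y, grid_resolution_x = 1, grid_resolution_y = 1,
                          max_grid_points = 400L,
                          variables = c("x", "y")) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("need at least 2 complete pairs")
  mk_grid <- function(v, res) {
    rng <- range(v)
    if ((rng[2] - rng[1]) / res > max_grid_points)
      res <- (rng[2] - rng[1]) / max_grid_points
    pad <- 3 * kde_bandwidth(v)
    seq(floor((rng[1] - pad) / res) * res,
        ceiling((rng[2] + pad) / res) * res, by = res)
  }
  gx <- mk_grid(x, grid_resolution_x)
  gy <- mk_grid(y, grid_resolution_y)
  bx <- kde_bandwidth(x); by <- kde_bandwidth(y)
  if (bx == 0 || by == 0) {
    # degenerate dimension: histogram masses
    ix <- pmin(pmax(findInterval(x, gx, rightmost.closed = TRUE), 1),
               length(gx) - 1)
    iy <- pmin(pmax(findInterval(y, gy, rightmost.closed = TRUE), 1),
               length(gy) - 1)
    cells <- matrix(0, length(gx) - 1, length(gy) - 1)
    for (i in seq_along(ix)) cells[ix[i], iy[i]] <- cells[ix[i], iy[i]] + 1
    cells <- cells / sum(cells)
    Fg <- apply(apply(cells, 2, cumsum), 1, cumsum)
    Fg <- rbind(0, cbind(0, t(Fg)))
  } else {
    Phx <- stats::pnorm(outer(gx, x, "-") / bx)
    Phy <- stats::pnorm(outer(gy, y, "-") / by)
    Fg <- (Phx %*% t(Phy)) / length(x)
    cells <- Fg[-1, -1, drop = FALSE] - Fg[-nrow(Fg), -1, drop = FALSE] -
      Fg[-1, -ncol(Fg), drop = FALSE] +
      Fg[-nrow(Fg), -ncol(Fg), drop = FALSE]
    cells <- pmax(cells, 0)
    cells <- cells / sum(cells)
  }
  structure(list(variables = variables, grid_x = gx, grid_y = gy,
                 cdf = Fg, cell_mass = cells,
                 marginal_x = rowSums(cells), marginal_y = colSums(cells),
                 bandwidths = c(x = bx, y = by)),
            class = "kde_joint_grid")
}

#' Rectangle probability from a joint CDF grid by inclusion-exclusion
#'
#' For a rectangle `(a, b] x (c, d]` with corners on the grid, returns
#' `F(b,d) - F(a,d) - F(b,c) + F(a,c)`, clipped at 0 against numerical
#' residue.
#'
#' @param joint A `kde_joint_grid` (or any list with `grid_x`, `grid_y`
#'   and a `cdf` matrix over them).
#' @param x_interval,y_interval Numeric `c(lo, hi)` lying on the grid.
#' @return Nonnegative mass.
#' @export
joint_interval_mass <- function(joint, x_interval, y_interval) {
  ix <- match_grid(joint$grid_x, x_interval)
  iy <- match_grid(joint$grid_y, y_interval)
  m <- joint$cdf[ix[2], iy[2]] - joint$cdf[ix[1], iy[2]] -
    joint$cdf[ix[2], iy[1]] + joint$cdf[ix[1], iy[1]]
  max(m, 0)
}

match_grid <- function(grid, interval) {
  idx <- vapply(interval, function(v) {
    i <- which(abs(grid - v) < 1e-8 * max(1, abs(v)))
    if (length(i) == 0) stop("interval endpoint ", v, " is not on the grid")
    i[1]
  }, integer(1))
  if (idx[2] <= idx[1]) stop("empty interval")
  idx
}

#' Joint two-stage draw inside a band rectangle
#'
#' A grid cell inside the `x_band` x `y_band` rectangle is chosen
#' proportionally to its inclusion-exclusion mass (edge cells prorated by
#' overlap area fraction), then the point is drawn uniformly inside the
#' cell overlap. A zero-mass rectangle falls back to independent marginal
#' draws within each band (flagged via attribute `"n_fallback"`).
#'
#' @param x_band,y_band Numeric `c(lo, hi)` bands.
#' @param joint_grid A [fit_joint_kde()] result.
#' @param n Number of draws.
#' @return A list with numeric vectors `x` and `y` of length `n`.
#' @export
sample_joint_within_bands <- function(x_band, y_band, joint_grid, n = 1) {
  gx <- joint_grid$grid_x; gy <- joint_grid$grid_y
  fx_lo <- pmax(gx[-length(gx)], x_band[1])
  fx_hi <- pmin(gx[-1], x_band[2])
  fy_lo <- pmax(gy[-length(gy)], y_band[1])
  fy_hi <- pmin(gy[-1], y_band[2])
  fx <- pmax(fx_hi - fx_lo, 0) / diff(gx)
  fy <- pmax(fy_hi - fy_lo, 0) / diff(gy)
  W <- joint_grid$cell_mass * outer(fx, fy)
  tot <- sum(W)
  if (tot <= 0) {
    mx <- structure(list(variable = joint_grid$variables[1], grid = gx,
                         masses = matrix(joint_grid$marginal_x /
                                           max(sum(joint_grid$marginal_x), 1e-300),
                                         nrow = 1,
                                         dimnames = list("(pooled)", NULL)),
                         strata = character(0)), class = "kde_grid")
    my <- structure(list(variable = joint_grid$variables[2], grid = gy,
                         masses = matrix(joint_grid$marginal_y /
                                           max(sum(joint_grid$marginal_y), 1e-300),
                                         nrow = 1,
                                         dimnames = list("(pooled)", NULL)),
                         strata = character(0)), class = "kde_grid")
    xs <- sample_within_band(x_band, mx, n = n)
    ys <- sample_within_band(y_band, my, n = n)
    return(structure(list(x = as.numeric(xs), y = as.numeric(ys)),
                     n_fallback = n))
  }
  pick <- sample.int(length(W), n, replace = TRUE, prob = as.vector(W))
  ci <- (pick - 1) %% nrow(W) + 1
  cj <- (pick - 1) %/% nrow(W) + 1
  structure(list(x = stats::runif(n, fx_lo[ci], fx_hi[ci]),
                 y = stats::runif(n, fy_lo[cj], fy_hi[cj])),
            n_fallback = 0L)
}
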