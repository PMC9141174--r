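#' Build a contiguity weight matrix on a grid
#'
#' Rook (4-neighbour) or queen (8-neighbour) adjacency among the valid cells
#' of a regular grid, with optional row standardization (each row of weights
#' sums to 1). Nodata cells are removed from the weight graph entirely;
#' valid cells left without any valid neighbour are flagged isolated and
#' excluded from the statistics.
#'
#' @param valid_mask Logical matrix, `TRUE` = cell participates.
#' @param scheme `"queen"` (default) or `"rook"`.
#' @param standardization `"row"` (default) or `"binary"`.
#' @return A `weight_matrix`: `cells` (grid indices of valid cells),
#'   `neighbors` (list of integer positions into `cells`), `weights`
#'   (list of numeric weights), `isolated` (logical), `dim`, `scheme`,
#'   `standardization`.
#' @export
build_weights <- function(valid_mask, scheme = c("queen", "rook"),
                          standardization = c("row", "binary")) {
  scheme <- match.arg(scheme)
  standardization <- match.arg(standardization)
  nr <- nrow(valid_mask); nc <- ncol(valid_mask)
  cells <- which(valid_mask)
  if (length(cells) < 2) stop("need at least 2 valid cells")
  pos <- matrix(NA_integer_, nr, nc)
  pos[cells] <- seq_along(cells)
  offs <- if (scheme == "rook") {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  }
  rws <- ((cells - 1L) %% nr) + 1L
  cls <- ((cells - 1L) %/% nr) + 1L
  neighbors <- vector("list", length(cells))
  weights <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    rr <- rws[i] + offs[, 1]; cc <- cls[i] + offs[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    nb <- pos[cbind(rr[ok], cc[ok])]
    nb <- nb[!is.na(nb)]
    neighbors[[i]] <- nb
    k <- length(nb)
    weights[[i]] <- if (k == 0) numeric(0)
                    else if (standardization == "row") rep(1 / k, k)
                    else rep(1, k)
  }
  isolated <- lengths(neighbors) == 0L
  if (all(isolated)) stop("all cells are isolated")
  structure(list(cells = cells, neighbors = neighbors, weights = weights,
                 isolated = isolated, dim = c(nr, nc), scheme = scheme,
                 standardization = standardization),
            class = "weight_matrix")
}

# Values at the non-isolated valid cells of w, in w's cell order.
weights_values <- function(x, w) {
  v <- x[w$cells]
  if (any(is.na(v[!w$isolated])))
    stop("`x` has NA at a valid cell of the weight matrix")
  v
}

# Spatial lag sum_j w_ij x_j for each non-isolated cell (NA for isolated).
spatial_lag <- function(v, w) {
  out <- rep(NA_real_, length(v))
  for (i in which(!w$isolated))
    out[i] <- sum(w$weights[[i]] * v[w$neighbors[[i]]])
  out
}

#' Global Moran's I
#'
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' over the non-isolated valid cells, with `S0` the total weight. Values near
#' 1 indicate strong positive spatial autocorrelation, near 0 none, negative
#' values alternation.
#'
#' @param x Numeric matrix (NA allowed only outside the weight graph).
#' @param w A [build_weights()] object.
#' @return Moran's I (scalar).
#' @export
global_morans_i <- function(x, w) {
  v <- weights_values(x, w)
  use <- !w$isolated
  z <- v - mean(v[use])
  denom <- sum(z[use]^2)
  if (denom == 0) stop("zero variance: Moran's I undefined")
  s0 <- sum(unlist(w$weights[use]))
  num <- 0
  for (i in which(use))
    num <- num + z[i] * sum(w$weights[[i]] * z[w$neighbors[[i]]])
  (sum(use) / s0) * num / denom
}

#' Local Moran's I
#'
#' `I_i = (x_i - xbar) / S^2 * sum_j w_ij (x_j - xbar)` with `S^2` the sample
#' variance (n - 1 denominator) over the participating cells. Positive values
#' mark cells resembling their neighbourhood (both high or both low),
#' negative values spatial outliers.
#'
#' @inheritParams global_morans_i
#' @return Matrix of local I values (NA at nodata/isolated cells).
#' @export
local_morans_i <- function(x, w) {
  v <- weights_values(x, w)
  use <- !w$isolated
  z <- v - mean(v[use])
  s2 <- sum(z[use]^2) / (sum(use) - 1)
  if (s2 == 0) stop("zero variance: local Moran's I undefined")
  lag_z <- spatial_lag(z, w)
  li <- z / s2 * lag_z
  out <- matrix(NA_real_, w$dim[1], w$dim[2])
  out[w$cells[use]] <- li[use]
  out
}

#' Conditional permutation p-values for local Moran's I
#'
#' For each cell the observed value is held fixed and `n_perm` random draws
#' of its neighbourhood are taken from the remaining values; the two-sided
#' pseudo p-value is `(count(|I*| >= |I_i|) + 1) / (n_perm + 1)`. One set of
#' random index draws is shared across cells (each cell maps them into its
#' own leave-one-out value vector), the standard fast scheme for conditional
#' randomization on lattices.
#'
#' @inheritParams global_morans_i
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed; identical seeds give identical p grids.
#' @return Matrix of p-values in `(0, 1]`.
#' @export
permutation_p <- function(x, w, n_perm = 999, seed = 1L) {
  if (n_perm < 99) stop("`n_perm` must be >= 99 for useful resolution")
  v <- weights_values(x, w)
  use <- which(!w$isolated)
  n <- length(use)
  z <- v - mean(v[use])
  s2 <- sum(z[use]^2) / (n - 1)
  if (s2 == 0) stop("zero variance")
  max_k <- max(lengths(w$neighbors[use]))
  ids <- with_seed(seed, {
    m <- matrix(0L, n_perm, max_k)
    for (r in seq_len(n_perm)) m[r, ] <- sample.int(n - 1L, max_k)
    m
  })
  obs_lag <- spatial_lag(z, w)
  p <- rep(NA_real_, length(v))
  zu <- z[use]
  for (ii in seq_along(use)) {
    i <- use[ii]
    k <- length(w$neighbors[[i]])
    others <- zu[-ii]
    sampled <- matrix(others[ids[, seq_len(k), drop = FALSE]], nrow = n_perm)
    lag_star <- as.numeric(sampled %*% w$weights[[i]])
    li_obs <- z[i] / s2 * obs_lag[i]
    li_star <- z[i] / s2 * lag_star
    p[i] <- (sum(abs(li_star) >= abs(li_obs)) + 1) / (n_perm + 1)
  }
  out <- matrix(NA_real_, w$dim[1], w$dim[2])
  out[w$cells] <- p
  out
}

#' LISA cluster classification
#'
#' Labels each significant cell by its Moran-scatter quadrant: HH (high value
#' in a high neighbourhood), LL, HL (high value among low neighbours), LH;
#' cells with `p > alpha` are NS (not significant). "High" compares the cell
#' value with the grid mean and the spatial lag with the mean lag.
#'
#' @param x Numeric matrix.
#' @param w A [build_weights()] object.
#' @param local_i Local Moran matrix from [local_morans_i()] (used only for
#'   its NA pattern).
#' @param p P-value matrix from [permutation_p()].
#' @param alpha Significance level (default 0.05).
#' @return Character matrix with labels `"HH"`, `"LL"`, `"HL"`, `"LH"`,
#'   `"NS"` (NA outside the graph).
#' @export
lisa_classify <- function(x, w, local_i, p, alpha = 0.05) {
  v <- weights_values(x, w)
  use <- !w$isolated
  z <- v - mean(v[use])
  lag <- spatial_lag(v, w)
  lag_c <- lag - mean(lag[use])
  out <- matrix(NA_character_, w$dim[1], w$dim[2])
  pv <- p[w$cells]
  lab <- ifelse(pv > alpha, "NS",
         ifelse(z > 0 & lag_c > 0, "HH",
         ifelse(z <= 0 & lag_c <= 0, "LL",
         ifelse(z > 0, "HL", "LH"))))
  lab[!use] <- NA_character_
  out[w$cells] <- lab
  out
}

#' Full LISA analysis of a grid
#'
#' Convenience wrapper: builds weights on the valid cells, computes global
#' and local Moran's I, permutation p-values and cluster labels.
#'
#' @param x Numeric matrix (NA = nodata).
#' @param scheme,standardization Passed to [build_weights()].
#' @param alpha Significance level.
#' @param n_perm Permutations.
#' @param seed Integer seed.
#' @return A `lisa_result`: `global_i`, `local_i`, `p`, `cluster`, `alpha`.
#' @export
lisa <- function(x, scheme = "queen", standardization = "row", alpha = 0.05,
                 n_perm = 999, seed = 1L) {
  w <- build_weights(!is.na(x), scheme, standardization)
  gi <- global_morans_i(x, w)
  li <- local_morans_i(x, w)
  p <- permutation_p(x, w, n_perm = n_perm, seed = seed)
  cl <- lisa_classify(x, w, li, p, alpha)
  structure(list(global_i = gi, local_i = li, p = p, cluster = cl,
                 alpha = alpha), class = "lisa_result")
}
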