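RISK_LEVELS <- c("extremely safe", "safe", "relatively safe",
                 "relatively dangerous", "dangerous", "extremely dangerous")

#' Relative population exposure risk
#'
#' Per-cell exposure risk `Q_i = P_i * M_i / mean(P * M)`: the product of
#' population density and PM2.5 concentration, normalized by its mean over
#' valid cells, so `mean(Q) = 1` by construction. Cells are valid only where
#' both inputs are valid.
#'
#' @param pm PM2.5 matrix (ug/m3).
#' @param pop Population density matrix (persons/km2), same grid.
#' @return A `risk_grid`: `q` (risk matrix) and `level` (classification
#'   matrix, see [classify_risk()]).
#' @export
relative_risk <- function(pm, pop) {
  if (!identical(dim(pm), dim(pop)))
    stop("PM2.5 and population grids must share one grid")
  valid <- !is.na(pm) & !is.na(pop)
  if (!any(valid)) stop("no cell valid in both inputs")
  prod <- pm * pop
  denom <- mean(prod[valid])
  if (denom == 0) stop("all population-concentration products are zero")
  q <- matrix(NA_real_, nrow(pm), ncol(pm))
  q[valid] <- prod[valid] / denom
  structure(list(q = q, level = classify_risk(q)), class = "risk_grid")
}

#' Classify relative exposure risk into six levels
#'
#' The fixed scheme: `Q = 0` extremely safe, `(0, 1]` safe, `(1, 2]`
#' relatively safe, `(2, 3]` relatively dangerous, `(3, 5]` dangerous,
#' `> 5` extremely dangerous (intervals closed on the right, which is the
#' only reading under which the six ranges tile `[0, Inf)` exactly).
#'
#' @param q Risk matrix or vector (>= 0 or `NA`).
#' @return Character matrix/vector of level labels.
#' @export
classify_risk <- function(q) {
  if (any(q < 0, na.rm = TRUE)) stop("risk values must be >= 0")
  lev <- ifelse(is.na(q), NA_character_,
         ifelse(q == 0, RISK_LEVELS[1],
         ifelse(q <= 1, RISK_LEVELS[2],
         ifelse(q <= 2, RISK_LEVELS[3],
         ifelse(q <= 3, RISK_LEVELS[4],
         ifelse(q <= 5, RISK_LEVELS[5], RISK_LEVELS[6]))))))
  if (is.matrix(q)) lev <- matrix(lev, nrow(q), ncol(q))
  lev
}

#' Aggregate exposure risk by region
#'
#' Unweighted arithmetic mean of `Q` over each region's valid cells (the
#' per-region values act as area-level summaries); a population-weighted
#' variant is available.
#'
#' @param risk A `risk_grid` from [relative_risk()].
#' @param regions Region-label matrix (character or factor) aligned with the
#'   risk grid; `NA` cells are outside all regions.
#' @param weights Optional population matrix for population-weighted means.
#' @return A data.frame `region`, `mean_q`, `n_cells`, ordered by decreasing
#'   `mean_q`; regions with no valid cell get `NA`.
#' @export
aggregate_regions <- function(risk, regions, weights = NULL) {
  q <- risk$q
  if (!identical(dim(q), dim(regions)))
    stop("`regions` must align with the risk grid")
  labs <- sort(unique(as.vector(regions[!is.na(regions)])))
  if (length(labs) == 0) stop("no region labels")
  rows <- lapply(labs, function(lb) {
    sel <- !is.na(regions) & regions == lb & !is.na(q)
    if (!any(sel))
      return(data.frame(region = lb, mean_q = NA_real_, n_cells = 0L))
    mq <- if (is.null(weights)) mean(q[sel])
          else stats::weighted.mean(q[sel], weights[sel])
    data.frame(region = lb, mean_q = mq, n_cells = sum(sel))
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_q, out$region), , drop = FALSE]
}
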