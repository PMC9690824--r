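## Gaussian two-step floating catchment area (G2SFCA) accessibility of park
## green space. Step 1: each park's supply-demand ratio R_j = S_j / sum of
## decay-weighted population within the d0 catchment of the park. Step 2:
## each demand unit's accessibility A_i = sum of decay-weighted R_j over
## parks within d0 of the unit. Distances are Euclidean from unit centroid
## to park geometric centroid; d0 defaults to 1250 m (a 15-minute walk).

ACCESS_LEVELS4 <- c("low", "medium", "mid-high", "high")
ACCESS_LEVELS3 <- c("low", "medium", "high")

#' Truncated Gaussian distance-decay weight
#'
#' G(d) = (exp(-(d/d0)^2 / 2) - exp(-1/2)) / (1 - exp(-1/2)) for d <= d0,
#' and 0 beyond. G(0) = 1, G(d0) = 0, strictly decreasing on [0, d0].
#'
#' @param d distance(s) in meters, nonnegative.
#' @param d0 catchment threshold in meters (default 1250).
#' @return weight(s) in \[0, 1\].
#' @examples
#' gaussianDecay(c(0, 625, 1250, 2000))
#' @export
gaussianDecay <- function(d, d0 = 1250) {
  if (any(d < 0)) stop("distances must be nonnegative")
  stopifnotScalarPositive(d0, "d0")
  w <- (exp(-0.5 * (d / d0)^2) - exp(-0.5)) / (1 - exp(-0.5))
  ifelse(d > d0, 0, w)
}

## Park geometric centroids and areas restricted to category == "park".
parkTable <- function(greens) {
  info <- greenInfo(greens)
  keep <- which(info$category == "park")
  ctr <- if (length(keep)) {
    t(vapply(geometries(greens)[keep], polygonCentroid, numeric(2)))
  } else matrix(numeric(0), 0, 2)
  data.frame(id = info$id[keep], S = info$area_m2[keep],
             cx = ctr[, 1], cy = ctr[, 2], stringsAsFactors = FALSE)
}

#' Step 1: per-park supply-demand ratios
#'
#' R_j = S_j / sum over units k with d_kj <= d0 of G(d_kj) * D_k, with S_j
#' the park area (m2) and D_k the unit population. Parks with no in-range
#' weighted demand are flagged unserved (R_j undefined, excluded from step
#' 2) rather than treated as infinite supply.
#'
#' @param greens a [GreenSpaceSet-class] (only "park" category is supply).
#' @param units a [DemandUnitSet-class].
#' @param d0 catchment threshold in meters (default 1250).
#' @return data.frame(id, S, cx, cy, demand, served, R) with one row per
#'   park; R is NA for unserved parks.
#' @export
supplyDemandRatios <- function(greens, units, d0 = 1250) {
  pk <- parkTable(greens)
  uc <- units@centroids
  D <- units@info$population
  pk$demand <- vapply(seq_len(nrow(pk)), function(j) {
    d <- sqrt((uc[, 1] - pk$cx[j])^2 + (uc[, 2] - pk$cy[j])^2)
    inR <- d <= d0
    if (!any(inR)) return(0)
    sum(gaussianDecay(d[inR], d0) * D[inR])
  }, numeric(1))
  pk$served <- pk$demand > 0
  pk$R <- ifelse(pk$served, pk$S / pk$demand, NA_real_)
  pk
}

#' Step 2: per-unit accessibility
#'
#' A_i = sum over served parks j with d_ij <= d0 of G(d_ij) * R_j, in m2 of
#' park per person. Units with no served park in range score 0. The result
#' also carries the per-capita benchmark and the supply flag
#' (A_i >= benchmark means the unit's accessible supply meets the city-wide
#' per-capita park provision), plus four-level and collapsed three-level
#' accessibility classes.
#'
#' @param units a [DemandUnitSet-class].
#' @param greens a [GreenSpaceSet-class].
#' @param ratios output of [supplyDemandRatios()]; recomputed when missing.
#' @param d0 catchment threshold (meters).
#' @param classMethod "quantile" (default) or "jenks" class breaks.
#' @return an [AccessibilityResult-class].
#' @export
accessibility <- function(units, greens, ratios = NULL, d0 = 1250,
                          classMethod = c("quantile", "jenks")) {
  classMethod <- match.arg(classMethod)
  if (is.null(ratios)) ratios <- supplyDemandRatios(greens, units, d0)
  pk <- ratios[ratios$served, , drop = FALSE]
  uc <- units@centroids
  A <- numeric(nrow(uc))
  if (nrow(pk)) {
    for (j in seq_len(nrow(pk))) {
      d <- sqrt((uc[, 1] - pk$cx[j])^2 + (uc[, 2] - pk$cy[j])^2)
      inR <- d <= d0
      if (any(inR)) {
        A[inR] <- A[inR] + gaussianDecay(d[inR], d0) * pk$R[j]
      }
    }
  }
  bench <- perCapitaBenchmark(greens, units)
  cls <- tryCatch(classifyAccessibility(A, method = classMethod),
                  error = function(e) {
                    list(class4 = factor(rep(ACCESS_LEVELS4[1], length(A)),
                                         ACCESS_LEVELS4),
                         class3 = factor(rep(ACCESS_LEVELS3[1], length(A)),
                                         ACCESS_LEVELS3))
                  })
  new("AccessibilityResult",
      units = data.frame(id = units@info$id,
                         population = units@info$population,
                         score = A,
                         class4 = cls$class4,
                         class3 = cls$class3,
                         supplyFlag = ifelse(A >= bench, "supply>=demand",
                                             "supply<demand"),
                         stringsAsFactors = FALSE),
      benchmark = bench, d0 = as.numeric(d0))
}

#' Per-capita park green space benchmark
#'
#' Total park area divided by total population (m2/person): the city-wide
#' provision against which each unit's accessibility is compared.
#'
#' @param greens a [GreenSpaceSet-class].
#' @param units a [DemandUnitSet-class] (its population total is the
#'   denominator).
#' @return m2 per person.
#' @export
perCapitaBenchmark <- function(greens, units) {
  pop <- totalPopulation(units)
  if (pop <= 0) stop("total population must be positive")
  info <- greenInfo(greens)
  sum(info$area_m2[info$category == "park"]) / pop
}

#' Classify accessibility scores
#'
#' Orders units into low / medium / mid-high / high accessibility (labels
#' monotone in the score) and also emits the three-level collapse
#' (low -> low, medium and mid-high -> medium, high -> high) used by the
#' integrated overlay.
#'
#' @param scores numeric accessibility scores.
#' @param method "quantile" (default) or "jenks".
#' @param k number of classes (default 4).
#' @return list(class4, class3, breaks): ordered factors and the inner
#'   break values.
#' @export
classifyAccessibility <- function(scores, method = c("quantile", "jenks"),
                                  k = 4L) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (length(unique(scores)) < k) {
    stop("fewer distinct accessibility values than classes")
  }
  breaks <- switch(method,
    quantile = stats::quantile(scores, probs = seq_len(k - 1L) / k,
                               names = FALSE, type = 7),
    jenks = jenksBreaks(scores, k))
  if (anyDuplicated(breaks)) {
    ## Tie-heavy scores (many zero-access units): fall back to breaks on the
    ## distinct values so classes stay ordered and nonempty.
    breaks <- stats::quantile(unique(scores), probs = seq_len(k - 1L) / k,
                              names = FALSE, type = 7)
  }
  if (anyDuplicated(breaks)) stop("degenerate accessibility breaks")
  lv4 <- if (k == 4L) ACCESS_LEVELS4 else paste0("class", seq_len(k))
  idx <- findInterval(scores, breaks, left.open = TRUE) + 1L
  class4 <- factor(lv4[idx], levels = lv4, ordered = TRUE)
  collapse <- if (k == 4L) c("low", "medium", "medium", "high") else
    lv4  # no collapse defined for k != 4
  class3 <- factor(collapse[idx],
                   levels = unique(collapse[order(seq_along(collapse))]),
                   ordered = TRUE)
  if (k == 4L) class3 <- factor(as.character(class3), ACCESS_LEVELS3,
                                ordered = TRUE)
  list(class4 = class4, class3 = class3, breaks = breaks)
}
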