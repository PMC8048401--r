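# Home-range overlap indices (after the standard Fieberg & Kochanny
# catalogue):
#   hr    directional polygon overlap: area(A_l ∩ B_l) / area(A_l)
#   phr   probability of B's isopleth under A's UD (directional)
#   vi    volume of intersection: sum_cells min(udA, udB)
#   ba    Bhattacharyya affinity: sum_cells sqrt(udA * udB)
#   udoi  UD overlap index: area(A_l ∩ B_l) * sum(udA * udB) / cell_area
#   hd    Hellinger-style distance, here 2 * (1 - ba)
# hr and phr may change when the arguments are swapped; vi, ba, udoi and hd
# are symmetric. Probabilistic indices require UDs; when the two estimates
# live on different template rasters, b's UD is resampled onto a's raster
# by cell-centre sampling and renormalised.

OVERLAP_INDICES <- c("hr", "phr", "vi", "ba", "udoi", "hd")

#' Overlap between two home-range estimates
#'
#' @param a,b home-range estimates sharing a CRS. `type = "hr"` works for
#'   any estimator; the probabilistic indices need UDs on both sides.
#' @param type one of `"hr"`, `"phr"`, `"vi"`, `"ba"`, `"udoi"`, `"hd"`.
#' @param levels levels to evaluate; defaults to the levels shared by `a`
#'   and `b`.
#' @param conditional for the UD-based indices, truncate each UD to its own
#'   level isopleth (and renormalise) before comparing.
#' @return a tibble with columns `level`, `index`, `value`.
#' @export
hr_overlap <- function(a, b, type = "hr", levels = NULL, conditional = FALSE) {
  stopifnot(inherits(a, "hr_estimate"), inherits(b, "hr_estimate"))
  type <- match.arg(type, OVERLAP_INDICES)
  if (a$crs != b$crs) {
    stop_domain(sprintf("CRS mismatch: EPSG:%d vs EPSG:%d.", a$crs, b$crs))
  }
  if (is.null(levels)) {
    levels <- intersect(a$levels, b$levels)
    if (!length(levels)) {
      stop_domain("The two estimates share no levels; supply `levels`.")
    }
  }
  levels <- check_levels(levels)

  if (type == "hr") {
    vals <- vapply(levels, function(l) {
      ga <- iso_geometry(a, l)
      gb <- iso_geometry(b, l)
      aa <- poly_area(ga)
      if (aa <= 0) return(0)
      if (identical(ga, gb)) return(1)  # self-overlap is exact
      poly_area(poly_intersection(ga, gb)) / aa
    }, numeric(1))
    return(tibble::tibble(level = levels, index = type, value = vals))
  }

  if (!is_probabilistic(a) || !is_probabilistic(b)) {
    stop_unsupported(sprintf(
      "Overlap index '%s' needs utilization distributions on both estimates.", type
    ))
  }
  udA <- a$ud$values
  udB <- resample_ud_onto(b, a$trast)
  ca <- trast_cellsize(a$trast)^2

  vals <- vapply(levels, function(l) {
    uA <- udA; uB <- udB
    if (conditional) {
      uA[!ud_level_mask(uA, l)] <- 0
      uB[sum(uB) > 0 & !ud_level_mask(uB, l)] <- 0
      if (sum(uA) > 0) uA <- uA / sum(uA)
      if (sum(uB) > 0) uB <- uB / sum(uB)
    }
    switch(type,
      phr = if (sum(udB) > 0) sum(uA[ud_level_mask(udB, l)]) else 0,
      vi = sum(pmin(uA, uB)),
      ba = sum(sqrt(uA * uB)),
      hd = 2 * (1 - sum(sqrt(uA * uB))),
      udoi = {
        ia <- poly_area(poly_intersection(iso_geometry(a, l), iso_geometry(b, l)))
        ia * sum(uA * uB) / ca
      }
    )
  }, numeric(1))
  tibble::tibble(level = levels, index = type, value = vals)
}

iso_geometry <- function(est, level) {
  iso <- est$isopleths
  row <- which(iso$level == level & iso$what == "estimate")
  if (!length(row)) {
    extra <- ud_to_isopleths(est, level)  # errors for geometric estimates
    return(extra$geometry[[1L]])
  }
  iso$geometry[[row[1L]]]
}

# sample b's UD at the cell centres of a target template raster, then
# renormalise; cells outside b's raster contribute zero mass
resample_ud_onto <- function(b, trast) {
  bt <- b$trast
  same <- isTRUE(all.equal(unclass(bt)[c("xmin", "xmax", "ymin", "ymax", "ncol", "nrow")],
                           unclass(trast)[c("xmin", "xmax", "ymin", "ymax", "ncol", "nrow")]))
  if (same) return(b$ud$values)
  xs <- trast_xcenters(trast)
  ys <- trast_ycenters(trast)
  csb <- trast_cellsize(bt)
  col <- floor((xs - bt$xmin) / csb) + 1
  row <- floor((bt$ymax - ys) / csb) + 1
  okc <- col >= 1 & col <= bt$ncol
  okr <- row >= 1 & row <= bt$nrow
  out <- matrix(0, nrow = trast$nrow, ncol = trast$ncol)
  if (any(okr) && any(okc)) {
    out[okr, okc] <- b$ud$values[row[okr], col[okc]]
  }
  s <- sum(out)
  if (s > 0) out <- out / s
  out
}

#' Pairwise overlap among several estimates
#'
#' Computes [hr_overlap()] for every ordered pair, emitting a long table
#' labelled by `from` and `to`.
#'
#' @param ests a named list of home-range estimates.
#' @param type overlap index, as in [hr_overlap()].
#' @param levels levels to evaluate (default: levels shared by each pair).
#' @param conditional see [hr_overlap()].
#' @return a tibble with columns `from`, `to`, `level`, `index`, `value`.
#' @export
hr_overlap_many <- function(ests, type = "hr", levels = NULL, conditional = FALSE) {
  stopifnot(is.list(ests), length(ests) >= 2L)
  nm <- names(ests) %||% as.character(seq_along(ests))
  rows <- list()
  for (i in seq_along(ests)) {
    for (j in seq_along(ests)) {
      if (i == j) next
      o <- hr_overlap(ests[[i]], ests[[j]], type = type, levels = levels,
                      conditional = conditional)
      o$from <- nm[i]
      o$to <- nm[j]
      rows <- c(rows, list(o))
    }
  }
  out <- dplyr::bind_rows(rows)
  out[, c("from", "to", "level", "index", "value")]
}
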