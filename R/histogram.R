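# 1D and 2D histograms of ion measurements.
#
# Charge histograms use 1 e bins centered on integers; mass histograms use
# 20 kDa bins. Bins are uniform and half-open [lo, hi), so a value on a
# bin edge lands in the bin to its right.

#' One-dimensional histogram with uniform half-open bins
#'
#' @param values numeric vector (NA dropped); may be empty.
#' @param bin_width positive bin width. Defaults: 1 (e) for
#'   `axis = "charge"`, 2e4 (Da) for `axis = "mass"`.
#' @param range optional `c(lo, hi)`; defaults to the data range expanded
#'   to whole bins. For the charge axis, bins are centered on integers.
#' @param axis `"charge"`, `"mass"`, or any label (sets defaults + units).
#' @return An object of class `ion_histogram`: `bin_edges`, `counts`,
#'   `mids`, `axis`, `units`.
#' @examples
#' h <- histogram1d(c(165, 165, 150), axis = "charge")
#' @export
histogram1d <- function(values, bin_width = NULL, range = NULL,
                        axis = "charge") {
  if (is.null(bin_width)) {
    bin_width <- switch(axis, charge = 1, mass = 2e4,
                        stop_invalid("bin_width required for axis '%s'", axis))
  }
  check_scalar(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  values <- values[is.finite(values)]
  units <- switch(axis, charge = "e", mass = "Da", "")
  # anchor so that for the charge axis integer values are bin centers
  anchor <- if (identical(axis, "charge")) -bin_width / 2 else 0
  if (is.null(range)) {
    if (!length(values)) {
      return(structure(list(bin_edges = anchor + c(0, bin_width),
                            counts = 0L,
                            mids = anchor + bin_width / 2,
                            axis = axis, units = units),
                       class = "ion_histogram"))
    }
    lo <- anchor + bin_width * floor((min(values) - anchor) / bin_width)
    hi <- anchor + bin_width * ceiling((max(values) - anchor) / bin_width)
    if (hi <= max(values)) hi <- hi + bin_width  # keep half-open top bin
  } else {
    lo <- range[1]
    hi <- range[2]
  }
  edges <- seq(lo, hi, by = bin_width)
  if (utils::tail(edges, 1) < hi - 1e-9 * bin_width) {
    edges <- c(edges, utils::tail(edges, 1) + bin_width)
  }
  inside <- values >= edges[1] & values < utils::tail(edges, 1)
  idx <- findInterval(values[inside], edges, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(bin_edges = edges, counts = counts,
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 axis = axis, units = units),
            class = "ion_histogram")
}

#' @export
print.ion_histogram <- function(x, ...) {
  cat(sprintf("<ion_histogram> axis=%s, %d bins of width %.4g %s, n=%d\n",
              x$axis, length(x$counts), diff(x$bin_edges[1:2]), x$units,
              sum(x$counts)))
  invisible(x)
}

#' @export
plot.ion_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$counts, type = "h",
                 xlab = sprintf("%s (%s)", x$axis, x$units),
                 ylab = "count", ...)
  invisible(x)
}

#' Two-dimensional mass/charge histogram with Rayleigh-line overlay
#'
#' Joint counts over uniform mass and charge bins, plus the Rayleigh-limit
#' charge evaluated at each mass-bin center (the dashed overlay line of
#' 2D CDMS histograms).
#'
#' @param mass_values,charge_values equal-length numeric vectors.
#' @param mass_bin,charge_bin bin widths (Da, e).
#' @param consts [rayleigh_constants()] for the overlay.
#' @return Class `ion_histogram2d`: `mass_edges`, `charge_edges`, `counts`
#'   (matrix, mass bins in rows), `rayleigh_charge` per mass-bin center.
#' @export
histogram2d <- function(mass_values, charge_values, mass_bin = 2e4,
                        charge_bin = 1, consts = rayleigh_constants()) {
  if (length(mass_values) != length(charge_values)) {
    stop_invalid("mass and charge vectors must have equal length")
  }
  hm <- histogram1d(mass_values, mass_bin, axis = "mass")
  hz <- histogram1d(charge_values, charge_bin, axis = "charge")
  ok <- is.finite(mass_values) & is.finite(charge_values) &
    mass_values >= hm$bin_edges[1] &
    mass_values < utils::tail(hm$bin_edges, 1) &
    charge_values >= hz$bin_edges[1] &
    charge_values < utils::tail(hz$bin_edges, 1)
  im <- findInterval(mass_values[ok], hm$bin_edges)
  iz <- findInterval(charge_values[ok], hz$bin_edges)
  counts <- matrix(0L, nrow = length(hm$counts), ncol = length(hz$counts))
  for (k in seq_along(im)) {
    counts[im[k], iz[k]] <- counts[im[k], iz[k]] + 1L
  }
  structure(list(mass_edges = hm$bin_edges, charge_edges = hz$bin_edges,
                 mass_mids = hm$mids, charge_mids = hz$mids,
                 counts = counts,
                 rayleigh_charge = rayleigh_charge_for_mass(hm$mids, consts)),
            class = "ion_histogram2d")
}

#' @export
print.ion_histogram2d <- function(x, ...) {
  cat(sprintf("<ion_histogram2d> %d mass x %d charge bins, n=%d\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
plot.ion_histogram2d <- function(x, ...) {
  graphics::image(x$mass_mids, x$charge_mids, x$counts,
                  xlab = "mass (Da)", ylab = "charge (e)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::lines(x$mass_mids, x$rayleigh_charge, lty = 2, col = "blue")
  invisible(x)
}

#' Export a histogram as a two-column data.frame
#'
#' @param hist an `ion_histogram`.
#' @return data.frame with `center` and `count`.
#' @export
histogram_table <- function(hist) {
  stopifnot(inherits(hist, "ion_histogram"))
  data.frame(center = hist$mids, count = hist$counts)
}
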