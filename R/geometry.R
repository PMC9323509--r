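# Well geometry and the two-part axial mesh.

#' Build the well geometry after plastic compression
#'
#' A cylindrical multiwell-plate well holds a cell-seeded collagen gel at its
#' base under a column of culture medium. Plastic compression removes
#' interstitial fluid, shrinking the cast gel volume by `compression_factor`
#' and concentrating the seeded cells by the same factor.
#'
#' @param seeded_density cell seeding density of the cast (pre-compression)
#'   gel, cells/mL
#' @param gel_volume_prestab cast gel volume before compression, uL
#' @param medium_volume culture medium volume above the gel, uL
#' @param compression_factor volumetric compression ratio (>= 1)
#' @param radius well radius, m (default 3.175 mm, 96-well plate)
#' @return an object of class `"well_geometry"`: radius, gel/medium heights
#'   and volumes (m, m3), and `density_post` (cell/m3 after compression)
#' @examples
#' g <- well_geometry(0.5e6)         # 0.5e6 cells/mL cast -> 20e6 cells/mL
#' g$density_post / 1e6              # cells/mL
#' @export
well_geometry <- function(seeded_density, gel_volume_prestab = 240,
                          medium_volume = 200, compression_factor = 40,
                          radius = 3.175e-3) {
  stopifnot(seeded_density > 0, gel_volume_prestab > 0, medium_volume > 0,
            radius > 0)
  if (compression_factor < 1) stop("compression_factor must be >= 1")
  area <- pi * radius^2
  gel_volume <- gel_volume_prestab * 1e-9 / compression_factor # uL -> m3
  medium_volume_m3 <- medium_volume * 1e-9
  structure(list(
    radius = radius, area = area,
    gel_height = gel_volume / area,
    medium_height = medium_volume_m3 / area,
    gel_volume = gel_volume, medium_volume = medium_volume_m3,
    density_post = seeded_density * compression_factor * 1e6, # cells/mL -> cell/m3
    compression_factor = compression_factor
  ), class = "well_geometry")
}

#' Build the two-part axial finite-volume mesh
#'
#' Uniform cells within each domain, with the gel-medium interface placed
#' exactly on a cell face. The axial coordinate runs upward from the well base
#' (z = 0) to the medium-air interface.
#'
#' @param geom a [well_geometry()]
#' @param n_cells total number of cells (>= 10)
#' @param gel_fraction fraction of cells assigned to the gel (default 0.2)
#' @return an object of class `"axial_mesh"`: `centres`, `widths` (m),
#'   `domain` (`"gel"`/`"medium"` per cell), `n_gel`, `interface_z`
#' @export
axial_mesh <- function(geom, n_cells = 100, gel_fraction = 0.2) {
  stopifnot(inherits(geom, "well_geometry"))
  if (n_cells < 10) stop("n_cells must be at least 10")
  if (gel_fraction <= 0 || gel_fraction >= 1) stop("gel_fraction must be in (0,1)")
  n_gel <- round(gel_fraction * n_cells)
  if (n_gel < 2) stop("mesh must place at least 2 cells in the gel")
  n_med <- n_cells - n_gel
  hg <- geom$gel_height / n_gel
  hm <- geom$medium_height / n_med
  widths <- c(rep(hg, n_gel), rep(hm, n_med))
  centres <- cumsum(widths) - widths / 2
  structure(list(
    centres = centres, widths = widths,
    domain = rep(c("gel", "medium"), c(n_gel, n_med)),
    n_gel = n_gel, interface_z = geom$gel_height, geom = geom
  ), class = "axial_mesh")
}

# volume-overlap weights of the bottom/middle/top thirds of the gel
.zone_weights <- function(mesh) {
  H <- mesh$interface_z
  edges <- c(0, cumsum(mesh$widths))
  ng <- mesh$n_gel
  w <- matrix(0, 3, ng, dimnames = list(c("bottom", "middle", "top"), NULL))
  zb <- c(0, H / 3, 2 * H / 3, H)
  for (z in 1:3) for (i in seq_len(ng)) {
    lo <- max(edges[i], zb[z]); hi <- min(edges[i + 1], zb[z + 1])
    w[z, i] <- max(0, hi - lo)
  }
  w
}
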