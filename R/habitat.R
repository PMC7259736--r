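#' Sampled area of a set of belt transects
#'
#' Belt transects are rectangular strip plots radiating from a survey
#' point, used to count cone-bearing whitebark pine.  Segments discarded in
#' the field (e.g. where transects overlap near the point) are subtracted
#' from the nominal area.  The study layout — four 10 x 50 m transects with
#' the first 5 m of two of them discarded — samples 1,900 m².
#'
#' @param n_transects Number of transects.
#' @param width,length Transect dimensions in metres.
#' @param discard Numeric vector of discarded initial lengths (m), one
#'   entry per discarded segment; must each be shorter than `length`.
#' @return Sampled area in square metres.
#' @examples
#' belt_transect_area()  # study default: 1900
#' @export
belt_transect_area <- function(n_transects = 4, width = 10, length = 50,
                               discard = c(5, 5)) {
  stopifnot(n_transects >= 0, width >= 0, length >= 0)
  if (any(discard < 0) || any(discard >= length)) {
    stop("discarded segments must be non-negative and shorter than the transect")
  }
  if (length(discard) > n_transects) {
    stop("more discarded segments than transects")
  }
  n_transects * width * length - sum(width * discard)
}

#' Whitebark pine cone density per hectare
#'
#' The cone-crop covariate: the density of cone-bearing whitebark pines
#' (trees counted over the belt-transect sampled area, scaled to per
#' hectare) multiplied by the mean number of cones per tree counted on the
#' survey date.
#'
#' @param n_cone_trees Count of cone-bearing trees in the sampled area.
#' @param sampled_area_m2 Sampled area in square metres (> 0).
#' @param mean_cones_per_tree Mean cones per cone-bearing tree (>= 0).
#' @return Cones per hectare.
#' @examples
#' cone_density_per_ha(19, 1900, 10)  # 1000 cones/ha
#' @export
cone_density_per_ha <- function(n_cone_trees, sampled_area_m2,
                                mean_cones_per_tree) {
  stopifnot(n_cone_trees >= 0, mean_cones_per_tree >= 0)
  if (sampled_area_m2 <= 0) stop("sampled area must be positive")
  (n_cone_trees / sampled_area_m2 * 10000) * mean_cones_per_tree
}

#' Point-centred-quarter stand summary
#'
#' Computes the Cottam-Curtis stand metrics from a modified point-quarter
#' sample: at each sampling location the area is split into four quadrants
#' and the nearest live tree per quadrant is recorded (species, distance,
#' circumference); quadrants with no tree within the search limit are
#' marked empty.  Overall density is `10000 / mean(distance)^2` trees/ha
#' (empty quadrants excluded from the mean-distance denominator),
#' apportioned to species by stem counts.  Frequency is the fraction of
#' locations at which a species occurs, with all locations — including
#' those with empty quadrants — in the denominator.  Basal area per stem is
#' `circumference^2 / (4 * pi)`.  The importance value of a species is the
#' sum of its relative density, relative frequency and relative dominance
#' (each in percent), so importance values sum to 300 over species.
#'
#' @param samples Data frame with columns `location`, `quadrant`, `species`,
#'   `distance_m`, `circumference_cm`.  Empty quadrants are rows with
#'   `species = NA` (distance/circumference ignored).
#' @return Data frame, one row per species: `n_stems`, `density_ha`,
#'   `rel_density`, `frequency`, `rel_frequency`, `basal_area_m2_ha`,
#'   `rel_dominance`, `importance_value`.  Attribute `total_density_ha`
#'   carries the all-species density.
#' @export
point_quarter_summary <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("location", "quadrant", "species", "distance_m",
                  "circumference_cm") %in% names(samples)))
  trees <- samples[!is.na(samples$species), , drop = FALSE]
  if (!nrow(trees)) stop("all quadrants are empty: no trees sampled")
  stopifnot(all(trees$distance_m > 0), all(trees$circumference_cm > 0))

  n_locations <- length(unique(samples$location))
  mean_dist <- mean(trees$distance_m)
  total_density <- 10000 / mean_dist^2          # trees per hectare

  sp <- sort(unique(trees$species))
  n_stems <- vapply(sp, function(s) sum(trees$species == s), 0)
  rel_density <- 100 * n_stems / sum(n_stems)
  density_ha <- total_density * n_stems / sum(n_stems)

  freq <- vapply(sp, function(s) {
    length(unique(trees$location[trees$species == s])) / n_locations
  }, 0)
  rel_frequency <- 100 * freq / sum(freq)

  # per-stem basal area from circumference: c^2 / (4 pi), cm^2 -> m^2
  ba_stem <- trees$circumference_cm^2 / (4 * pi) / 1e4
  mean_ba <- vapply(sp, function(s) mean(ba_stem[trees$species == s]), 0)
  ba_ha <- density_ha * mean_ba                 # m^2 per hectare
  rel_dominance <- 100 * ba_ha / sum(ba_ha)

  out <- data.frame(
    species = sp,
    n_stems = as.integer(n_stems),
    density_ha = density_ha,
    rel_density = rel_density,
    frequency = freq,
    rel_frequency = rel_frequency,
    basal_area_m2_ha = ba_ha,
    rel_dominance = rel_dominance,
    importance_value = rel_density + rel_frequency + rel_dominance,
    row.names = NULL
  )
  if (any(out$importance_value > 300 + 1e-9)) {
    warning("importance value exceeds the nominal 300 maximum")
  }
  attr(out, "total_density_ha") <- total_density
  out
}
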