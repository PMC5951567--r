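#' The 57-feature radiomic panel
#'
#' Catalogue of the quantitative nodule features computed by the package,
#' grouped into eight categories: 1 location, 2 size, 3 shape, 4 radiodensity,
#' 5 nodule texture, 6 texture of the nodule-free surrounding lung, 7 nodule
#' surface, 8 distribution of the nodule surface exemplars. The cancer/control
#' columns are published screening-cohort marginals (mean and SD per class,
#' n = 408 malignant / 318 benign) and are used as the default class marginals
#' of the cohort simulator; \code{family} and \code{shift} define the marginal
#' family used to simulate each feature (Gaussian, or a shifted lognormal for
#' skewed strictly-positive features, moment-matched to the mean/SD).
#'
#' \code{centroid_z} is reported by the feature extractor as the vertical
#' offset of the nodule centroid from the carina landmark, the form in which
#' the vertical-location feature enters the classifier.
#'
#' @return a data.frame with one row per feature: \code{id}, \code{name},
#'   \code{label}, \code{category}, \code{cancer_mean}, \code{cancer_sd},
#'   \code{control_mean}, \code{control_sd}, \code{family}, \code{shift}.
#' @export
featureCatalog <- function() {
  ## id, name, label, cat, cancer mean, cancer sd, control mean, control sd,
  ## family, shift
  raw <- list(
    list(1L, "centroid_x", "Centroid_x", 1L, 154.78, 74.5, 142.21, 78.73, "gaussian", 0),
    list(2L, "centroid_y", "Centroid_y", 1L, 143.95, 47.18, 151.84, 55.47, "gaussian", 0),
    list(3L, "centroid_z", "Offset carina centroid_z", 1L, 203.38, 60.1, 186.88, 65.91, "gaussian", 0),
    list(4L, "volume", "Volume", 2L, 3305.34, 6361.01, 345.45, 819.51, "lognormal", 0),
    list(5L, "surface_area", "Surface Area", 2L, 1673.08, 2150.55, 345.04, 501.95, "lognormal", 0),
    list(6L, "sphericity", "Sphericity", 3L, 0.51, 0.21, 0.6, 0.29, "gaussian", 0),
    list(7L, "sphere_fit_factor", "Sphere Fit Factor", 3L, 6.82, 8.31, 5.28, 5.82, "lognormal", 1),
    list(8L, "estimated_radius", "Estimated Radius", 3L, 7.61, 3.99, 3.59, 1.57, "lognormal", 0),
    list(9L, "min_enclosing_brick_x", "Minimum Enclosing Brick x", 3L, 19.82, 12.12, 9.46, 5.51, "lognormal", 0),
    list(10L, "min_enclosing_brick_y", "Minimum Enclosing Brick y", 3L, 19.63, 12.13, 10.11, 6.72, "lognormal", 0),
    list(11L, "min_enclosing_brick", "Minimum Enclosing Brick", 3L, 16.49, 14.51, 4.97, 2.65, "lognormal", 0),
    list(12L, "max_brick_length", "Maximum Brick length", 3L, 24.08, 16.27, 11.31, 7.04, "lognormal", 0),
    list(13L, "elongation", "Elongation", 3L, -0.25, 0.4, -0.31, 0.47, "gaussian", 0),
    list(14L, "flatness", "Flatness", 3L, -0.56, 0.99, -1.01, 1.05, "gaussian", 0),
    list(15L, "hu_mean", "HU_mean", 4L, -209.18, 163.55, -465.23, 201.91, "gaussian", 0),
    list(16L, "hu_variance", "HU_variance", 4L, 614546.92, 3444392.14, 295011.7, 609422.64, "lognormal", 0),
    list(17L, "hu_skew", "HU_skew", 4L, -2.64, 10.09, -2.39, 1.2, "gaussian", 0),
    list(18L, "hu_kurtosis", "HU_kurtosis", 4L, 31.36, 91.51, 10.55, 10.05, "lognormal", 0),
    list(19L, "hu_entropy", "HU_entropy", 4L, 7.89, 1.77, 6.76, 1.76, "gaussian", 0),
    list(20L, "location", "Location", 1L, 6.37, 3.42, 7.06, 3.16, "gaussian", 0),
    list(21L, "sila_tex", "SILA_Tex", 5L, 122.91, 34.32, 58.62, 38.1, "gaussian", 0),
    list(22L, "texture_risk", "Texture_Risk", 5L, 2.17, 0.57, 1.36, 0.54, "gaussian", 0),
    list(23L, "vessels", "Vessels", 6L, 1.88, 2.8, 0.75, 1.29, "lognormal", 0),
    list(24L, "background", "Background", 6L, 9.49, 9.56, 9.59, 11.25, "lognormal", 0),
    list(25L, "sila_fibrosis", "SILA_Fibrosis", 6L, 32.32, 17.84, 27.42, 22.96, "gaussian", 0),
    list(26L, "sila_low_attenuation", "SILA_low attenuation", 6L, 35.54, 6.33, 32.69, 19.86, "gaussian", 0),
    list(27L, "n_vertices", "Number of Vertices", 7L, 2711.4, 4745.67, 515.25, 697.45, "lognormal", 0),
    list(28L, "n_faces", "Number of Faces", 7L, 5419.18, 9488.83, 1026.56, 1395.09, "lognormal", 0),
    list(29L, "willmore_energy_2", "Willmore Bending Energy_2", 7L, 1574.75, 3792.16, 480.61, 721.39, "lognormal", 0),
    list(30L, "willmore_energy", "Willmore Bending Energy", 7L, 2269.82, 6283.03, 802.67, 1116.04, "lognormal", 0),
    list(31L, "min_mean_curv", "Minimum Mean Curvature", 7L, -0.92, 0.65, -0.28, 0.46, "gaussian", 0),
    list(32L, "max_mean_curv", "Maximum Mean Curvature", 7L, 3.57, 2.44, 3.27, 1.82, "lognormal", 0),
    list(33L, "avg_pos_mean_curv", "Average Positive Mean Curvature", 7L, 0.34, 0.11, 0.58, 0.2, "lognormal", 0),
    list(34L, "skew_pos_mean_curv", "Skew Positive Mean Curvature", 7L, 2.89, 2.04, 2.01, 1.2, "lognormal", 0),
    list(35L, "min_gauss_curv", "Minimum Gaussian Curvature", 7L, -1.01, 0.87, -0.87, 0.84, "gaussian", 0),
    list(36L, "max_gauss_curv", "Maximum Gaussian Curvature", 7L, 15.43, 30.41, 12.6, 21.14, "lognormal", 0),
    list(37L, "avg_pos_gauss_curv", "Average positive Gaussian Curvature", 7L, 0.29, 0.29, 0.61, 0.52, "lognormal", 0),
    list(38L, "skew_pos_gauss_curv", "Skew Positive Gaussian Curvature", 7L, 7.57, 3.82, 4.66, 2.09, "lognormal", 0),
    list(39L, "min_sharp", "Minimum Sharp", 7L, 8.82e-05, 9.35e-04, 8.86e-04, 2.41e-03, "lognormal", 0),
    list(40L, "max_sharp", "Maximum Sharp", 7L, 38.99, 62.98, 22.44, 52.57, "lognormal", 0),
    list(41L, "avg_sharp", "Average Sharp", 7L, 0.59, 0.43, 1.01, 0.78, "lognormal", 0),
    list(42L, "skew_sharp", "Skew Sharp", 7L, 7.95, 7.45, 4.25, 3.53, "lognormal", 0),
    list(43L, "min_curved", "Minimum Curved", 7L, 0.01, 0.03, 0.07, 0.1, "lognormal", 0),
    list(44L, "max_curved", "Maximum Curved", 7L, 5.72, 4.21, 4.8, 3.05, "lognormal", 0),
    list(45L, "avg_curved", "Average Curved", 7L, 0.58, 0.19, 0.96, 0.32, "lognormal", 0),
    list(46L, "skew_curved", "Skew Curved", 7L, 2.87, 2.26, 1.79, 1.25, "lognormal", 0),
    list(47L, "min_shape_index", "Minimum Shape Index", 7L, -0.98, 0.01, -0.98, 0.02, "gaussian", 0),
    list(48L, "max_shape_index", "Maximum Shape Index", 7L, 0.98, 0.16, 0.55, 0.61, "gaussian", 0),
    list(49L, "avg_shape_index", "Average Shape Index", 7L, -0.29, 0.18, -0.55, 0.13, "gaussian", 0),
    list(50L, "skew_shape_index", "Skew Shape Index", 7L, 1.63, 0.91, 1.72, 1.42, "gaussian", 0),
    list(51L, "intrinsic_curv_index", "Intrinsic Curvature Index", 7L, 37.78, 118.81, 15.7, 21.56, "lognormal", 0),
    list(52L, "extrinsic_curv_index", "Extrinsic Curvature Index", 7L, 113.69, 284.16, 39.41, 57.05, "lognormal", 0),
    list(53L, "sila_morpheme", "SILA morpheme", 8L, 36.02, 11.24, 19.71, 12.61, "gaussian", 0),
    list(54L, "morpheme_avg_curv", "Morpheme Average Curvature", 8L, 0.74, 0.23, 1.05, 0.32, "lognormal", 0),
    list(55L, "morpheme_skew_curv", "Morpheme Skew Curvature", 8L, 2.33, 1.73, 1.57, 1.04, "lognormal", 0),
    list(56L, "local_sila_avg", "Local SILA Average", 8L, 27.65, 8.71, 15.3, 9.26, "gaussian", 0),
    list(57L, "local_sila_skew", "Local SILA Skew", 8L, 0.71, 0.42, 0.49, 0.68, "gaussian", 0))
  out <- data.frame(
    id = vapply(raw, `[[`, integer(1), 1),
    name = vapply(raw, `[[`, character(1), 2),
    label = vapply(raw, `[[`, character(1), 3),
    category = vapply(raw, `[[`, integer(1), 4),
    cancer_mean = vapply(raw, `[[`, numeric(1), 5),
    cancer_sd = vapply(raw, `[[`, numeric(1), 6),
    control_mean = vapply(raw, `[[`, numeric(1), 7),
    control_sd = vapply(raw, `[[`, numeric(1), 8),
    family = vapply(raw, `[[`, character(1), 9),
    shift = vapply(raw, `[[`, numeric(1), 10),
    stringsAsFactors = FALSE)
  stopifnot(identical(out$id, 1:57))
  out
}

#' Names of the 57 panel features in canonical order
#'
#' @return character(57) machine-readable feature names, ordered by catalogue
#'   id.
#' @export
featureNames57 <- function() featureCatalog()$name
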