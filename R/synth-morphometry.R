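# Morphometric feature naming and generation. The feature battery mirrors a
# standard surface-reconstruction output: nine measures for each of 34
# cortical regions per hemisphere plus three measures for 45 non-cortical
# segmentations, 747 features in all.

cortical_regions <- function() c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
  "transversetemporal", "insula", "frontalpole")

cortical_measures <- function() c(
  "NumVert", "SurfArea", "GrayVol", "ThickAvg", "ThickStd",
  "MeanCurv", "GausCurv", "FoldInd", "CurvInd")

noncortical_regions <- function() c(
  "Left-Lateral-Ventricle", "Left-Inf-Lat-Vent", "Left-Cerebellum-White-Matter",
  "Left-Cerebellum-Cortex", "Left-Thalamus-Proper", "Left-Caudate",
  "Left-Putamen", "Left-Pallidum", "3rd-Ventricle", "4th-Ventricle",
  "Brain-Stem", "Left-Hippocampus", "Left-Amygdala", "CSF",
  "Left-Accumbens-area", "Left-VentralDC", "Left-vessel", "Left-choroid-plexus",
  "Right-Lateral-Ventricle", "Right-Inf-Lat-Vent",
  "Right-Cerebellum-White-Matter", "Right-Cerebellum-Cortex",
  "Right-Thalamus-Proper", "Right-Caudate", "Right-Putamen", "Right-Pallidum",
  "Right-Hippocampus", "Right-Amygdala", "Right-Accumbens-area",
  "Right-VentralDC", "Right-vessel", "Right-choroid-plexus", "5th-Ventricle",
  "WM-hypointensities", "Left-WM-hypointensities", "Right-WM-hypointensities",
  "non-WM-hypointensities", "Left-non-WM-hypointensities",
  "Right-non-WM-hypointensities", "Optic-Chiasm", "CC_Posterior",
  "CC_Mid_Posterior", "CC_Central", "CC_Mid_Anterior", "CC_Anterior")

noncortical_measures <- function() c("Volume_mm3", "normMean", "normStdDev")

# plausible scale per measure type: c(mean, sd)
morph_measure_scales <- function() list(
  NumVert = c(5000, 800), SurfArea = c(3000, 500), GrayVol = c(8000, 1200),
  ThickAvg = c(2.5, 0.15), ThickStd = c(0.5, 0.08), MeanCurv = c(0.12, 0.02),
  GausCurv = c(0.05, 0.015), FoldInd = c(50, 12), CurvInd = c(5, 1.5),
  Volume_mm3 = c(4000, 700), normMean = c(80, 6), normStdDev = c(8, 1.5))

#' Names of the morphometric feature battery
#'
#' @return Character vector of the 747 morphometric feature names: 9 measures
#'   for each of 34 cortical regions in both hemispheres
#'   (`lh_<region>_<measure>`, `rh_<region>_<measure>`) and 3 measures for 45
#'   non-cortical segmentations (`<region>_<measure>`).
#' @export
morphometry_feature_names <- function() {
  cort <- as.vector(outer(
    as.vector(outer(c("lh", "rh"), cortical_regions(), paste, sep = "_")),
    cortical_measures(), paste, sep = "_"))
  nonc <- as.vector(outer(noncortical_regions(), noncortical_measures(),
                          paste, sep = "_"))
  c(cort, nonc)
}

morph_column_sd <- function(column) {
  scales <- morph_measure_scales()
  meas <- names(scales)[vapply(names(scales), function(m) endsWith(column, m),
                               logical(1))]
  scales[[meas[1]]][2]
}

# core generator shared by generate_morphometry() and generate_cohort();
# assumes the caller set the RNG state
generate_morphometry_table <- function(pheno, config) {
  cols <- morphometry_feature_names()
  scales <- morph_measure_scales()
  n <- nrow(pheno)
  vals <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (j in seq_along(cols)) {
    sc <- scales[[sub("^.*_", "", cols[j])]]
    if (is.null(sc)) {  # measure names containing "_" (Volume_mm3)
      meas <- names(scales)[vapply(names(scales), function(m) endsWith(cols[j], m),
                                   logical(1))]
      sc <- scales[[meas[1]]]
    }
    vals[, j] <- stats::rnorm(n, sc[1], sc[2])
  }
  me <- config$morph_effect
  if (!is.null(me)) {
    adhd <- pheno$dx != "TD"
    for (k in seq_len(nrow(me))) {
      j <- me$column[k]
      vals[adhd, j] <- vals[adhd, j] + me$d[k] * morph_column_sd(j)
    }
  }
  cbind(pheno[, c("subject_id", "site", "dx")], as.data.frame(vals),
        stringsAsFactors = FALSE)
}

#' Generate a morphometry table for a configured cohort
#'
#' Stand-alone morphometric generator: draws the phenotype labels implied by
#' the configuration, then a 747-column feature table with the configured
#' standardized class effects applied to ADHD subjects.
#'
#' @param config A [cohort_config()].
#' @return Data frame with `subject_id`, `site`, `dx` and the 747 features
#'   named as in [morphometry_feature_names()].
#' @export
generate_morphometry <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  pheno <- with_seed(derive_seed(config$seed, "phenotypes"),
                     generate_phenotypes(config))
  with_seed(derive_seed(config$seed, "morphometry"),
            generate_morphometry_table(pheno, config))
}
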