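#' Feature manifest: the 107-feature universe
#'
#' Names, classes and human-readable labels of every feature the extractor
#' produces: 14 shape/size (SS), 18 first-order statistics (FOS), and 75
#' textural features over five matrix families (24 GLCM, 16 GLRLM,
#' 16 GLSZM, 5 NGTDM, 14 GLDM).
#'
#' @return data.frame with columns `feature` (e.g. `"glcm_JointEntropy"`),
#'   `class` (SS/FOS/GLCM/GLRLM/GLSZM/NGTDM/GLDM), `label` (English name)
#'   and `group` (SS/FOS/textural).
#' @export
feature_manifest <- function() {
  spell <- function(x) {
    # CamelCase -> spaced lower-case label
    s <- gsub("([a-z0-9])([A-Z])", "\\1 \\2", x)
    s <- gsub("([A-Z])([A-Z][a-z])", "\\1 \\2", s)
    s <- tolower(s)
    paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  }
  base <- rbind(
    data.frame(class = "SS", name = names(.shape_template)),
    data.frame(class = "FOS", name = names(.fos_template)),
    data.frame(class = "GLCM", name = names(.glcm_template)),
    data.frame(class = "GLRLM", name = names(.glrlm_template)),
    data.frame(class = "GLSZM", name = names(.glszm_template)),
    data.frame(class = "NGTDM", name = names(.ngtdm_template)),
    data.frame(class = "GLDM", name = names(.gldm_template))
  )
  prefix <- c(SS = "shape", FOS = "firstorder", GLCM = "glcm",
              GLRLM = "glrlm", GLSZM = "glszm", NGTDM = "ngtdm",
              GLDM = "gldm")
  lab <- spell(base$name)
  lab <- sub("^10 percentile$", "10th percentile", lab)
  lab <- sub("^90 percentile$", "90th percentile", lab)
  lab <- sub("^Maximum2 d diameter", "Maximum 2D diameter", lab)
  lab <- sub("^Maximum3 d diameter$", "Maximum 3D diameter", lab)
  lab <- sub("slice$", "(slice)", lab)
  lab[base$name == "Maximum2DDiameterColumn"] <- "Maximum 2D diameter (column)"
  lab[base$name == "Maximum2DDiameterRow"] <- "Maximum 2D diameter (row)"
  lab[base$name == "Maximum2DDiameterSlice"] <- "Maximum 2D diameter (slice)"
  lab[base$name == "SumSquares"] <- "Sum squares"
  lab[base$name == "SurfaceVolumeRatio"] <- "Surface to volume ratio"
  lab[base$name == "Id"] <- "Inverse difference"
  lab[base$name == "Idm"] <- "Inverse difference moment"
  lab[base$name == "Idmn"] <- "Inverse difference moment normalized"
  lab[base$name == "Idn"] <- "Inverse difference normalized"
  lab[base$name == "Imc1"] <- "Informational measure of correlation 1"
  lab[base$name == "Imc2"] <- "Informational measure of correlation 2"
  lab[base$name == "MCC"] <- "Maximal correlation coefficient"
  lab[base$class == "GLRLM" & base$name == "GrayLevelNonUniformity"] <-
    "Gray level non-uniformity (GLRLM)"
  lab[base$class == "GLDM" & base$name == "GrayLevelNonUniformity"] <-
    "Gray level non-uniformity (GLDM)"
  lab[base$class == "GLDM" & base$name == "HighGrayLevelEmphasis"] <-
    "High gray level emphasis (GLDM)"
  lab[base$class == "GLDM" & base$name == "LowGrayLevelEmphasis"] <-
    "Low gray level emphasis (GLDM)"
  data.frame(
    feature = paste(prefix[base$class], base$name, sep = "_"),
    class = base$class,
    label = lab,
    group = ifelse(base$class == "SS", "SS",
                   ifelse(base$class == "FOS", "FOS", "textural")),
    stringsAsFactors = FALSE
  )
}

.shape_template <- c(
  Elongation = 0, Flatness = 0, LeastAxisLength = 0, MajorAxisLength = 0,
  Maximum2DDiameterColumn = 0, Maximum2DDiameterRow = 0,
  Maximum2DDiameterSlice = 0, Maximum3DDiameter = 0, MeshVolume = 0,
  MinorAxisLength = 0, Sphericity = 0, SurfaceArea = 0,
  SurfaceVolumeRatio = 0, VoxelVolume = 0)
.fos_template <- c(
  `10Percentile` = 0, `90Percentile` = 0, Energy = 0, Entropy = 0,
  InterquartileRange = 0, Kurtosis = 0, Maximum = 0, Mean = 0,
  MeanAbsoluteDeviation = 0, Median = 0, Minimum = 0, Range = 0,
  RobustMeanAbsoluteDeviation = 0, RootMeanSquared = 0, Skewness = 0,
  TotalEnergy = 0, Uniformity = 0, Variance = 0)
.glcm_template <- c(
  Autocorrelation = 0, ClusterProminence = 0, ClusterShade = 0,
  ClusterTendency = 0, Contrast = 0, Correlation = 0, DifferenceAverage = 0,
  DifferenceEntropy = 0, DifferenceVariance = 0, Id = 0, Idm = 0, Idmn = 0,
  Idn = 0, Imc1 = 0, Imc2 = 0, InverseVariance = 0, JointAverage = 0,
  JointEnergy = 0, JointEntropy = 0, MCC = 0, MaximumProbability = 0,
  SumAverage = 0, SumEntropy = 0, SumSquares = 0)
.glrlm_template <- c(
  ShortRunEmphasis = 0, LongRunEmphasis = 0, GrayLevelNonUniformity = 0,
  GrayLevelNonUniformityNormalized = 0, RunLengthNonUniformity = 0,
  RunLengthNonUniformityNormalized = 0, RunPercentage = 0,
  GrayLevelVariance = 0, RunVariance = 0, RunEntropy = 0,
  LowGrayLevelRunEmphasis = 0, HighGrayLevelRunEmphasis = 0,
  ShortRunLowGrayLevelEmphasis = 0, ShortRunHighGrayLevelEmphasis = 0,
  LongRunLowGrayLevelEmphasis = 0, LongRunHighGrayLevelEmphasis = 0)
.glszm_template <- c(
  SmallAreaEmphasis = 0, LargeAreaEmphasis = 0, GrayLevelNonUniformity = 0,
  GrayLevelNonUniformityNormalized = 0, SizeZoneNonUniformity = 0,
  SizeZoneNonUniformityNormalized = 0, ZonePercentage = 0,
  GrayLevelVariance = 0, ZoneVariance = 0, ZoneEntropy = 0,
  LowGrayLevelZoneEmphasis = 0, HighGrayLevelZoneEmphasis = 0,
  SmallAreaLowGrayLevelEmphasis = 0, SmallAreaHighGrayLevelEmphasis = 0,
  LargeAreaLowGrayLevelEmphasis = 0, LargeAreaHighGrayLevelEmphasis = 0)
.ngtdm_template <- c(
  Coarseness = 0, Contrast = 0, Busyness = 0, Complexity = 0, Strength = 0)
.gldm_template <- c(
  SmallDependenceEmphasis = 0, LargeDependenceEmphasis = 0,
  GrayLevelNonUniformity = 0, DependenceNonUniformity = 0,
  DependenceNonUniformityNormalized = 0, GrayLevelVariance = 0,
  DependenceVariance = 0, DependenceEntropy = 0, LowGrayLevelEmphasis = 0,
  HighGrayLevelEmphasis = 0, SmallDependenceLowGrayLevelEmphasis = 0,
  SmallDependenceHighGrayLevelEmphasis = 0,
  LargeDependenceLowGrayLevelEmphasis = 0,
  LargeDependenceHighGrayLevelEmphasis = 0)

#' Extract all 107 radiomic features from one ROI
#'
#' Runs the shape/size, first-order and five texture-matrix extractors on
#' one image/mask pair with fixed-bin-number discretization. Deterministic.
#'
#' @param image a [volume_image()].
#' @param mask a [roi_mask()] on the same grid.
#' @param Ng number of gray levels for discretization (default 32).
#' @return Named numeric vector of exactly 107 features, names matching
#'   [feature_manifest()].
#' @export
extract_all <- function(image, mask, Ng = 32) {
  disc <- discretize_fixed_bin_number(image, mask, Ng)
  pref <- function(v, p) stats::setNames(v, paste0(p, "_", names(v)))
  out <- c(
    pref(shape_features(mask, image$spacing), "shape"),
    pref(first_order_features(image, mask, disc), "firstorder"),
    pref(glcm_features(disc), "glcm"),
    pref(glrlm_features(disc), "glrlm"),
    pref(glszm_features(disc), "glszm"),
    pref(ngtdm_features(disc), "ngtdm"),
    pref(gldm_features(disc), "gldm")
  )
  universe <- feature_manifest()$feature
  stopifnot(setequal(names(out), universe))
  out[universe]
}
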