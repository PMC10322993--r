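#' Desikan-Killiany cortical region names
#'
#' The 34 gyral/sulcal cortical regions per hemisphere of the
#' Desikan-Killiany parcellation, in a fixed canonical order used by every
#' map-valued object in this package.
#'
#' @return Character vector of 34 region names.
#' @export
dk_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")
}

#' Subcortical structures carried by the cohort table
#'
#' Volume-only structures simulated and analysed per hemisphere; the first
#' three form the striatal composite.
#'
#' @return Character vector of structure names.
#' @export
subcortical_structures <- function() {
  c("caudate", "putamen", "pallidum", "hippocampus")
}

#' Lobe assignment for the Desikan-Killiany regions
#'
#' Total partition of the 34 cortical regions into the four classical lobes.
#' Cingulate regions are split between the frontal (anterior) and parietal
#' (posterior) lobes; the insula and the medial temporal regions
#' (entorhinal, parahippocampal, temporal pole) are assigned to the temporal
#' lobe.
#'
#' @return Named character vector mapping region name to one of
#'   `"frontal"`, `"parietal"`, `"temporal"`, `"occipital"`.
#' @export
dk_lobes <- function() {
  lobes <- c(
    bankssts = "temporal", caudalanteriorcingulate = "frontal",
    caudalmiddlefrontal = "frontal", cuneus = "occipital",
    entorhinal = "temporal", frontalpole = "frontal", fusiform = "temporal",
    inferiorparietal = "parietal", inferiortemporal = "temporal",
    insula = "temporal", isthmuscingulate = "parietal",
    lateraloccipital = "occipital", lateralorbitofrontal = "frontal",
    lingual = "occipital", medialorbitofrontal = "frontal",
    middletemporal = "temporal", paracentral = "frontal",
    parahippocampal = "temporal", parsopercularis = "frontal",
    parsorbitalis = "frontal", parstriangularis = "frontal",
    pericalcarine = "occipital", postcentral = "parietal",
    posteriorcingulate = "parietal", precentral = "frontal",
    precuneus = "parietal", rostralanteriorcingulate = "frontal",
    rostralmiddlefrontal = "frontal", superiorfrontal = "frontal",
    superiorparietal = "parietal", superiortemporal = "temporal",
    supramarginal = "parietal", temporalpole = "temporal",
    transversetemporal = "temporal")
  stopifnot(setequal(names(lobes), dk_regions()))
  lobes[dk_regions()]
}

# Canonical bilateral region keys "<region>_<hemi>", lh block then rh block.
bilateral_regions <- function(regions = dk_regions()) {
  c(paste0(regions, "_lh"), paste0(regions, "_rh"))
}

# Column names in a cohort table for one measure over all bilateral regions.
measure_columns <- function(measure, regions = dk_regions()) {
  paste0(bilateral_regions(regions), "_", measure)
}

subcortical_columns <- function() {
  paste0(bilateral_regions(subcortical_structures()), "_vol")
}

# Global covariate paired with each regional measure family.
global_for_measure <- function(measure) {
  switch(measure,
    gmv = "tbv_mm3", vol = "tbv_mm3",
    sa = "tsa_mm2",
    ct = "wmt_mm",
    stop("unknown measure: ", measure))
}

measure_families <- function() c("gmv", "sa", "ct", "vol")
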