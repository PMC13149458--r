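#' AAL-90 region labels
#'
#' Region names of the automated anatomical labeling atlas (AAL, version 1)
#' restricted to the 90 cortical and subcortical regions (cerebellum
#' excluded), in the standard atlas order with left/right hemispheres
#' alternating. These labels define the canonical node order used for all
#' connectomes of a cohort.
#'
#' @return Character vector of 90 unique region names, e.g. `"Amygdala_L"`.
#' @export
#' @examples
#' labs <- aal90_labels()
#' length(labs)
aal90_labels <- function() {
  stems <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
  )
  as.vector(t(outer(stems, c("_L", "_R"), paste0)))
}

#' Validate a set of region labels
#'
#' Labels must be unique non-empty strings; their order is the node order of
#' every connectome that carries them. Any number of regions is accepted so
#' that reduced parcellations can be used in simulation studies; the default
#' atlas is [aal90_labels()].
#'
#' @param labels character vector of region names.
#' @return The labels, invisibly, after validation.
#' @export
validate_labels <- function(labels) {
  if (!is.character(labels) || length(labels) < 2) {
    stop("labels must be a character vector with at least 2 region names")
  }
  if (anyDuplicated(labels)) {
    stop("region labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (any(!nzchar(labels)) || anyNA(labels)) {
    stop("region labels must be non-empty strings")
  }
  invisible(labels)
}

#' Read region labels from a file (one name per line)
#'
#' @param path file with one region name per line.
#' @return character vector of validated labels.
#' @export
read_labels <- function(path) {
  labels <- readLines(path, warn = FALSE)
  labels <- trimws(labels)
  labels <- labels[nzchar(labels)]
  validate_labels(labels)
  labels
}
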