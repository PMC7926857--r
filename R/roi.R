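# Desikan-Killiany cortical parcellation: 34 regions per hemisphere.
# Canonical feature order is left hemisphere then right, each hemisphere
# alphabetical by region label.
.dk_labels <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal"
)

#' Canonical Desikan-Killiany ROI names
#'
#' The 68 cortical regions of the Desikan-Killiany atlas in the package's
#' canonical order: the 34 left-hemisphere regions (prefix `lh_`) in
#' alphabetical order, followed by the 34 right-hemisphere regions
#' (prefix `rh_`). Every cortical-thickness table handled by the package is
#' reordered to this sequence, so feature vectors and fitted hyperplane
#' normals are always index-aligned.
#'
#' @return Character vector of length 68.
#' @examples
#' head(dk_roi_names())
#' @export
dk_roi_names <- function() {
  c(paste0("lh_", .dk_labels), paste0("rh_", .dk_labels))
}

# resolve a set of atlas labels (optionally hemisphere-specific) to indices
# in the canonical 68-vector; `hemi` one of "both", "lh", "rh"
.roi_index <- function(labels, hemi = "both") {
  roi <- dk_roi_names()
  wanted <- switch(hemi,
    both = c(paste0("lh_", labels), paste0("rh_", labels)),
    lh = paste0("lh_", labels),
    rh = paste0("rh_", labels)
  )
  bad <- setdiff(wanted, roi)
  if (length(bad) > 0) {
    stop("unknown ROI name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  match(wanted, roi)
}
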