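#' Desikan-Killiany cortical parcellation names
#'
#' The fixed, ordered dictionary of the 68 cortical regions of interest (34 per
#' hemisphere) used throughout the pipeline. Regional tables, parcellations and
#' statistical outputs all key ROIs by these names, in this order, so results can
#' be joined against external atlases and plotted by downstream tools.
#'
#' @param hemi Which hemisphere(s) to return: `"both"` (default, 68 names with
#'   `lh_`/`rh_` prefixes), `"lh"` or `"rh"` (34 prefixed names), or `"bare"`
#'   (the 34 unprefixed region names).
#' @return Character vector of ROI names.
#' @export
#' @examples
#' length(dk_roi_names())    # 68
#' head(dk_roi_names("bare"))
dk_roi_names <- function(hemi = c("both", "lh", "rh", "bare")) {
  hemi <- match.arg(hemi)
  base <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
    "temporalpole", "transversetemporal", "insula"
  )
  switch(hemi,
    bare = base,
    lh   = paste0("lh_", base),
    rh   = paste0("rh_", base),
    both = c(paste0("lh_", base), paste0("rh_", base))
  )
}

# label reserved for vertices outside the cortical parcellation
UNKNOWN_LABEL <- "unknown"
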