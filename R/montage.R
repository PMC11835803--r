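#' Default 62-channel scalp montage
#'
#' Channel labels of a 62-electrode extended 10-20 scalp montage (the scalp
#' subset of a 64-channel cap, mastoid and ocular channels excluded).
#'
#' @return Character vector of 62 channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fpz", "Fp2", "AF3", "AF4",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "CB1", "O1", "Oz", "O2", "CB2")
}

#' Default scalp-region map
#'
#' Partition of the montage into four disjoint scalp regions used for
#' region-level group statistics. Channels not listed (far temporal-occipital
#' and cerebellar sites) belong to no region and are excluded from regional
#' averages. The map is an ordinary named list and can be edited freely.
#'
#' @return Named list of character vectors: `frontal`, `central`, `parietal`,
#'   `occipital`.
#' @export
default_region_map <- function() {
  list(
    frontal  = c("Fp1", "Fp2", "AF3", "AF4", "F7", "F5", "F3", "F1", "Fz",
                 "F2", "F4", "F6", "F8"),
    central  = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
                 "FT8", "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
    parietal = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
                 "TP8", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
    occipital = c("PO3", "POz", "PO4", "O1", "Oz", "O2")
  )
}

validate_region_map <- function(map, labels) {
  if (anyDuplicated(unlist(map)))
    stop("region map assigns a channel to more than one region")
  missing <- setdiff(unlist(map), labels)
  # regions may reference channels absent from a reduced montage; they are
  # simply dropped, but a region with no channel present is an error
  present <- lapply(map, intersect, labels)
  empty <- names(present)[vapply(present, length, 1L) == 0L]
  if (length(empty))
    stop("region(s) with no channel in the montage: ",
         paste(empty, collapse = ", "))
  present
}
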