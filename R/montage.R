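#' Standard 32-channel montage
#'
#' Channel names (10/20 nomenclature) of the 32-electrode recording montage
#' assumed throughout the package: FP1, FP2, F7, F3, Fz, F4, F8, FC5, FC1,
#' FCz, FC2, FC6, T7, C3, Cz, C4, T8, TP9, CP5, CP1, CP2, CP6, TP10, P7, P3,
#' Pz, P4, P8, O1, O2, F9 and F10.
#'
#' @return Character vector of 32 channel names.
#' @export
default_montage <- function() {
  c("FP1", "FP2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FCz", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "O2", "F9", "F10")
}

#' Construct a left/right mirror map for a montage
#'
#' A mirror map pairs each left-hemisphere channel with its right homologue
#' across the nasion-inion axis and lists the midline channels that map onto
#' themselves.  Together the pairs and the midline must cover every channel
#' of the montage exactly once, and applying the map twice is the identity.
#'
#' @param pairs Two-column character matrix; each row an unordered
#'   left/right channel pair.
#' @param midline Character vector of midline channel names.
#' @return An object of class `mirror_map`.
#' @seealso [default_mirror_map()], [mirror_remap()]
#' @export
mirror_map <- function(pairs, midline) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("`pairs` must have two columns")
  all_ch <- c(as.vector(pairs), midline)
  if (anyDuplicated(all_ch)) {
    stop("mirror map mentions channel(s) more than once: ",
         paste(unique(all_ch[duplicated(all_ch)]), collapse = ", "))
  }
  structure(list(pairs = pairs, midline = as.character(midline)),
            class = "mirror_map")
}

#' Mirror map for the standard 32-channel montage
#'
#' Left/right homologue pairs (F7-F8, F3-F4, FC5-FC6, FC1-FC2, T7-T8, C3-C4,
#' TP9-TP10, CP5-CP6, CP1-CP2, P7-P8, P3-P4, O1-O2, FP1-FP2, F9-F10) and the
#' midline set (Fz, FCz, Cz, Pz).
#'
#' @return A `mirror_map` covering [default_montage()].
#' @export
default_mirror_map <- function() {
  mirror_map(
    pairs = rbind(
      c("FP1", "FP2"), c("F7", "F8"), c("F3", "F4"), c("FC5", "FC6"),
      c("FC1", "FC2"), c("T7", "T8"), c("C3", "C4"), c("TP9", "TP10"),
      c("CP5", "CP6"), c("CP1", "CP2"), c("P7", "P8"), c("P3", "P4"),
      c("O1", "O2"), c("F9", "F10")),
    midline = c("Fz", "FCz", "Cz", "Pz"))
}

# Permutation of channel indices realizing the mirror swap; errors if any
# channel of `channels` is not covered by the map.
.mirror_permutation <- function(map, channels) {
  stopifnot(inherits(map, "mirror_map"))
  covered <- c(as.vector(map$pairs), map$midline)
  missing <- setdiff(channels, covered)
  if (length(missing) > 0L) {
    stop("channel(s) missing from mirror map: ", paste(missing, collapse = ", "))
  }
  perm <- seq_along(channels)
  names(perm) <- channels
  for (i in seq_len(nrow(map$pairs))) {
    l <- map$pairs[i, 1L]; r <- map$pairs[i, 2L]
    li <- match(l, channels); ri <- match(r, channels)
    if (!is.na(li) && !is.na(ri)) {
      perm[li] <- ri
      perm[ri] <- li
    } else if (xor(is.na(li), is.na(ri))) {
      stop("channel pair ", l, "/", r, " only partially present; cannot mirror")
    }
  }
  unname(perm)
}
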