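#' Canonical sEMG channel layout
#'
#' The BMCA montage records 10 lower-limb muscles, five per side:
#' iliopsoas (IL), rectus femoris (RF), tibialis anterior (TA), extensor
#' hallucis longus (EHL) and gastrocnemius (G), prefixed `R-`/`L-`.
#' Channels close to the stimulation electrode (the iliopsoas pair by
#' default) carry strong stimulus artifacts and are flagged for median
#' filtering.
#'
#' @param names ordered character vector of exactly 10 unique channel names.
#' @param artifact_channels subset of `names` flagged for median filtering.
#' @return an object of class `channel_layout`.
#' @examples
#' channel_layout()
#' @export
channel_layout <- function(names = default_channels(),
                           artifact_channels = c("R-IL", "L-IL")) {
  if (length(names) != 10L || anyDuplicated(names))
    stop("channel layout requires exactly 10 unique channel names")
  if (!all(artifact_channels %in% names))
    stop("artifact_channels must be a subset of the channel names")
  structure(list(names = as.character(names),
                 artifact_channels = as.character(artifact_channels)),
            class = "channel_layout")
}

#' @rdname channel_layout
#' @export
default_channels <- function() {
  c("R-IL", "R-RF", "R-TA", "R-EHL", "R-G",
    "L-IL", "L-RF", "L-TA", "L-EHL", "L-G")
}

#' Names of the six BMCA voluntary movements
#'
#' Bilateral and single-sided hip flexion/extension and ankle
#' dorsiflexion/plantarflexion.
#' @return character vector of length 6.
#' @export
bmca_movements <- function() {
  c("BL-Hip", "R-Hip", "L-Hip", "BL-Ankle", "R-Ankle", "L-Ankle")
}

#' @export
print.channel_layout <- function(x, ...) {
  cat("sEMG channel layout (", length(x$names), " channels)\n", sep = "")
  cat("  ", paste(x$names, collapse = ", "), "\n", sep = "")
  cat("  artifact-flagged: ", paste(x$artifact_channels, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
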