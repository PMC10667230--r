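#' Anatomical label set of the calvaria representation
#'
#' The standardized spherical map carries one categorical label per grid
#' point: five bone plates (LF, RF, LP, RP, O = left/right frontal,
#' left/right parietal, occipital), six sutures (M, LC, RC, S, LL, RL =
#' metopic, left/right coronal, sagittal, left/right lambdoid) and the
#' calvaria--cranial-base boundary ring (BASE).
#'
#' `label_codes()` returns the documented integer code table used by the
#' on-disk map format.
#'
#' @return Character vector of label names, or a named integer vector of
#'   file codes.
#' @export
all_labels <- function() {
  c("LF", "RF", "LP", "RP", "O", "M", "LC", "RC", "S", "LL", "RL", "BASE")
}

#' @rdname all_labels
#' @export
bone_labels <- function() c("LF", "RF", "LP", "RP", "O")

#' @rdname all_labels
#' @export
suture_labels <- function() c("M", "LC", "RC", "S", "LL", "RL")

#' @rdname all_labels
#' @export
label_codes <- function() {
  stats::setNames(seq_along(all_labels()), all_labels())
}

# Mirror partner (left-right, x -> -x) of each label.
mirror_label <- function(lab) {
  swap <- c(LF = "RF", RF = "LF", LP = "RP", RP = "LP", O = "O", M = "M",
            LC = "RC", RC = "LC", S = "S", LL = "RL", RL = "LL", BASE = "BASE")
  unname(swap[lab])
}
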