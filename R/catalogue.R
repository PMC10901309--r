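#' The 10-item movement-toward-midline (MTM) catalogue
#'
#' The catalogue of infant midline-contact behaviours scored by observation:
#' foot-to-foot (`FF`), foot-to-leg (`FL`), hand-to-hand (`HH`), hand-to-face
#' (`HF`), hand-to-mouth (`HM`), hand-to-trunk (`HT`), hand-to-leg (`HL`),
#' `PEDIPULATION` (feet sliding/grabbing in midline contact), `MANIPULATION`
#' (both hands brought together with sliding/grabbing) and `FIDDLING`
#' (repeated touching/grasping of an object or clothing). Items split into a
#' lower-limb group (`FF`, `FL`, `PEDIPULATION`) and an upper-limb group (the
#' remaining seven); the groups are disjoint and cover the catalogue.
#'
#' @return A list with character vectors `items`, `lower`, `upper`.
#' @examples
#' cat <- mtm_catalogue()
#' setdiff(cat$items, c(cat$lower, cat$upper)) # character(0)
#' @export
mtm_catalogue <- function() {
  lower <- c("FF", "FL", "PEDIPULATION")
  upper <- c("HH", "HF", "HM", "HT", "HL", "MANIPULATION", "FIDDLING")
  list(items = c(lower, upper), lower = lower, upper = upper)
}

# Canonicalize item labels (case-insensitive); error on unknown items.
canonical_items <- function(item) {
  cat <- mtm_catalogue()
  up <- toupper(trimws(as.character(item)))
  bad <- setdiff(unique(up), cat$items)
  if (length(bad) > 0L) {
    stop_mtm(
      sprintf(
        "unknown MTM item(s): %s (catalogue: %s)",
        paste(bad, collapse = ", "), paste(cat$items, collapse = ", ")
      ),
      "mtmpose_catalogue_error"
    )
  }
  up
}
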