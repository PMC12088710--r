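#' The ten-class OCT annotation schema
#'
#' Integer coding of the ten tissue/artefact classes used for pixel-wise
#' annotation of intracoronary OCT cross-sections. Background is 0 so that
#' sparse masks compress well; the remaining classes are coded 1..9.
#'
#' @return A list with components:
#'   \describe{
#'     \item{class_ids}{named integer vector mapping class name to code
#'       (background = 0, lumen = 1, guidewire_artefact = 2, side_branch = 3,
#'       intima = 4, media = 5, lipid = 6, calcium = 7, thrombus = 8,
#'       plaque_rupture = 9).}
#'     \item{plaque_classes}{names of the two quantified plaque classes
#'       (\code{"lipid"}, \code{"calcium"}).}
#'     \item{cca_exempt_classes}{classes never removed by connected-component
#'       filtering (\code{"thrombus"}, \code{"plaque_rupture"}).}
#'   }
#' @examples
#' sch <- label_schema()
#' sch$class_ids[["lipid"]]
#' @export
label_schema <- function() {
  ids <- c(
    background         = 0L,
    lumen              = 1L,
    guidewire_artefact = 2L,
    side_branch        = 3L,
    intima             = 4L,
    media              = 5L,
    lipid              = 6L,
    calcium            = 7L,
    thrombus           = 8L,
    plaque_rupture     = 9L
  )
  list(
    class_ids          = ids,
    plaque_classes     = c("lipid", "calcium"),
    cca_exempt_classes = c("thrombus", "plaque_rupture")
  )
}

#' Look up a class code by name
#'
#' @param name class name from [label_schema()].
#' @return integer class code.
#' @export
class_code <- function(name) {
  ids <- label_schema()$class_ids
  if (!name %in% names(ids)) {
    stop("unknown class name: ", name, call. = FALSE)
  }
  ids[[name]]
}

# internal shorthands used throughout
.CODES <- c(
  background = 0L, lumen = 1L, guidewire_artefact = 2L, side_branch = 3L,
  intima = 4L, media = 5L, lipid = 6L, calcium = 7L, thrombus = 8L,
  plaque_rupture = 9L
)

#' Validate a frame against the label schema
#'
#' Report-only check: a frame is expected to contain at least one lumen pixel
#' (the centroid anchor of all quantification) and only codes 0..9.
#'
#' @param frame an [oct_frame()].
#' @return character vector of issue codes, empty when the frame is
#'   well-formed. Possible issues: \code{"ISSUE_NO_LUMEN"},
#'   \code{"ISSUE_UNKNOWN_LABEL"}.
#' @export
validate_frame <- function(frame) {
  stopifnot(inherits(frame, "oct_frame"))
  issues <- character(0)
  vals <- frame$labels
  if (!any(vals == .CODES[["lumen"]])) {
    issues <- c(issues, "ISSUE_NO_LUMEN")
  }
  if (any(vals < 0L | vals > 9L)) {
    issues <- c(issues, "ISSUE_UNKNOWN_LABEL")
  }
  issues
}
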