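#' Define a marker
#'
#' A marker is one measured quantity per participant: a plasma biomarker
#' concentration or a cognitive test score. Each marker declares the direction
#' its values move as Alzheimer's pathology advances, which orients the
#' abnormal mixture component and the sign convention of composite scores.
#'
#' @param name Unique marker name (string).
#' @param modality `"plasma"` or `"cognitive"`.
#' @param direction Direction of pathological change: `"increase"` or
#'   `"decrease"`.
#' @param units Free-text measurement units (e.g. `"pg/mL"`).
#' @return A one-row data frame with columns `name`, `modality`, `direction`,
#'   `units`.
#' @seealso [default_panel()]
#' @export
marker_def <- function(name, modality = c("plasma", "cognitive"),
                       direction = c("increase", "decrease"), units = "") {
  modality <- match.arg(modality)
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  data.frame(name = name, modality = modality, direction = direction,
             units = units, stringsAsFactors = FALSE)
}

#' Default marker panel
#'
#' The nine-marker panel used throughout: five plasma biomarkers (the
#' amyloid-beta 42/40 ratio, which falls as brain amyloid accumulates, and
#' p-tau181, p-tau231, NfL and GFAP, which rise with tauopathy,
#' neurodegeneration and neuroinflammation) and four cognitive scores
#' (paired-associates first-trial memory, Tower of London planning, NEPSY-II
#' visuomotor precision, and IED set-shifting stages completed), all of which
#' fall with decline.
#'
#' @return A data frame of marker definitions (one row per marker).
#' @export
default_panel <- function() {
  rbind(
    marker_def("abeta42_40", "plasma", "decrease", "ratio"),
    marker_def("ptau181", "plasma", "increase", "pg/mL"),
    marker_def("ptau231", "plasma", "increase", "pg/mL"),
    marker_def("nfl", "plasma", "increase", "pg/mL"),
    marker_def("gfap", "plasma", "increase", "pg/mL"),
    marker_def("pal", "cognitive", "decrease", "score"),
    marker_def("tol", "cognitive", "decrease", "score"),
    marker_def("nepsy", "cognitive", "decrease", "score"),
    marker_def("ied", "cognitive", "decrease", "score")
  )
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  need <- c("name", "modality", "direction", "units")
  if (!all(need %in% names(panel)))
    stop("panel must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(panel$name))
    stop("panel: marker names must be unique")
  if (!all(panel$modality %in% c("plasma", "cognitive")))
    stop("panel: modality must be 'plasma' or 'cognitive'")
  if (!all(panel$direction %in% c("increase", "decrease")))
    stop("panel: direction must be 'increase' or 'decrease'")
  invisible(panel)
}

#' Marker names by modality
#'
#' @param panel A marker panel data frame.
#' @return Character vector of marker names.
#' @export
plasma_markers <- function(panel = default_panel()) {
  validate_panel(panel)
  panel$name[panel$modality == "plasma"]
}

#' @rdname plasma_markers
#' @export
cognitive_markers <- function(panel = default_panel()) {
  validate_panel(panel)
  panel$name[panel$modality == "cognitive"]
}

marker_direction <- function(panel, marker) {
  panel$direction[match(marker, panel$name)]
}
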