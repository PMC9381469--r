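# Vertebral-level coordinate system.
#
# The study span is C2-T12 for calibration plus L1-L3 as the lumbar reference;
# L4/L5 are representable for input tolerance but never enter the reference.
# C1 has no measurable trabecular vertebral body and is not representable.

.LEVEL_NAMES <- c(paste0("C", 2:7), paste0("T", 1:12), paste0("L", 1:5))
.LEVEL_REGIONS <- c(rep("cervical", 6), rep("thoracic", 12), rep("lumbar", 5))

#' Vertebral levels of the spine model
#'
#' The 23 representable vertebral levels (C2--C7, T1--T12, L1--L5) with their
#' anatomical region and craniocaudal ordinal (C2 = 1 ... L5 = 23). C1 is not
#' representable: it lacks a trabecular vertebral body, so no trabecular vBMD
#' can be measured there.
#'
#' @return A `data.frame` with columns `name`, `region`, `ordinal`.
#' @export
#' @examples
#' vertebralLevels()
vertebralLevels <- function() {
  data.frame(
    name = .LEVEL_NAMES,
    region = .LEVEL_REGIONS,
    ordinal = seq_along(.LEVEL_NAMES),
    stringsAsFactors = FALSE
  )
}

#' Parse vertebral level names
#'
#' Case-insensitive parsing to canonical level names (`C2`...`T12`, `L1`...`L5`).
#' Unknown tokens (including `C1`) are rejected with the offending token(s).
#'
#' @param x character vector of level names.
#' @return character vector of canonical level names.
#' @export
#' @examples
#' parseLevel(c("c2", "t12", "L1"))
parseLevel <- function(x) {
  up <- toupper(trimws(as.character(x)))
  bad <- unique(up[!up %in% .LEVEL_NAMES])
  if (length(bad) > 0) {
    dataError(sprintf(
      "Unknown vertebral level(s): %s. Valid levels are C2-C7, T1-T12, L1-L5.",
      paste(sQuote(bad), collapse = ", ")
    ))
  }
  up
}

#' Craniocaudal ordering of two levels
#'
#' @param a,b level names (any case).
#' @return integer vector: -1 if `a` is cranial to `b`, 0 if identical,
#'   1 if `a` is caudal to `b`.
#' @export
#' @examples
#' levelOrder("C2", "T12")
levelOrder <- function(a, b) {
  oa <- match(parseLevel(a), .LEVEL_NAMES)
  ob <- match(parseLevel(b), .LEVEL_NAMES)
  as.integer(sign(oa - ob))
}

#' Anatomical region of a vertebral level
#'
#' @param level level names (any case).
#' @return character vector: `"cervical"`, `"thoracic"` or `"lumbar"`.
#' @export
#' @examples
#' regionOf(c("C6", "T1", "L3"))
regionOf <- function(level) {
  .LEVEL_REGIONS[match(parseLevel(level), .LEVEL_NAMES)]
}

#' Level subsets used throughout the pipeline
#'
#' `cervicothoracicLevels()` returns the 18 calibration target levels C2--T12;
#' `lumbarReferenceLevels()` returns the fixed reference levels L1--L3.
#'
#' @return character vector of canonical level names.
#' @export
#' @examples
#' cervicothoracicLevels()
cervicothoracicLevels <- function() .LEVEL_NAMES[1:18]

#' @rdname cervicothoracicLevels
#' @export
lumbarReferenceLevels <- function() c("L1", "L2", "L3")

# Order an arbitrary set of level names craniocaudally.
orderLevels <- function(levels) {
  levels[order(match(levels, .LEVEL_NAMES))]
}
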