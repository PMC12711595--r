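#' The default behavioral-reaction ethogram
#'
#' Returns the 13-point reaction-intensity scoring table used to quantify
#' vigilance responses to playback stimuli. Scores run from 0 (no reaction,
#' the focal animal continues feeding or ruminating) to 12 (rapid
#' retreat/flight). Scores 0--5 describe minimal responses that do not
#' interrupt natural behavior, 6--9 describe cessation of natural behavior
#' with sustained attention toward the stimulus, and 10--12 describe full
#' vigilance responses including relocation away from the stimulus.
#'
#' The table ships as an editable CSV in
#' `system.file("extdata", "ethogram.csv", package = "vigilr")`; this
#' function reads it so users can substitute their own ethogram file via
#' [read_ethogram()].
#'
#' @return A named integer vector mapping behavior codes to intensity scores
#'   in `0:12`.
#' @seealso [read_ethogram()], [score_behavior()], [categorize()]
#' @export
#' @examples
#' eth <- default_ethogram()
#' eth[["one ear moves"]]
#' eth[["run away"]]
default_ethogram <- function() {
  read_ethogram(system.file("extdata", "ethogram.csv", package = "vigilr",
                            mustWork = TRUE))
}

#' Read an ethogram scoring table from CSV
#'
#' @param path Path to a CSV file with columns `behavior_code` and
#'   `intensity` (integers in 0--12).
#' @return A named integer vector mapping behavior codes to intensities.
#' @export
read_ethogram <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("behavior_code", "intensity") %in% names(tab))) {
    stop("ethogram file must have columns 'behavior_code' and 'intensity'")
  }
  scores <- as.integer(tab$intensity)
  if (anyNA(scores) || any(scores < 0L | scores > 12L)) {
    stop("ethogram intensities must be integers in 0..12")
  }
  if (anyDuplicated(tab$behavior_code)) {
    stop("duplicated behavior_code in ethogram: ",
         paste(unique(tab$behavior_code[duplicated(tab$behavior_code)]),
               collapse = ", "))
  }
  stats::setNames(scores, tab$behavior_code)
}

#' Look up the reaction intensity of a behavior code
#'
#' @param code Character vector of behavior codes.
#' @param ethogram Named integer vector as returned by [default_ethogram()].
#' @return Integer vector of intensities (0--12).
#' @export
#' @examples
#' score_behavior("stops chewing/ruminating and looks", default_ethogram())
score_behavior <- function(code, ethogram = default_ethogram()) {
  miss <- setdiff(unique(code), names(ethogram))
  if (length(miss) > 0) {
    stop("unknown behavior code(s): ", paste(miss, collapse = ", "))
  }
  unname(ethogram[code])
}

#' Group a reaction-intensity score into its descriptive category
#'
#' Category A (scores 0--5) is no reaction or minimal behavioral change,
#' B (6--9) is cessation of natural behavior with sustained attention, and
#' C (10--12) is a full vigilance response including relocation.
#'
#' @param score Numeric vector of scores in \[0, 12\]. Non-integer scores
#'   (e.g. time-weighted intensities) are rounded to the underlying index
#'   before categorization.
#' @return Factor with levels `A`, `B`, `C`.
#' @export
#' @examples
#' categorize(c(0, 7, 12))
categorize <- function(score) {
  s <- round(score)
  if (anyNA(s) || any(s < 0 | s > 12)) {
    stop("scores must lie in [0, 12]")
  }
  cut(s, breaks = c(-0.5, 5.5, 9.5, 12.5), labels = c("A", "B", "C"))
}
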