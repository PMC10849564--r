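#' Ordered developmental age ladder
#'
#' An age ladder is the ordered set of sampled developmental ages, with the
#' last label designated the adult (terminal) reference age. Consecutive
#' pairs of labels form *stages*; maturation statistics are accumulated per
#' stage. The staged subset is configurable because embryonic ages are often
#' reported but excluded from stage accounting.
#'
#' @param labels character vector of unique age labels, ordered youngest to
#'   oldest.
#' @param adult the designated adult label; must equal the last label.
#' @param stage_set optional character vector of stage names of the form
#'   `"A-B"` where `A`, `B` are consecutive labels. Defaults to all
#'   consecutive pairs.
#' @return an object of class `age_ladder` with fields `labels`, `adult`,
#'   `stage_from`, `stage_to`, `stage_names`.
#' @export
age_ladder <- function(labels, adult = labels[length(labels)],
                       stage_set = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("age ladder needs at least 2 labels")
  if (anyDuplicated(labels)) stop("age labels must be unique")
  if (!identical(adult, labels[length(labels)]))
    stop("adult must be the last label of the ladder")
  if (is.null(stage_set)) {
    from <- labels[-length(labels)]
    to <- labels[-1L]
  } else {
    parts <- strsplit(stage_set, "-", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) stop("stage names must be of the form 'A-B'")
    from <- vapply(parts, `[`, "", 1L)
    to <- vapply(parts, `[`, "", 2L)
    i <- match(from, labels)
    j <- match(to, labels)
    if (anyNA(i) || anyNA(j) || any(j != i + 1L))
      stop("every stage pair must be consecutive within labels")
  }
  structure(
    list(labels = labels, adult = adult, stage_from = from, stage_to = to,
         stage_names = paste(from, to, sep = "-")),
    class = "age_ladder"
  )
}

#' Default 8-age ladder of the developing preoptic area
#'
#' Eight ages from E16 to P65 with P65 as adult. Staging uses the five
#' postnatal stages P0-P4, P4-P10, P10-P18, P18-P28 and P28-P65; embryonic
#' distances are computed and reported but excluded from stage accounting.
#'
#' @return an [age_ladder()].
#' @export
poa_age_ladder <- function() {
  age_ladder(
    c("E16", "E18", "P0", "P4", "P10", "P18", "P28", "P65"),
    stage_set = c("P0-P4", "P4-P10", "P10-P18", "P18-P28", "P28-P65")
  )
}

#' @export
print.age_ladder <- function(x, ...) {
  cat("age_ladder:", paste(x$labels, collapse = " < "),
      sprintf("(adult: %s, %d stages)\n", x$adult, length(x$stage_from)))
  invisible(x)
}

age_index <- function(ladder, ages) {
  i <- match(as.character(ages), ladder$labels)
  if (anyNA(i)) {
    stop("age label(s) not in ladder: ",
         paste(unique(as.character(ages)[is.na(i)]), collapse = ", "))
  }
  i
}
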