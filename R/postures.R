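#' Posture and fatigue classes
#'
#' The toolkit distinguishes seven postures: standing plus walking, running
#' and jumping, each in a rested ("normal") and a fatigued state. The six
#' dynamic classes carry 0-based class indices used by the classifier;
#' standing is produced by the generator and the usage statistics but is not
#' part of the exercise-fatigue classification task.
#'
#' @param include_stand logical; include the generator-only STAND class.
#' @return A data.frame with columns `name`, `class_index` (0-based, `NA` for
#'   STAND), `activity` (WALK/RUN/JUMP/STAND) and `fatigued` (logical).
#' @examples
#' posture_classes()
#' @export
posture_classes <- function(include_stand = TRUE) {
  df <- data.frame(
    name = c("WALK", "RUN", "JUMP",
             "WALK_FATIGUED", "RUN_FATIGUED", "JUMP_FATIGUED", "STAND"),
    class_index = c(0L, 1L, 2L, 3L, 4L, 5L, NA_integer_),
    activity = c("WALK", "RUN", "JUMP", "WALK", "RUN", "JUMP", "STAND"),
    fatigued = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  if (!include_stand) df <- df[df$name != "STAND", ]
  df
}

#' Names of the six classifier classes, ordered by class index
#' @return Character vector of length 6.
#' @export
classifier_classes <- function() {
  pc <- posture_classes(include_stand = FALSE)
  pc$name[order(pc$class_index)]
}

#' Fatigued posture classes
#' @return Character vector of the three fatigued class names.
#' @export
fatigue_classes <- function() {
  pc <- posture_classes()
  pc$name[pc$fatigued]
}

assert_posture <- function(posture) {
  if (!is.character(posture) || length(posture) != 1L ||
      !posture %in% posture_classes()$name) {
    stop("unknown posture: ", paste(posture, collapse = ", "),
         " (expected one of ", paste(posture_classes()$name, collapse = ", "), ")",
         call. = FALSE)
  }
  posture
}
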