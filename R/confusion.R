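#' Build or construct a 2x2 confusion table
#'
#' `confusion_table()` assembles a screen-vs-reference 2x2 table from the
#' four cell counts; `build_confusion()` tallies it from paired per-child
#' screen results and reference states.
#'
#' @param tp,fn,fp,tn nonnegative cell counts: true positives, false
#'   negatives, false positives, true negatives.
#' @return An object of class `confusion_table` (named list with elements
#'   `tp`, `fn`, `fp`, `tn`).
#' @export
#' @examples
#' confusion_table(6, 0, 4, 15)
#' build_confusion(c("positive", "positive", "negative"),
#'                 c("diseased", "healthy", "healthy"))
confusion_table <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop_input("confusion-table cells must be nonnegative whole numbers")
  }
  if (sum(cells) < 1) stop_input("confusion table must contain at least one observation")
  structure(as.list(cells), class = "confusion_table")
}

#' @rdname confusion_table
#' @param screen vector of screen results: `"positive"`/`"negative"` or
#'   logical (TRUE = positive).
#' @param state vector of reference states: `"diseased"`/`"healthy"` or
#'   logical (TRUE = diseased). Records with missing entries must be
#'   excluded upstream.
#' @export
build_confusion <- function(screen, state) {
  if (length(screen) != length(state)) {
    stop_input("`screen` and `state` must have the same length")
  }
  if (length(screen) == 0) stop_input("empty screen/state vectors")
  pos <- as_binary(screen, "positive", "negative", "screen")
  dis <- as_binary(state, "diseased", "healthy", "state")
  confusion_table(
    tp = sum(pos & dis), fn = sum(!pos & dis),
    fp = sum(pos & !dis), tn = sum(!pos & !dis)
  )
}

as_binary <- function(x, yes, no, what) {
  if (is.logical(x)) {
    if (anyNA(x)) stop_input(sprintf("`%s` contains missing values", what))
    return(x)
  }
  x <- as.character(x)
  if (anyNA(x) || !all(x %in% c(yes, no))) {
    stop_input(sprintf("`%s` must be \"%s\"/\"%s\" with no missing values",
                       what, yes, no))
  }
  x == yes
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(screen = c("positive", "negative"),
                              state = c("diseased", "healthy")))
  print(m)
  invisible(x)
}

n_total <- function(t) t$tp + t$fn + t$fp + t$tn
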