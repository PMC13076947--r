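#' Interaction threshold schemes
#'
#' Each synergy metric comes with published cut-offs that partition the real
#' line into antagonistic, additive and synergistic classes. The rule is:
#' scores at or above `synergy_min` are synergistic, scores at or below
#' `additive_low` are antagonistic, everything strictly between is additive.
#' The built-in schemes are:
#'
#' * `loewe`: synergistic `>= 30`, additive in `(0, 30)`, antagonistic `<= 0`
#' * `bliss`: synergistic `>= 3.68`, additive in `(-3.37, 3.68)`,
#'   antagonistic `<= -3.37`
#' * `zip`: synergistic `>= 3.87`, antagonistic `<= -3.37`; the additive
#'   interval is extended to `(-3.37, 3.87)` so that the three classes
#'   partition the line (the published additive upper cut of 3.68 would leave
#'   `[3.68, 3.87)` unassigned)
#' * `hsa`: synergistic `>= 2.64`, additive in `(-4.48, 2.64)`,
#'   antagonistic `<= -4.48`
#'
#' @param metric One of `"loewe"`, `"bliss"`, `"zip"`, `"hsa"`, or
#'   `"custom"` (supply the cuts yourself).
#' @param synergy_min,additive_low,additive_high Cut-offs for a custom scheme;
#'   must satisfy `additive_low <= additive_high <= synergy_min`.
#' @return A `threshold_scheme` object.
#' @examples
#' label_interaction(c(-5, 10, 35), threshold_scheme("loewe"))
#' @export
threshold_scheme <- function(metric = c("loewe", "bliss", "zip", "hsa", "custom"),
                             synergy_min = NULL, additive_low = NULL,
                             additive_high = NULL) {
  metric <- match.arg(metric)
  builtin <- list(
    loewe = c(low = 0, high = 30, syn = 30),
    bliss = c(low = -3.37, high = 3.68, syn = 3.68),
    zip = c(low = -3.37, high = 3.87, syn = 3.87),
    hsa = c(low = -4.48, high = 2.64, syn = 2.64)
  )
  if (metric == "custom") {
    if (is.null(synergy_min) || is.null(additive_low)) {
      stop("custom schemes need `synergy_min` and `additive_low`")
    }
    if (is.null(additive_high)) additive_high <- synergy_min
  } else {
    cuts <- builtin[[metric]]
    additive_low <- cuts[["low"]]
    additive_high <- cuts[["high"]]
    synergy_min <- cuts[["syn"]]
  }
  if (!(additive_low <= additive_high && additive_high <= synergy_min)) {
    stop("cuts must satisfy additive_low <= additive_high <= synergy_min")
  }
  structure(
    list(metric = metric, synergy_min = synergy_min,
         additive_low = additive_low, additive_high = additive_high),
    class = "threshold_scheme"
  )
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat(sprintf(
    "<threshold_scheme %s> synergistic >= %g | additive (%g, %g) | antagonistic <= %g\n",
    x$metric, x$synergy_min, x$additive_low, x$synergy_min, x$additive_low
  ))
  invisible(x)
}

interaction_levels <- c("antagonistic", "additive", "synergistic")

#' Label interaction classes from continuous synergy scores
#'
#' Applies a [threshold_scheme()] to a numeric vector of scores. The synergy
#' cut is inclusive (`>=`), the antagonism cut is inclusive (`<=`), and the
#' additive class takes the open interior, so every finite score receives
#' exactly one label and the label is monotone non-decreasing in the score.
#'
#' @param score Numeric vector of finite synergy scores.
#' @param scheme A `threshold_scheme` or a metric name understood by
#'   [threshold_scheme()].
#' @return A factor with levels antagonistic < additive < synergistic.
#' @export
label_interaction <- function(score, scheme = "loewe") {
  if (!inherits(scheme, "threshold_scheme")) scheme <- threshold_scheme(scheme)
  if (any(!is.finite(score))) {
    stop("scores must be finite; found NA/NaN/Inf at position ",
         which(!is.finite(score))[1])
  }
  cls <- ifelse(score >= scheme$synergy_min, "synergistic",
                ifelse(score <= scheme$additive_low, "antagonistic", "additive"))
  factor(cls, levels = interaction_levels, ordered = TRUE)
}

#' Collapse three interaction classes to a binary outcome
#'
#' Synergistic combinations form the positive class; additive and antagonistic
#' combinations are grouped together as the negative class, the convention
#' used when synergy prediction is evaluated as binary classification.
#'
#' @param labels Character or factor vector with values among
#'   antagonistic / additive / synergistic.
#' @return A factor with levels negative < positive.
#' @export
binarize_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), interaction_levels)
  if (length(bad) > 0) {
    stop("unknown interaction class: ", paste(bad, collapse = ", "))
  }
  factor(ifelse(labels == "synergistic", "positive", "negative"),
         levels = c("negative", "positive"))
}
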