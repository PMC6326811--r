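#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_vline labs
#'   scale_fill_manual theme_minimal
NULL

category_palette <- c(
  GENOMIC = "grey10",       # genomically encoded termini
  SINGLE_A_452 = "grey60",  # single A at mature+1 (possibly templated)
  OLIGO_A = "#2166AC",      # oligo(A) additions, n >= 2
  MONO_A = "#92C5DE",
  NON_A_TAIL = "#B2182B",
  UNCLASSIFIED = "grey85"
)

#' Stacked terminus-distribution bar chart
#'
#' End position on the x axis, percentage of fragments on the y axis,
#' stacked by category — the standard way 3' RACE terminus distributions
#' are presented (genomic termini dark, the ambiguous single-A class light
#' grey, oligo(A) additions blue).
#'
#' @param object A `category_table`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.category_table <- function(object, ...) {
  L_m <- attr(object, "L_m")
  ggplot(object, aes(x = .data$end_position, y = .data$pct,
                     fill = .data$category)) +
    geom_col() +
    geom_vline(xintercept = L_m + 0.5, linetype = "dashed",
               colour = "grey40") +
    scale_fill_manual(values = category_palette, drop = FALSE) +
    labs(x = "3' end position", y = "% of fragments enclosing the 3' end",
         fill = "terminus") +
    theme_minimal()
}

#' @export
plot.category_table <- function(x, ...) print(autoplot(x, ...))

#' Digestion end-position distribution plot
#'
#' @param object A `digestion_distribution`.
#' @param ... Ignored.
#' @return A ggplot object; a dashed line marks the template/A-tail
#'   boundary when known.
#' @export
autoplot.digestion_distribution <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$end_position,
                          y = .data$n / attr(object, "n_molecules"))) +
    geom_col(fill = "#2166AC") +
    labs(x = "final 3' end position", y = "fraction of molecules") +
    theme_minimal()
  b <- attr(object, "boundary")
  if (!is.na(b)) {
    p <- p + geom_vline(xintercept = b + 0.5, linetype = "dashed",
                        colour = "grey40")
  }
  p
}

#' @export
plot.digestion_distribution <- function(x, ...) print(autoplot(x, ...))

#' Condition-contrast bar chart
#'
#' Diverging per-category percentage differences between two conditions.
#'
#' @param object A `terminus_contrast`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.terminus_contrast <- function(object, ...) {
  ggplot(object, aes(x = .data$category, y = .data$delta_pct,
                     fill = .data$category)) +
    geom_col() +
    scale_fill_manual(values = category_palette, drop = FALSE, guide = "none") +
    labs(x = NULL, y = "percentage-point difference (A - B)") +
    theme_minimal()
}

#' @export
plot.terminus_contrast <- function(x, ...) print(autoplot(x, ...))
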