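#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a category table into per-category totals
#'
#' @param x A `category_table`.
#' @param ... Ignored.
#' @return Tibble with one row per category: `category`, `n`, `pct`.
#' @export
tidy.category_table <- function(x, ...) category_pct(x)

#' One-row summary of a category table
#'
#' @param x A `category_table`.
#' @param ... Ignored.
#' @return Tibble with `denominator`, `mature_pct`, `single_a_pct`,
#'   `oligo_a_pct`, `genomic_pct`.
#' @export
glance.category_table <- function(x, ...) {
  p <- category_pct(x)
  pick <- function(cat) sum(p$pct[p$category == cat])
  tibble(
    denominator = attr(x, "denominator"),
    mature_pct = mature_pct(x),
    single_a_pct = pick("SINGLE_A_452"),
    oligo_a_pct = pick("OLIGO_A"),
    genomic_pct = pick("GENOMIC")
  )
}

#' Tidy a condition contrast
#'
#' @param x A `terminus_contrast`.
#' @param ... Ignored.
#' @return The contrast as a plain tibble.
#' @export
tidy.terminus_contrast <- function(x, ...) as_tibble(x)

#' One-row summary of a condition contrast
#'
#' @param x A `terminus_contrast`.
#' @param ... Ignored.
#' @return Tibble with `mature_delta`, `oligo_a_delta`,
#'   `shift_mature_down_oligo_up`.
#' @export
glance.terminus_contrast <- function(x, ...) {
  tibble(
    mature_delta = attr(x, "mature_delta"),
    oligo_a_delta = attr(x, "oligo_a_delta"),
    shift_mature_down_oligo_up = attr(x, "shift_mature_down_oligo_up")
  )
}

#' Tidy a digestion distribution
#'
#' @param x A `digestion_distribution`.
#' @param ... Ignored.
#' @return Tibble with `end_position`, `n`, `fraction`.
#' @export
tidy.digestion_distribution <- function(x, ...) {
  as_tibble(x) |>
    dplyr::mutate(fraction = .data$n / attr(x, "n_molecules"))
}

#' Write a category-table summary as JSON
#'
#' @param table A `category_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(table, path) {
  payload <- list(
    denominator = attr(table, "denominator"),
    L_m = attr(table, "L_m"),
    by_category = category_pct(table),
    by_position = as_tibble(table)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
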