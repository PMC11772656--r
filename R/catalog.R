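#' Formation metadata
#'
#' Reference table of the drafting formations the package knows about: the
#' solo runner and formations F1-F12 (one to six pacers in various spatial
#' arrangements, 1.2 m longitudinal gaps). The geometry notes are
#' descriptive metadata only; the package never computes flow.
#'
#' @return A tibble with columns `formation`, `n_pacers`, `geometry_note`.
#' @export
formation_info <- function() {
  tibble::tribble(
    ~formation, ~n_pacers, ~geometry_note,
    "SOLO", 0L, "unshielded runner",
    "F1",   1L, "one pacer ahead, lateral offset",
    "F2",   2L, "two pacers side by side ahead",
    "F3",   3L, "three pacers in a row ahead; main runner trails between two",
    "F4",   1L, "one pacer directly ahead",
    "F5",   3L, "three pacers, tighter arrow",
    "F6",   3L, "three pacers, arrow variant",
    "F7",   3L, "degenerate three-pacer variant (increased drag)",
    "F8",   6L, "six pacers (special-event formation)",
    "F9",   6L, "six pacers, main runner off-centre",
    "F10",  6L, "six pacers (special-event formation)",
    "F11",  5L, "inverted-arrow five-pacer formation (special events)",
    "F12",  2L, "one pacer directly ahead, one directly behind"
  )
}

new_drag_catalog <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("drag_catalog", class(df))
  df
}

catalog_row_to_curve <- function(row) {
  drag_curve(row$a, row$b, row$c,
    formation = row$formation, position = row$position,
    fit_speed_range = c(row$fit_lo, row$fit_hi),
    provenance = row$provenance
  )
}

#' Build a formation drag catalog
#'
#' Assembles a catalog of quadratic drag curves keyed by (formation,
#' position). Each config row supplies either coefficients `a`, `b`, `c`
#' directly or four drag samples `v1..v4`, `d1..d4`, which are fitted with
#' [fit_drag_curve()]. The catalog must contain the `SOLO`/`MAIN` reference
#' entry, every curve must be positive on [5, 6] m/s, and duplicate keys are
#' rejected.
#'
#' @param config A data frame with columns `formation`, `position`, an
#'   optional `provenance`, and either `a`,`b`,`c` or `v1..v4`,`d1..d4`
#'   (rows may mix the two styles; sample columns win when both are
#'   complete).
#' @return A `drag_catalog` tibble with columns `formation`, `position`,
#'   `a`, `b`, `c`, `fit_lo`, `fit_hi`, `provenance`.
#' @examples
#' build_catalog(tibble::tibble(formation = "SOLO", position = "MAIN",
#'                              a = 0.493, b = -3.256, c = 7.878))
#' @export
build_catalog <- function(config) {
  config <- tibble::as_tibble(config)
  if (!all(c("formation", "position") %in% names(config))) {
    abort("catalog config needs `formation` and `position` columns.")
  }
  key <- paste(config$formation, config$position, sep = "/")
  if (anyDuplicated(key)) {
    abort(sprintf(
      "duplicate (formation, position) keys: %s.",
      paste(unique(key[duplicated(key)]), collapse = ", ")
    ))
  }
  sample_cols <- c(paste0("v", 1:4), paste0("d", 1:4))
  if (!"provenance" %in% names(config)) config$provenance <- NA_character_
  rows <- purrr::pmap(config, function(...) {
    row <- list(...)
    filled <- function(cols) {
      all(cols %in% names(row)) &&
        all(vapply(row[cols], function(x) is.finite(x %||% NA_real_), TRUE))
    }
    prov <- row$provenance
    if (is.null(prov) || is.na(prov)) prov <- NULL
    if (filled(sample_cols)) {
      samples <- tibble::tibble(
        v = unlist(row[paste0("v", 1:4)], use.names = FALSE),
        drag = unlist(row[paste0("d", 1:4)], use.names = FALSE)
      )
      curve <- fit_drag_curve(samples, row$formation, row$position,
        provenance = prov %||% "fitted from samples"
      )
    } else if (filled(c("a", "b", "c"))) {
      curve <- drag_curve(row$a, row$b, row$c,
        formation = row$formation, position = row$position,
        provenance = prov %||% "coefficients"
      )
    } else {
      abort(sprintf(
        "catalog row %s/%s supplies neither coefficients nor four samples.",
        row$formation, row$position
      ))
    }
    tibble::tibble(
      formation = curve$formation, position = curve$position,
      a = curve$a, b = curve$b, c = curve$c,
      fit_lo = curve$fit_speed_range[1], fit_hi = curve$fit_speed_range[2],
      provenance = curve$provenance %||% "coefficients"
    )
  })
  catalog <- new_drag_catalog(dplyr::bind_rows(rows))
  if (!any(catalog$formation == "SOLO" & catalog$position == "MAIN")) {
    abort("catalog must contain the SOLO/MAIN reference entry.")
  }
  catalog
}

#' Default paper-anchored drag catalog
#'
#' Catalog of drag curves for the formations and positions the race
#' analyses need. The solo curve is the published polynomial; every
#' main-runner curve is the solo polynomial scaled by one minus the drag
#' reduction quoted at the target pace (F1 19%, F2/F3 42%, F4 54%, F12 62%,
#' F11 74%, F5/F6 21% relative to F3). Constant-ratio scaling is the
#' simplest extension of a single-speed reduction to the whole speed window
#' and is flagged in each entry's provenance. Pacer curves are synthetic
#' defaults (lead pacers at 0.97 of solo drag, the sheltered trailing pacer
#' of F12 at 0.45) and are meant to be overridden by fitted coefficients
#' when available; the optimized race times are almost insensitive to them
#' because pacer budgets and pacer spending scale together.
#'
#' @return A `drag_catalog` tibble (see [build_catalog()]).
#' @examples
#' default_catalog()
#' @export
default_catalog <- function() {
  solo <- c(a = 0.493, b = -3.256, c = 7.878)
  printed <- "printed target-pace reduction (scaled solo)"
  synthetic <- "synthetic pacer default (scaled solo)"
  spec <- tibble::tribble(
    ~formation, ~position, ~mult, ~provenance,
    "SOLO", "MAIN", 1.00, "embedded solo polynomial",
    "F1",  "MAIN", 0.81, printed,
    "F2",  "MAIN", 0.58, printed,
    "F3",  "MAIN", 0.58, printed,
    "F4",  "MAIN", 0.46, printed,
    "F5",  "MAIN", 0.58 * 0.79, "printed reduction relative to F3 (scaled solo)",
    "F6",  "MAIN", 0.58 * 0.79, "printed reduction relative to F3 (scaled solo)",
    "F11", "MAIN", 0.26, printed,
    "F12", "MAIN", 0.38, printed,
    "F1",  "P1", 0.97, synthetic,
    "F2",  "P1", 0.97, synthetic,
    "F2",  "P2", 0.97, synthetic,
    "F3",  "P1", 0.97, synthetic,
    "F3",  "P2", 0.97, synthetic,
    "F3",  "P3", 0.97, synthetic,
    "F4",  "P1", 0.97, synthetic,
    "F12", "P1", 0.97, synthetic,
    "F12", "P2", 0.45, synthetic
  )
  build_catalog(dplyr::mutate(spec,
    a = .data$mult * solo[["a"]],
    b = .data$mult * solo[["b"]],
    c = .data$mult * solo[["c"]],
    mult = NULL
  ))
}

#' Look up one curve in a catalog
#'
#' @param catalog A `drag_catalog`.
#' @param formation,position Key of the entry to extract.
#' @return A [drag_curve()].
#' @export
catalog_curve <- function(catalog, formation, position = "MAIN") {
  row <- dplyr::filter(
    tibble::as_tibble(catalog),
    .data$formation == !!formation, .data$position == !!position
  )
  if (nrow(row) != 1) {
    abort(sprintf("catalog has no entry for %s/%s.", formation, position))
  }
  catalog_row_to_curve(as.list(row))
}

#' Read and write catalog CSV files
#'
#' The on-disk catalog format is a plain CSV with columns `formation`,
#' `position`, `provenance` and either `a`,`b`,`c` or `v1..v4`,`d1..d4`;
#' [write_catalog_csv()] writes coefficients with full precision so a
#' read/write round trip reproduces the catalog exactly.
#'
#' @param path File path.
#' @param catalog A `drag_catalog`.
#' @return `read_catalog_csv()` returns a `drag_catalog`;
#'   `write_catalog_csv()` returns `path` invisibly.
#' @export
read_catalog_csv <- function(path) {
  build_catalog(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_catalog_csv
#' @export
write_catalog_csv <- function(catalog, path) {
  df <- tibble::as_tibble(catalog)[, c("formation", "position", "a", "b", "c",
                                       "provenance")]
  readr::write_csv(df, path)
  invisible(path)
}
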