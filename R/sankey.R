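#' Aggregate shift records into a Sankey flow set
#'
#' Pools both arms' baseline categories into a hierarchically ordered center
#' column (most severe category on top: HyLaw, then Cholestasis, Temple,
#' NNN) and tallies each arm's baseline-to-destination flows: the comparator
#' (placebo) arm flows leftward, the active arm rightward. Each flow carries
#' its shift direction so upward flows render pink and downward flows green.
#'
#' Flow `fraction` is the within-arm proportion, which keeps the two sides
#' visually comparable under unequal randomization (e.g. 1:3); absolute
#' counts are always retained in `n`.
#'
#' @param shifts a [shift_records()] tibble.
#' @param manifest a [trial_manifest()]; its arm labels must cover the data.
#' @param scheme the [banding_scheme()] used to build `shifts`; defaults to
#'   the one stored on it.
#' @return Object of class `sankey_flows`: list with `baseline_nodes`
#'   (category, pooled count, per-arm counts) and `flows` (arm, side,
#'   origin, destination, n, direction, fraction).
#' @export
build_flows <- function(shifts, manifest, scheme = NULL) {
  scheme <- scheme %||% attr(shifts, "scheme") %||% banding_scheme()
  arms <- unique(as.character(shifts$arm))
  known <- c(manifest$active, manifest$comparator)
  if (length(setdiff(arms, known))) {
    stop("arm label(s) not in manifest: ",
         paste(setdiff(arms, known), collapse = ", "), call. = FALSE)
  }
  lev <- quadrant_levels(scheme, decreasing = TRUE)  # severity descending
  shifts <- shifts |>
    as_tibble() |>
    mutate(origin = factor(as.character(.data$origin), levels = lev),
           destination = factor(as.character(.data$destination), levels = lev))

  nodes <- shifts |>
    count(category = .data$origin, name = "count", .drop = FALSE) |>
    arrange(.data$category)
  per_arm <- shifts |>
    count(.data$arm, category = .data$origin, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "arm", values_from = "n",
                       values_fill = 0L)
  nodes <- left_join(nodes, per_arm, by = "category")

  flows <- shifts |>
    count(.data$arm, .data$origin, .data$destination, .data$direction,
          name = "n") |>
    mutate(side = ifelse(.data$arm == manifest$comparator, "left", "right")) |>
    group_by(.data$arm) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    arrange(.data$side, .data$origin, .data$destination)

  structure(list(baseline_nodes = nodes, flows = flows,
                 manifest = manifest, scheme = scheme),
            class = "sankey_flows")
}

#' @export
print.sankey_flows <- function(x, ...) {
  cat("<sankey_flows>", sum(x$baseline_nodes$count), "subjects;",
      nrow(x$flows), "distinct flows",
      sprintf("(left = %s, right = %s)\n",
              x$manifest$comparator, x$manifest$active))
  print(x$baseline_nodes)
  invisible(x)
}

#' @export
tidy.sankey_flows <- function(x, ...) x$flows

#' @export
glance.sankey_flows <- function(x, ...) {
  x$flows |>
    group_by(.data$arm) |>
    summarise(n_subjects = sum(.data$n),
              upward_total = sum(.data$n[.data$direction == "upward"]),
              upward_paths = sum(.data$direction == "upward" & .data$n > 0),
              downward_total = sum(.data$n[.data$direction == "downward"]),
              .groups = "drop")
}

#' Cross-table of baseline-to-peak category counts for one arm
#'
#' Origin categories are rows and destination categories columns, both in
#' descending severity order; every cell of the grid is present (zeros
#' included). Cell colour class follows the shift direction: red for upward
#' shifts of concern (potential DILI), green for downward (potential
#' efficacy), grey for the diagonal, yellow for lateral neutral shifts.
#'
#' @param shifts a [shift_records()] tibble.
#' @param arm arm label to tabulate.
#' @param scheme the scheme used to build `shifts` (defaults to its
#'   attribute).
#' @return Tibble of class `dili_crosstab` (`origin`, `destination`, `n`,
#'   `color_class`) with `arm` attribute; see [crosstab_matrix()] for the
#'   matrix view.
#' @export
build_cross_table <- function(shifts, arm, scheme = NULL) {
  scheme <- scheme %||% attr(shifts, "scheme") %||% banding_scheme()
  lev <- quadrant_levels(scheme, decreasing = TRUE)
  sub <- shifts |> as_tibble() |> filter(.data$arm == .env$arm)
  grid <- tidyr::expand_grid(
    origin = factor(lev, levels = lev),
    destination = factor(lev, levels = lev)
  )
  counts <- sub |>
    count(origin = factor(as.character(.data$origin), levels = lev),
          destination = factor(as.character(.data$destination), levels = lev),
          name = "n")
  out <- grid |>
    left_join(counts, by = c("origin", "destination")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           direction = classify_shift(.data$origin, .data$destination, scheme),
           color_class = shift_color_class(.data$direction))
  structure(out, class = c("dili_crosstab", class(out)),
            arm = arm, scheme = scheme)
}

#' Matrix view of a cross-table
#'
#' @param xtab a [build_cross_table()] result.
#' @param what `"n"` for counts or `"color_class"`.
#' @return Matrix with origin rows and destination columns.
#' @export
crosstab_matrix <- function(xtab, what = c("n", "color_class")) {
  what <- match.arg(what)
  lev <- levels(xtab$origin)
  m <- matrix(if (what == "n") 0L else NA_character_,
              length(lev), length(lev), dimnames = list(origin = lev,
                                                        destination = lev))
  m[cbind(as.character(xtab$origin), as.character(xtab$destination))] <-
    if (what == "n") xtab$n else as.character(xtab$color_class)
  m
}

#' @export
print.dili_crosstab <- function(x, ...) {
  cat("<dili_crosstab> arm:", attr(x, "arm"), "| total:", sum(x$n), "\n")
  print(crosstab_matrix(x))
  invisible(x)
}

#' @export
tidy.dili_crosstab <- function(x, ...) {
  as_tibble(x) |> mutate(arm = attr(x, "arm"), .before = 1)
}

#' @export
glance.dili_crosstab <- function(x, ...) {
  tibble(arm = attr(x, "arm"), n_subjects = sum(x$n),
         upward_total = sum(x$n[x$color_class == "red"]),
         upward_paths = sum(x$color_class == "red" & x$n > 0),
         downward_total = sum(x$n[x$color_class == "green"]))
}

#' Summarise upward shifts of concern across arms
#'
#' Totals the red (upward) cells of each arm's cross-table and counts the
#' distinct upward paths (nonzero red cells).
#'
#' @param cross_tables a list of [build_cross_table()] results (or a single
#'   one).
#' @return Tibble: `arm`, `upward_total`, `upward_paths`.
#' @export
upward_shift_summary <- function(cross_tables) {
  if (inherits(cross_tables, "dili_crosstab")) {
    cross_tables <- list(cross_tables)
  }
  purrr::map_dfr(cross_tables, function(x) {
    tibble(arm = attr(x, "arm"),
           upward_total = sum(x$n[x$color_class == "red"]),
           upward_paths = sum(x$color_class == "red" & x$n > 0))
  })
}

#' Export a cross-table as CSV (long form with colour class)
#'
#' @param xtab a [build_cross_table()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crosstab_csv <- function(xtab, path) {
  readr::write_csv(tidy(xtab), path)
  invisible(path)
}
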