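DIR_FILLS <- c(upward = "#f2a0b6", downward = "#7fc97f",
               lateral = "#bdbdbd", none = "#d9d9d9")
CLASS_FILLS <- c(red = "#f2a0b6", green = "#7fc97f",
                 grey = "#d9d9d9", yellow = "#ffe08a")
SHAPE_CODES <- c(square = 15, plus = 3, triangle = 17, star = 8)

## display floor for log axes; never used for categorization
floor_eps <- function(x, eps = 0.01) pmax(x, eps)

#' @rdname autoplot-dishtools
#' @export
autoplot.edish_points <- function(object, eps = 0.01, ...) {
  scheme <- attr(object, "scheme")
  dat <- as_tibble(object) |>
    mutate(x = floor_eps(.data$x, eps), y = floor_eps(.data$y, eps))
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y,
                                    colour = .data$arm)) +
    ggplot2::geom_vline(xintercept = scheme$alt_cuts, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = scheme$tb_cuts, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Peak on-treatment AT (xULN)",
                  y = "Peak on-treatment TB (xULN)",
                  colour = "Arm", title = "eDISH") +
    ggplot2::theme_bw()
}

#' @rdname autoplot-dishtools
#' @export
autoplot.mdish_points <- function(object, eps = 0.01, ...) {
  ## no quadrant boundaries: they carry no discriminatory value in xBL space
  dat <- as_tibble(object) |>
    mutate(x = floor_eps(.data$x, eps), y = floor_eps(.data$y, eps))
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y, colour = .data$arm)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Peak on-treatment ALT (xBL)",
                  y = "Peak on-treatment TB (xBL)",
                  colour = "Arm", title = "mDISH") +
    ggplot2::theme_bw()
}

#' @rdname autoplot-dishtools
#' @export
autoplot.composite_points <- function(object, eps = 0.01, ...) {
  dat <- as_tibble(object) |>
    mutate(x = floor_eps(.data$x, eps), y = floor_eps(.data$y, eps),
           origin = droplevels(.data$origin))
  cols <- ORIGIN_MARKERS$marker_colour
  names(cols) <- ORIGIN_MARKERS$origin
  shp <- SHAPE_CODES[ORIGIN_MARKERS$marker_shape]
  names(shp) <- ORIGIN_MARKERS$origin
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y,
                                    colour = .data$origin,
                                    shape = .data$origin)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_manual(values = cols, drop = TRUE) +
    ggplot2::scale_shape_manual(values = shp, drop = TRUE) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Peak on-treatment ALT (xBL)",
                  y = "Peak on-treatment TB (xBL)",
                  colour = "Origin", shape = "Origin",
                  title = paste("Composite mDISH - destination",
                                attr(object, "destination"))) +
    ggplot2::theme_bw()
}

## ---- Sankey geometry ----------------------------------------------------

smoothstep <- function(t) t * t * (3 - 2 * t)

## Stack node heights top-down; returns tibble(category, top, bottom)
stack_nodes <- function(categories, heights, gap = 0.03) {
  tops <- -(cumsum(c(0, utils::head(heights, -1))) +
              gap * (seq_along(heights) - 1))
  tibble(category = categories, top = tops, bottom = tops - heights)
}

## ribbon polygon between two vertical intervals
ribbon_poly <- function(id, x0, x1, y0_top, y0_bot, y1_top, y1_bot,
                        npts = 40) {
  t <- seq(0, 1, length.out = npts)
  s <- smoothstep(t)
  x <- x0 + (x1 - x0) * t
  tibble(id = id,
         x = c(x, rev(x)),
         y = c(y0_top + (y1_top - y0_top) * s,
               rev(y0_bot + (y1_bot - y0_bot) * s)))
}

## compute all plot pieces for a sankey_flows object
sankey_geometry <- function(object, proportional = TRUE, gap = 0.03,
                            node_w = 0.07) {
  lev <- as.character(object$baseline_nodes$category)  # severity descending
  flows <- object$flows |>
    mutate(origin = factor(as.character(.data$origin), levels = lev),
           destination = factor(as.character(.data$destination),
                                levels = lev),
           thick = if (proportional) .data$fraction else .data$n)

  side_x <- c(left = -1, right = 1)
  pieces <- list()

  ## center node heights: per category, the larger of the two sides' outflow
  out_by <- flows |>
    group_by(.data$side, .data$origin) |>
    summarise(h = sum(.data$thick), .groups = "drop")
  ctr_h <- purrr::map_dbl(lev, function(cat) {
    h <- out_by$h[as.character(out_by$origin) == cat]
    if (length(h) == 0) 0 else max(h)
  })
  keep <- ctr_h > 0
  center <- stack_nodes(lev[keep], ctr_h[keep], gap) |>
    mutate(x0 = -node_w, x1 = node_w, column = "center")

  ribbons <- list()
  side_nodes <- list()
  for (sd in c("left", "right")) {
    fl <- flows |>
      filter(.data$side == sd) |>
      arrange(.data$origin, .data$destination)
    if (nrow(fl) == 0) next
    ## destination column stacking
    dest_h <- fl |>
      group_by(.data$destination) |>
      summarise(h = sum(.data$thick), .groups = "drop") |>
      arrange(.data$destination)
    dn <- stack_nodes(as.character(dest_h$destination), dest_h$h, gap)
    dn$x0 <- side_x[[sd]] - node_w
    dn$x1 <- side_x[[sd]] + node_w
    dn$column <- sd
    side_nodes[[sd]] <- dn

    ## slice allocation: origin slices from center-node top, destination
    ## slices from side-node top, both in the flow sort order above
    fl <- fl |>
      group_by(.data$origin) |>
      mutate(o_off = cumsum(.data$thick) - .data$thick) |>
      ungroup() |>
      group_by(.data$destination) |>
      mutate(d_off = cumsum(.data$thick) - .data$thick) |>
      ungroup()
    fl <- fl |>
      mutate(origin = as.character(.data$origin),
             destination = as.character(.data$destination)) |>
      left_join(center |> select("category", o_top = "top"),
                by = c(origin = "category")) |>
      left_join(dn |> select("category", d_top = "top"),
                by = c(destination = "category"))
    x_ctr <- if (sd == "left") -node_w else node_w
    x_sid <- if (sd == "left") side_x[[sd]] + node_w else side_x[[sd]] - node_w
    ribbons[[sd]] <- purrr::map_dfr(seq_len(nrow(fl)), function(i) {
      ribbon_poly(
        id = paste(sd, i),
        x0 = x_ctr, x1 = x_sid,
        y0_top = fl$o_top[i] - fl$o_off[i],
        y0_bot = fl$o_top[i] - fl$o_off[i] - fl$thick[i],
        y1_top = fl$d_top[i] - fl$d_off[i],
        y1_bot = fl$d_top[i] - fl$d_off[i] - fl$thick[i]
      ) |>
        mutate(direction = as.character(fl$direction[i]))
    })
  }

  nodes <- bind_rows(c(list(center = center), side_nodes))
  counts <- object$baseline_nodes
  nodes <- nodes |>
    left_join(counts |> mutate(category = as.character(.data$category)) |>
                select("category", "count"),
              by = "category")
  list(nodes = nodes, ribbons = bind_rows(ribbons), side_x = side_x,
       node_w = node_w)
}

#' Plot methods for dishtools result objects
#'
#' `autoplot()` methods returning ggplot objects for eDISH/mDISH/composite
#' point sets, Sankey flow sets, cross-tables and waterfall data.
#'
#' @param object the result object.
#' @param eps display floor for log-scaled multiples (never affects
#'   categorization).
#' @param proportional draw Sankey ribbon thickness as within-arm
#'   proportions (`TRUE`, robust to unequal randomization) or absolute
#'   counts.
#' @param ... unused.
#' @return A ggplot object.
#' @name autoplot-dishtools
NULL

#' @rdname autoplot-dishtools
#' @export
autoplot.sankey_flows <- function(object, proportional = TRUE, ...) {
  geo <- sankey_geometry(object, proportional = proportional)
  man <- object$manifest
  lab <- tibble(
    x = c(-1, 0, 1),
    y = max(geo$nodes$top) + 0.12,
    text = c(man$comparator, "Baseline", man$active)
  )
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = geo$ribbons,
      ggplot2::aes(.data$x, .data$y, group = .data$id,
                   fill = .data$direction),
      alpha = 0.85, colour = NA) +
    ggplot2::scale_fill_manual(values = DIR_FILLS, name = "Shift") +
    ggplot2::geom_rect(
      data = geo$nodes,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                   ymin = .data$bottom, ymax = .data$top),
      fill = "grey30") +
    ggplot2::geom_text(
      data = geo$nodes |> filter(.data$column == "center"),
      ggplot2::aes(x = 0, y = (.data$top + .data$bottom) / 2,
                   label = paste0(.data$category, " (", .data$count, ")")),
      colour = "white", size = 3) +
    ggplot2::geom_text(
      data = geo$nodes |> filter(.data$column != "center"),
      ggplot2::aes(x = (.data$x0 + .data$x1) / 2,
                   y = (.data$top + .data$bottom) / 2,
                   label = .data$category),
      colour = "white", size = 2.6) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(.data$x, .data$y, label = .data$text),
                       fontface = "bold", size = 4) +
    ggplot2::theme_void()
}

#' @rdname autoplot-dishtools
#' @export
autoplot.dili_crosstab <- function(object, ...) {
  dat <- as_tibble(object) |>
    mutate(destination = factor(.data$destination,
                                levels = rev(levels(.data$destination))))
  ggplot2::ggplot(dat, ggplot2::aes(.data$destination, .data$origin,
                                    fill = .data$color_class)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3.5) +
    ggplot2::scale_fill_manual(values = CLASS_FILLS, guide = "none") +
    ggplot2::scale_x_discrete(position = "top") +
    ggplot2::labs(title = paste("Shifts -", attr(object, "arm")),
                  x = "On-treatment peak category", y = "Baseline category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' @rdname autoplot-dishtools
#' @param severity_lines horizontal ALT cut-offs in U/L for the waterfall
#'   severity bands.
#' @export
autoplot.dili_waterfall <- function(object,
                                    severity_lines = c(300, 600, 900), ...) {
  e <- object$entries
  man <- object$manifest
  e$fill <- ifelse(e$new_jaundice, "new jaundice",
                   ifelse(e$arm == man$comparator, "placebo", "active"))
  fills <- c(placebo = "#4472c4", active = "#b08d57",
             `new jaundice` = "#2e9e4f")
  n <- nrow(e)
  pad <- max(4, ceiling(0.05 * n))
  box <- object$summaries
  box$x <- ifelse(box$arm == man$comparator, -pad / 2, n + pad / 2)
  outl <- box |>
    select("arm", "x", "outliers") |>
    tidyr::unnest("outliers")

  p <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = severity_lines, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_rect(
      data = e,
      ggplot2::aes(xmin = .data$rank - 0.45, xmax = .data$rank + 0.45,
                   ymin = pmin(.data$baseline_alt,
                               .data$baseline_alt + .data$bar_value),
                   ymax = pmax(.data$baseline_alt,
                               .data$baseline_alt + .data$bar_value),
                   fill = .data$fill)) +
    ggplot2::geom_line(data = e,
                       ggplot2::aes(.data$rank, .data$baseline_alt,
                                    group = .data$arm),
                       colour = "black", linewidth = 0.5) +
    ggplot2::geom_boxplot(
      data = box,
      ggplot2::aes(x = .data$x,
                   ymin = .data$whisker_low, lower = .data$q1,
                   middle = .data$median, upper = .data$q3,
                   ymax = .data$whisker_high, group = .data$arm),
      stat = "identity", width = pad * 0.8, fill = "grey90") +
    ggplot2::scale_fill_manual(values = fills, name = NULL) +
    ggplot2::labs(x = paste0("Subjects (", man$comparator,
                             " ascending | ", man$active,
                             " descending baseline ALT)"),
                  y = "ALT (U/L)",
                  title = paste("Modified waterfall -", object$mode)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
  if (nrow(outl)) {
    p <- p + ggplot2::geom_point(
      data = outl, ggplot2::aes(.data$x, .data$outliers),
      shape = 1, size = 1.2, colour = "grey30")
  }
  p
}

## shared figure writer: svg or png by extension, deterministic output
write_figure <- function(plot, path, width = 10, height = 7) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir,
                             call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    svg = grDevices::svg(path, width = width, height = height),
    png = grDevices::png(path, width = width * 100, height = height * 100,
                         res = 100),
    stop("unsupported figure format: .", ext, " (use .svg or .png)",
         call. = FALSE)
  )
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}

#' Render a Sankey flow set to SVG or PNG
#'
#' Draws the center-anchored Sankey (placebo flows left, active right,
#' upward shifts pink, downward green) and, when `crosstabs` are supplied,
#' the per-arm cross-tables beneath the diagram. Output is byte-stable for
#' fixed input and style.
#'
#' @param flow_set a [build_flows()] result.
#' @param path output file (`.svg` or `.png`).
#' @param crosstabs optional list of [build_cross_table()] results to render
#'   under the diagram (needs the patchwork package).
#' @param proportional see [autoplot.sankey_flows()].
#' @param width,height figure size in inches.
#' @return `path`, invisibly.
#' @export
render_sankey <- function(flow_set, path, crosstabs = NULL,
                          proportional = TRUE, width = 10, height = 7) {
  p <- autoplot(flow_set, proportional = proportional)
  if (!is.null(crosstabs) && requireNamespace("patchwork", quietly = TRUE)) {
    tabs <- purrr::map(crosstabs, autoplot)
    p <- patchwork::wrap_plots(
      p, patchwork::wrap_plots(tabs, nrow = 1),
      ncol = 1, heights = c(2, 1))
  }
  write_figure(p, path, width, height)
}

#' Render a modified waterfall plot to SVG or PNG
#'
#' @param waterfall a [build_waterfall()] result.
#' @param path output file (`.svg` or `.png`).
#' @param severity_lines horizontal ALT cut-offs in U/L (default
#'   300/600/900).
#' @param width,height figure size in inches.
#' @return `path`, invisibly.
#' @export
render_waterfall <- function(waterfall, path,
                             severity_lines = c(300, 600, 900),
                             width = 12, height = 6) {
  write_figure(autoplot(waterfall, severity_lines = severity_lines),
               path, width, height)
}

#' Render an eDISH, mDISH or composite scatter to SVG or PNG
#'
#' @param points an `edish_points`, `mdish_points` or `composite_points`
#'   object.
#' @param path output file (`.svg` or `.png`).
#' @param width,height figure size in inches.
#' @return `path`, invisibly.
#' @export
render_points <- function(points, path, width = 7, height = 6) {
  write_figure(autoplot(points), path, width, height)
}
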