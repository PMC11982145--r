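#' Classical eDISH scatter coordinates (xULN)
#'
#' One point per analyzable subject: peak on-treatment AT (x) versus peak TB
#' (y), both in multiples of ULN, with the baseline (origin) and peak
#' (destination) quadrant categories attached. Peaks are independent maxima:
#' the AT peak day need not be the TB peak day.
#'
#' @param profiles a [derive_profiles()] result.
#' @param scheme a [banding_scheme()].
#' @return Tibble of class `edish_points` (`subject_id`, `arm`, `x`, `y`,
#'   `origin`, `destination`) with a `quadrant_counts` attribute (per-arm
#'   destination-category counts, retrievable with [quadrant_counts()]).
#' @export
edish_points <- function(profiles, scheme = banding_scheme()) {
  shifts <- shift_records(profiles, scheme)
  pts <- shifts |>
    as_tibble() |>
    select("subject_id", "arm", x = "peak_at_xuln", y = "peak_tb_xuln",
           "origin", "destination")
  counts <- pts |> count(.data$arm, category = .data$destination, .drop = FALSE)
  structure(pts, class = c("edish_points", class(pts)),
            quadrant_counts = counts, scheme = scheme, space = "xULN")
}

#' Per-arm destination quadrant counts of an eDISH point set
#'
#' @param x an [edish_points()] result.
#' @return Tibble `arm`, `category`, `n`.
#' @export
quadrant_counts <- function(x) attr(x, "quadrant_counts")

#' mDISH scatter coordinates (xBL)
#'
#' One point per subject: peak on-treatment ALT and TB in multiples of the
#' subject's own baseline. Subjects with a zero or missing baseline for
#' either analyte have no defined xBL and are excluded; they are listed in
#' the `excluded` attribute. Because every subject is re-anchored to its own
#' baseline, subjects with identical relative changes coincide on mDISH no
#' matter how different their absolute values are, so no severity boundaries
#' are drawn in this space.
#'
#' @param profiles a [derive_profiles()] result.
#' @param scheme scheme used to annotate origin/destination categories
#'   (still computed in xULN space).
#' @return Tibble of class `mdish_points` (`subject_id`, `arm`, `x`, `y`,
#'   `origin`, `destination`).
#' @export
mdish_points <- function(profiles, scheme = banding_scheme()) {
  wide <- profiles_wide(profiles)
  need <- c("alt_peak_xbl", "tb_peak_xbl")
  if (!all(need %in% names(wide))) {
    stop("profiles lack ALT or TB rows needed for mDISH", call. = FALSE)
  }
  ok <- !is.na(wide$alt_peak_xbl) & !is.na(wide$tb_peak_xbl)
  excluded <- wide |>
    filter(!.env$ok) |>
    mutate(reason = "xBL undefined (zero or missing baseline, or no on-treatment value)") |>
    select("subject_id", "arm", "reason")
  sub <- wide |> filter(.env$ok)
  cat_ok <- !is.na(sub$at_baseline_xuln) & !is.na(sub$tb_baseline_xuln) &
    !is.na(sub$at_peak_xuln) & !is.na(sub$tb_peak_xuln)
  origin <- destination <- rep(NA_character_, nrow(sub))
  if (any(cat_ok)) {
    origin[cat_ok] <- as.character(assign_quadrant(
      sub$at_baseline_xuln[cat_ok], sub$tb_baseline_xuln[cat_ok], scheme))
    destination[cat_ok] <- as.character(assign_quadrant(
      sub$at_peak_xuln[cat_ok], sub$tb_peak_xuln[cat_ok], scheme))
  }
  pts <- sub |>
    mutate(origin = factor(.env$origin, levels = quadrant_levels(scheme)),
           destination = factor(.env$destination,
                                levels = quadrant_levels(scheme))) |>
    select("subject_id", "arm", x = "alt_peak_xbl", y = "tb_peak_xbl",
           "origin", "destination")
  structure(pts, class = c("mdish_points", class(pts)),
            excluded = excluded, scheme = scheme, space = "xBL")
}

#' Flag potential Hy's Law subjects
#'
#' A subject is flagged when the on-treatment peak destination category is
#' HyLaw (AT >= 3xULN and TB > 2xULN by default). Alkaline phosphatase is
#' carried as an annotation for the reviewer ("no substantial ALP elevation"
#' has no accepted numeric threshold) and never changes the flag.
#'
#' @param profiles a [derive_profiles()] result.
#' @param scheme a [banding_scheme()].
#' @return Tibble: `subject_id`, `arm`, `potential_hys_law`, `annotation`
#'   (peak ALP in xULN when measured, otherwise `NA`).
#' @export
flag_potential_hys_law <- function(profiles, scheme = banding_scheme()) {
  shifts <- shift_records(profiles, scheme)
  alp <- profiles |>
    as_tibble() |>
    filter(.data$analyte == "ALP", !is.na(.data$peak_xuln)) |>
    select("subject_id", alp_peak_xuln = "peak_xuln")
  shifts |>
    as_tibble() |>
    left_join(alp, by = "subject_id") |>
    mutate(potential_hys_law = .data$destination == "HyLaw",
           annotation = ifelse(is.na(.data$alp_peak_xuln), NA_character_,
                               sprintf("ALP %.1fxULN", .data$alp_peak_xuln))) |>
    select("subject_id", "arm", "potential_hys_law", "annotation")
}

## fixed marker encoding for origin categories, stable across all composite
## plots (extra-band labels fall back to their base category's marker)
ORIGIN_MARKERS <- tibble(
  origin = c("NNN", "Normal", "NearNormal", "NNN-TBmid",
             "Temple", "Temple-TBmid", "Cholestasis", "HyLaw"),
  marker_colour = c("forestgreen", "forestgreen", "forestgreen",
                    "forestgreen", "blue", "blue", "orange", "red"),
  marker_shape = c("square", "square", "square", "square",
                   "plus", "plus", "triangle", "star")
)

#' Marker encoding for a category of origin
#'
#' Fixed legend used by every composite plot: NNN green square, Temple blue
#' plus, Cholestasis orange triangle, HyLaw red star.
#'
#' @param origin character/factor of category labels.
#' @return Tibble with `marker_colour` and `marker_shape` per element.
#' @export
origin_marker <- function(origin) {
  i <- match(as.character(origin), ORIGIN_MARKERS$origin)
  tibble(marker_colour = ORIGIN_MARKERS$marker_colour[i],
         marker_shape = ORIGIN_MARKERS$marker_shape[i])
}

#' Composite mDISH plot data for one destination category
#'
#' Restricts the mDISH (xBL) point set to subjects whose on-treatment peak
#' lands in `destination`, marking each point by its category of origin so a
#' reviewer can see where every arrival came from. Over all destination
#' categories these sets partition the mDISH-eligible subjects.
#'
#' @param profiles a [derive_profiles()] result.
#' @param destination a category label of `scheme`.
#' @param scheme a [banding_scheme()].
#' @return Tibble of class `composite_points` with marker columns; possibly
#'   zero rows.
#' @export
composite_points <- function(profiles, destination,
                             scheme = banding_scheme()) {
  destination <- as.character(destination)
  if (!destination %in% quadrant_levels(scheme)) {
    stop("unknown destination category: ", destination, call. = FALSE)
  }
  pts <- mdish_points(profiles, scheme) |>
    as_tibble() |>
    filter(!is.na(.data$destination),
           .data$destination == .env$destination)
  out <- dplyr::bind_cols(pts, origin_marker(pts$origin))
  structure(out, class = c("composite_points", class(out)),
            destination = destination, scheme = scheme)
}

#' Export scatter point data as CSV
#'
#' @param points an `edish_points`, `mdish_points` or `composite_points`
#'   tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(points, path) {
  readr::write_csv(as_tibble(points), path)
  invisible(path)
}
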