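#' Define an eDISH banding scheme
#'
#' A banding scheme partitions the (AT, TB) plane of multiples of the upper
#' limit of normal (xULN) into quadrant categories. The classical scheme uses
#' a vertical cut at aminotransferase (AT) 3xULN (inclusive: band boundary
#' belongs to the elevated side) and a horizontal cut at total bilirubin (TB)
#' 2xULN (strict: the boundary belongs to the non-jaundiced side), giving the
#' four categories NNN (normal/near-normal), Temple (AT elevated, no
#' jaundice), Cholestasis (jaundice without substantial AT elevation) and
#' HyLaw (both elevated).
#'
#' Two optional refinements are supported:
#' * `extra_tb_band = TRUE` inserts an intermediate bilirubin band
#'   (1.5, 2] xULN, splitting NNN and Temple into `NNN`/`NNN-TBmid` and
#'   `Temple`/`Temple-TBmid`, for six categories in total.
#' * `split_nnn = TRUE` splits the low-AT, low-TB region at AT 1xULN into
#'   `Normal` (AT <= 1xULN) and `NearNormal` (1 < AT < `alt_cut`).
#'
#' Categories carry a componentwise partial order on their (AT band, TB band)
#' ranks; [classify_shift()] uses it to call a move upward, downward, lateral
#' or none. A severity rank (TB band first, then AT band) orders categories
#' for display, with HyLaw on top and the tie between Cholestasis and Temple
#' broken in favour of the jaundiced category.
#'
#' @param alt_cut AT cut in xULN; a point is in the elevated AT band when
#'   AT >= `alt_cut`. Default 3.
#' @param tb_cut TB cut in xULN; a point is jaundiced when TB > `tb_cut`
#'   (strict). Default 2.
#' @param extra_tb_band add the intermediate TB band (`tb_mid`, `tb_cut`].
#' @param tb_mid lower edge of the intermediate TB band (default 1.5).
#' @param split_nnn split the low AT band at 1xULN into Normal/NearNormal.
#'
#' @return An object of class `banding_scheme`: a list with the cut vectors
#'   and a `categories` tibble (`label`, `alt_rank`, `tb_rank`,
#'   `severity_rank`).
#' @examples
#' banding_scheme()
#' banding_scheme(extra_tb_band = TRUE)
#' @export
banding_scheme <- function(alt_cut = 3, tb_cut = 2,
                           extra_tb_band = FALSE, tb_mid = 1.5,
                           split_nnn = FALSE) {
  stopifnot(is.numeric(alt_cut), length(alt_cut) == 1, alt_cut > 0,
            is.numeric(tb_cut), length(tb_cut) == 1, tb_cut > 0)
  alt_cuts <- if (split_nnn) c(1, alt_cut) else alt_cut
  tb_cuts <- if (extra_tb_band) c(tb_mid, tb_cut) else tb_cut
  if (is.unsorted(alt_cuts, strictly = TRUE) || is.unsorted(tb_cuts, strictly = TRUE)) {
    stop("band cuts must be strictly increasing", call. = FALSE)
  }

  n_alt <- length(alt_cuts) + 1L
  n_tb <- length(tb_cuts) + 1L
  grid <- expand.grid(alt_band = seq_len(n_alt) - 1L,
                      tb_band = seq_len(n_tb) - 1L)
  grid$label <- mapply(band_label, grid$alt_band, grid$tb_band,
                       MoreArgs = list(n_alt = n_alt, n_tb = n_tb,
                                       split_nnn = split_nnn))

  ## Merged cells (split_nnn keeps one Cholestasis label across both low AT
  ## bands) get the minimum rank on each axis as their representative.
  categories <- grid |>
    group_by(.data$label) |>
    summarise(alt_rank = min(.data$alt_band),
              tb_rank = min(.data$tb_band),
              .groups = "drop") |>
    arrange(.data$tb_rank, .data$alt_rank) |>
    mutate(severity_rank = row_number())

  structure(
    list(alt_cuts = alt_cuts, tb_cuts = tb_cuts,
         alt_cut = alt_cut, tb_cut = tb_cut,
         extra_tb_band = extra_tb_band, tb_mid = tb_mid,
         split_nnn = split_nnn,
         categories = categories,
         cell_labels = grid),
    class = "banding_scheme"
  )
}

## label for one (alt band, tb band) cell; bands indexed from 0
band_label <- function(alt_band, tb_band, n_alt, n_tb, split_nnn) {
  alt_top <- alt_band == n_alt - 1L
  tb_top <- tb_band == n_tb - 1L
  base <-
    if (tb_top && alt_top) "HyLaw"
    else if (tb_top) "Cholestasis"
    else if (alt_top) "Temple"
    else if (split_nnn && alt_band == 0L) "Normal"
    else if (split_nnn) "NearNormal"
    else "NNN"
  ## intermediate TB band tags non-jaundiced labels
  if (n_tb == 3L && tb_band == 1L) paste0(base, "-TBmid") else base
}

#' @export
print.banding_scheme <- function(x, ...) {
  cat("<banding_scheme> AT cut(s) >= ", paste(x$alt_cuts, collapse = ", "),
      " xULN; TB cut(s) > ", paste(x$tb_cuts, collapse = ", "), " xULN\n",
      sep = "")
  cat("categories (severity ascending): ",
      paste(x$categories$label, collapse = " < "), "\n", sep = "")
  invisible(x)
}

#' Category labels of a banding scheme
#'
#' @param scheme a [banding_scheme()].
#' @param decreasing if `TRUE`, most severe first (the Sankey node order:
#'   HyLaw topmost, ties between jaundiced and AT-elevated categories broken
#'   in favour of the jaundiced one).
#' @return Character vector of category labels.
#' @export
quadrant_levels <- function(scheme = banding_scheme(), decreasing = FALSE) {
  lv <- scheme$categories$label
  if (decreasing) rev(lv) else lv
}

#' Assign eDISH quadrant categories
#'
#' Maps multiples of ULN for aminotransferase and total bilirubin to the
#' quadrant category of `scheme`. The AT boundary is inclusive
#' (AT >= cut is elevated) and the TB boundaries are strict (TB > cut is the
#' higher band), so the classical boundary point (3, 2) lands in Temple.
#'
#' @param at_xuln,tb_xuln numeric vectors of peak (or baseline) AT and TB in
#'   xULN; finite and non-negative.
#' @param scheme a [banding_scheme()].
#' @return Factor of category labels with levels in ascending severity order.
#' @examples
#' assign_quadrant(c(5, 3, 0.8, 1.2), c(3, 2, 0.5, 2.5))
#' @export
assign_quadrant <- function(at_xuln, tb_xuln, scheme = banding_scheme()) {
  if (length(at_xuln) != length(tb_xuln)) {
    stop("`at_xuln` and `tb_xuln` must have the same length", call. = FALSE)
  }
  if (!is.numeric(at_xuln) || !is.numeric(tb_xuln) ||
      any(!is.finite(at_xuln)) || any(!is.finite(tb_xuln)) ||
      any(at_xuln < 0) || any(tb_xuln < 0)) {
    stop("AT and TB multiples must be finite and >= 0", call. = FALSE)
  }
  alt_band <- rowSums(outer(at_xuln, scheme$alt_cuts, `>=`))
  tb_band <- rowSums(outer(tb_xuln, scheme$tb_cuts, `>`))
  key <- paste(alt_band, tb_band)
  cells <- scheme$cell_labels
  lab <- cells$label[match(key, paste(cells$alt_band, cells$tb_band))]
  factor(lab, levels = quadrant_levels(scheme))
}

#' Classify a baseline-to-peak category shift
#'
#' Uses the componentwise partial order on (AT band, TB band): a shift is
#' `upward` when the destination is strictly above the origin (potential
#' DILI), `downward` when strictly below (potential improvement/efficacy),
#' `none` when origin and destination coincide, and `lateral` when the two
#' categories are incomparable (e.g. Temple vs Cholestasis).
#'
#' @param origin,destination category labels (character or factor) from
#'   `scheme`.
#' @param scheme a [banding_scheme()].
#' @return Factor with levels `upward`, `downward`, `lateral`, `none`.
#' @examples
#' classify_shift("NNN", "HyLaw")       # upward
#' classify_shift("Temple", "NNN")      # downward
#' classify_shift("Temple", "Cholestasis")  # lateral
#' @export
classify_shift <- function(origin, destination, scheme = banding_scheme()) {
  cats <- scheme$categories
  o <- match(as.character(origin), cats$label)
  d <- match(as.character(destination), cats$label)
  if (anyNA(o) || anyNA(d)) {
    bad <- unique(c(as.character(origin)[is.na(o)],
                    as.character(destination)[is.na(d)]))
    stop("unknown category label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  da <- cats$alt_rank[d] - cats$alt_rank[o]
  dt <- cats$tb_rank[d] - cats$tb_rank[o]
  dir <- ifelse(o == d, "none",
         ifelse(da >= 0 & dt >= 0, "upward",
         ifelse(da <= 0 & dt <= 0, "downward", "lateral")))
  factor(dir, levels = c("upward", "downward", "lateral", "none"))
}

#' Shift direction to cross-table colour class
#'
#' The cross-table colour convention: red for upward shifts of concern
#' (potential DILI), green for downward shifts (potential efficacy), grey for
#' no shift, yellow for lateral (neutral) shifts.
#'
#' @param direction factor/character as returned by [classify_shift()].
#' @return Factor with levels `red`, `green`, `grey`, `yellow`.
#' @export
shift_color_class <- function(direction) {
  map <- c(upward = "red", downward = "green", none = "grey",
           lateral = "yellow")
  factor(unname(map[as.character(direction)]),
         levels = c("red", "green", "grey", "yellow"))
}

#' Round a proportion to a whole-number percent
#'
#' Computes `100 * numerator / denominator` rounded half-up to an integer,
#' the convention used for reported baseline-category proportions (e.g.
#' 13 of 46 reports as 28).
#'
#' @param numerator,denominator non-negative counts with
#'   `numerator <= denominator` and `denominator > 0`. Vectorised.
#' @return Integer percent(s).
#' @examples
#' report_proportion(13, 46)  # 28
#' report_proportion(81, 765) # 11
#' @export
report_proportion <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be > 0", call. = FALSE)
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop("need 0 <= numerator <= denominator", call. = FALSE)
  }
  as.integer(floor(100 * numerator / denominator + 0.5))
}
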