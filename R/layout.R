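#' Generate a TMT trial layout
#'
#' Places the 25 targets of one TMT trial on a 5 x 5 grid of square cells
#' (4.32 deg of visual angle per cell), one target per cell, at uniformly
#' random positions within each cell subject to a minimum pairwise
#' centre-to-centre separation. The sequence order (which target carries which
#' label) is randomly assigned to grid cells. Part A is labelled "1".."25";
#' part B alternates numbers and letters ("1", "A", "2", "B", ..., "13").
#'
#' The grid is tangent-linear: cell edges are equally spaced on the screen
#' (in cm / pixels), with the nominal angular cell size converted at the screen
#' centre. Coordinates of the returned targets are in degrees (origin screen
#' centre, y up) and separation is enforced in degree space.
#'
#' @param part `"A"` or `"B"`.
#' @param geometry a [screen_geometry()]; must be large enough to contain the
#'   grid.
#' @param seed integer seed; identical seeds give identical layouts.
#' @param grid_cell_deg angular cell size in degrees (default 4.32).
#' @param min_separation minimum centre-to-centre target distance in degrees
#'   (default 1.35, i.e. one target diameter).
#' @param radius target circumcircle radius in degrees (default 0.675).
#' @param margin inset of admissible centre positions from the cell border, in
#'   degrees at screen centre (default = `radius`, keeping each circle inside
#'   its cell).
#' @param max_tries per-cell rejection-sampling budget before the constraint
#'   set is declared infeasible.
#' @return a data frame of class `tmt_layout` with columns `label`,
#'   `seq_index`, `x`, `y` (degrees), `radius`, and attributes `part` and
#'   `grid_cell_deg`.
#' @examples
#' lay <- generate_layout("B", seed = 1)
#' head(lay)
#' @export
generate_layout <- function(part = c("A", "B"), geometry = screen_geometry(),
                            seed = NULL, grid_cell_deg = 4.32,
                            min_separation = 1.35, radius = 0.675,
                            margin = radius, max_tries = 1000) {
  part <- match.arg(part)
  cell_cm <- tan(grid_cell_deg * pi / 180) * geometry$distance_cm
  if (5 * cell_cm > geometry$width_cm || 5 * cell_cm > geometry$height_cm)
    stop("screen too small to contain the 5 x 5 grid at this cell size")
  margin_cm <- tan(margin * pi / 180) * geometry$distance_cm
  if (2 * margin_cm >= cell_cm)
    stop("margin leaves no admissible area within a grid cell")

  with_seed(seed, {
    # cell lower-left corners in cm, grid centred on the screen centre
    corners <- expand.grid(col = 0:4, row = 0:4)
    cx0 <- (corners$col - 2.5) * cell_cm
    cy0 <- (corners$row - 2.5) * cell_cm
    px <- py <- numeric(25)
    for (i in seq_len(25)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        xc <- cx0[i] + margin_cm + runif(1) * (cell_cm - 2 * margin_cm)
        yc <- cy0[i] + margin_cm + runif(1) * (cell_cm - 2 * margin_cm)
        xd <- atan(xc / geometry$distance_cm) * 180 / pi
        yd <- atan(yc / geometry$distance_cm) * 180 / pi
        if (i == 1 ||
            all(sqrt((px[seq_len(i - 1)] - xd)^2 +
                     (py[seq_len(i - 1)] - yd)^2) >= min_separation)) {
          px[i] <- xd; py[i] <- yd; ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("layout constraints infeasible: rejection sampling exhausted ",
             "(cell ", i, ")")
    }
    cell <- sample.int(25)  # sequence position -> grid cell
    out <- data.frame(label = tmt_labels(part),
                      seq_index = seq_len(25),
                      x = px[cell], y = py[cell],
                      radius = radius,
                      stringsAsFactors = FALSE)
    structure(out, part = part, grid_cell_deg = grid_cell_deg,
              class = c("tmt_layout", "data.frame"))
  })
}

# Label sequence for a test half: "1".."25" (A) or "1","A",..,"13" (B).
tmt_labels <- function(part) {
  if (part == "A") return(as.character(1:25))
  lab <- character(25)
  lab[seq(1, 25, by = 2)] <- as.character(1:13)
  lab[seq(2, 24, by = 2)] <- LETTERS[1:12]
  lab
}
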