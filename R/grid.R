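#' Tissue compartment
#'
#' An axis-aligned rectangular region of the grid representing one tissue
#' type (lumen, epithelium, lamina propria, lymph node, blood, or a generic
#' region). The region covers the half-open box
#' `[xmin, xmax) x [ymin, ymax)` in continuous coordinates. By default a
#' compartment contains its agents; agent types listed in `permeable` may
#' cross its boundary into neighbouring compartments.
#'
#' @param name one of `"lumen"`, `"epithelium"`, `"lamina_propria"`,
#'   `"lymph_node"`, `"blood"`, `"generic"`.
#' @param xmin,xmax,ymin,ymax region bounds in grid-cell units.
#' @param permeable character vector of agent types allowed to cross, or
#'   `TRUE` for all types.
#' @return an object of class `compartment`.
#' @export
compartment <- function(name, xmin, xmax, ymin, ymax, permeable = character(0)) {
  name <- match.arg(name, c("lumen", "epithelium", "lamina_propria",
                            "lymph_node", "blood", "generic"))
  stopifnot(xmax > xmin, ymax > ymin)
  structure(list(name = name, xmin = xmin, xmax = xmax,
                 ymin = ymin, ymax = ymax, permeable = permeable),
            class = "compartment")
}

.compartment_permeable_for <- function(comp, agent_type) {
  isTRUE(comp$permeable) || agent_type %in% comp$permeable
}

#' Two-dimensional simulation space
#'
#' A `width x height` grid of unit cells with an overlaid continuous space:
#' agents hold continuous positions in `[0, width) x [0, height)` and the
#' grid cell of a position is its floor. Compartments must partition the
#' grid (no overlap, full cover); the default is a single generic
#' compartment spanning the whole grid.
#'
#' @param width,height integer cell counts, both at least 1.
#' @param compartments list of [compartment()] objects.
#' @return an object of class `grid_space`.
#' @export
grid_space <- function(width, height, compartments = NULL) {
  stopifnot(width >= 1, height >= 1)
  if (is.null(compartments)) {
    compartments <- list(compartment("generic", 0, width, 0, height))
  }
  area <- 0
  for (cp in compartments) {
    stopifnot(inherits(cp, "compartment"))
    if (cp$xmin < 0 || cp$xmax > width || cp$ymin < 0 || cp$ymax > height) {
      stop("compartment ", cp$name, " lies outside the grid")
    }
    area <- area + (cp$xmax - cp$xmin) * (cp$ymax - cp$ymin)
  }
  if (length(compartments) > 1L) {
    for (i in seq_along(compartments)) {
      for (j in seq_along(compartments)) {
        if (i >= j) next
        a <- compartments[[i]]; b <- compartments[[j]]
        if (a$xmin < b$xmax && b$xmin < a$xmax &&
            a$ymin < b$ymax && b$ymin < a$ymax) {
          stop("compartments ", a$name, " and ", b$name, " overlap")
        }
      }
    }
  }
  if (abs(area - width * height) > 1e-9) {
    stop("compartments must cover the grid exactly (cover ", area,
         " of ", width * height, " cells)")
  }
  structure(list(width = width, height = height, compartments = compartments),
            class = "grid_space")
}

#' @export
print.grid_space <- function(x, ...) {
  cat(sprintf("<grid_space> %dx%d, %d compartment(s): %s\n",
              x$width, x$height, length(x$compartments),
              paste(vapply(x$compartments, `[[`, "", "name"),
                    collapse = ", ")))
  invisible(x)
}

#' Grid cell of a continuous position
#'
#' @param x,y continuous coordinates.
#' @return integer matrix with columns `cx`, `cy` (0-based cell indices).
#' @export
cell_of <- function(x, y) {
  cbind(cx = as.integer(floor(x)), cy = as.integer(floor(y)))
}

#' Compartment index containing a position
#'
#' @param space a [grid_space()].
#' @param x,y continuous coordinates (vectorized).
#' @return integer vector of compartment indices.
#' @export
compartment_at <- function(space, x, y) {
  idx <- rep(NA_integer_, length(x))
  for (i in seq_along(space$compartments)) {
    cp <- space$compartments[[i]]
    hit <- is.na(idx) & x >= cp$xmin & x < cp$xmax & y >= cp$ymin & y < cp$ymax
    idx[hit] <- i
  }
  if (anyNA(idx)) stop("position outside all compartments")
  idx
}

# Reflect positions into the half-open interval [lo, hi) using triangle-wave
# folding; robust to displacements larger than the interval.
.reflect_into <- function(p, lo, hi) {
  w <- hi - lo
  q <- (p - lo) %% (2 * w)
  r <- ifelse(q <= w, q, 2 * w - q)
  lo + pmin(r, w * (1 - 1e-12))
}
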