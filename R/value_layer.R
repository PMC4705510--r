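#' Cytokine value layer
#'
#' A value layer is a grid-aligned scalar field holding one cytokine or
#' chemokine concentration per grid cell, in relative units. It evolves by
#' a discrete diffusion--evaporation rule (see [diffuse_step()]): each step
#' the whole field is multiplied by the evaporation constant `ce` after a
#' fraction `cd` of the neighbour differences has been exchanged.
#'
#' Values are stored as a matrix with `height` rows and `width` columns;
#' the grid cell at integer coordinate `(x, y)` (0-based) lives at
#' `values[y + 1, x + 1]`.
#'
#' @param name cytokine identifier (e.g. `"IL12"`, `"TGFb"`).
#' @param width,height grid dimensions in cells.
#' @param ce evaporation constant in `[0, 1]`: per-step retention factor.
#' @param cd diffusion constant in `[0, 1]`: weight on the neighbour
#'   difference sum.
#' @param neighborhood `"von_neumann"` (4 neighbours) or `"moore"` (8).
#' @param boundary `"zero_flux"` (out-of-bounds neighbours mirror the centre
#'   value, contributing zero difference) or `"torus"` (indices wrap).
#' @param mode `"normalized"` divides `cd` by the neighbourhood size before
#'   applying the update, which keeps non-negative fields non-negative for
#'   any `ce, cd` in `[0, 1]`; `"raw"` applies the literal rule.
#' @param clamp_nonnegative set negative results to zero after each step.
#' @param values optional initial matrix (`height` x `width`).
#' @return an object of class `value_layer`.
#' @export
value_layer <- function(name, width, height, ce = 0.98, cd = 0.6,
                        neighborhood = c("von_neumann", "moore"),
                        boundary = c("zero_flux", "torus"),
                        mode = c("normalized", "raw"),
                        clamp_nonnegative = TRUE, values = NULL) {
  neighborhood <- match.arg(neighborhood)
  boundary <- match.arg(boundary)
  mode <- match.arg(mode)
  stopifnot(width >= 1, height >= 1,
            ce >= 0, ce <= 1, cd >= 0, cd <= 1)
  if (is.null(values)) {
    values <- matrix(0, nrow = height, ncol = width)
  } else {
    values <- as.matrix(values)
    if (nrow(values) != height || ncol(values) != width) {
      stop("values must be a ", height, " x ", width, " matrix")
    }
  }
  if (!all(is.finite(values))) stop("layer values must be finite")
  if (clamp_nonnegative && any(values < 0)) {
    stop("layer values must be non-negative when clamp_nonnegative is TRUE")
  }
  structure(
    list(name = name, width = width, height = height, ce = ce, cd = cd,
         neighborhood = neighborhood, boundary = boundary, mode = mode,
         clamp_nonnegative = clamp_nonnegative, values = values),
    class = "value_layer"
  )
}

#' @export
print.value_layer <- function(x, ...) {
  cat(sprintf(
    "<value_layer %s> %dx%d  ce=%g cd=%g  %s/%s/%s  sum=%g max=%g\n",
    x$name, x$width, x$height, x$ce, x$cd, x$neighborhood, x$boundary,
    x$mode, sum(x$values), max(x$values)))
  invisible(x)
}

.neighbor_offsets <- function(neighborhood) {
  vn <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (neighborhood == "von_neumann") return(vn)
  c(vn, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
}

# Matrix whose [row, col] entry is the value at (x + dx, y + dy) under the
# boundary rule. Rows index y, columns index x. For zero_flux, clamping the
# index to the edge makes the out-of-bounds neighbour equal the centre cell,
# so its difference contribution is exactly zero.
.shift_values <- function(v, dx, dy, boundary) {
  nr <- nrow(v)
  nc <- ncol(v)
  ri <- seq_len(nr) + dy
  ci <- seq_len(nc) + dx
  if (boundary == "torus") {
    ri <- ((ri - 1L) %% nr) + 1L
    ci <- ((ci - 1L) %% nc) + 1L
    return(v[ri, ci, drop = FALSE])
  }
  out_r <- ri < 1L | ri > nr
  out_c <- ci < 1L | ci > nc
  ri <- pmin(pmax(ri, 1L), nr)
  ci <- pmin(pmax(ci, 1L), nc)
  s <- v[ri, ci, drop = FALSE]
  # a neighbour with either coordinate out of bounds mirrors the centre
  # cell, so the whole offending row/column band reverts to centre values
  # (this matters for diagonal offsets, where only one axis may overflow)
  if (any(out_r)) s[out_r, ] <- v[out_r, , drop = FALSE]
  if (any(out_c)) s[, out_c] <- v[, out_c, drop = FALSE]
  s
}

#' One synchronous diffusion--evaporation step
#'
#' Updates every cell from the previous step's values:
#' `v_n = ce * (v_{n-1} + cd' * sum_neighbours(v_neighbour - v_centre))`,
#' where `cd'` is `cd` in raw mode and `cd / |N|` in normalized mode
#' (`|N|` = neighbourhood size). The update is double-buffered: all new
#' values are computed from the step `n - 1` field.
#'
#' On a torus the pairwise neighbour differences cancel, so total mass
#' scales exactly by `ce` each step (the basis of the conservation tests).
#'
#' @param layer a [value_layer()].
#' @return the layer advanced by one step.
#' @export
diffuse_step <- function(layer) {
  stopifnot(inherits(layer, "value_layer"))
  v <- layer$values
  if (!all(is.finite(v))) {
    stop("corrupted layer state: non-finite values in layer ", layer$name)
  }
  offs <- .neighbor_offsets(layer$neighborhood)
  acc <- matrix(0, nrow = nrow(v), ncol = ncol(v))
  for (o in offs) {
    acc <- acc + .shift_values(v, o[1L], o[2L], layer$boundary)
  }
  diff_sum <- acc - length(offs) * v
  cd_eff <- if (layer$mode == "normalized") layer$cd / length(offs) else layer$cd
  new_v <- layer$ce * (v + cd_eff * diff_sum)
  if (layer$clamp_nonnegative) new_v <- pmax(new_v, 0)
  layer$values <- new_v
  layer
}

#' Central-difference gradient of a layer at a grid cell
#'
#' Used by chemotaxis-enabled agents to bias their movement direction.
#' Out-of-bounds neighbours follow the layer's boundary mode.
#'
#' @param layer a [value_layer()].
#' @param cell integer vector `c(x, y)`, 0-based grid coordinates.
#' @return numeric `c(gx, gy)`.
#' @export
gradient_at <- function(layer, cell) {
  stopifnot(inherits(layer, "value_layer"), length(cell) == 2L)
  x <- as.integer(cell[1L])
  y <- as.integer(cell[2L])
  if (x < 0L || x >= layer$width || y < 0L || y >= layer$height) {
    stop("cell (", x, ", ", y, ") out of bounds")
  }
  at <- function(xx, yy) {
    if (layer$boundary == "torus") {
      xx <- xx %% layer$width
      yy <- yy %% layer$height
    } else {
      xx <- min(max(xx, 0L), layer$width - 1L)
      yy <- min(max(yy, 0L), layer$height - 1L)
    }
    layer$values[yy + 1L, xx + 1L]
  }
  gx <- (at(x + 1L, y) - at(x - 1L, y)) / 2
  gy <- (at(x, y + 1L) - at(x, y - 1L)) / 2
  c(gx, gy)
}

#' Deposit a concentration into one grid cell
#'
#' @param layer a [value_layer()].
#' @param cell integer `c(x, y)`, 0-based.
#' @param value non-negative concentration (relative units).
#' @param semantics `"set"` overwrites, `"add"` increments, `"set_max"`
#'   writes `max(current, value)`. Secreting cells in the reference
#'   scenarios use `"set"` with value 70.
#' @return the modified layer.
#' @export
deposit <- function(layer, cell, value, semantics = c("set", "add", "set_max")) {
  semantics <- match.arg(semantics)
  stopifnot(inherits(layer, "value_layer"), length(cell) == 2L)
  if (!is.finite(value) || value < 0) stop("deposit value must be non-negative")
  x <- as.integer(cell[1L])
  y <- as.integer(cell[2L])
  if (x < 0L || x >= layer$width || y < 0L || y >= layer$height) {
    stop("cell (", x, ", ", y, ") out of bounds")
  }
  cur <- layer$values[y + 1L, x + 1L]
  layer$values[y + 1L, x + 1L] <- switch(semantics,
    set = value,
    add = cur + value,
    set_max = max(cur, value)
  )
  layer
}

#' Write a dense layer dump
#'
#' Appends one block per call: a header line `# layer=<name> cycle=<n>`
#' followed by the `height x width` matrix as tab-separated rows
#' (row-major, row `i` = grid row `y = i - 1`).
#'
#' @param layer a [value_layer()].
#' @param cycle cycle number for the header.
#' @param path file path; created if missing.
#' @param append append to an existing dump file.
#' @return `path`, invisibly.
#' @export
write_layer_dump <- function(layer, cycle, path, append = FALSE) {
  con <- file(path, open = if (append) "at" else "wt")
  on.exit(close(con))
  writeLines(sprintf("# layer=%s cycle=%d", layer$name, as.integer(cycle)), con)
  utils::write.table(layer$values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a layer dump written by [write_layer_dump()]
#'
#' @param path dump file path.
#' @return a list of blocks, each `list(name, cycle, values)`.
#' @export
read_layer_dump <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# layer=", lines)
  if (length(hdr) == 0L) stop("not a layer dump file: ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  lapply(seq_along(hdr), function(i) {
    m <- regmatches(lines[hdr[i]],
                    regexec("^# layer=(\\S+) cycle=(\\d+)", lines[hdr[i]]))[[1L]]
    body <- lines[(hdr[i] + 1L):ends[i]]
    body <- body[nzchar(body)]
    vals <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE),
                                  as.numeric))
    list(name = m[2L], cycle = as.integer(m[3L]), values = vals)
  })
}
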