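#' Per-cycle population counts as a long table
#'
#' Collects the per-cycle reports into one data frame with a row per
#' `(cycle, type, state)` for every combination whose population is ever
#' nonzero over the run (zeros are filled in for cycles where such a
#' combination is momentarily empty), in deterministic (cycle, type,
#' state) order.
#'
#' @param x a `sim_state` or a list of cycle reports.
#' @return data frame with columns `cycle`, `type`, `state`, `count`.
#' @export
reports_to_df <- function(x) {
  reports <- if (inherits(x, "sim_state")) x$reports else x
  if (length(reports) == 0L) stop("no cycle reports")
  combos <- unique(do.call(rbind, lapply(reports, function(r)
    r$counts[, c("type", "state")])))
  combos <- combos[order(combos$type, combos$state), , drop = FALSE]
  out <- do.call(rbind, lapply(reports, function(r) {
    merged <- merge(combos, r$counts, by = c("type", "state"),
                    all.x = TRUE, sort = FALSE)
    merged$count[is.na(merged$count)] <- 0L
    merged <- merged[order(merged$type, merged$state), , drop = FALSE]
    data.frame(cycle = r$cycle, merged, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$cycle, out$type, out$state), , drop = FALSE]
}

#' Write per-cycle counts as a tab-separated file
#'
#' @param x a `sim_state`, a list of cycle reports, or a data frame from
#'   [reports_to_df()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(x, path) {
  df <- if (is.data.frame(x)) x else reports_to_df(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a counts file written by [write_counts_tsv()]
#'
#' @param path file path.
#' @return data frame with columns `cycle`, `type`, `state`, `count`.
#' @export
read_counts_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

.DEFAULT_STATE_COLORS <- c(
  "bacterium:infectious" = "#D95F02",
  "bacterium:tolerogenic" = "#66A61E",
  "dendritic_cell:immature" = "#7570B3",
  "dendritic_cell:effector" = "#E7298A",
  "dendritic_cell:tolerogenic" = "#1B9E77",
  "t_cell:naive" = "#CCCCCC",
  "t_cell:Th1" = "#FF0000",
  "t_cell:Th17" = "#FF00FF",
  "t_cell:Treg" = "#0000FF"
)

#' Snapshot rendering specification
#'
#' Maps three value layers onto the three primary colour channels and
#' assigns glyph colours per agent state. The default channel map renders
#' IFN-gamma as red, IL-17 as blue and IL-10 as green, so regions where
#' Th1 and Th17 activity overlap appear purple; the map is fully
#' configurable (e.g. an inflammatory-red / regulatory-green scheme).
#' Dead agents are always drawn black.
#'
#' @param channels named character vector mapping exactly the names
#'   `red`, `green`, `blue` to layer names.
#' @param state_colors named vector of `"type:state"` glyph colours (hex).
#' @param scale pixels per grid cell.
#' @return an object of class `snapshot_spec`.
#' @export
snapshot_spec <- function(channels = c(red = "IFNg", green = "IL10",
                                       blue = "IL17"),
                          state_colors = .DEFAULT_STATE_COLORS,
                          scale = 1L) {
  if (!identical(sort(names(channels)), c("blue", "green", "red"))) {
    stop("channels must map exactly red, green and blue to layer names")
  }
  if (anyDuplicated(unname(channels))) {
    stop("each channel must map a distinct layer")
  }
  stopifnot(scale >= 1)
  structure(list(channels = channels, state_colors = state_colors,
                 scale = as.integer(scale)), class = "snapshot_spec")
}

#' Render a headless PNG snapshot of the simulation
#'
#' Background pixels encode the three mapped layers, each normalized by
#' the layer's running maximum over the simulation so far (zero if the
#' layer never held mass); agent glyphs are single pixels coloured by
#' state, with dead cells black regardless of type.
#'
#' @param state a `sim_state`.
#' @param spec a [snapshot_spec()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(state, spec = snapshot_spec(), path) {
  stopifnot(inherits(state, "sim_state"), inherits(spec, "snapshot_spec"))
  w <- state$space$width
  h <- state$space$height
  sc <- spec$scale
  img <- array(0, dim = c(h * sc, w * sc, 3L))
  for (k in seq_along(c("red", "green", "blue"))) {
    ch <- c("red", "green", "blue")[k]
    lname <- spec$channels[[ch]]
    ly <- state$layers[[lname]]
    if (is.null(ly)) stop("snapshot channel references unknown layer: ",
                          lname)
    mx <- state$running_max[[lname]]
    if (is.na(mx) || mx <= 0) mx <- max(ly$values)
    plane <- if (mx > 0) pmin(ly$values / mx, 1) else
      matrix(0, nrow = h, ncol = w)
    img[, , k] <- plane %x% matrix(1, sc, sc)
  }
  ag <- state$agents
  if (nrow(ag) > 0L) {
    px <- pmin(pmax(floor(ag$x * sc), 0), w * sc - 1) + 1L
    py <- pmin(pmax(floor(ag$y * sc), 0), h * sc - 1) + 1L
    key <- paste(ag$type, ag$state, sep = ":")
    col <- spec$state_colors[key]
    col[is.na(col)] <- "#FFFFFF"
    col[!ag$alive | ag$state == "dead"] <- "#000000"
    rgb <- grDevices::col2rgb(col) / 255
    for (i in seq_len(nrow(ag))) {
      img[py[i], px[i], ] <- rgb[, i]
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Benchmark the reference scenarios
#'
#' Runs each preset for the given number of cycles under the same seed and
#' tabulates the structural performance profile: initialization cost and
#' per-100-cycle simulation cost (measured elapsed time in arbitrary,
#' hardware-dependent units), peak live solver instances, intracellular
#' scale executions, and solver-service call/integration counts. Absolute
#' times are not reproducible across machines; the instance and invocation
#' counts are exact.
#'
#' @param presets preset names to run.
#' @param cycles cycles per scenario.
#' @param seed shared master seed.
#' @return data frame with one row per scenario.
#' @export
run_benchmark <- function(presets = c("RM", "BM", "MS", "DF"), cycles = 20L,
                          seed = 1L) {
  rows <- lapply(presets, function(p) {
    st <- run_scenario(scenario_preset(p, seed = seed, cycles = cycles))
    cm <- cost_metrics(st)
    data.frame(
      scenario = p,
      cycles = cycles,
      init_cost = cm$init_time,
      cycle_cost_per100 = sum(cm$time) / max(cycles, 1L) * 100,
      est_cycle_cost = estimate_cycle_cost(cm, st$config$frequencies),
      peak_solver_instances = cm$solver$peak_instances,
      intracellular_executions = cm$executions[["intracellular"]],
      solver_calls = cm$solver$calls,
      integrations = cm$solver$integrations,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a benchmark table as TSV
#'
#' @param bench data frame from [run_benchmark()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(bench, path) {
  utils::write.table(bench, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
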