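#' Run manifest
#'
#' The resolved configuration plus provenance fields every output file
#' embeds or references, so any artifact can be regenerated exactly.
#'
#' @param config resolved configuration.
#' @param n_runs number of simulations covered.
#' @return Named list.
#' @export
run_manifest <- function(config, n_runs = 1L) {
  list(
    package = "goalgrow",
    version = as.character(utils::packageVersion("goalgrow")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_runs = n_runs,
    config = config
  )
}

#' Write / read an experiment table
#'
#' CSV with columns `sim_id, mode, seed, n_steps, red, green, yellow,
#' blue, total, final_goal_neurons`; a JSON manifest is written alongside
#' as `<path>.manifest.json`. Reading restores the `experiment_table`
#' class and `n_objects` attribute, and round-trips all values exactly.
#'
#' @param tab an `experiment_table`.
#' @param path output CSV path.
#' @param config resolved configuration for the manifest (optional).
#' @return `write_results` returns `path` invisibly; `read_results`
#'   returns the table.
#' @export
write_results <- function(tab, path, config = NULL) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  manifest <- run_manifest(config, n_runs = nrow(tab))
  manifest$n_objects <- attr(tab, "n_objects")
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  tab <- utils::read.csv(path)
  mpath <- paste0(path, ".manifest.json")
  if (file.exists(mpath)) {
    man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    if (!is.null(man$n_objects)) attr(tab, "n_objects") <- man$n_objects
  }
  class(tab) <- c("experiment_table", "data.frame")
  tab
}

#' Write / read a per-tick trajectory log
#'
#' JSON-lines, one record per tick with fields `t`, `x`, `y`, `heading`,
#' `lambda`, `n_goal_neurons`, `touches` (array of colors) and `growth`
#' (tick/donors/n_created/zeta/truncated, present only on growth ticks).
#' The first line is the run manifest.
#'
#' @param result a `simulation_result`.
#' @param path output path.
#' @return `write_trajectory` returns `path` invisibly;
#'   `read_trajectory` returns a list `manifest`, `records`.
#' @export
write_trajectory <- function(result, path) {
  tr <- result$trajectory
  growth_by_tick <- list()
  for (ev in result$growth_events) growth_by_tick[[as.character(ev$tick)]] <- ev
  con <- file(path, open = "wt")
  on.exit(close(con))
  man <- run_manifest(result$config, n_runs = 1L)
  writeLines(jsonlite::toJSON(list(manifest = man), auto_unbox = TRUE,
                              digits = NA, null = "null"), con)
  for (i in seq_len(nrow(tr))) {
    rec <- list(t = tr$t[i], x = tr$x[i], y = tr$y[i],
                heading = tr$heading[i], lambda = tr$lambda[i],
                n_goal_neurons = tr$n_goal[i],
                touches = I(result$touches[[i]]))
    ev <- growth_by_tick[[as.character(tr$t[i])]]
    if (!is.null(ev)) {
      rec$growth <- list(tick = ev$tick, donors = I(ev$donors),
                         n_created = ev$n_created,
                         zeta = ev$zeta_final, truncated = ev$truncated)
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  manifest <- jsonlite::fromJSON(lines[1], simplifyVector = TRUE)$manifest
  records <- lapply(lines[-1], jsonlite::fromJSON, simplifyVector = TRUE)
  list(manifest = manifest, records = records)
}

#' World snapshot as JSON
#'
#' Serializes the live/dead objects (id, color, x, y, alive) and the
#' organism pose.
#'
#' @param world a `jca_world`.
#' @param pose pose to embed; defaults to the world's.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly.
#' @export
world_to_json <- function(world, pose = world$pose, path = NULL) {
  x <- list(
    field = world$field,
    objects = data.frame(id = world$id, color = COLOR_NAMES[world$color],
                         x = world$x, y = world$y, alive = world$alive),
    organism = list(x = pose$x, y = pose$y, heading = pose$heading,
                    start_x = pose$start_x, start_y = pose$start_y)
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Network snapshot as JSON
#'
#' Full connection lists and weights of the controller, for replay and
#' inspection.
#'
#' @param net a `network_state`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly.
#' @export
network_to_json <- function(net, path = NULL) {
  js <- jsonlite::toJSON(network_to_list(net), auto_unbox = TRUE,
                         digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
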