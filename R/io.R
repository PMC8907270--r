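#' Read and write trajectory tables
#'
#' The canonical on-disk trajectory format is tab-separated text with a
#' header naming the unit-suffixed columns `time_min`, `cell_id`,
#' `phenotype`, `x_um`, `y_um` (optionally `area_um2`, `perimeter_um`,
#' `px_um`, `py_um`).  The unit suffixes are the unit metadata: a file
#' with bare `x`/`y` columns is rejected rather than silently assumed
#' to be calibrated.  Synthetic and simulated tracks share this dialect
#' so the analysis is source-blind.
#'
#' @param x data.frame (one or many cells) to write.
#' @param path file path.
#' @param strict if `TRUE`, rows out of time order are an error; the
#'   default re-sorts within each cell with a warning.
#' @return `read_trajectory_table`: the validated data.frame.
#' @export
write_trajectory_table <- function(x, path) {
  need <- c("time_min", "cell_id", "phenotype", "x_um", "y_um")
  if (!all(need %in% names(x)))
    stop("missing columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_table
#' @export
read_trajectory_table <- function(path, strict = FALSE) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("time_min", "cell_id", "x_um", "y_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    bare <- intersect(c("x", "y", "t", "time"), names(df))
    if (length(bare))
      stop("unit mismatch: found uncalibrated columns (",
           paste(bare, collapse = ", "),
           "); expected unit-suffixed time_min/x_um/y_um")
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  fixed <- FALSE
  out <- do.call(rbind, lapply(split(df, df$cell_id), function(sub) {
    if (is.unsorted(sub$time_min, strictly = TRUE)) {
      if (strict) stop("non-monotone time stamps for cell ", sub$cell_id[1])
      fixed <<- TRUE
      sub <- sub[order(sub$time_min), ]
      if (any(diff(sub$time_min) <= 0))
        stop("duplicated time stamps for cell ", sub$cell_id[1])
    }
    sub
  }))
  if (fixed) warning("rows were out of time order and have been re-sorted")
  rownames(out) <- NULL
  out
}

snapshot_format_version <- "senCPM-snapshot-1"

#' Write and read lattice snapshots
#'
#' Lossless plain-text round trip of a [lattice_state()]: the grid is
#' stored as a whitespace-delimited integer block and the cell table
#' (ids, phenotypes, targets, polarity at full precision) plus
#' dimensions, elapsed MCS and a format version tag go to a JSON
#' sidecar (`<path>.json`).
#'
#' @param state a [lattice_state()].
#' @param path grid file path.
#' @return `read_snapshot`: the reconstructed `lattice_state`.
#' @export
write_snapshot <- function(state, path) {
  write.table(state$grid, path, sep = " ", row.names = FALSE,
              col.names = FALSE)
  meta <- list(version = snapshot_format_version,
               width = state$width, height = state$height,
               mcs_elapsed = state$mcs_elapsed,
               cells = state$cells)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing snapshot metadata: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$version, snapshot_format_version))
    stop("snapshot format version mismatch: found ",
         meta$version %||% "<none>", ", expected ", snapshot_format_version)
  g <- as.matrix(read.table(path, header = FALSE))
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  if (nrow(g) != meta$width || ncol(g) != meta$height)
    stop("snapshot grid dimensions do not match metadata")
  cells <- as.data.frame(meta$cells)
  structure(list(grid = g, cells = cells,
                 width = meta$width, height = meta$height,
                 mcs_elapsed = as.integer(meta$mcs_elapsed)),
            class = "lattice_state")
}

#' Export a phenotype-colored snapshot image
#'
#' Writes an 8-bit PNG of the lattice for visual inspection: medium
#' white, normal cells light, senescent cells dark, cell boundaries
#' black.
#'
#' @param state a [lattice_state()].
#' @param path PNG path.
#' @export
snapshot_image <- function(state, path) {
  pcode <- phenotype_code(state$cells$phenotype)
  lut <- c(1, 0.8, 0.45)  # medium, normal, senescent gray levels
  g <- state$grid
  img <- matrix(lut[1], state$width, state$height)
  for (c in seq_len(nrow(state$cells))) img[g == c] <- lut[pcode[c] + 1]
  sh <- function(m, dx, dy)
    m[(seq_len(nrow(m)) - 1 - dx) %% nrow(m) + 1,
      (seq_len(ncol(m)) - 1 - dy) %% ncol(m) + 1, drop = FALSE]
  img[g != sh(g, 1, 0) | g != sh(g, 0, 1)] <- 0
  grDevices::png(path, width = state$width, height = state$height)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::image(seq_len(state$width), seq_len(state$height), img,
                  col = grDevices::gray.colors(256, 0, 1), useRaster = TRUE,
                  axes = FALSE, xlab = "", ylab = "")
  invisible(path)
}

#' Write a run manifest
#'
#' Records, as JSON, everything needed to regenerate a set of outputs:
#' a configuration snapshot, the seeds used, wall-clock start/end, and
#' an inventory of the output files with MD5 checksums.  Written
#' atomically (temp file then rename).
#'
#' @param path manifest path (JSON).
#' @param config named list describing the run configuration.
#' @param seeds seeds used.
#' @param files character vector of produced files.
#' @param started POSIXct start time.
#' @return invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, config, seeds, files,
                               started = Sys.time()) {
  files <- files[file.exists(files)]
  man <- list(version = "senCPM-manifest-1",
              config = config, seeds = seeds,
              started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
              finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              files = data.frame(path = files,
                                 md5 = unname(tools::md5sum(files)),
                                 stringsAsFactors = FALSE))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  file.rename(tmp, path)
  invisible(man)
}
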