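# Serialization: VTK legacy structured-points output (interoperable ASCII),
# RDS checkpoints (bit-exact native round trip), CSV diagnostics, and the
# run manifest.

#' Write simulation fields to disk
#'
#' `"vtk"` writes a legacy ASCII STRUCTURED_POINTS file holding `phi`, `p`
#' (scalars), `u` (vector), and the deformation tensor components; 2D
#' states are written as z-degenerate grids.  `"rds"` writes the native
#' checkpoint (bit-exact round trip via [read_fields()]).
#' @param state `tf_state`.
#' @param path output file path.
#' @param format `"vtk"` or `"rds"`.
#' @export
write_fields <- function(state, path, format = c("vtk", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(state, path)
    return(invisible(path))
  }
  g <- state$grid
  nd <- g$ndim
  n3 <- c(g$n, 1L)[1:3]
  h3 <- c(g$h, g$h[1])[1:3]
  o3 <- c(g$origin, 0)[1:3]
  npts <- prod(n3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "thromboflow fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n3[1], n3[2], n3[3]),
               sprintf("ORIGIN %g %g %g", o3[1], o3[2], o3[3]),
               sprintf("SPACING %g %g %g", h3[1], h3[2], h3[3]),
               sprintf("POINT_DATA %d", npts)), con)
  wscal <- function(name, a) {
    writeLines(c(sprintf("SCALARS %s double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(a), digits = 17), con)
  }
  wscal("phi", state$phi)
  wscal("p", state$p)
  writeLines("VECTORS u double", con)
  uu <- cbind(as.vector(state$u[[1]]), as.vector(state$u[[2]]),
              if (nd == 3L) as.vector(state$u[[3]]) else 0)
  writeLines(paste(format(uu[, 1], digits = 17),
                   format(uu[, 2], digits = 17),
                   format(uu[, 3], digits = 17)), con)
  F <- state_deformation(state)
  for (nm in names(F)) wscal(nm, F[[nm]])
  invisible(path)
}

#' Read fields written by [write_fields()]
#' @param path file path.
#' @param format `"vtk"` or `"rds"` (guessed from the extension).
#' @return for RDS, the `tf_state`; for VTK, a list with `dims`, `origin`,
#'   `spacing`, and the named field arrays.
#' @export
read_fields <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "vtk"
  if (format == "rds") return(readRDS(path))
  lines <- readLines(path)
  if (lines[1] != "# vtk DataFile Version 3.0" ||
      lines[3] != "ASCII" || lines[4] != "DATASET STRUCTURED_POINTS")
    stop("not a legacy ASCII VTK structured-points file")
  dims <- as.integer(strsplit(lines[5], " ")[[1]][-1])
  origin <- as.numeric(strsplit(lines[6], " ")[[1]][-1])
  spacing <- as.numeric(strsplit(lines[7], " ")[[1]][-1])
  npts <- prod(dims)
  out <- list(dims = dims, origin = origin, spacing = spacing)
  i <- 9
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^SCALARS ", ln)) {
      nm <- strsplit(ln, " ")[[1]][2]
      vals <- as.numeric(lines[(i + 2):(i + 1 + npts)])
      out[[nm]] <- array(vals, dim = dims[dims > 1])
      i <- i + 2 + npts
    } else if (grepl("^VECTORS ", ln)) {
      nm <- strsplit(ln, " ")[[1]][2]
      mat <- do.call(rbind, lapply(strsplit(trimws(lines[(i + 1):(i + npts)]),
                                            " +"), as.numeric))
      out[[nm]] <- lapply(1:3, function(d) array(mat[, d], dim = dims[dims > 1]))
      i <- i + 1 + npts
    } else i <- i + 1
  }
  out
}

#' Write a platelet ensemble as CSV (and optionally a VTK point cloud)
#' @param ensemble `PlateletEnsemble`.
#' @param path CSV path.
#' @param vtk optional VTK polydata path.
#' @export
write_ensemble <- function(ensemble, path, vtk = NULL) {
  utils::write.csv(ensemble[, c("id", "x", "y", "z", "radius", "state")],
                   path, row.names = FALSE)
  if (!is.null(vtk)) {
    con <- file(vtk, "w"); on.exit(close(con))
    n <- nrow(ensemble)
    writeLines(c("# vtk DataFile Version 3.0", "platelets", "ASCII",
                 "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
    writeLines(paste(ensemble$x, ensemble$y, ensemble$z), con)
    writeLines(c(sprintf("POINT_DATA %d", n), "SCALARS radius double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(format(ensemble$radius), con)
  }
  invisible(path)
}

#' Run manifest
#'
#' Provenance record written next to every CLI run: config hash, seed,
#' package version, wall times, emitted files, and a diagnostics summary.
#' @param config plain-value config list.
#' @param seed integer seed.
#' @param files character vector of emitted files.
#' @param summary named list of summary numbers.
#' @param started,finished POSIXct wall times.
#' @export
run_manifest <- function(config, seed, files = character(),
                         summary = list(), started = Sys.time(),
                         finished = Sys.time()) {
  list(config_hash = config_hash(config), seed = seed,
       package_version = as.character(utils::packageVersion("thromboflow")),
       started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
       finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
       files = as.list(files), summary = summary)
}

#' Deterministic hash of a config list
#' @param config list of plain values.
#' @export
config_hash <- function(config) {
  ser <- serialize(config[order(names(config))], NULL, version = 2)
  # djb2-style rolling hash over the serialized payload; the modulus keeps
  # every intermediate below 2^53 so double arithmetic stays exact
  h <- 5381
  for (b in as.integer(ser)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a manifest as JSON
#' @param manifest from [run_manifest()].
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
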