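## File formats: cross-section TSV, long-format profile TSV, multi-frame
## TIFF with a YAML sidecar, and the YAML run configuration.
## Units on disk are fixed: depth cm, energy MeV, time s, sigma mbarn.

#' Write a cross-section table as TSV
#'
#' Tab-separated columns (energy, denergy, sigma, dsigma) with provenance
#' comment headers (isotope, config hash, stage).
#'
#' @param x a \linkS4class{CrossSectionTable}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeXsecTable <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# isotope: ", x@isotope), con)
  for (key in intersect(c("configHash", "seed", "stage"), names(x@meta)))
    writeLines(paste0("# ", key, ": ", x@meta[[key]]), con)
  writeLines(paste(c("energy", "denergy", "sigma", "dsigma"),
                   collapse = "\t"), con)
  write.table(format(x@table, digits = 10, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cross-section table from TSV
#'
#' Expects the header (energy, denergy, sigma, dsigma); comment lines
#' starting with '#' carry provenance.  Malformed rows are rejected with
#' their line numbers; non-monotone energies are an error.
#'
#' @param path file to read.
#' @param isotope isotope label; taken from the '# isotope:' header when
#'   omitted.
#' @return A \linkS4class{CrossSectionTable}.
#' @export
readXsecTable <- function(path, isotope = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty cross-section table file: ", path)
  comments <- grep("^#", lines, value = TRUE)
  if (is.null(isotope)) {
    m <- regmatches(comments, regexec("^# isotope:\\s*(\\S+)", comments))
    hits <- vapply(m, length, 0L) == 2
    isotope <- if (any(hits)) m[[which(hits)[1]]][2] else "unknown"
  }
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body)) stop("empty cross-section table file: ", path)
  header <- strsplit(lines[body[1]], "\t")[[1]]
  need <- c("energy", "denergy", "sigma", "dsigma")
  if (!identical(header, need))
    stop("expected header ", paste(need, collapse = "\t"), " in ", path)
  rows <- body[-1]
  if (!length(rows)) stop("cross-section table has no data rows: ", path)
  parsed <- strsplit(lines[rows], "\t")
  bad <- which(vapply(parsed, function(p)
    length(p) != 4 || anyNA(suppressWarnings(as.numeric(p))), TRUE))
  if (length(bad))
    stop("malformed rows in ", path, " at line(s): ",
         paste(rows[bad], collapse = ", "))
  m <- do.call(rbind, lapply(parsed, as.numeric))
  if (any(diff(m[, 1]) <= 0))
    stop("energies must be strictly increasing in ", path)
  crossSectionTable(isotope, m[, 1], m[, 3], m[, 2], m[, 4],
                    meta = list(source = path))
}

#' Write a cross-section table as an EXFOR-like CSV
#'
#' Columns EN, EN-ERR, DATA, DATA-ERR (MeV, mbarn) with REACTION/ISOTOPE
#' comment headers, for exchange with nuclear-data tooling.
#'
#' @param x a \linkS4class{CrossSectionTable}.
#' @param path output file.
#' @param target target nuclide in the reaction string.
#' @return \code{path}, invisibly.
#' @export
writeExforCsv <- function(x, path, target = "8-O-16") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# REACTION: ", target, "(P,X)", x@isotope),
               "# UNITS: EN MeV, DATA mbarn",
               "EN,EN-ERR,DATA,DATA-ERR"), con)
  tb <- x@table
  writeLines(sprintf("%.6g,%.6g,%.6g,%.6g", tb$energy, tb$denergy,
                     tb$sigma, tb$dsigma), con)
  invisible(path)
}

#' Write a depth-profile series as long-format TSV
#'
#' Columns: depth, time, exposure, intensity, variance, mask.
#'
#' @param series a \linkS4class{DepthProfileSeries}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDepthProfileSeries <- function(series, path) {
  depth <- profileDepth(series)
  tt <- frameTimes(series)
  long <- data.frame(
    depth = rep(depth, times = length(tt)),
    time = rep(tt, each = length(depth)),
    exposure = rep(frameExposures(series), each = length(depth)),
    intensity = as.vector(intensityMatrix(series)),
    variance = as.vector(varianceMatrix(series)),
    mask = rep(depthMask(series), times = length(tt)))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- S4Vectors::metadata(series)
  for (key in intersect(c("configHash", "seed", "stage"), names(meta)))
    writeLines(paste0("# ", key, ": ", meta[[key]]), con)
  write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a depth-profile series from long-format TSV
#'
#' @param path file produced by \code{\link{writeDepthProfileSeries}}.
#' @return A \linkS4class{DepthProfileSeries}.
#' @export
readDepthProfileSeries <- function(path) {
  long <- read.delim(path, comment.char = "#")
  need <- c("depth", "time", "exposure", "intensity", "variance", "mask")
  if (!all(need %in% colnames(long)))
    stop("expected columns ", paste(need, collapse = ", "), " in ", path)
  depth <- sort(unique(long$depth))
  tt <- sort(unique(long$time))
  long <- long[order(long$time, long$depth), ]
  nz <- length(depth); nt <- length(tt)
  if (nrow(long) != nz * nt)
    stop("incomplete depth x time grid in ", path)
  depthProfileSeries(
    matrix(long$intensity, nz, nt),
    matrix(long$variance, nz, nt),
    depth, tt,
    exposure = long$exposure[match(tt, long$time)],
    mask = as.logical(long$mask[seq_len(nz)]),
    meta = list(source = path))
}

#' Write a Cherenkov stack as multi-frame TIFF plus sidecar
#'
#' 16-bit grayscale multi-frame TIFF (counts clipped to [0, 65535]) and a
#' YAML sidecar (same path with extension .yaml) holding the frame times,
#' exposure, pixel pitch and provenance (seed, config hash).
#'
#' @param stack a \linkS4class{CherenkovStack}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeCherenkovStack <- function(stack, path) {
  maxCount <- 65535
  frames <- lapply(seq_len(nFrames(stack)), function(i)
    pmin(pmax(stack@frames[, , i], 0), maxCount) / maxCount)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  side <- c(list(frameTimes = stack@frameTimes,
                 exposure = stack@exposure,
                 pixelPitch = stack@pixelPitch,
                 maxCount = maxCount),
            stack@meta)
  yaml::write_yaml(side, sub("\\.tiff?$", ".yaml", path))
  invisible(path)
}

#' Read a Cherenkov stack from TIFF plus sidecar
#'
#' @param path TIFF written by \code{\link{writeCherenkovStack}}.
#' @return A \linkS4class{CherenkovStack} in counts.
#' @export
readCherenkovStack <- function(path) {
  sidePath <- sub("\\.tiff?$", ".yaml", path)
  if (!file.exists(sidePath)) stop("missing sidecar: ", sidePath)
  side <- yaml::read_yaml(sidePath)
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(frames[[1]]), length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]] * side$maxCount
  meta <- side[setdiff(names(side),
                       c("frameTimes", "exposure", "pixelPitch",
                         "maxCount"))]
  .cherenkovStack(arr, as.numeric(side$frameTimes),
                  as.numeric(side$exposure), side$pixelPitch, meta = meta)
}

#' Write a forward profile as TSV
#'
#' Columns: depth, raw, smeared, sigma; window in a comment header.
#'
#' @param profile a \linkS4class{ForwardProfile}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeForwardProfile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# window_s: ", profile@window[1], " ",
                    profile@window[2]), con)
  df <- data.frame(depth = profile@depth, raw = profile@raw,
                   smeared = profile@smeared,
                   sigma = if (length(profile@sigma)) profile@sigma else 0)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a forward profile from TSV
#' @param path file produced by \code{\link{writeForwardProfile}}.
#' @return A \linkS4class{ForwardProfile}.
#' @export
readForwardProfile <- function(path) {
  lines <- readLines(path, n = 5)
  wl <- grep("^# window_s:", lines, value = TRUE)
  window <- if (length(wl))
    as.numeric(strsplit(sub("^# window_s:\\s*", "", wl[1]), " ")[[1]])
  else c(0, Inf)
  df <- read.delim(path, comment.char = "#")
  new("ForwardProfile", depth = df$depth, window = window, raw = df$raw,
      smeared = df$smeared, sigma = df$sigma,
      perIsotope = matrix(numeric(0), length(df$depth), 0))
}
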