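## Minimal STAR table I/O: a single data_ block containing one loop_ with
## RELION-style _rln column tags. Sufficient for particle metadata and the
## fitted-track / polished-output tables this package exchanges.

#' Read a STAR data loop as a data frame
#'
#' @param path path to a STAR file with one `data_` block and one `loop_`.
#' @return a data.frame with one column per `_tag`, character columns
#'   converted to numeric where possible.
#' @export
readStarTable <- function(path) {
  if (!file.exists(path)) stop("STAR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  loopAt <- which(lines == "loop_")
  if (length(loopAt) == 0L) stop("no loop_ found in STAR file ", path)
  body <- lines[(loopAt[1] + 1L):length(lines)]
  isTag <- startsWith(body, "_")
  nTags <- match(FALSE, isTag) - 1L
  if (is.na(nTags) || nTags == 0L) stop("no columns or no rows in STAR loop of ", path)
  tags <- sub("\\s+#\\d+$", "", body[seq_len(nTags)])
  rows <- body[(nTags + 1L):length(body)]
  rows <- rows[!startsWith(rows, "data_")]
  fields <- strsplit(rows, "\\s+")
  bad <- which(lengths(fields) != nTags)
  if (length(bad))
    stop("STAR row ", bad[1], " has ", lengths(fields)[bad[1]],
         " fields, expected ", nTags, " in ", path)
  out <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(out) <- tags
  for (j in seq_along(out)) {
    num <- suppressWarnings(as.numeric(out[[j]]))
    if (!anyNA(num)) out[[j]] <- num
  }
  out
}

#' Write a data frame as a STAR loop
#'
#' @param df data.frame; column names are used as STAR tags (prefix them
#'   with `_`, e.g. `_rlnCoordinateX`, or bare names are prefixed
#'   automatically).
#' @param path output path.
#' @param blockName name of the `data_` block.
#' @return the path, invisibly.
#' @export
writeStarTable <- function(df, path, blockName = "particles") {
  tags <- ifelse(startsWith(names(df), "_"), names(df), paste0("_", names(df)))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("", paste0("data_", blockName), "", "loop_",
               paste0(tags, " #", seq_along(tags))), con)
  cols <- lapply(df, function(x) {
    if (is.numeric(x)) format(x, digits = 15, trim = TRUE, scientific = FALSE)
    else as.character(x)
  })
  writeLines(do.call(paste, cols), con)
  invisible(path)
}

.requiredParticleCols <- c("_rlnMicrographName", "_rlnCoordinateX",
                           "_rlnCoordinateY", "_rlnImageName")

#' Read a particle metadata table
#'
#' Expects a STAR loop with micrograph name, X/Y coordinates (pixels,
#' 0-based, origin at the first stored pixel) and a particle image
#' reference. The image reference is the path of the per-particle movie
#' stack, optionally prefixed `index@` (RELION style); the movie frame count
#' F is inferred from the referenced stack's header.
#'
#' @param path path to the STAR file.
#' @param checkStacks logical; verify referenced stacks exist and read their
#'   frame counts (default TRUE).
#' @return a data.frame with columns micrographName, coordX, coordY,
#'   imageName, imageIndex and (when `checkStacks`) nFrames, one row per
#'   particle, in file order.
#' @export
readParticleTable <- function(path, checkStacks = TRUE) {
  tab <- readStarTable(path)
  missing <- setdiff(.requiredParticleCols, names(tab))
  if (length(missing))
    stop("particle table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  ref <- as.character(tab[["_rlnImageName"]])
  hasIdx <- grepl("@", ref, fixed = TRUE)
  idx <- rep(NA_integer_, length(ref))
  idx[hasIdx] <- as.integer(sub("@.*$", "", ref[hasIdx]))
  stackPath <- sub("^.*@", "", ref)
  out <- data.frame(
    micrographName = as.character(tab[["_rlnMicrographName"]]),
    coordX = as.numeric(tab[["_rlnCoordinateX"]]),
    coordY = as.numeric(tab[["_rlnCoordinateY"]]),
    imageName = stackPath, imageIndex = idx,
    stringsAsFactors = FALSE)
  if (checkStacks) {
    dir <- dirname(path)
    resolved <- ifelse(file.exists(out$imageName),
                       out$imageName, file.path(dir, out$imageName))
    gone <- !file.exists(resolved)
    if (any(gone))
      stop("particle table references missing image stack: ",
           out$imageName[which(gone)[1]])
    depths <- vapply(unique(resolved), stackDepth, integer(1))
    out$nFrames <- depths[match(resolved, unique(resolved))]
  }
  out
}

#' Write a particle metadata table
#'
#' Inverse of [readParticleTable()]; extra columns (fitted track parameters,
#' polished image references) are written as additional tags.
#'
#' @param df data.frame with columns micrographName, coordX, coordY,
#'   imageName (and optionally more).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeParticleTable <- function(df, path) {
  out <- data.frame(
    `_rlnMicrographName` = df$micrographName,
    `_rlnCoordinateX` = df$coordX,
    `_rlnCoordinateY` = df$coordY,
    `_rlnImageName` = df$imageName,
    check.names = FALSE, stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c("micrographName", "coordX", "coordY",
                                "imageName", "imageIndex", "nFrames"))
  renames <- c(alphaX = "_cpTrackAlphaX", betaX = "_cpTrackBetaX",
               alphaY = "_cpTrackAlphaY", betaY = "_cpTrackBetaY",
               polishedImageName = "_cpPolishedImageName")
  for (col in extra) {
    tag <- if (col %in% names(renames)) renames[[col]] else paste0("_", col)
    out[[tag]] <- df[[col]]
  }
  writeStarTable(out, path)
}
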