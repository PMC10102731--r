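#' Controller JSON serialization
#'
#' The JSON object carries `memory_size` and a `table` keyed by `"m,s"`
#' (0-based memory, direction name) with `"m',action"` values, plus
#' optional metadata (`seed`, `utility`, `config_hash`).
#'
#' @param ctrl a [controller()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @param meta optional named list of metadata to embed.
#' @export
controller_to_json <- function(ctrl, path = NULL, meta = NULL) {
  dirs <- directions()
  tab <- list()
  for (m in seq_len(ctrl$memory_size)) for (s in 1:4) {
    tab[[sprintf("%d,%s", m - 1L, dirs[s])]] <-
      sprintf("%d,%s", ctrl$mnext[m, s] - 1L, dirs[ctrl$act[m, s]])
  }
  obj <- c(list(memory_size = ctrl$memory_size, table = tab), meta)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path); invisible(path)
}

#' @rdname controller_to_json
#' @param json JSON string or file path.
#' @export
controller_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  M <- as.integer(obj$memory_size)
  dirs <- directions()
  mnext <- matrix(0L, M, 4); act <- matrix(0L, M, 4)
  for (key in names(obj$table)) {
    ks <- strsplit(key, ",", fixed = TRUE)[[1]]
    vs <- strsplit(obj$table[[key]], ",", fixed = TRUE)[[1]]
    m <- as.integer(ks[1]) + 1L
    s <- match(ks[2], dirs)
    mnext[m, s] <- as.integer(vs[1]) + 1L
    act[m, s] <- match(vs[2], dirs)
  }
  controller(M, mnext, act)
}

#' Concept JSON serialization
#'
#' Carries cells (x, y lists), prior, symbol labels and the conditional
#' table flattened row-major (per cell, over symbols).
#'
#' @param cpt a [concept()].
#' @param path optional file path.
#' @param meta optional named list of metadata.
#' @export
concept_to_json <- function(cpt, path = NULL, meta = NULL) {
  obj <- c(list(cells = list(x = cpt$cells[, 1], y = cpt$cells[, 2]),
                prior = cpt$prior,
                symbols = cpt$symbols,
                conditional = as.vector(t(cpt$cond))), meta)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path); invisible(path)
}

#' @rdname concept_to_json
#' @param json JSON string or file path.
#' @export
concept_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  cells <- cbind(obj$cells$x, obj$cells$y)
  K <- length(obj$symbols)
  concept(cells, obj$prior,
          matrix(obj$conditional, nrow(cells), K, byrow = TRUE),
          symbols = as.character(obj$symbols))
}

#' Common-concept JSON serialization
#' @param cc a common concept (see [common_concept]).
#' @param path optional file path.
#' @param meta optional named list of metadata.
#' @export
common_concept_to_json <- function(cc, path = NULL, meta = NULL) {
  obj <- c(list(kind = cc$kind, mapping = cc$mapping, score = cc$score,
                alpha = cc$alpha, seed = cc$seed,
                concept = jsonlite::fromJSON(concept_to_json(cc$concept))),
           meta)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path); invisible(path)
}

#' @rdname common_concept_to_json
#' @param json JSON string or file path.
#' @export
common_concept_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  cpt <- concept_from_json(jsonlite::toJSON(obj$concept, auto_unbox = TRUE,
                                            digits = NA))
  new_common_concept(obj$kind, as.integer(obj$mapping), cpt, obj$score,
                     alpha = obj$alpha, seed = obj$seed)
}

#' Export a symmetry spectrum as CSV
#'
#' RFC-4180 CSV with a header row: the operation parameters, the utility
#' in bits, and the normalized utility.
#'
#' @param spectrum a `symmetry_spectrum`.
#' @param path output file.
#' @export
spectrum_to_csv <- function(spectrum, path) {
  utils::write.csv(spectrum$entries, path, row.names = FALSE)
  invisible(path)
}

#' Render a concept as one greyscale image per symbol
#'
#' For each symbol y, writes a portable greymap (ASCII PGM) of
#' `p(r0 | y)` over the concept's rectangular support, normalized per
#' symbol: the per-symbol maximum is black, probability zero is white.
#' Symbols with zero marginal probability produce a blank image with a
#' warning.
#'
#' @param cpt a [concept()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param maxval PGM grey levels (default 255).
#' @return invisible character vector of the files written.
#' @export
render_concept <- function(cpt, dir, prefix = "symbol", maxval = 255L) {
  sup <- cpt$prior > 0
  cells <- cpt$cells[sup, , drop = FALSE]
  xs <- sort(unique(cells[, 1])); ys <- sort(unique(cells[, 2]))
  if (nrow(cells) != length(xs) * length(ys))
    stop("concept support must be a full rectangle to render")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  joint <- cpt$cond[sup, , drop = FALSE] * cpt$prior[sup]
  files <- character(0)
  for (k in seq_along(cpt$symbols)) {
    py <- sum(joint[, k])
    img <- matrix(0, length(ys), length(xs))
    if (py <= 1e-15) {
      warning("symbol ", cpt$symbols[k],
              " has zero probability; blank image")
    } else {
      post <- joint[, k] / py                     # p(r0 | y)
      ix <- match(cells[, 1], xs)
      iy <- match(cells[, 2], ys)
      img[cbind(iy, ix)] <- post / max(post)      # per-symbol normalization
    }
    # top row of the image = northernmost y; black = per-symbol max
    grey <- round((1 - img[rev(seq_along(ys)), , drop = FALSE]) * maxval)
    f <- file.path(dir, sprintf("%s_%s.pgm", prefix, cpt$symbols[k]))
    lines <- c("P2",
               sprintf("# p(r0|y=%s), black = per-symbol max",
                       cpt$symbols[k]),
               sprintf("%d %d", length(xs), length(ys)),
               as.character(maxval),
               apply(grey, 1, paste, collapse = " "))
    writeLines(lines, f)
    files <- c(files, f)
  }
  invisible(files)
}

# small stable polynomial hash of a string, for config fingerprints
config_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
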