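# Annotated song library: metadata only (id, nominal BPM, optional beat grid).
# A song's beat grid holds beat times in seconds at nominal tempo; songs
# without a grid are isochronous at 60/bpm for duration_s seconds.

#' Build a song library tibble
#'
#' @param song_id Character vector of unique song identifiers.
#' @param bpm Positive nominal tempi, beats per minute.
#' @param beat_grid Optional list column of strictly increasing beat-time
#'   vectors (seconds, at nominal tempo); `NULL` entries mean an isochronous
#'   grid at `60 / bpm` over `duration_s` is implied.
#' @param duration_s Song duration in seconds at nominal tempo (default 120,
#'   a two-minute excerpt); ignored for songs with an explicit grid, whose
#'   duration is the grid's last beat.
#' @return A tibble of class `song_library` with columns `song_id`, `bpm`,
#'   `duration_s`, `beat_grid` (list column).
#' @export
song_library <- function(song_id, bpm, beat_grid = NULL, duration_s = 120) {
  song_id <- as.character(song_id)
  if (anyDuplicated(song_id)) {
    abort("duplicate song_id in library", class = "gaitsync_format")
  }
  if (any(!is.finite(bpm) | bpm <= 0)) {
    bad <- which(!is.finite(bpm) | bpm <= 0)
    abort(sprintf("non-positive bpm in library row(s) %s",
                  paste(bad, collapse = ", ")),
          class = "gaitsync_format")
  }
  if (is.null(beat_grid)) beat_grid <- vector("list", length(song_id))
  for (i in seq_along(beat_grid)) {
    g <- beat_grid[[i]]
    if (!is.null(g) && (length(g) < 2 || is.unsorted(g, strictly = TRUE))) {
      abort(sprintf("beat grid of song '%s' must be strictly increasing with >= 2 beats",
                    song_id[i]),
            class = "gaitsync_format")
    }
  }
  out <- tibble::tibble(
    song_id = song_id,
    bpm = as.numeric(bpm),
    duration_s = rep_len(as.numeric(duration_s), length(song_id)),
    beat_grid = beat_grid
  )
  class(out) <- c("song_library", class(out))
  out
}

#' Load a song library from CSV or JSON
#'
#' The CSV dialect has columns `song_id,bpm` and optionally `duration_s` and
#' `grid_file` (a sidecar text file, one beat timestamp per line, resolved
#' relative to the CSV). The JSON dialect is an array of objects with keys
#' `song_id`, `bpm`, optional `duration_s` and embedded `beat_grid` arrays.
#' Malformed rows are reported with their row number.
#'
#' @param path Path to a `.csv` or `.json` library file.
#' @return A `song_library` tibble (possibly empty).
#' @seealso [write_library()] for the inverse; round-trips are bit-exact on
#'   `song_id`, `bpm` and `beat_grid`.
#' @examples
#' lib <- load_library(system.file("extdata", "example_library.csv",
#'                                 package = "gaitsync"))
#' nearest_song(lib, target_spm = 117)
#' @export
load_library <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("library file not found: %s", path), class = "gaitsync_format")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    if (length(rows) == 0) return(song_library(character(), numeric()))
    grids <- purrr::map(rows, function(r) {
      if (is.null(r$beat_grid)) NULL else as.numeric(unlist(r$beat_grid))
    })
    return(song_library(
      song_id = purrr::map_chr(rows, function(r) as.character(r$song_id)),
      bpm = purrr::map_dbl(rows, function(r) as.numeric(r$bpm)),
      beat_grid = grids,
      duration_s = purrr::map_dbl(rows, function(r) {
        if (is.null(r$duration_s)) 120 else as.numeric(r$duration_s)
      })
    ))
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) return(song_library(character(), numeric()))
  if (!all(c("song_id", "bpm") %in% names(df))) {
    abort("library CSV needs song_id and bpm columns", class = "gaitsync_format")
  }
  bpm <- suppressWarnings(as.numeric(df$bpm))
  if (any(is.na(bpm) | bpm <= 0)) {
    bad <- which(is.na(bpm) | bpm <= 0)
    abort(sprintf("invalid bpm in library row(s) %s of %s",
                  paste(bad, collapse = ", "), path),
          class = "gaitsync_format")
  }
  grids <- vector("list", nrow(df))
  if ("grid_file" %in% names(df)) {
    base <- dirname(path)
    for (i in seq_len(nrow(df))) {
      gf <- df$grid_file[i]
      if (!is.na(gf) && nzchar(gf)) {
        gpath <- file.path(base, gf)
        if (!file.exists(gpath)) {
          abort(sprintf("grid file missing for row %d: %s", i, gpath),
                class = "gaitsync_format")
        }
        grids[[i]] <- as.numeric(readLines(gpath))
      }
    }
  }
  dur <- if ("duration_s" %in% names(df)) as.numeric(df$duration_s) else 120
  dur[is.na(dur)] <- 120
  song_library(df$song_id, bpm, beat_grid = grids, duration_s = dur)
}

#' Write a song library
#'
#' CSV libraries get one sidecar `<song_id>.grid` file per song with an
#' explicit beat grid; JSON libraries embed the grids.
#'
#' @param library A `song_library` tibble.
#' @param path Destination `.csv` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- purrr::pmap(library, function(song_id, bpm, duration_s, beat_grid) {
      r <- list(song_id = song_id, bpm = bpm, duration_s = duration_s)
      if (!is.null(beat_grid)) r$beat_grid <- beat_grid
      r
    })
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  base <- dirname(path)
  grid_file <- purrr::map2_chr(library$song_id, library$beat_grid, function(id, g) {
    if (is.null(g)) return("")
    gf <- paste0(id, ".grid")
    writeLines(format(g, digits = 17, scientific = FALSE, trim = TRUE),
               file.path(base, gf))
    gf
  })
  out <- tibble::tibble(song_id = library$song_id,
                        bpm = library$bpm,
                        duration_s = library$duration_s,
                        grid_file = grid_file)
  readr::write_csv(out, path)
  invisible(path)
}

#' Generate a synthetic annotated library
#'
#' Isochronous songs with tempi evenly covering a BPM range, emulating the
#' tempo-annotated pop selections used with adaptive players (several songs
#' available for any walking cadence).
#'
#' @param n_songs Number of songs.
#' @param bpm_range Length-2 numeric, inclusive tempo range (default
#'   `c(80, 140)`, the typical walking range).
#' @param duration_s Duration of each song in seconds (default 120).
#' @return A `song_library` tibble.
#' @export
synthetic_library <- function(n_songs = 30, bpm_range = c(80, 140),
                              duration_s = 120) {
  bpm <- seq(bpm_range[1], bpm_range[2], length.out = n_songs)
  song_library(sprintf("song%03d", seq_len(n_songs)), bpm,
               duration_s = duration_s)
}

#' Select the song whose tempo is nearest a target cadence
#'
#' Minimises `|bpm - target_spm|` over the library after exclusions. Ties are
#' broken deterministically by lexicographically smallest `song_id`, so
#' experiments replay identically.
#'
#' @param library A `song_library` tibble.
#' @param target_spm Target cadence in steps per minute.
#' @param exclude Character vector of `song_id`s to exclude (e.g. songs
#'   already played).
#' @return A one-row `song_library` tibble.
#' @export
nearest_song <- function(library, target_spm, exclude = character()) {
  cand <- library[!(library$song_id %in% exclude), , drop = FALSE]
  if (nrow(cand) == 0) {
    abort("no candidate songs after exclusions", class = "gaitsync_selection")
  }
  d <- abs(cand$bpm - target_spm)
  best <- which(d == min(d))
  if (length(best) > 1) {
    best <- best[order(cand$song_id[best])][1]
  }
  cand[best, , drop = FALSE]
}

# nominal inter-beat intervals of a song (seconds at nominal tempo)
song_intervals <- function(song_row) {
  g <- song_row$beat_grid[[1]]
  if (is.null(g)) {
    ibi <- 60 / song_row$bpm
    n_beats <- max(2L, floor(song_row$duration_s / ibi) + 1L)
    list(first_offset = 0, intervals = rep(ibi, n_beats - 1L))
  } else {
    list(first_offset = g[1], intervals = diff(g))
  }
}
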