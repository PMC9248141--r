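#' Read a multi-specimen 3D landmark dataset
#'
#' Supported dialects:
#' * `tps` — blocks of `LM3=K`, one `x y z` line per landmark, `ID=` per
#'   specimen. Missing landmarks may be coded as `NA NA NA`, blank fields, or
#'   the `9999 9999 9999` sentinel triple.
#' * `nts` — plain-matrix dialect: an optional leading comment line(s)
#'   starting with `"`, a header `1 N 3K <missing-flag> [sentinel] DIM=3`,
#'   then one row of 3K numbers per specimen.
#' * `csv` — long form with columns `specimen_id, species, landmark_id, x, y,
#'   z` (missing coded as empty/`NA`).
#'
#' @param path file to read.
#' @param format one of `"tps"`, `"nts"`, `"csv"`. Guessed from the file
#'   extension when omitted.
#' @param species_filter optional species name; `csv` files may carry several
#'   species, the other formats one.
#' @param ... passed to [landmark_dataset()] (e.g. `bilateral_pairs`).
#' @return a [landmark_dataset()].
#' @export
read_landmarks <- function(path, format = c("tps", "nts", "csv"),
                           species_filter = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tps = "tps", nts = "nts", csv = "csv",
                     stop("cannot guess landmark format from extension: ",
                          path))
  }
  format <- match.arg(format)
  switch(format,
         tps = read_landmarks_tps(path, species_filter, ...),
         nts = read_landmarks_nts(path, species_filter, ...),
         csv = read_landmarks_csv(path, species_filter, ...))
}

MISSING_SENTINEL <- 9999

parse_coord_row <- function(fields, path, line_no) {
  fields[fields %in% c("", "NA", "NaN", "na")] <- NA_character_
  vals <- suppressWarnings(as.numeric(fields))
  bad <- !is.na(fields) & is.na(vals)
  if (any(bad))
    stop(sprintf("parse error in %s line %d: non-numeric field '%s'",
                 path, line_no, fields[bad][1]))
  vals[!is.na(vals) & vals == MISSING_SENTINEL] <- NA_real_
  vals
}

read_landmarks_tps <- function(path, species_filter = NULL, ...) {
  lines <- readLines(path, warn = FALSE)
  specs <- list()
  ids <- character()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; next }
    m <- regmatches(ln, regexec("^LM3?\\s*=\\s*([0-9]+)$", ln,
                                ignore.case = TRUE))[[1]]
    if (length(m) == 0)
      stop(sprintf("parse error in %s line %d: expected LM3=K, got '%s'",
                   path, i, ln))
    k <- as.integer(m[2])
    if (i + k > length(lines))
      stop(sprintf("parse error in %s line %d: truncated block", path, i))
    block <- matrix(NA_real_, k, 3)
    for (j in seq_len(k)) {
      fields <- strsplit(trimws(lines[i + j]), "\\s+")[[1]]
      if (length(fields) != 3)
        stop(sprintf("parse error in %s line %d: expected 3 coordinates",
                     path, i + j))
      block[j, ] <- parse_coord_row(fields, path, i + j)
    }
    i <- i + k + 1L
    id <- sprintf("spec_%03d", length(specs) + 1L)
    # trailing ID=/SCALE= lines belong to this block
    while (i <= length(lines) &&
           grepl("^(ID|IMAGE|SCALE)\\s*=", trimws(lines[i]),
                 ignore.case = TRUE)) {
      ln2 <- trimws(lines[i])
      if (grepl("^ID\\s*=", ln2, ignore.case = TRUE))
        id <- sub("^ID\\s*=\\s*", "", ln2, ignore.case = TRUE)
      i <- i + 1L
    }
    specs[[length(specs) + 1L]] <- block
    ids <- c(ids, id)
  }
  if (!length(specs)) stop("no landmark blocks found in ", path)
  ks <- vapply(specs, nrow, integer(1))
  if (length(unique(ks)) != 1)
    stop(sprintf("inconsistent landmark count across specimens in %s: %s",
                 path, paste(unique(ks), collapse = ", ")))
  coords <- array(NA_real_, c(ks[1], 3, length(specs)))
  for (s in seq_along(specs)) coords[, , s] <- specs[[s]]
  landmark_dataset(coords,
                   species = species_filter %||% "unknown",
                   specimen_ids = ids, ...)
}

read_landmarks_nts <- function(path, species_filter = NULL, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  body_start <- which(!startsWith(trimws(lines), "\""))[1]
  if (is.na(body_start)) stop("no header found in ", path)
  header <- strsplit(trimws(lines[body_start]), "\\s+")[[1]]
  if (length(header) < 4)
    stop(sprintf("parse error in %s line %d: bad NTS header", path,
                 body_start))
  n <- as.integer(header[2])
  p3 <- as.integer(header[3])
  if (is.na(n) || is.na(p3) || p3 %% 3 != 0)
    stop(sprintf("parse error in %s line %d: NTS header must give N and 3K",
                 path, body_start))
  k <- p3 %/% 3
  rows <- lines[(body_start + 1L):length(lines)]
  vals <- unlist(strsplit(trimws(paste(rows, collapse = " ")), "\\s+"))
  if (length(vals) != n * p3)
    stop(sprintf("structural error in %s: expected %d values, found %d",
                 path, n * p3, length(vals)))
  nums <- parse_coord_row(vals, path, body_start + 1L)
  coords <- array(NA_real_, c(k, 3, n))
  for (s in seq_len(n))
    coords[, , s] <- matrix(nums[((s - 1) * p3 + 1):(s * p3)], k, 3,
                            byrow = TRUE)
  landmark_dataset(coords, species = species_filter %||% "unknown", ...)
}

read_landmarks_csv <- function(path, species_filter = NULL, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "landmark_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("csv landmark file must have columns specimen_id, species, ",
         "landmark_id, x, y, z (", path, ")")
  if (!is.null(species_filter) && "species" %in% names(df))
    df <- df[df$species == species_filter, , drop = FALSE]
  if (!nrow(df)) stop("no rows in ", path,
                      if (!is.null(species_filter))
                        paste0(" for species ", species_filter) else "")
  species <- if ("species" %in% names(df)) unique(df$species) else "unknown"
  if (length(species) > 1)
    stop("csv contains several species (", paste(species, collapse = ", "),
         "); pass species_filter")
  ids <- unique(df$specimen_id)
  lm_ids <- sort(unique(as.integer(df$landmark_id)))
  k <- length(lm_ids)
  per_spec <- table(df$specimen_id)
  if (length(unique(per_spec)) != 1 || unique(per_spec) != k)
    stop("structural error in ", path,
         ": inconsistent landmark count across specimens")
  coords <- array(NA_real_, c(k, 3, length(ids)))
  row_l <- match(as.integer(df$landmark_id), lm_ids)
  row_s <- match(df$specimen_id, ids)
  for (d in 1:3) {
    v <- df[[c("x", "y", "z")[d]]]
    v <- suppressWarnings(as.numeric(v))
    v[!is.na(v) & v == MISSING_SENTINEL] <- NA_real_
    coords[cbind(row_l, d, row_s)] <- v
  }
  landmark_dataset(coords, species = species, specimen_ids = ids,
                   landmark_ids = lm_ids, ...)
}

#' Write a landmark dataset
#'
#' Round-trip contract: `read_landmarks(write_landmarks(d))` reproduces the
#' coordinates to at least 12 significant digits and identical missing masks.
#' Missing landmarks are emitted as `NA`.
#'
#' @param dataset a [landmark_dataset()].
#' @param path output file.
#' @param format `"tps"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(dataset, path, format = c("tps", "csv")) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (n_specimens(dataset) < 1) stop("refusing to write an empty dataset")
  format <- match.arg(format)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.15g", v))
  if (format == "tps") {
    k <- n_landmarks(dataset)
    out <- character()
    for (s in seq_len(n_specimens(dataset))) {
      m <- dataset$coords[, , s]
      out <- c(out, sprintf("LM3=%d", k),
               apply(m, 1, function(r) paste(fmt(r), collapse = " ")),
               sprintf("ID=%s", dataset$specimen_ids[s]))
    }
    writeLines(out, path)
  } else {
    n <- n_specimens(dataset)
    k <- n_landmarks(dataset)
    df <- data.frame(
      specimen_id = rep(dataset$specimen_ids, each = k),
      species = dataset$species,
      landmark_id = rep(dataset$landmark_ids, n),
      x = fmt(as.vector(dataset$coords[, 1, ])),
      y = fmt(as.vector(dataset$coords[, 2, ])),
      z = fmt(as.vector(dataset$coords[, 3, ])))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
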