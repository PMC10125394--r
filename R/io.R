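# Plain-text I/O: two-column CSV spectra, directory-of-CSV studies,
# spectral-grid directories, JSON models, NetPBM images.

#' Read / write a spectrum as two-column CSV
#'
#' Columns `wavenumber_cm-1, absorbance`. On read, JCAMP-DX-style header
#' comment lines (`##TITLE=...`) are tolerated and ignored.
#'
#' @param spectrum an [ir_spectrum()].
#' @param path file path.
#' @return `write_spectrum_csv` returns the path invisibly;
#'   `read_spectrum_csv` returns an [ir_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  df <- data.frame(`wavenumber_cm-1` = spectrum$grid$values,
                   absorbance = spectrum$absorbance, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        check.names = FALSE)
  nu <- df[[1]]
  step <- diff(nu)
  if (length(step) > 0 && max(abs(step - step[1])) > 1e-6) {
    stop("wavenumber column is not evenly spaced")
  }
  g <- wavenumber_grid(nu[1], nu[length(nu)] + 1e-9,
                       if (length(step) > 0) step[1] else 1)
  ir_spectrum(g, df[[2]])
}

#' Write / read a study as a directory of CSV spectra
#'
#' One subdirectory per slide record (`<tissue_id>_<replicate_id>/`)
#' holding `spectrum_###.csv` files and a `metadata.json` sidecar with
#' `tissue_id`, `replicate_id`, `fixation_time_h` and optional `ihc`.
#'
#' @param records list of [tissue_record()]s.
#' @param dir study directory.
#' @return `write_study` returns `dir` invisibly; `read_study` a list of
#'   [tissue_record()]s.
#' @export
write_study <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in records) {
    sub <- file.path(dir, paste0(rec$tissue_id, "_", rec$replicate_id))
    dir.create(sub, showWarnings = FALSE)
    for (i in seq_len(nrow(rec$spectra))) {
      write_spectrum_csv(ir_spectrum(rec$grid, rec$spectra[i, ]),
                         file.path(sub, sprintf("spectrum_%03d.csv", i)))
    }
    meta <- list(tissue_id = rec$tissue_id, replicate_id = rec$replicate_id,
                 fixation_time_h = rec$fixation_time)
    if (!is.null(rec$ihc)) meta$ihc <- as.list(rec$ihc)
    jsonlite::write_json(meta, file.path(sub, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  subs <- sort(list.dirs(dir, recursive = FALSE))
  if (length(subs) == 0) stop("no record directories found in ", dir)
  lapply(subs, function(sub) {
    meta <- jsonlite::read_json(file.path(sub, "metadata.json"),
                                simplifyVector = TRUE)
    files <- sort(list.files(sub, pattern = "^spectrum_.*\\.csv$",
                             full.names = TRUE))
    spectra <- lapply(files, read_spectrum_csv)
    grid <- spectra[[1]]$grid
    mat <- do.call(rbind, lapply(spectra, function(s) s$absorbance))
    ihc <- if (!is.null(meta$ihc)) unlist(meta$ihc) else NULL
    ft <- meta$fixation_time_h
    if (is.null(ft)) ft <- NA_real_
    tissue_record(meta$tissue_id, meta$replicate_id, ft, mat, grid, ihc)
  })
}

#' Write / read a spectral grid directory
#'
#' `grid.json` holds the shape and pixel pitch; per-pixel spectra are
#' stored as `r{row}_c{col}.csv` for tissue pixels only.
#'
#' @param grid a `spectral_grid`.
#' @param dir target directory.
#' @return `write_spectral_grid` returns `dir` invisibly;
#'   `read_spectral_grid` a `spectral_grid`.
#' @export
write_spectral_grid <- function(grid, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(list(shape = grid$shape, pixel_mm = grid$pixel_mm),
                       file.path(dir, "grid.json"), auto_unbox = FALSE,
                       digits = NA)
  idx <- which(grid$tissue_mask, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    write_spectrum_csv(ir_spectrum(grid$grid, grid$spectra[i, ]),
                       file.path(dir, sprintf("r%03d_c%03d.csv",
                                              idx[i, 1], idx[i, 2])))
  }
  invisible(dir)
}

#' @rdname write_spectral_grid
#' @export
read_spectral_grid <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "grid.json"),
                              simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  files <- list.files(dir, pattern = "^r[0-9]+_c[0-9]+\\.csv$")
  rr <- as.integer(sub("^r([0-9]+)_c([0-9]+)\\.csv$", "\\1", files))
  cc <- as.integer(sub("^r([0-9]+)_c([0-9]+)\\.csv$", "\\2", files))
  ord <- order((cc - 1L) * shape[1] + rr)  # column-major, matches which()
  files <- files[ord]; rr <- rr[ord]; cc <- cc[ord]
  mask <- matrix(FALSE, shape[1], shape[2])
  mask[cbind(rr, cc)] <- TRUE
  spectra_list <- lapply(file.path(dir, files), read_spectrum_csv)
  g <- spectra_list[[1]]$grid
  spectra <- do.call(rbind, lapply(spectra_list, function(s) s$absorbance))
  structure(list(shape = shape, pixel_mm = meta$pixel_mm,
                 tissue_mask = mask, t_eff = NULL, grid = g,
                 spectra = spectra),
            class = "spectral_grid")
}

#' Save / load a fitted fixation model as versioned JSON
#'
#' @param model a [fit_plsr()] model.
#' @param path JSON file path.
#' @param provenance optional list (seed, config digest, ...) stored
#'   verbatim.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   a `plsr_model`.
#' @export
write_model_json <- function(model, path, provenance = NULL) {
  payload <- list(
    format = "fixir-plsr", version = 1L,
    wavenumber = model$wavenumber,
    x_mean = model$x_mean, y_mean = model$y_mean,
    weights = model$weights, x_loadings = model$x_loadings,
    y_loadings = model$y_loadings, coefficients = model$coefficients,
    n_components = model$n_components,
    variance_explained = model$variance_explained,
    provenance = provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "fixir-plsr") {
    stop("not a fixir model file: ", path)
  }
  structure(list(x_mean = p$x_mean, y_mean = p$y_mean,
                 weights = as.matrix(p$weights),
                 x_loadings = as.matrix(p$x_loadings),
                 y_loadings = p$y_loadings,
                 coefficients = p$coefficients,
                 n_components = as.integer(p$n_components),
                 variance_explained = p$variance_explained,
                 wavenumber = p$wavenumber),
            class = "plsr_model")
}

#' Write / read NetPBM images (plain text)
#'
#' RGB arrays are written as plain PPM (P3); single-channel masks /
#' grayscale matrices as plain PGM (P2) with values scaled to 0-255.
#' Logical matrices round-trip as 0/255 masks.
#'
#' @param img RGB array (`rows x cols x 3`, values in `[0, 1]`), numeric
#'   matrix in `[0, 1]`, or logical matrix.
#' @param path output path (`.ppm` / `.pgm`).
#' @return `write_pnm` returns `path` invisibly; `read_pnm` an RGB array
#'   (P3) or numeric matrix in `[0, 1]` (P2).
#' @export
write_pnm <- function(img, path) {
  if (is.logical(img)) img <- matrix(as.numeric(img), nrow(img), ncol(img))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(dim(img)) == 3) {
    nr <- dim(img)[1]; nc <- dim(img)[2]
    writeLines(c("P3", paste(nc, nr), "255"), con)
    q <- round(pmin(pmax(img, 0), 1) * 255)  # pmax first: keeps dim()
    # interleave channels row by row
    flat <- matrix(0L, nrow = nc * 3, ncol = nr)
    for (ch in 1:3) flat[seq(ch, nc * 3, by = 3), ] <- t(q[, , ch])
    writeLines(apply(flat, 2, paste, collapse = " "), con)
  } else {
    nr <- nrow(img); nc <- ncol(img)
    writeLines(c("P2", paste(nc, nr), "255"), con)
    q <- round(pmin(pmax(img, 0), 1) * 255)
    writeLines(apply(t(q), 2, paste, collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_pnm
#' @export
read_pnm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  magic <- trimws(lines[1])
  tokens <- scan(text = paste(lines[-1], collapse = "\n"), what = numeric(),
                 quiet = TRUE)
  nc <- tokens[1]; nr <- tokens[2]; maxval <- tokens[3]
  px <- tokens[-(1:3)] / maxval
  if (magic == "P2") {
    matrix(px, nr, nc, byrow = TRUE)
  } else if (magic == "P3") {
    img <- array(0, dim = c(nr, nc, 3))
    for (ch in 1:3) {
      img[, , ch] <- matrix(px[seq(ch, length(px), by = 3)], nr, nc,
                            byrow = TRUE)
    }
    img
  } else {
    stop("unsupported NetPBM magic: ", magic)
  }
}
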