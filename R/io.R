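#' @name dib_io
#' @title Readers and writers for the three measurement formats
#'
#' @description
#' All on-disk formats are plain text with mandatory headers; leading
#' comment lines of the form `# key: value` carry metadata (osmolalities,
#' scan rate, composition).  Write-then-read round-trips are identity up to
#' floating-point formatting.
#'
#' * Shrinkage series CSV: columns `t_s, R1_um, R2_um, r_um`.
#' * Thermogram CSV: columns `T_C, heat_flow_mW`.
#' * Spectrum: two-column (wavenumber cm^-1, intensity), comma- or
#'   whitespace-delimited.
NULL

fmt_num <- function(x) sprintf("%.15g", x)

write_meta <- function(path, meta) {
  lines <- purrr::imap_chr(meta, function(v, k) sprintf("# %s: %s", k, v))
  readr::write_lines(lines, path)
}

read_meta <- function(path) {
  lines <- readr::read_lines(path)
  is_comment <- grepl("^\\s*#", lines)
  n_skip <- match(FALSE, is_comment) - 1L
  meta <- list()
  for (ln in lines[seq_len(n_skip)]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  list(meta = meta, n_skip = n_skip, n_lines = length(lines))
}

meta_num <- function(meta, key, default = NA_real_) {
  if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
}

#' Write a shrinkage series to CSV
#'
#' @param series A `shrinkage_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @rdname dib_io
#' @export
write_shrinkage_series <- function(series, path) {
  meta <- list(
    osmolality1_mOsm_kg = fmt_num(attr(series, "osmolality1")),
    osmolality2_mOsm_kg = fmt_num(attr(series, "osmolality2")),
    geometry_mode = attr(series, "geometry_mode") %||% "sphere")
  comp <- attr(series, "composition")
  if (!is.null(comp)) {
    meta$lipid <- comp$lipid
    meta$chol_ratio <- comp$chol_ratio
    meta$chi_asa <- fmt_num(comp$chi_asa)
    meta$pH <- fmt_num(comp$pH)
  }
  if (!is.null(attr(series, "seed"))) meta$seed <- attr(series, "seed")
  write_meta(path, meta)
  readr::write_csv(as_tibble(series)[c("t_s", "R1_um", "R2_um", "r_um")],
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a shrinkage series from CSV
#'
#' @rdname dib_io
#' @export
read_shrinkage_series <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("file not found: %s", path))
  info <- read_meta(path)
  dat <- readr::read_csv(path, skip = info$n_skip, show_col_types = FALSE,
                         comment = "")
  need <- c("t_s", "R1_um", "R2_um", "r_um")
  if (!all(need %in% names(dat))) {
    stop_domain(sprintf(
      "malformed header on line %d of %s: expected columns %s",
      info$n_skip + 1L, path, paste(need, collapse = ", ")))
  }
  line0 <- info$n_skip + 1L  # header line number
  bad_t <- which(diff(dat$t_s) <= 0)
  if (length(bad_t) > 0) {
    stop_domain(sprintf("non-increasing time axis at line %d of %s",
                        line0 + bad_t[1] + 1L, path))
  }
  bad_r <- which(dat$R1_um <= 0 | dat$R2_um <= 0 | dat$r_um < 0)
  if (length(bad_r) > 0) {
    stop_domain(sprintf("non-positive radius at line %d of %s",
                        line0 + bad_r[1], path))
  }
  m <- info$meta
  osm1 <- meta_num(m, "osmolality1_mOsm_kg")
  osm2 <- meta_num(m, "osmolality2_mOsm_kg")
  mode <- m$geometry_mode %||% "sphere"
  ser <- new_shrinkage_series(dat, osmolality1 = osm1, osmolality2 = osm2,
                              geometry_mode = mode)
  # reconstruct the initial state from the observations; with enough samples
  # a quadratic trend evaluated at t = 0 suppresses single-sample noise
  if (is.finite(osm1) && is.finite(osm2)) {
    R10 <- dat$R1_um[1]
    R20 <- dat$R2_um[1]
    if (nrow(dat) >= 10) {
      R10 <- unname(predict(lm(R1_um ~ t_s + I(t_s^2), data = dat),
                            tibble(t_s = dat$t_s[1])))
      R20 <- unname(predict(lm(R2_um ~ t_s + I(t_s^2), data = dat),
                            tibble(t_s = dat$t_s[1])))
    }
    V <- volumes_from_radii(R10, R20, dat$r_um[1], mode)
    attr(ser, "state0") <- droplet_pair_state(
      V$V1, V$V2, osm1, osm2, A = pi * dat$r_um[1]^2)
  }
  if (!is.null(m$lipid)) {
    attr(ser, "composition") <- list(
      lipid = m$lipid, chol_ratio = m$chol_ratio,
      chi_asa = meta_num(m, "chi_asa"), pH = meta_num(m, "pH"))
  }
  ser
}

#' Write a thermogram to CSV
#'
#' @param thermo A [thermogram()].
#' @rdname dib_io
#' @export
write_thermogram <- function(thermo, path) {
  meta <- list(scan_rate_C_min = fmt_num(attr(thermo, "scan_rate")),
               n_lipid_mol = fmt_num(attr(thermo, "n_lipid")))
  comp <- attr(thermo, "composition")
  if (!is.null(comp) && is.character(comp)) meta$composition <- comp
  write_meta(path, meta)
  readr::write_csv(as_tibble(thermo)[c("T_C", "heat_flow_mW")], path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a thermogram from CSV
#'
#' @rdname dib_io
#' @export
read_thermogram <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("file not found: %s", path))
  info <- read_meta(path)
  dat <- readr::read_csv(path, skip = info$n_skip, show_col_types = FALSE,
                         comment = "")
  need <- c("T_C", "heat_flow_mW")
  if (!all(need %in% names(dat))) {
    stop_domain(sprintf(
      "malformed header on line %d of %s: expected columns %s",
      info$n_skip + 1L, path, paste(need, collapse = ", ")))
  }
  bad <- which(diff(dat$T_C) <= 0)
  if (length(bad) > 0) {
    stop_domain(sprintf("non-increasing temperature axis at line %d of %s",
                        info$n_skip + bad[1] + 2L, path))
  }
  m <- info$meta
  thermogram(dat$T_C, dat$heat_flow_mW,
             scan_rate = meta_num(m, "scan_rate_C_min", 5),
             n_lipid = meta_num(m, "n_lipid_mol", 1e-5),
             composition = m$composition)
}

#' Write a spectrum as two-column text
#'
#' @param spec A `raman_spectrum`.
#' @rdname dib_io
#' @export
write_spectrum <- function(spec, path) {
  meta <- list()
  if (!is.null(attr(spec, "label"))) meta$label <- attr(spec, "label")
  if (length(meta) > 0) write_meta(path, meta) else readr::write_lines(character(), path)
  readr::write_lines(
    paste(fmt_num(spec$wavenumber_cm1), fmt_num(spec$intensity)),
    path, append = TRUE)
  invisible(path)
}

#' Read a two-column spectrum (whitespace- or comma-delimited)
#'
#' @param path File path.
#' @rdname dib_io
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("file not found: %s", path))
  info <- read_meta(path)
  lines <- readr::read_lines(path)
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  body <- lines[body_idx]
  parts <- strsplit(trimws(body), "[,[:space:]]+")
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0) {
    stop_domain(sprintf("malformed spectrum row at line %d of %s",
                        body_idx[bad[1]], path))
  }
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  nn <- which(is.na(w) | is.na(y))
  if (length(nn) > 0) {
    stop_domain(sprintf("non-numeric spectrum value at line %d of %s",
                        body_idx[nn[1]], path))
  }
  badw <- which(diff(w) <= 0)
  if (length(badw) > 0) {
    stop_domain(sprintf("non-increasing wavenumber axis at line %d of %s",
                        body_idx[badw[1] + 1L], path))
  }
  raman_spectrum(w, y, label = info$meta$label)
}

.run_config_defaults <- function() {
  list(
    temperature_C = 30,
    seed = NULL,
    osmotic = list(geometry_mode = "sphere", window = 5L),
    dsc = list(pre_window = c(-40, -32), post_window = c(-8, 0),
               endothermic_down = FALSE),
    raman = list(normalize_center_cm1 = 2849, anchor_cm1 = 1606,
                 window_cm1 = 10)
  )
}

#' Read and validate a run configuration
#'
#' Loads a YAML run configuration, rejects unknown keys, fills defaults
#' (measurement temperature 30 degrees C; sphere geometry; DSC baseline
#' windows flanking the transition; Raman normalisation at 2849 cm^-1 and
#' aspirin anchor at 1606 cm^-1) and returns a validated list.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A `dib_run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .run_config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_domain(sprintf("config not found: %s", path))
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      stop_domain(sprintf("unknown config keys: %s",
                          paste(unknown, collapse = ", ")))
    }
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && is.list(user[[k]])) {
        bad <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(bad) > 0) {
          stop_domain(sprintf("unknown config keys under '%s': %s", k,
                              paste(bad, collapse = ", ")))
        }
        cfg[[k]][names(user[[k]])] <- user[[k]]
      } else {
        cfg[[k]] <- user[[k]]
      }
    }
  }
  if (cfg$temperature_C < -273.15) stop_domain("temperature below absolute zero")
  structure(cfg, class = "dib_run_config")
}
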