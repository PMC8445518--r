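#' Read and write list-mode coincidence files
#'
#' Versioned delimited text format.  Header lines start with `#` and carry
#' `key=value` pairs (format version, scanner geometry, seed, config hash,
#' counts, and the sign convention `delta_t_ps = t_a - t_b`; a positive
#' time difference displaces the annihilation toward crystal `b` by
#' `c*dt/2` along the LOR).  The body is one tab-separated row per event:
#' `ring_a crystal_a ring_b crystal_b delta_t_ps kernel_id component`
#' (`component`: 0 = n/a, 1 = fast, 2 = slow) plus, when available, the
#' debug column `geometric_dt_ps`.  Floating-point columns are written with
#' 17 significant digits so a write/read round trip is value-exact.
#'
#' @param lm a `listmode` object from [simulate_acquisition()].
#' @param path file path.
#' @return `write_listmode()` returns `path` invisibly; `read_listmode()`
#'   returns a `listmode` object.
#' @export
write_listmode <- function(lm, path) {
  stopifnot(inherits(lm, "listmode"))
  s <- lm$scanner
  hdr <- c(
    "format=tofmix-listmode-v1",
    "convention=delta_t_ps = t_a - t_b; positive dt displaces the annihilation toward crystal b",
    sprintf("n_crystals_per_ring=%d", s$n_crystals_per_ring),
    sprintf("n_rings=%d", s$n_rings),
    sprintf("ring_radius_mm=%.17g", s$ring_radius_mm),
    sprintf("crystal_pitch_transaxial_mm=%.17g", s$crystal_pitch_transaxial_mm),
    sprintf("crystal_pitch_axial_mm=%.17g", s$crystal_pitch_axial_mm),
    sprintf("crystal_depth_mm=%.17g", s$crystal_depth_mm),
    sprintf("min_sector_difference=%d", s$min_sector_difference),
    sprintf("timing_model=%s", lm$header$timing_model),
    sprintf("seed=%s", if (is.null(lm$header$seed)) "NA" else lm$header$seed),
    sprintf("config_hash=%s", lm$header$config_hash),
    sprintf("n_emissions=%s", lm$header$n_emissions),
    sprintf("n_accepted=%d", nrow(lm$events)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  ev <- lm$events
  num_cols <- intersect(c("delta_t_ps", "geometric_dt_ps"), names(ev))
  for (cn in num_cols) ev[[cn]] <- sprintf("%.17g", ev[[cn]])
  writeLines(paste(names(ev), collapse = "\t"), con)
  write.table(ev, con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_listmode
#' @export
read_listmode <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr_lines <- sub("^#", "", lines[is_hdr])
  kv <- strsplit(hdr_lines, "=", fixed = TRUE)
  header <- stats::setNames(
    lapply(kv, function(p) paste(p[-1], collapse = "=")),
    vapply(kv, `[[`, character(1), 1))
  if (!identical(header$format, "tofmix-listmode-v1"))
    stop("not a tofmix list-mode file: ", path)
  scanner <- ring_scanner(
    n_crystals_per_ring = as.integer(header$n_crystals_per_ring),
    n_rings = as.integer(header$n_rings),
    ring_radius_mm = as.numeric(header$ring_radius_mm),
    crystal_pitch_transaxial_mm = as.numeric(header$crystal_pitch_transaxial_mm),
    crystal_pitch_axial_mm = as.numeric(header$crystal_pitch_axial_mm),
    crystal_depth_mm = as.numeric(header$crystal_depth_mm),
    min_sector_difference = as.integer(header$min_sector_difference))
  body <- lines[!is_hdr]
  events <- read.delim(text = body, sep = "\t", header = TRUE)
  for (cn in intersect(c("ring_a", "crystal_a", "ring_b", "crystal_b",
                         "kernel_id", "component"), names(events)))
    events[[cn]] <- as.integer(events[[cn]])
  seed <- suppressWarnings(as.integer(header$seed))
  structure(list(events = events, scanner = scanner,
                 header = list(seed = if (is.na(seed)) NULL else seed,
                               config_hash = header$config_hash,
                               timing_model = header$timing_model,
                               n_emissions = as.numeric(header$n_emissions),
                               n_accepted = nrow(events))),
            class = "listmode")
}
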