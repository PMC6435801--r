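# All text artifacts are TSV with '# key: value' metadata header lines and
# floats printed with 17 significant digits for lossless round-trips.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_tsv_meta <- function(df, file, meta = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col) if (is.numeric(col)) fmt_num(col) else as.character(col))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(file)
}

read_tsv_meta <- function(file) {
  lines <- readLines(file)
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[is_meta]
  body <- lines[!is_meta]
  if (!length(body)) stop(sprintf("%s: no header line found", file))
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([^:]+):\\s*(.*)$", ml))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- body[-1]
  df <- if (length(rows)) {
    parts <- strsplit(rows, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != length(header))
    if (length(bad))
      stop(sprintf("%s: line %d has %d fields, expected %d",
                   file, which(!is_meta)[bad[1] + 1L], lengths(parts)[bad[1]],
                   length(header)))
    m <- do.call(rbind, parts)
    out <- tibble::as_tibble(setNames(as.data.frame(m, stringsAsFactors = FALSE),
                                      header))
    for (cc in names(out)) {
      suppress <- suppressWarnings(as.numeric(out[[cc]]))
      if (all(is.na(suppress) == (out[[cc]] == "NA"))) out[[cc]] <- suppress
    }
    out
  } else {
    tibble::as_tibble(setNames(rep(list(numeric()), length(header)), header))
  }
  attr(df, "meta") <- meta
  df
}

#' Write / read a free-energy profile as TSV
#'
#' Columns `R_nm`, `value_kT`, `stderr_kT` with metadata header lines for
#' temperature, pressure, component and zero-reference distance. Round-trips
#' at full double precision.
#'
#' @param profile An [fe_profile()].
#' @param file Path.
#' @return `write_profile` returns the path invisibly; `read_profile`
#'   returns the `fe_profile`.
#' @export
write_profile <- function(profile, file) {
  stopifnot(inherits(profile, "fe_profile"))
  m <- profile_meta(profile)
  write_tsv_meta(
    tibble::tibble(R_nm = profile$R, value_kT = profile$value,
                   stderr_kT = profile$stderr),
    file,
    meta = list(temperature_K = m$temperature, pressure_bar = m$pressure,
                component = m$component, R_ref_nm = m$R_ref))
  invisible(file)
}

#' @rdname write_profile
#' @export
read_profile <- function(file) {
  df <- read_tsv_meta(file)
  need <- c("R_nm", "value_kT", "stderr_kT")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: profile file needs columns %s", file,
                 paste(need, collapse = ", ")))
  meta <- attr(df, "meta")
  num <- function(x, default) {
    if (is.null(x)) default else suppressWarnings(as.numeric(x))
  }
  fe_profile(df$R_nm, df$value_kT, df$stderr_kT,
             temperature = num(meta$temperature_K, 298),
             pressure = num(meta$pressure_bar, 1),
             component = meta$component %||% "F",
             R_ref = num(meta$R_ref_nm, NA_real_))
}

#' Write / read a per-frame energy table as TSV
#'
#' Any tibble of per-frame energies (e.g. from [ladder_energy_table()] or a
#' backend export) with optional `# key: value` metadata headers.
#'
#' @param table A tibble.
#' @param file Path.
#' @param meta Named list of metadata values.
#' @export
write_energy_table <- function(table, file, meta = list()) {
  write_tsv_meta(tibble::as_tibble(table), file, meta = meta)
  invisible(file)
}

#' @rdname write_energy_table
#' @export
read_energy_table <- function(file) {
  read_tsv_meta(file)
}

#' Write / read conformations as XYZ
#'
#' Multi-frame XYZ with coordinates in nm; bead labels default to "CA".
#'
#' @param frames An n x 3 matrix or an n x 3 x F array.
#' @param file Path.
#' @param labels Per-bead labels.
#' @param comment Comment line content.
#' @export
write_xyz <- function(frames, file, labels = NULL, comment = "pmfdecomp") {
  if (is.matrix(frames)) frames <- array(frames, c(nrow(frames), 3, 1))
  n <- dim(frames)[1]
  labels <- labels %||% rep("CA", n)
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(dim(frames)[3])) {
    writeLines(c(as.character(n), sprintf("%s frame %d", comment, f)), con)
    writeLines(sprintf("%s %.17g %.17g %.17g", labels,
                       frames[, 1, f], frames[, 2, f], frames[, 3, f]), con)
  }
  invisible(file)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  out <- list(); i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("%s: line %d: expected an atom count", file, i))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4))
      stop(sprintf("%s: malformed coordinate line near line %d", file, i + 2L))
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    out[[length(out) + 1L]] <- m
    i <- i + 2L + n
  }
  if (length(out) == 1L) out[[1]] else {
    arr <- array(unlist(out), c(nrow(out[[1]]), 3, length(out)))
    arr
  }
}

#' Write / read a conformation as CA-only PDB
#'
#' Minimal alpha-carbon convention: one CA ATOM record per bead, coordinates
#' converted nm <-> Angstrom.
#'
#' @param conformation n x 3 matrix (nm).
#' @param file Path.
#' @export
write_pdb_ca <- function(conformation, file) {
  n <- nrow(conformation)
  ang <- conformation * 10
  lines <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), seq_len(n), ang[, 1], ang[, 2], ang[, 3])
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' @rdname write_pdb_ca
#' @export
read_pdb_ca <- function(file) {
  lines <- grep("^ATOM", readLines(file), value = TRUE)
  if (!length(lines)) stop(sprintf("%s: no ATOM records", file))
  m <- t(vapply(lines, function(l) {
    as.numeric(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54)))
  }, numeric(3)))
  dimnames(m) <- NULL
  m / 10
}
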