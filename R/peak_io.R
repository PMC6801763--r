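#' @importFrom stats setNames approx aggregate runif rnorm sd
#' @importFrom utils read.csv read.delim write.csv
NULL

AA_1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# Sanity windows for amide shifts; violations warn, never stop, because
# unusual-but-real peaks (e.g. sidechain NH2 folded into the window edge)
# should survive the reader.
check_shift_windows <- function(peaks, h_window = c(5, 12),
                                n_window = c(95, 140)) {
  bad_h <- peaks$delta_h < h_window[1] | peaks$delta_h > h_window[2]
  bad_n <- peaks$delta_n < n_window[1] | peaks$delta_n > n_window[2]
  if (any(bad_h)) {
    warning(sprintf("%d peak(s) with 1H shift outside [%g, %g] ppm",
                    sum(bad_h), h_window[1], h_window[2]))
  }
  if (any(bad_n)) {
    warning(sprintf("%d peak(s) with 15N shift outside [%g, %g] ppm",
                    sum(bad_n), n_window[1], n_window[2]))
  }
  invisible(peaks)
}

validate_peaks <- function(peaks, where = "peak list") {
  stopifnot(is.data.frame(peaks))
  needed <- c("residue_id", "residue_name", "delta_h", "delta_n", "height")
  missing_cols <- setdiff(needed, names(peaks))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s is missing column(s): %s", where,
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- unique(peaks$residue_id[duplicated(peaks$residue_id)])
  if (length(dup) > 0) {
    stop(sprintf("duplicate residue_id in %s: %s", where,
                 paste(dup, collapse = ", ")))
  }
  check_shift_windows(peaks)
  peaks[order(peaks$residue_id), , drop = FALSE]
}

#' Read an assigned HSQC peak list
#'
#' Supported dialects: `"csv"` and `"tsv"` with header
#' `residue_id,residue_name,delta_h_ppm,delta_n_ppm,height` (height may be
#' empty), and `"sparky"` for Sparky-style `.list` files with lines like
#' `G12N-H  110.42  8.251 [height]`. By convention Sparky w1 is the 15N
#' dimension and w2 the 1H dimension; set `sparky_w1 = "h"` to override.
#'
#' @param path Path to the peak-list file.
#' @param dialect One of `"csv"`, `"tsv"`, `"sparky"`.
#' @param sparky_w1 Which nucleus the first Sparky frequency column holds,
#'   `"n"` (default, standard convention) or `"h"`.
#' @return A data frame with columns `residue_id`, `residue_name`,
#'   `delta_h`, `delta_n`, `height`, sorted by residue, one row per assigned
#'   amide peak. Duplicate residues are an error; shifts outside the amide
#'   window only warn.
#' @export
read_peak_table <- function(path, dialect = c("csv", "tsv", "sparky"),
                            sparky_w1 = c("n", "h")) {
  dialect <- match.arg(dialect)
  sparky_w1 <- match.arg(sparky_w1)
  if (dialect %in% c("csv", "tsv")) {
    raw <- if (dialect == "csv") {
      read.csv(path, stringsAsFactors = FALSE)
    } else {
      read.delim(path, stringsAsFactors = FALSE)
    }
    needed <- c("residue_id", "residue_name", "delta_h_ppm", "delta_n_ppm")
    missing_cols <- setdiff(needed, names(raw))
    if (length(missing_cols) > 0) {
      stop(sprintf("'%s': missing column(s) %s", path,
                   paste(missing_cols, collapse = ", ")))
    }
    if (nrow(raw) == 0) stop(sprintf("'%s': empty peak list", path))
    if (!"height" %in% names(raw)) raw$height <- NA_real_
    bad <- which(!is.finite(raw$delta_h_ppm) | !is.finite(raw$delta_n_ppm) |
                   is.na(raw$residue_id))
    if (length(bad) > 0) {
      stop(sprintf("'%s': malformed row at data line %d", path, bad[1]))
    }
    peaks <- data.frame(
      residue_id = as.integer(raw$residue_id),
      residue_name = ifelse(is.na(raw$residue_name) | raw$residue_name == "",
                            NA_character_, as.character(raw$residue_name)),
      delta_h = as.numeric(raw$delta_h_ppm),
      delta_n = as.numeric(raw$delta_n_ppm),
      height = suppressWarnings(as.numeric(raw$height)),
      stringsAsFactors = FALSE
    )
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    # drop header / comment lines
    lines <- lines[!grepl("^(Assignment|#)", lines, ignore.case = TRUE)]
    if (length(lines) == 0) stop(sprintf("'%s': empty peak list", path))
    rows <- lapply(seq_along(lines), function(i) {
      toks <- strsplit(lines[i], "[[:space:]]+")[[1]]
      if (length(toks) < 3) {
        stop(sprintf("'%s': malformed Sparky line %d: '%s'", path, i, lines[i]))
      }
      m <- regmatches(toks[1],
                      regexec("^([A-Za-z]{1,3})([0-9]+)N-H$", toks[1]))[[1]]
      if (length(m) == 0) {
        stop(sprintf("'%s': unrecognized assignment '%s' at line %d",
                     path, toks[1], i))
      }
      code <- toupper(m[2])
      name <- if (nchar(code) == 1 && code %in% names(AA_1TO3)) {
        AA_1TO3[[code]]
      } else code
      w1 <- as.numeric(toks[2]); w2 <- as.numeric(toks[3])
      if (!is.finite(w1) || !is.finite(w2)) {
        stop(sprintf("'%s': malformed Sparky line %d: '%s'", path, i, lines[i]))
      }
      h <- if (length(toks) >= 4) as.numeric(toks[4]) else NA_real_
      data.frame(
        residue_id = as.integer(m[3]),
        residue_name = name,
        delta_h = if (sparky_w1 == "n") w2 else w1,
        delta_n = if (sparky_w1 == "n") w1 else w2,
        height = h,
        stringsAsFactors = FALSE
      )
    })
    peaks <- do.call(rbind, rows)
  }
  validate_peaks(peaks, where = sprintf("'%s'", path))
}

#' Write an assigned HSQC peak list
#'
#' Inverse of [read_peak_table()]; round-trips peak data losslessly for all
#' three dialects (heights are preserved including missingness; Sparky output
#' has no height column when all heights are missing).
#'
#' @param peaks Peak data frame as returned by [read_peak_table()].
#' @param path Output path.
#' @param dialect One of `"csv"`, `"tsv"`, `"sparky"`.
#' @export
write_peak_table <- function(peaks, path, dialect = c("csv", "tsv", "sparky")) {
  dialect <- match.arg(dialect)
  peaks <- validate_peaks(peaks)
  if (dialect %in% c("csv", "tsv")) {
    out <- data.frame(
      residue_id = peaks$residue_id,
      residue_name = peaks$residue_name,
      delta_h_ppm = sprintf("%.17g", peaks$delta_h),
      delta_n_ppm = sprintf("%.17g", peaks$delta_n),
      height = ifelse(is.na(peaks$height), "",
                      sprintf("%.17g", peaks$height)),
      stringsAsFactors = FALSE
    )
    sep <- if (dialect == "csv") "," else "\t"
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(names(out), collapse = sep), con)
    writeLines(do.call(paste, c(unname(out), sep = sep)), con)
  } else {
    aa3to1 <- setNames(names(AA_1TO3), AA_1TO3)
    code <- ifelse(is.na(peaks$residue_name), "X",
                   ifelse(peaks$residue_name %in% names(aa3to1),
                          aa3to1[peaks$residue_name], peaks$residue_name))
    lines <- sprintf("%s%dN-H %.17g %.17g", code, peaks$residue_id,
                     peaks$delta_n, peaks$delta_h)
    has_h <- !is.na(peaks$height)
    lines[has_h] <- sprintf("%s %.17g", lines[has_h], peaks$height[has_h])
    writeLines(c("Assignment w1 w2 height", lines), path)
  }
  invisible(path)
}

new_titration_point <- function(index, ratio, protein_conc, ligand_conc,
                                peaks) {
  list(index = index, ratio = ratio, protein_conc = protein_conc,
       ligand_conc = ligand_conc, peaks = peaks)
}

#' Construct and validate a titration series
#'
#' @param points A list of titration points (each a list with `index`,
#'   `ratio`, `protein_conc`, `ligand_conc`, `peaks`).
#' @param label Free-text label.
#' @param mode `"constant-protein"` (the aliquot-replacement scheme in which
#'   protein concentration is held fixed while ligand increases) or
#'   `"dilution-corrected"`.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(points, label = "",
                             mode = c("constant-protein",
                                      "dilution-corrected")) {
  mode <- match.arg(mode)
  stopifnot(is.list(points), length(points) >= 1)
  ratios <- vapply(points, `[[`, numeric(1), "ratio")
  if (ratios[1] != 0) {
    stop("first titration point must be the free state (ratio 0)")
  }
  if (any(diff(ratios) <= 0)) {
    stop("titration ratios must be strictly increasing")
  }
  for (pt in points) {
    rel <- abs(pt$ligand_conc - pt$ratio * pt$protein_conc)
    if (rel > 1e-9 * max(1, abs(pt$ligand_conc))) {
      stop(sprintf(
        "point %d: ligand_conc %g inconsistent with ratio %g x protein %g",
        pt$index, pt$ligand_conc, pt$ratio, pt$protein_conc))
    }
  }
  free_res <- points[[1]]$peaks$residue_id
  for (pt in points[-1]) {
    extra <- setdiff(pt$peaks$residue_id, free_res)
    if (length(extra) > 0) {
      stop(sprintf("point %d contains residue(s) absent from the free reference: %s",
                   pt$index, paste(extra, collapse = ", ")))
    }
  }
  structure(list(points = points, label = label, mode = mode),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  ratios <- vapply(x$points, `[[`, numeric(1), "ratio")
  cat(sprintf("titration series '%s' (%s): %d points, ratios %s\n",
              x$label, x$mode, length(x$points),
              paste(format(ratios), collapse = ", ")))
  cat(sprintf("  protein %g mM; %d residues at free reference\n",
              x$points[[1]]$protein_conc, nrow(x$points[[1]]$peaks)))
  invisible(x)
}

#' Load a titration from a config plus per-point peak lists
#'
#' The config (YAML file or an equivalent list) supplies `label`,
#' `protein_conc_mM` (scalar or per-point list), `ratios` (starting at 0,
#' strictly increasing), optional `mode`, `dialect`, `csp_weight` and `seed`,
#' and `peak_files` unless given via `peak_files`. One peak file per ratio;
#' ligand concentration is derived as `ratio * protein_conc` unless a
#' `ligand_conc_mM` list is given explicitly (then checked for consistency).
#'
#' @param config Path to a YAML config file, or a named list.
#' @param peak_files Optional character vector of peak-list paths overriding
#'   the config's `peak_files` (resolved relative to the config file).
#' @param dialect Peak-list dialect; default taken from the config (`"csv"`
#'   if unset).
#' @return A validated [titration_series()].
#' @export
load_titration <- function(config, peak_files = NULL, dialect = NULL) {
  base_dir <- "."
  if (is.character(config) && length(config) == 1) {
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  ratios <- as.numeric(unlist(config$ratios))
  if (length(ratios) < 2) stop("config must list at least two ratios")
  if (is.null(peak_files)) {
    peak_files <- as.character(unlist(config$peak_files))
    peak_files <- ifelse(file.exists(peak_files), peak_files,
                         file.path(base_dir, peak_files))
  }
  if (length(peak_files) != length(ratios)) {
    stop(sprintf("%d peak file(s) for %d configured titration points",
                 length(peak_files), length(ratios)))
  }
  protein <- as.numeric(unlist(config$protein_conc_mM))
  if (length(protein) == 1) protein <- rep(protein, length(ratios))
  if (length(protein) != length(ratios)) {
    stop("protein_conc_mM must be a scalar or one value per point")
  }
  if (is.null(dialect)) dialect <- config$dialect %||% "csv"
  ligand <- if (!is.null(config$ligand_conc_mM)) {
    as.numeric(unlist(config$ligand_conc_mM))
  } else {
    ratios * protein
  }
  points <- lapply(seq_along(ratios), function(i) {
    peaks <- read_peak_table(peak_files[i], dialect = dialect)
    new_titration_point(i, ratios[i], protein[i], ligand[i], peaks)
  })
  titration_series(points, label = config$label %||% "",
                   mode = config$mode %||% "constant-protein")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a CSP table
#'
#' One row per residue per titration point, with missing (intermediate
#' exchange) points written as an explicit empty field, never as zero.
#' Round-trips bit-exactly with [read_csp_table()].
#'
#' @param profiles A `csp_profiles` data frame from [build_profiles()].
#' @param path Output CSV path.
#' @export
write_csp_table <- function(profiles, path) {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0)
  out <- data.frame(
    residue_id = profiles$residue_id,
    point_index = profiles$point_index,
    ratio = sprintf("%.17g", profiles$ratio),
    ligand_conc_mM = sprintf("%.17g", profiles$ligand_conc),
    delta_delta_ppm = ifelse(profiles$flag == "missing", "",
                             sprintf("%.17g", profiles$delta_delta)),
    flag = profiles$flag,
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  writeLines(do.call(paste, c(unname(out), sep = ",")), con)
  invisible(path)
}

#' Read a CSP table written by [write_csp_table()]
#'
#' @param path CSV path.
#' @return A `csp_profiles` data frame.
#' @export
read_csp_table <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(delta_delta_ppm = "character"))
  profiles <- data.frame(
    residue_id = as.integer(raw$residue_id),
    point_index = as.integer(raw$point_index),
    ratio = as.numeric(raw$ratio),
    ligand_conc = as.numeric(raw$ligand_conc_mM),
    delta_delta = ifelse(raw$delta_delta_ppm == "", NA_real_,
                         suppressWarnings(as.numeric(raw$delta_delta_ppm))),
    flag = raw$flag,
    stringsAsFactors = FALSE
  )
  class(profiles) <- c("csp_profiles", "data.frame")
  profiles
}
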