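#' Construct a 3-D image volume
#'
#' Container for a CT-like scalar volume: a 3-D array of intensities in
#' Hounsfield units plus the voxel spacing and world origin in millimetres.
#'
#' @param data 3-D numeric array of voxel intensities.
#' @param spacing Numeric length-3, voxel spacing (sx, sy, sz) in mm; all > 0.
#' @param origin Numeric length-3, world coordinate of voxel (0, 0, 0) in mm.
#' @return An object of class `image_volume` with elements `data`, `spacing`,
#'   `origin`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (any(dim(data) < 1L))
    stop("`data` must have extent >= 1 in every axis")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Construct a label mask
#'
#' Integer lesion mask paired with an [image_volume()]: 0 is background,
#' each positive integer k marks the voxels of lesion k.
#'
#' @param labels 3-D array of non-negative integers.
#' @param spacing,origin As in [image_volume()].
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  if (any(labels != round(labels)) || any(labels < 0))
    stop("`labels` must contain non-negative integers (fractional or ",
         "probabilistic masks are not supported)")
  storage.mode(labels) <- "integer"
  vol <- image_volume(array(0, dim(labels)), spacing, origin)
  structure(list(labels = labels, spacing = vol$spacing, origin = vol$origin),
            class = "label_mask")
}

# ---------------------------------------------------------------------------
# NRRD: minimal reader/writer for attached, little-endian raw / gzip / ascii
# encodings with diagonal space directions. Covers the files this package
# writes and the common single-volume NRRDs produced by 3DSlicer-style tools.

.nrrd_type_map <- c(
  "signed char" = "int8", "int8" = "int8", "int8_t" = "int8",
  "uchar" = "uint8", "unsigned char" = "uint8", "uint8" = "uint8",
  "uint8_t" = "uint8",
  "short" = "int16", "short int" = "int16", "signed short" = "int16",
  "int16" = "int16", "int16_t" = "int16",
  "ushort" = "uint16", "unsigned short" = "uint16", "uint16" = "uint16",
  "uint16_t" = "uint16",
  "int" = "int32", "signed int" = "int32", "int32" = "int32",
  "int32_t" = "int32",
  "float" = "float", "double" = "double")

.nrrd_type_bytes <- c(int8 = 1L, uint8 = 1L, int16 = 2L, uint16 = 2L,
                      int32 = 4L, float = 4L, double = 8L)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (length(magic) != 1L || !grepl("^NRRD000", magic))
    stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop("truncated NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(m) != 3L) stop("malformed NRRD header line: ", line)
    fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  need <- function(f) {
    if (is.null(fields[[f]])) stop("NRRD header missing field '", f, "'")
    fields[[f]]
  }
  ndim <- as.integer(need("dimension"))
  if (ndim != 3L) stop("only 3-D NRRD volumes are supported (dimension = ",
                       ndim, ")")
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- .nrrd_type_map[[tolower(need("type"))]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields$type)
  enc <- tolower(need("encoding"))

  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    if (length(vecs) != 3L)
      stop("NRRD 'space directions' must hold three vectors")
    dirs <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    spacing <- sqrt(colSums(dirs^2))
  }
  if (is.null(spacing))
    stop("NRRD header missing spacing metadata ",
         "(field 'spacings' or 'space directions')")

  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])

  n <- prod(sizes)
  if (enc %in% c("raw", "gzip", "gz")) {
    datcon <- con
    if (enc != "raw") {
      blob <- readBin(con, "raw", n = file.info(path)$size)
      datcon <- gzcon(rawConnection(blob))
      on.exit(close(datcon), add = TRUE)
    }
    vals <- switch(type,
      int8 = readBin(datcon, "integer", n, size = 1L, signed = TRUE),
      uint8 = readBin(datcon, "integer", n, size = 1L, signed = FALSE),
      int16 = readBin(datcon, "integer", n, size = 2L, signed = TRUE,
                      endian = "little"),
      uint16 = readBin(datcon, "integer", n, size = 2L, signed = FALSE,
                       endian = "little"),
      int32 = readBin(datcon, "integer", n, size = 4L, endian = "little"),
      float = readBin(datcon, "double", n, size = 4L, endian = "little"),
      double = readBin(datcon, "double", n, size = 8L, endian = "little"))
  } else if (enc %in% c("ascii", "txt", "text")) {
    vals <- scan(con, what = numeric(), n = n, quiet = TRUE)
  } else {
    stop("unsupported NRRD encoding: ", enc)
  }
  if (length(vals) != n)
    stop("truncated NRRD data in ", path, " (expected ", n, " values, got ",
         length(vals), ")")
  arr <- array(vals, dim = sizes)
  list(data = arr, spacing = spacing, origin = origin,
       integer_type = type %in% c("int8", "uint8", "int16", "uint16", "int32"))
}

write_nrrd <- function(data, spacing, origin, path) {
  int_data <- is.integer(data) ||
    (all(is.finite(data)) && all(data == round(data)) &&
       max(abs(data)) < .Machine$integer.max)
  type <- if (int_data) "int32" else "double"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# written by lesioncv",
    paste0("type: ", if (int_data) "int" else "double"),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(dim(data), collapse = " ")),
    paste0("space directions: ",
           sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   spacing[1], spacing[2], spacing[3])),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    paste0("space origin: ",
           sprintf("(%.17g,%.17g,%.17g)", origin[1], origin[2], origin[3])),
    "")
  writeLines(hdr, con, sep = "\n")
  if (int_data) {
    writeBin(as.integer(data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(data), con, size = 8L, endian = "little")
  }
  invisible(path)
}

.detect_format <- function(path, format = "auto") {
  if (format != "auto") return(format)
  lp <- tolower(path)
  if (grepl("\\.nrrd$", lp)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  stop("cannot infer volume format from extension of ", path,
       "; pass format = 'nrrd' or 'nifti'")
}

#' Read a volumetric image
#'
#' Reads an NRRD or NIfTI-1 volume into an [image_volume()]. Voxel spacing is
#' taken from the file header; a header without spacing metadata is an error.
#'
#' @param path Path to a `.nrrd`, `.nii` or `.nii.gz` file.
#' @param format `"auto"` (by extension), `"nrrd"` or `"nifti"`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nrrd", "nifti")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  format <- .detect_format(path, format)
  if (format == "nrrd") {
    x <- read_nrrd(path)
    image_volume(x$data, x$spacing, x$origin)
  } else {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
      stop("NIfTI header of ", path,
           " is missing valid spacing metadata (field 'pixdim')")
    arr <- as.array(img)
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
    if (length(dim(arr)) > 3L) arr <- arr[, , , 1, drop = TRUE]
    org <- tryCatch(-RNifti::origin(img) * 0, error = function(e) c(0, 0, 0))
    image_volume(arr, pd[1:3], org)
  }
}

#' Read a lesion label mask
#'
#' As [read_volume()] but validates and returns a [label_mask()].
#'
#' @inheritParams read_volume
#' @return A [label_mask()].
#' @export
read_mask <- function(path, format = c("auto", "nrrd", "nifti")) {
  v <- read_volume(path, match.arg(format))
  label_mask(v$data, v$spacing, v$origin)
}

#' Write a volumetric image or label mask
#'
#' Writes to NRRD (raw little-endian encoding) or NIfTI-1. Integer-valued
#' arrays are stored as 32-bit integers, everything else as doubles.
#'
#' @param x An [image_volume()] or [label_mask()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"nrrd"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, format = c("auto", "nrrd", "nifti")) {
  format <- .detect_format(path, match.arg(format))
  data <- if (inherits(x, "label_mask")) x$labels else x$data
  if (format == "nrrd") {
    write_nrrd(data, x$spacing, x$origin, path)
  } else {
    img <- RNifti::asNifti(data)
    RNifti::pixdim(img) <- x$spacing
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Tabular IO

#' Write a per-lesion feature table
#'
#' One row per lesion: `patient_id`, `lesion_id`, then the 75 features in
#' canonical order. Values are written with 12 significant digits so the
#' table round-trips losslessly at that precision.
#'
#' @param rows A data.frame with columns `patient_id`, `lesion_id` and one
#'   column per feature, or a list of lists with elements `patient_id`,
#'   `lesion_id`, `features` (named numeric).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(rows, path) {
  if (is.data.frame(rows)) {
    df <- rows
  } else {
    if (length(rows) == 0L) {
      df <- as.data.frame(setNames(
        rep(list(numeric(0)), 2L + length(feature_names())),
        c("patient_id", "lesion_id", feature_names())))
      df$patient_id <- character(0)
    } else {
      nm <- names(rows[[1]]$features)
      for (r in rows) {
        if (!identical(names(r$features), nm))
          stop("inconsistent feature names across rows")
      }
      df <- data.frame(patient_id = vapply(rows, function(r)
                         as.character(r$patient_id), ""),
                       lesion_id = vapply(rows, function(r)
                         as.integer(r$lesion_id), 0L),
                       stringsAsFactors = FALSE)
      feat <- do.call(rbind, lapply(rows, function(r) r$features))
      colnames(feat) <- nm
      df <- cbind(df, as.data.frame(feat))
    }
  }
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-lesion feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Read a patient manifest
#'
#' Expects at least columns `patient_id` and `cohort`; extra columns (paths,
#' covariates such as sex) are carried through.
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("patient_id", "cohort"), names(df))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  df$cohort <- as.character(df$cohort)
  if (anyDuplicated(df$patient_id))
    stop("manifest contains duplicated patient ids")
  df
}
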