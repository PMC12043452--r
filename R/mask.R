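#' Binary voxel masks of segmented tumors
#'
#' A `voxel_mask` is a 3D binary occupancy grid (1 = tumor, 0 = non-tumor)
#' with a physical voxel spacing in millimetres per axis and the physical
#' position (mm) of the centre of voxel (0,0,0). Axis order is (x, y, z) as
#' declared in MetaIO/NRRD headers; voxel indices are 0-based with
#' voxel-centred sampling.
#'
#' @param occupancy 3D array; any value > 0 is treated as tumor.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin numeric length-3, physical position of the first voxel
#'   centre in mm.
#' @return An object of class `voxel_mask` with elements `occupancy`
#'   (integer 0/1 array), `spacing` and `origin`.
#' @examples
#' m <- voxel_mask(array(1L, c(10, 10, 10)), spacing = c(1, 1, 1))
#' mask_volume(m)  # 1 cm^3
#' @export
voxel_mask <- function(occupancy, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(occupancy) || length(dim(occupancy)) != 3L)
    stop("`occupancy` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  occ <- array(as.integer(occupancy > 0), dim = dim(occupancy))
  structure(list(occupancy = occ, spacing = spacing, origin = origin),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$occupancy)
  cat("Binary tumor mask:", paste(d, collapse = " x "), "voxels\n")
  cat("  spacing [mm]:", paste(format(x$spacing), collapse = " x "), "\n")
  cat("  occupied voxels:", sum(x$occupancy), sprintf("(volume %.3f cm^3)\n",
      mask_volume(x)))
  invisible(x)
}

#' Tumor volume of a mask in cm^3
#'
#' Number of occupied voxels times the voxel volume, converted from mm^3.
#'
#' @param mask a [voxel_mask()].
#' @return Volume in cm^3 (= mL).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  sum(mask$occupancy) * prod(mask$spacing) / 1000
}

#' Ellipsoid tumor volume (SIOP convention)
#'
#' V = (pi/6) a b c for full axis lengths a, b, c in cm, the approximation
#' used for database tumor volumes in the SIOP protocol.
#'
#' @param a,b,c full axis lengths in cm, strictly positive.
#' @return Volume in cm^3.
#' @examples
#' ellipsoid_volume(2, 2, 2)  # sphere of radius 1 cm
#' @export
ellipsoid_volume <- function(a, b, c) {
  if (any(c(a, b, c) <= 0)) stop("axes must be strictly positive", call. = FALSE)
  pi / 6 * a * b * c
}

#' Percent tumor volume reduction
#'
#' @param v_pre pre-chemotherapy volume, cm^3 (> 0).
#' @param v_post post-chemotherapy volume, cm^3 (>= 0).
#' @return 100 (v_pre - v_post) / v_pre; negative if the tumor grew.
#' @examples
#' volume_reduction(126.25, 10.58)
#' @export
volume_reduction <- function(v_pre, v_post) {
  if (any(v_pre <= 0)) stop("`v_pre` must be > 0", call. = FALSE)
  if (any(v_post < 0)) stop("`v_post` must be >= 0", call. = FALSE)
  100 * (v_pre - v_post) / v_pre
}

# ---- MetaIO / NRRD I/O -----------------------------------------------------

.metaio_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                   MET_USHORT = "integer", MET_SHORT = "integer",
                   MET_UINT = "integer", MET_INT = "integer",
                   MET_FLOAT = "double", MET_DOUBLE = "double")
.metaio_sizes <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_USHORT = 2, MET_SHORT = 2,
                   MET_UINT = 4, MET_INT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)

.read_mhd_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("malformed MetaIO header line: ", lines[bad][1], call. = FALSE)
  stats::setNames(vapply(kv, `[`, "", 3L), vapply(kv, `[`, "", 2L))
}

.read_mask_mhd <- function(path) {
  h <- .read_mhd_header(path)
  need <- function(key) {
    if (!key %in% names(h)) stop("MetaIO header lacks ", key, call. = FALSE)
    h[[key]]
  }
  ndims <- as.integer(need("NDims"))
  if (!identical(ndims, 3L)) stop("expected a 3D volume, got NDims = ", ndims,
                                  call. = FALSE)
  dims <- as.integer(strsplit(trimws(need("DimSize")), "\\s+")[[1]])
  type <- trimws(need("ElementType"))
  if (!type %in% names(.metaio_types))
    stop("unsupported ElementType: ", type, call. = FALSE)
  spacing <- if ("ElementSpacing" %in% names(h))
    as.numeric(strsplit(trimws(h[["ElementSpacing"]]), "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if ("Offset" %in% names(h))
    as.numeric(strsplit(trimws(h[["Offset"]]), "\\s+")[[1]]) else c(0, 0, 0)
  msb <- identical(toupper(trimws(h[["ElementByteOrderMSB"]] %||% "False")), "TRUE")
  datafile <- trimws(need("ElementDataFile"))
  if (identical(datafile, "LOCAL"))
    stop("inline (LOCAL) MetaIO payloads are not supported", call. = FALSE)
  raw_path <- file.path(dirname(path), datafile)
  if (!file.exists(raw_path)) stop("raw payload not found: ", raw_path, call. = FALSE)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
  vals <- readBin(con, what = .metaio_types[[type]], n = n,
                  size = .metaio_sizes[[type]],
                  signed = if (.metaio_sizes[[type]] < 4) signed else TRUE,
                  endian = if (msb) "big" else "little")
  if (length(vals) != n) stop("raw payload shorter than DimSize implies", call. = FALSE)
  voxel_mask(array(vals, dim = dims), spacing = spacing, origin = origin)
}

.read_mask_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path, call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("NRRD header ended before blank line", call. = FALSE)
    if (!nzchar(line)) break
    if (grepl("^#", line)) next
    m <- regexec("^([^:]+):=?\\s*(.*)$", line)[[1]]
    parts <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(parts) != 3L) stop("malformed NRRD field: ", line, call. = FALSE)
    fields[[tolower(trimws(parts[2]))]] <- trimws(parts[3])
  }
  dim_n <- as.integer(fields[["dimension"]] %||%
                        stop("NRRD header lacks dimension", call. = FALSE))
  if (!identical(dim_n, 3L)) stop("expected a 3D volume, got dimension = ",
                                  dim_n, call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- fields[["type"]] %||% stop("NRRD header lacks type", call. = FALSE)
  typemap <- list(
    "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
    "uchar" = list(what = "integer", size = 1, signed = FALSE),
    "uint8" = list(what = "integer", size = 1, signed = FALSE),
    "short" = list(what = "integer", size = 2, signed = TRUE),
    "int16" = list(what = "integer", size = 2, signed = TRUE),
    "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
    "uint16" = list(what = "integer", size = 2, signed = FALSE),
    "int" = list(what = "integer", size = 4, signed = TRUE),
    "int32" = list(what = "integer", size = 4, signed = TRUE),
    "float" = list(what = "double", size = 4, signed = TRUE),
    "double" = list(what = "double", size = 8, signed = TRUE))
  tp <- typemap[[type]]
  if (is.null(tp)) stop("unsupported NRRD type: ", type, call. = FALSE)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    # diagonal direction vectors only, e.g. (0.9375,0,0) (0,0.9375,0) (0,0,5.5)
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    mat <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    offdiag <- mat; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-9))
      stop("only axis-aligned NRRD space directions are supported", call. = FALSE)
    spacing <- abs(diag(mat))
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]),
                                  ",")[[1]])
  encoding <- tolower(fields[["encoding"]] %||% "raw")
  n <- prod(sizes)
  if (encoding %in% c("raw")) {
    endian <- if (grepl("big", tolower(fields[["endian"]] %||% "little")))
      "big" else "little"
    vals <- readBin(con, what = tp$what, n = n, size = tp$size,
                    signed = if (tp$size < 4) tp$signed else TRUE,
                    endian = endian)
  } else if (encoding %in% c("ascii", "text", "txt")) {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", encoding, call. = FALSE)
  if (length(vals) != n) stop("NRRD payload shorter than sizes imply", call. = FALSE)
  voxel_mask(array(vals, dim = sizes), spacing = spacing, origin = origin)
}

#' Read a tumor mask from MetaIO or NRRD
#'
#' Reads a 3D volume saved in the MetaIO standard (`.mhd` text header plus
#' `.raw` payload) or in NRRD (attached header; `raw` or `ascii` encoding).
#' Non-binary voxel values, e.g. label maps with values \{0, 255\}, are
#' thresholded at > 0.
#'
#' @param path path to a `.mhd` or `.nrrd` file; the format is chosen by
#'   extension, falling back to content sniffing.
#' @return A [voxel_mask()].
#' @seealso [write_mask()]
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mhd") return(.read_mask_mhd(path))
  if (ext %in% c("nrrd", "nhdr")) return(.read_mask_nrrd(path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("^NRRD", first)) return(.read_mask_nrrd(path))
  .read_mask_mhd(path)
}

#' Write a tumor mask to MetaIO or NRRD
#'
#' Occupancy is stored as unsigned 8-bit integers; spacing and origin are
#' written to the header and survive a read/write round trip exactly.
#'
#' @param mask a [voxel_mask()].
#' @param path output path; `.mhd` writes a MetaIO header plus a sibling
#'   `.raw` payload, `.nrrd` writes a single attached-header NRRD file.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  ext <- tolower(tools::file_ext(path))
  dims <- dim(mask$occupancy)
  payload <- as.raw(as.integer(mask$occupancy))
  num <- function(x) paste(format(x, digits = 17, scientific = FALSE,
                                  trim = TRUE), collapse = " ")
  if (ext == "mhd") {
    raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
    header <- c(
      "ObjectType = Image",
      "NDims = 3",
      "BinaryData = True",
      "BinaryDataByteOrderMSB = False",
      "ElementByteOrderMSB = False",
      paste("DimSize =", num(dims)),
      paste("ElementSpacing =", num(mask$spacing)),
      paste("Offset =", num(mask$origin)),
      "ElementType = MET_UCHAR",
      paste("ElementDataFile =", raw_name))
    writeLines(header, path)
    writeBin(payload, file.path(dirname(path), raw_name))
  } else if (ext %in% c("nrrd")) {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- c(
      "NRRD0004",
      "# binary tumor mask",
      "type: unsigned char",
      "dimension: 3",
      paste("sizes:", num(dims)),
      paste("spacings:", num(mask$spacing)),
      paste("space origin:", paste0("(", paste(format(mask$origin, digits = 17,
            scientific = FALSE, trim = TRUE), collapse = ","), ")")),
      "encoding: raw",
      "endian: little",
      "")
    writeChar(paste0(paste(header, collapse = "\n"), "\n"), con, eos = NULL)
    writeBin(payload, con)
  } else stop("unsupported extension '", ext, "': use .mhd or .nrrd",
              call. = FALSE)
  invisible(path)
}

#' Resample a mask to a new voxel spacing (nearest neighbour)
#'
#' Physical-space nearest-neighbour resampling: each output voxel centre
#' takes the value of the nearest input voxel centre, using spacing and
#' origin (not array-index scaling), so anisotropic inputs such as thick-
#' slice MRI masks are handled correctly. The physical extent is preserved
#' up to one voxel per axis.
#'
#' @param mask a [voxel_mask()].
#' @param target_spacing numeric scalar or length-3, mm (> 0); the default
#'   1 mm matches the isotropic standardisation used for simulator input.
#' @return A [voxel_mask()] at the target spacing.
#' @export
resample_nearest <- function(mask, target_spacing = 1) {
  stopifnot(inherits(mask, "voxel_mask"))
  t <- rep_len(as.numeric(target_spacing), 3L)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("`target_spacing` must be > 0", call. = FALSE)
  sp <- mask$spacing
  n_in <- dim(mask$occupancy)
  n_out <- pmax(1L, as.integer(round(n_in * sp / t)))
  idx <- vector("list", 3L)
  origin_out <- numeric(3L)
  for (ax in 1:3) {
    # first output centre sits half a voxel inside the input physical extent
    origin_out[ax] <- mask$origin[ax] - sp[ax] / 2 + t[ax] / 2
    centers <- origin_out[ax] + (seq_len(n_out[ax]) - 1) * t[ax]
    i <- round((centers - mask$origin[ax]) / sp[ax])
    idx[[ax]] <- pmin(pmax(i, 0), n_in[ax] - 1L) + 1L
  }
  occ <- mask$occupancy[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  voxel_mask(array(occ, dim = n_out), spacing = t, origin = origin_out)
}

#' Synthesize an ellipsoid-like binary tumor mask
#'
#' Generates a deterministic, seeded stand-in for a segmented patient tumor:
#' a randomly oriented superellipsoid whose boundary is perturbed by smooth
#' low-frequency radial noise, voxelized at the requested spacing and scaled
#' by bisection so that [mask_volume()] is within 1\% of the target. Real
#' Wilms' tumors are non-ellipsoidal, which is why the generator supports a
#' boundary irregularity rather than an exact ellipsoid.
#'
#' @param target_volume target volume in cm^3 (> 0, at least one voxel).
#' @param spacing isotropic voxel spacing in mm.
#' @param seed integer seed; the same seed always yields the same mask.
#' @param irregularity boundary perturbation amplitude in `[0, 1]`; 0 gives
#'   a smooth superellipsoid.
#' @return A [voxel_mask()] labelled as synthetic (attribute `synthetic`).
#' @examples
#' m <- synthesize_ellipsoid_mask(1, spacing = 2, seed = 1)
#' mask_volume(m)
#' @export
synthesize_ellipsoid_mask <- function(target_volume, spacing = 1, seed = 1,
                                      irregularity = 0.15) {
  if (target_volume <= 0) stop("`target_volume` must be > 0", call. = FALSE)
  spacing <- as.numeric(spacing)[1]
  if (spacing <= 0) stop("`spacing` must be > 0", call. = FALSE)
  vox_mm3 <- spacing^3
  if (target_volume * 1000 < vox_mm3)
    stop("target volume is smaller than one voxel at this spacing",
         call. = FALSE)
  if (irregularity < 0 || irregularity > 1)
    stop("`irregularity` must be in [0, 1]", call. = FALSE)
  local_seed(seed)

  # nominal radius (mm) of the equal-volume sphere
  r0 <- (3 * target_volume * 1000 / (4 * pi))^(1 / 3)
  ax <- stats::runif(3, 0.75, 1.35)            # per-axis anisotropy
  ax <- ax / prod(ax)^(1 / 3)
  p <- stats::runif(1, 2, 3)                   # superellipsoid exponent
  # smooth radial perturbation: a few random low-frequency cosine modes
  nmodes <- 6L
  k <- matrix(stats::rnorm(3 * nmodes, sd = 1.2 / r0), nrow = 3)
  ph <- stats::runif(nmodes, 0, 2 * pi)
  amp <- stats::runif(nmodes, 0.3, 1)
  amp <- amp / sum(amp)

  half <- r0 * max(ax) * (1.35 + irregularity)
  n <- as.integer(ceiling(2 * half / spacing)) + 3L
  cent <- (n + 1) / 2
  cs <- (seq_len(n) - cent) * spacing
  gx <- array(cs, c(n, n, n))
  gy <- aperm(gx, c(2, 1, 3))
  gz <- aperm(gx, c(3, 2, 1))
  shape <- (abs(gx / ax[1])^p + abs(gy / ax[2])^p + abs(gz / ax[3])^p)^(1 / p)
  if (irregularity > 0) {
    noise <- 0
    for (j in seq_len(nmodes))
      noise <- noise + amp[j] * cos(k[1, j] * gx + k[2, j] * gy +
                                    k[3, j] * gz + ph[j])
    shape <- shape * (1 + irregularity * noise)
  }
  target_vox <- target_volume * 1000 / vox_mm3
  lo <- 0; hi <- r0 * 3
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    cnt <- sum(shape <= mid)
    if (abs(cnt - target_vox) / target_vox <= 0.005) break
    if (cnt > target_vox) hi <- mid else lo <- mid
  }
  occ <- array(as.integer(shape <= mid), dim = c(n, n, n))
  m <- voxel_mask(occ, spacing = rep(spacing, 3))
  if (abs(mask_volume(m) - target_volume) / target_volume > 0.01)
    stop("could not voxelize the target volume to within 1% at spacing ",
         spacing, " mm", call. = FALSE)
  attr(m, "synthetic") <- TRUE
  m
}
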