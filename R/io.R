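#' Read and write image volumes
#'
#' NIfTI (`.nii` / `.nii.gz`, via RNifti) and uncompressed single-file
#' MetaImage (`.mha`) are supported; the format is chosen by extension.
#' Only axis-aligned geometry (spacing + origin) is carried; a volume
#' written and re-read preserves data, spacing and origin.
#'
#' @param vol An [image_volume()].
#' @param path Output path ending in `.nii`, `.nii.gz` or `.mha`.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   an [image_volume()].
#' @export
write_volume <- function(vol, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    aff <- diag(4)
    diag(aff)[1:3] <- vol$spacing
    aff[1:3, 4] <- vol$origin
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mha$", path)) {
    write_metaimage(vol, path)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    aff <- RNifti::xform(img)
    image_volume(array(as.numeric(img), dim(img)[1:3]),
                 spacing = RNifti::pixdim(img)[1:3], origin = aff[1:3, 4])
  } else if (grepl("\\.mha$", path)) {
    read_metaimage(path)
  } else {
    stop("unsupported volume format: ", path)
  }
}

# Minimal uncompressed MetaImage (.mha) writer: MET_FLOAT, local data.
write_metaimage <- function(vol, path) {
  d <- vol_dim(vol)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    "ObjectType = Image\nNDims = 3\nBinaryData = True\n",
    "BinaryDataByteOrderMSB = False\nCompressedData = False\n",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1\n",
    sprintf("Offset = %.10g %.10g %.10g\n", vol$origin[1], vol$origin[2],
            vol$origin[3]),
    "CenterOfRotation = 0 0 0\nAnatomicalOrientation = RAI\n",
    sprintf("ElementSpacing = %.10g %.10g %.10g\n", vol$spacing[1],
            vol$spacing[2], vol$spacing[3]),
    sprintf("DimSize = %d %d %d\n", d[1], d[2], d[3]),
    "ElementType = MET_FLOAT\nElementDataFile = LOCAL\n")
  writeChar(hdr, con, eos = NULL)
  writeBin(as.numeric(vol$data), con, size = 4, endian = "little")
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "\n") break
      line <- paste0(line, ch)
    }
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$ElementDataFile, "LOCAL"))
    stop("only single-file (LOCAL) MetaImage is supported")
  if (!identical(hdr$ElementType, "MET_FLOAT"))
    stop("only MET_FLOAT MetaImage is supported")
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  n <- prod(d)
  v <- readBin(con, "numeric", n, size = 4, endian = "little")
  image_volume(array(v, d),
               spacing = as.numeric(strsplit(hdr$ElementSpacing,
                                             "\\s+")[[1]]),
               origin = as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]))
}

#' Read or write ROI boxes as JSON
#'
#' @param rois List of [roi_box()]es.
#' @param path File path.
#' @return `write_rois` returns `path` invisibly; `read_rois` the list.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(lapply(rois, unclass), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  lapply(x, function(r) roi_box(r$slice, r$row, r$col, r$height, r$width,
                                if (is.null(r$label)) NA else r$label))
}
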