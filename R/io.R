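#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file and returns either a 3D scalar map or a 4D timeseries
#' array. Voxel sizes (mm) are attached as the `voxel_size` attribute; for 4D
#' data the repetition time (s) is attached as `tr`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A numeric array of dimension 3 or 4 with attributes `voxel_size`
#'   (length-3 numeric, mm) and, for 4D data, `tr` (seconds).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) < 3L || length(d) > 4L) {
    stop(sprintf("expected a 3D or 4D NIfTI volume, got %d dimensions", length(d)),
         call. = FALSE)
  }
  pix <- RNifti::pixdim(img)
  out <- array(as.numeric(img), dim = d)
  attr(out, "voxel_size") <- as.numeric(pix[1:3])
  if (length(d) == 4L) attr(out, "tr") <- as.numeric(pix[4])
  out
}

#' Write a NIfTI volume
#'
#' @param x 3D or 4D numeric array; attributes `voxel_size` and `tr` (if
#'   present) are stored in the header.
#' @param path Output path (`.nii.gz` recommended).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  d <- dim(x)
  if (is.null(d) || length(d) < 3L || length(d) > 4L) {
    stop("`x` must be a 3D or 4D array", call. = FALSE)
  }
  vs <- attr(x, "voxel_size")
  if (is.null(vs)) vs <- c(2, 2, 2)
  tr <- attr(x, "tr")
  pix <- if (length(d) == 4L) c(vs, if (is.null(tr)) 1 else tr) else vs
  img <- RNifti::asNifti(array(as.numeric(x), dim = d))
  RNifti::pixdim(img) <- pix
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a typed TSV table
#'
#' Reads a tab-separated table with a header row and checks it against a
#' simple schema: a character vector of required column names, optionally
#' named by type (`"character"`, `"numeric"`, `"integer"`).
#'
#' @param path Path to a TSV file.
#' @param schema Required columns. Unnamed entries are only checked for
#'   presence; named entries (name = column, value = type) are also
#'   type-checked/coerced.
#' @param key Optional column that must contain unique values
#'   (e.g. `"subject_id"`).
#' @return A tibble.
#' @export
read_table <- function(path, schema = character(), key = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  cols <- if (is.null(names(schema))) schema else names(schema)
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0L) {
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(names(schema))) {
    for (cn in names(schema)) {
      want <- schema[[cn]]
      if (want %in% c("numeric", "integer") && !is.numeric(tab[[cn]])) {
        suppressWarnings(conv <- as.numeric(tab[[cn]]))
        bad <- which(is.na(conv) & !is.na(tab[[cn]]))
        if (length(bad) > 0L) {
          stop(sprintf("column '%s' has non-numeric value at row %d", cn, bad[1L]),
               call. = FALSE)
        }
        tab[[cn]] <- conv
      }
      if (want == "character") tab[[cn]] <- as.character(tab[[cn]])
    }
  }
  if (!is.null(key)) {
    if (anyDuplicated(tab[[key]])) {
      stop(sprintf("duplicate values in key column '%s'", key), call. = FALSE)
    }
  }
  tab
}

#' Write a table as TSV
#'
#' @param tab Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(tab, path) {
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
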