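#' Construct a subjects-by-features matrix container
#'
#' A `feature_matrix` holds one voxelwise (or otherwise vectorized) imaging
#' feature per column and one subject per row. It is the `Y` consumed by
#' every harmonization and evaluation routine in the package. When the
#' features originate from masked 3-D maps, the grid shape and the in-mask
#' voxel indices are carried along so that harmonized data can be written
#' back as NIfTI maps.
#'
#' @param values Numeric matrix, subjects in rows, features in columns.
#' @param subject_ids Character vector of unique subject identifiers, one
#'   per row. Defaults to existing rownames or `sub_1 ... sub_n`.
#' @param mask_shape Optional integer 3-vector, the 3-D grid dimensions the
#'   features were sampled from.
#' @param mask_indices Optional integer vector of 0-based linear voxel
#'   indices (x fastest, i.e. column-major over the grid), one per feature.
#' @param modality Free-text tag such as `"ALFF"` or `"ReHo"`.
#'
#' @return An object of class `feature_matrix`: the numeric matrix with
#'   subject ids as rownames and attributes `mask_shape`, `mask_indices`
#'   and `modality`.
#' @export
feature_matrix <- function(values, subject_ids = NULL, mask_shape = NULL,
                           mask_indices = NULL, modality = "feature") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) {
    abort("A feature_matrix needs at least 2 subjects (rows).")
  }
  if (ncol(values) < 1L) {
    abort("A feature_matrix needs at least 1 feature (column).")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values))
    abort(sprintf(
      "feature_matrix values must be finite: %d non-finite entries, first at index %d.",
      length(bad), bad[1L]
    ))
  }
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values) %||% paste0("sub_", seq_len(nrow(values)))
  }
  subject_ids <- as.character(subject_ids)
  if (length(subject_ids) != nrow(values)) {
    abort("subject_ids must have one entry per row of values.")
  }
  if (anyDuplicated(subject_ids)) {
    abort("subject_ids must be unique.")
  }
  if (!is.null(mask_shape)) {
    mask_shape <- as.integer(mask_shape)
    if (length(mask_shape) != 3L) abort("mask_shape must have length 3.")
    if (is.null(mask_indices)) abort("mask_indices required when mask_shape is given.")
    mask_indices <- as.integer(mask_indices)
    if (length(mask_indices) != ncol(values)) {
      abort(sprintf(
        "mask_indices length (%d) must equal the number of features (%d).",
        length(mask_indices), ncol(values)
      ))
    }
    if (any(mask_indices < 0L) || any(mask_indices >= prod(mask_shape))) {
      abort("mask_indices out of range for mask_shape.")
    }
  }
  rownames(values) <- subject_ids
  structure(values,
    mask_shape = mask_shape, mask_indices = mask_indices,
    modality = modality, class = c("feature_matrix", "matrix", "array")
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d subjects x %d features (%s)%s\n",
    nrow(x), ncol(x), attr(x, "modality"),
    if (!is.null(attr(x, "mask_shape"))) {
      sprintf(", grid %s", paste(attr(x, "mask_shape"), collapse = "x"))
    } else ""
  ))
  invisible(x)
}

# Strip the container class but keep the data; used before heavy algebra.
fm_values <- function(x) {
  y <- unclass(x)
  attr(y, "mask_shape") <- NULL
  attr(y, "mask_indices") <- NULL
  attr(y, "modality") <- NULL
  y
}

# Rebuild a feature_matrix with new values but the same metadata.
fm_like <- function(values, template) {
  feature_matrix(values,
    subject_ids = rownames(template),
    mask_shape = attr(template, "mask_shape"),
    mask_indices = attr(template, "mask_indices"),
    modality = attr(template, "modality")
  )
}

#' Load a feature matrix from NIfTI maps or a delimited file
#'
#' With several 3-D NIfTI feature maps (one per subject) and an optional
#' binary mask, returns the masked voxels of each map as one row per
#' subject. Voxels are linearized 0-based with the x index moving fastest
#' (column-major over the grid), so the same mask always yields the same
#' feature ordering. With a single delimited file, reads a numeric matrix
#' with a header row of feature names and a first column of subject ids
#' (the format written by [write_feature_matrix()]).
#'
#' @param paths Character vector of 3-D NIfTI file paths (one per subject),
#'   or a single path to a CSV matrix file.
#' @param mask Optional path to a binary 3-D NIfTI mask, or a logical/0-1
#'   3-D array. Ignored for delimited input.
#' @param subject_ids Optional subject ids; defaults to file basenames
#'   (NIfTI input) or the file's first column (delimited input).
#' @param modality Modality tag stored on the result.
#'
#' @return A [feature_matrix()].
#' @export
load_feature_matrix <- function(paths, mask = NULL, subject_ids = NULL,
                                modality = "feature") {
  is_nifti <- grepl("\\.nii(\\.gz)?$", paths, ignore.case = TRUE)
  if (length(paths) == 1L && !is_nifti[1L]) {
    return(read_feature_csv(paths, modality = modality))
  }
  if (!all(is_nifti)) {
    abort("Mix of NIfTI and non-NIfTI paths; supply either NIfTI maps or one delimited file.")
  }
  imgs <- lapply(paths, RNifti::readNifti)
  shape <- dim(imgs[[1L]])
  if (length(shape) != 3L) {
    abort(sprintf("Expected 3-D maps; '%s' has %d dimensions.", paths[1L], length(shape)))
  }
  aff <- RNifti::xform(imgs[[1L]])
  for (i in seq_along(imgs)[-1L]) {
    if (!identical(dim(imgs[[i]]), shape)) {
      abort(sprintf(
        "Grid shape mismatch: '%s' is %s, expected %s.",
        paths[i], paste(dim(imgs[[i]]), collapse = "x"),
        paste(shape, collapse = "x")
      ))
    }
    if (max(abs(RNifti::xform(imgs[[i]]) - aff)) > 1e-4) {
      abort(sprintf("Affine mismatch beyond tolerance 1e-4 in '%s'.", paths[i]))
    }
  }
  if (is.null(mask)) {
    mask_arr <- array(TRUE, dim = shape)
  } else {
    mask_arr <- read_mask(mask, shape)
  }
  # 0-based, x-fastest linearization: R arrays are column-major, so
  # which() over the 3-D mask already enumerates voxels x fastest.
  idx1 <- which(mask_arr)
  values <- t(vapply(imgs, function(im) as.numeric(im)[idx1], numeric(length(idx1))))
  if (anyNA(values)) {
    bad <- which(is.na(values))
    abort(sprintf(
      "NaN in-mask voxels: %d missing values, first at matrix index %d.",
      length(bad), bad[1L]
    ))
  }
  if (is.null(subject_ids)) {
    subject_ids <- sub("\\.nii(\\.gz)?$", "", basename(paths), ignore.case = TRUE)
  }
  feature_matrix(values,
    subject_ids = subject_ids, mask_shape = shape,
    mask_indices = idx1 - 1L, modality = modality
  )
}

read_mask <- function(mask, shape) {
  if (is.character(mask)) mask <- RNifti::readNifti(mask)
  mask <- as.array(mask)
  if (!identical(as.integer(dim(mask)), as.integer(shape))) {
    abort(sprintf(
      "Mask shape %s does not match map shape %s.",
      paste(dim(mask), collapse = "x"), paste(shape, collapse = "x")
    ))
  }
  vals <- unique(as.numeric(mask))
  if (!all(vals %in% c(0, 1))) abort("Mask must be binary (0/1).")
  array(as.numeric(mask) > 0, dim = shape)
}

#' Write a feature matrix to a delimited file
#'
#' Writes a CSV with a `subject_id` first column and one named column per
#' feature, at full double precision so a write/read round trip is exact.
#'
#' @param x A [feature_matrix()] (or plain numeric matrix).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  m <- as.matrix(unclass(x))
  df <- data.frame(
    subject_id = rownames(m) %||% paste0("sub_", seq_len(nrow(m))),
    m,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  colnames(df)[-1L] <- colnames(m) %||% paste0("f", seq_len(ncol(m)))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

read_feature_csv <- function(path, modality = "feature") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) {
    abort(sprintf("Delimited feature file '%s' must have a 'subject_id' column.", path))
  }
  ids <- as.character(df$subject_id)
  m <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  storage.mode(m) <- "double"
  feature_matrix(m, subject_ids = ids, modality = modality)
}

#' Write harmonized features back to a 4-D NIfTI stack
#'
#' Inverse of [load_feature_matrix()] for masked NIfTI input: places each
#' subject's features back at their voxel coordinates (zero elsewhere).
#'
#' @param x A [feature_matrix()] carrying `mask_shape`/`mask_indices`.
#' @param path Output NIfTI path (4-D, subjects along the 4th dimension).
#' @return `path`, invisibly.
#' @export
write_feature_nifti <- function(x, path) {
  shape <- attr(x, "mask_shape")
  if (is.null(shape)) abort("No mask geometry stored on this feature_matrix.")
  idx1 <- attr(x, "mask_indices") + 1L
  arr <- array(0, dim = c(shape, nrow(x)))
  npervol <- prod(shape)
  for (i in seq_len(nrow(x))) {
    arr[(i - 1L) * npervol + idx1] <- unclass(x)[i, ]
  }
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}
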