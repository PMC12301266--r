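#' Construct a feature table
#'
#' A feature table holds a samples-by-features matrix of non-negative LC-MS
#' intensities (arbitrary units) together with a per-feature acquisition
#' method tag (e.g. `"RP+"`, `"RP-"`, `"HILIC-"`). Missing measurements are
#' stored as `NA` until [impute_lod()] replaces them with a limit-of-detection
#' estimate. Intensities from different acquisition methods are normalized
#' separately (see [normalize_to_internal_standard()]).
#'
#' @param intensities numeric matrix, samples in rows, features in columns;
#'   `rownames` are sample ids and `colnames` feature ids. Values must be
#'   non-negative where present; `NA` marks a missing measurement.
#' @param method character vector of acquisition-method tags, one per feature
#'   (recycled if length 1). Defaults to a single `"default"` channel.
#' @return an object of class `feature_table` with elements `intensities`
#'   and `method`.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("f1", "f2"))
#' )
#' ft <- feature_table(m)
#' sample_ids(ft)
#' @export
feature_table <- function(intensities, method = "default") {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop_imdsig("`intensities` must be a numeric matrix")
  }
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop_imdsig("`intensities` must have sample rownames and feature colnames")
  }
  if (length(method) == 1L) {
    method <- rep(method, ncol(intensities))
  }
  if (length(method) != ncol(intensities)) {
    stop_imdsig("`method` must give one tag per feature")
  }
  names(method) <- colnames(intensities)
  x <- structure(
    list(intensities = intensities, method = method),
    class = "feature_table"
  )
  validate_feature_table(x)
  x
}

validate_feature_table <- function(x) {
  m <- x$intensities
  sid <- rownames(m)
  fid <- colnames(m)
  dup <- sid[duplicated(sid)]
  if (length(dup)) {
    stop_imdsig("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  }
  for (tag in unique(x$method)) {
    f <- fid[x$method == tag]
    dupf <- f[duplicated(f)]
    if (length(dupf)) {
      stop_imdsig(
        "duplicated feature id(s) within method '", tag, "': ",
        paste(unique(dupf), collapse = ", ")
      )
    }
  }
  if (any(m < 0, na.rm = TRUE)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop_imdsig(
      "negative intensity at sample '", sid[bad[1]],
      "', feature '", fid[bad[2]], "'"
    )
  }
  invisible(x)
}

#' @rdname feature_table
#' @param x a `feature_table`
#' @export
sample_ids <- function(x) rownames(x$intensities)

#' @rdname feature_table
#' @export
feature_ids <- function(x) colnames(x$intensities)

#' @export
print.feature_table <- function(x, ...) {
  m <- x$intensities
  cat(
    "feature_table: ", nrow(m), " samples x ", ncol(m), " features (",
    paste(unique(x$method), collapse = ", "), "); ",
    sum(is.na(m)), " missing cells\n",
    sep = ""
  )
  invisible(x)
}

#' Subset a feature table
#'
#' @param x a `feature_table`
#' @param samples,features character vectors of ids (or logical/integer
#'   indices) to keep; `NULL` keeps all.
#' @return a `feature_table`
#' @export
subset_features <- function(x, samples = NULL, features = NULL) {
  m <- x$intensities
  if (!is.null(samples)) m <- m[samples, , drop = FALSE]
  if (!is.null(features)) m <- m[, features, drop = FALSE]
  feature_table(m, method = x$method[colnames(m)])
}

#' Read a delimited feature table
#'
#' Reads a samples-in-rows delimited text table whose header row carries the
#' feature ids and whose first column carries the sample ids. Empty cells and
#' the string `NA` become missing values; any other non-numeric cell is a
#' hard error naming the offending sample and feature. Set
#' `features_in_rows = TRUE` for the common metabolomics dialect with one row
#' per feature.
#'
#' @param path file path
#' @param sep field delimiter (default tab)
#' @param features_in_rows logical; transpose on read
#' @param method per-feature method tags passed to [feature_table()]
#' @return a [feature_table()]
#' @export
read_feature_table <- function(path, sep = "\t", features_in_rows = FALSE,
                               method = "default") {
  if (!file.exists(path)) {
    stop_imdsig("file not found: ", path)
  }
  raw <- utils::read.table(path,
    sep = sep, header = TRUE, check.names = FALSE,
    colClasses = "character", quote = "\"", comment.char = ""
  )
  if (ncol(raw) < 2L) {
    stop_imdsig("expected an id column plus at least one data column in ", path)
  }
  ids <- raw[[1L]]
  dat <- raw[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow(dat), ncol(dat),
    dimnames = list(ids, colnames(dat))
  )
  for (j in seq_len(ncol(dat))) {
    cell <- trimws(dat[[j]])
    empty <- cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(num))
    if (length(bad)) {
      stop_imdsig(
        "non-numeric value '", cell[bad[1]], "' at row '", ids[bad[1]],
        "', column '", colnames(dat)[j], "' in ", path
      )
    }
    num[empty] <- NA_real_
    vals[, j] <- num
  }
  if (features_in_rows) {
    vals <- t(vals)
  }
  dupc <- colnames(vals)[duplicated(colnames(vals))]
  if (length(dupc)) {
    stop_imdsig("duplicated id(s) in header: ", paste(unique(dupc), collapse = ", "))
  }
  feature_table(vals, method = method)
}

#' Write a feature table to delimited text
#'
#' @param x a `feature_table`
#' @param path output path
#' @param sep field delimiter
#' @return `path`, invisibly
#' @export
write_feature_table <- function(x, path, sep = "\t") {
  m <- x$intensities
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path,
    sep = sep, quote = FALSE, row.names = FALSE, na = ""
  )
  invisible(path)
}

#' Construct and read sample metadata
#'
#' Sample metadata assigns each sample a class label (`"control"` or an IMD
#' identifier), a treatment status, and a role. Only `role == "study"`
#' samples enter training and diagnosis; pooled-QC and blank injections are
#' carried for normalization and filtering only.
#'
#' @param sample_id character vector of sample ids
#' @param class_label `"control"` or an IMD id per sample
#' @param treatment_status one of `"untreated"`, `"treated"`, `"unknown"`
#' @param role one of `"study"`, `"qc"`, `"blank"`
#' @return a `data.frame` of class `sample_metadata`
#' @export
sample_metadata <- function(sample_id, class_label,
                            treatment_status = "unknown", role = "study") {
  df <- data.frame(
    sample_id = as.character(sample_id),
    class_label = as.character(class_label),
    treatment_status = rep_len(as.character(treatment_status), length(sample_id)),
    role = rep_len(as.character(role), length(sample_id)),
    stringsAsFactors = FALSE
  )
  bad_role <- setdiff(unique(df$role), c("study", "qc", "blank"))
  if (length(bad_role)) {
    stop_imdsig("unknown role(s): ", paste(bad_role, collapse = ", "))
  }
  bad_tr <- setdiff(unique(df$treatment_status), c("untreated", "treated", "unknown"))
  if (length(bad_tr)) {
    stop_imdsig("unknown treatment_status: ", paste(bad_tr, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    stop_imdsig(
      "duplicated sample id(s) in metadata: ",
      paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")
    )
  }
  miss <- df$role == "study" & (is.na(df$class_label) | df$class_label == "")
  if (any(miss)) {
    stop_imdsig(
      "study sample(s) without class label: ",
      paste(df$sample_id[miss], collapse = ", ")
    )
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' @rdname sample_metadata
#' @param path TSV with columns `sample_id`, `class_label` and optionally
#'   `treatment_status`, `role`
#' @param sep field delimiter
#' @export
read_sample_metadata <- function(path, sep = "\t") {
  df <- utils::read.table(path,
    sep = sep, header = TRUE,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  need <- c("sample_id", "class_label")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols)) {
    stop_imdsig("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  sample_metadata(
    df$sample_id, df$class_label,
    treatment_status = df$treatment_status %||% "unknown",
    role = df$role %||% "study"
  )
}

#' @rdname sample_metadata
#' @param x a `sample_metadata`
#' @export
write_sample_metadata <- function(x, path, sep = "\t") {
  utils::write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Study-sample ids by class
#'
#' @param metadata a [sample_metadata()]
#' @return `control_ids()`: ids of control study samples; `imd_groups()`:
#'   named list of study-sample id vectors, one per IMD class.
#' @export
control_ids <- function(metadata) {
  metadata$sample_id[metadata$role == "study" & metadata$class_label == "control"]
}

#' @rdname control_ids
#' @export
imd_groups <- function(metadata) {
  st <- metadata[metadata$role == "study" & metadata$class_label != "control", ]
  split(st$sample_id, st$class_label)
}
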