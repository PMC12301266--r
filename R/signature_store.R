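#' Construct an IMD signature
#'
#' An IMD signature is the diagnostic template for one inherited metabolic
#' disorder: a set of metabolites, each with a reference score (the mean
#' control-referenced Z-score observed in patients), an expert weight
#' multiplier, and the number of refinement rounds that contributed to the
#' score. The iteration counter and provenance record how the signature was
#' built and refined.
#'
#' @param imd_id disorder identifier
#' @param entries data.frame with columns `feature_id`, `reference_score`,
#'   `weight_multiplier` (> 0, default 1) and `n_contributions` (>= 1,
#'   default 1)
#' @param iteration refinement round counter (0 = freshly discovered)
#' @param provenance list of per-round records (training sample ids)
#' @return object of class `imd_signature`
#' @export
imd_signature <- function(imd_id, entries, iteration = 0L,
                          provenance = list()) {
  if (!is.data.frame(entries) || !nrow(entries)) {
    stop_imdsig("signature '", imd_id, "' must have at least one entry")
  }
  if (is.null(entries$weight_multiplier)) entries$weight_multiplier <- 1
  if (is.null(entries$n_contributions)) entries$n_contributions <- 1L
  need <- c("feature_id", "reference_score", "weight_multiplier", "n_contributions")
  missing_cols <- setdiff(need, colnames(entries))
  if (length(missing_cols)) {
    stop_imdsig("entries missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(entries$weight_multiplier <= 0)) {
    stop_imdsig("weight multipliers must be > 0")
  }
  if (any(entries$n_contributions < 1)) {
    stop_imdsig("n_contributions must be >= 1")
  }
  if (anyDuplicated(entries$feature_id)) {
    stop_imdsig("duplicated metabolite(s) in signature '", imd_id, "'")
  }
  entries <- entries[order(entries$feature_id), need]
  entries$reference_score <- as.numeric(entries$reference_score)
  entries$weight_multiplier <- as.numeric(entries$weight_multiplier)
  entries$n_contributions <- as.numeric(entries$n_contributions)
  rownames(entries) <- NULL
  structure(
    list(
      imd_id = imd_id, entries = entries,
      iteration = as.integer(iteration), provenance = provenance
    ),
    class = "imd_signature"
  )
}

#' @export
print.imd_signature <- function(x, ...) {
  cat(
    "imd_signature '", x$imd_id, "': ", nrow(x$entries),
    " metabolites, iteration ", x$iteration, "\n",
    sep = ""
  )
  invisible(x)
}

#' Effective (expert-weighted) reference scores of a signature
#'
#' @param sig an [imd_signature()]
#' @return named numeric vector `reference_score * weight_multiplier`
#' @export
effective_scores <- function(sig) {
  stats::setNames(
    sig$entries$reference_score * sig$entries$weight_multiplier,
    sig$entries$feature_id
  )
}

store_schema_check <- function(obj, path) {
  if (!is.list(obj) || is.null(obj$signatures)) {
    stop_imdsig("signature store schema violation at /signatures: missing")
  }
  for (id in names(obj$signatures)) {
    sg <- obj$signatures[[id]]
    base <- paste0("/signatures/", id)
    if (is.null(sg$iteration)) {
      stop_imdsig("signature store schema violation at ", base, "/iteration: missing")
    }
    if (is.null(sg$entries) || !length(sg$entries)) {
      stop_imdsig("signature store schema violation at ", base, "/entries: missing or empty")
    }
    for (fid in names(sg$entries)) {
      e <- sg$entries[[fid]]
      for (field in c("reference_score", "weight_multiplier", "n_contributions")) {
        if (is.null(e[[field]]) || !is.numeric(e[[field]])) {
          stop_imdsig(
            "signature store schema violation at ", base, "/entries/", fid,
            "/", field, ": missing or non-numeric"
          )
        }
      }
    }
  }
  invisible(obj)
}

#' Read and write the JSON signature store
#'
#' The signature store is a JSON document holding every discovered
#' `imd_signature`, keyed by disorder id, with metabolites keyed by feature
#' id. Writing is canonical (sorted keys, unboxed scalars, full precision),
#' so a write-read-write round trip is byte-identical; reading validates the
#' schema and reports violations with a JSON-pointer-style path.
#'
#' @param store named list of [imd_signature()] objects (names = IMD ids)
#' @param path JSON file path
#' @return `read_signature_store()`: named list of `imd_signature` objects;
#'   `write_signature_store()`: `path`, invisibly.
#' @export
write_signature_store <- function(store, path) {
  ids <- sort(names(store))
  sigs <- lapply(ids, function(id) {
    sg <- store[[id]]
    e <- sg$entries[order(sg$entries$feature_id), ]
    entries <- lapply(seq_len(nrow(e)), function(i) {
      list(
        reference_score = e$reference_score[i],
        weight_multiplier = e$weight_multiplier[i],
        n_contributions = e$n_contributions[i]
      )
    })
    names(entries) <- e$feature_id
    list(
      imd_id = sg$imd_id,
      iteration = sg$iteration,
      provenance = sg$provenance,
      entries = entries
    )
  })
  names(sigs) <- ids
  obj <- list(
    format = "imdsig-signature-store",
    version = 1L,
    signatures = sigs
  )
  json <- jsonlite::toJSON(obj,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_signature_store
#' @export
read_signature_store <- function(path) {
  if (!file.exists(path)) stop_imdsig("signature store not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  store_schema_check(obj, path)
  sigs <- obj$signatures
  out <- lapply(names(sigs), function(id) {
    sg <- sigs[[id]]
    fids <- names(sg$entries)
    entries <- data.frame(
      feature_id = fids,
      reference_score = vapply(sg$entries, function(e) as.numeric(e$reference_score), numeric(1)),
      weight_multiplier = vapply(sg$entries, function(e) as.numeric(e$weight_multiplier), numeric(1)),
      n_contributions = vapply(sg$entries, function(e) as.numeric(e$n_contributions), numeric(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
    imd_signature(sg$imd_id %||% id, entries,
      iteration = sg$iteration,
      provenance = sg$provenance %||% list()
    )
  })
  names(out) <- names(sigs)
  out
}
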