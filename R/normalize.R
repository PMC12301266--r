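#' Choose the internal standard with the lowest QC coefficient of variation
#'
#' Each acquisition method is normalized against the spiked stable-isotope
#' internal standard whose intensity is most reproducible across pooled-QC
#' injections. Candidates not measured in every QC sample are ineligible;
#' ties are broken by input order.
#'
#' @param x a [feature_table()] containing the QC samples
#' @param qc_sample_ids ids of the pooled-QC samples in `x`
#' @param candidates feature ids of the candidate internal standards
#' @param method optional method tag; candidates are restricted to it
#' @return the chosen feature id, with attribute `cv` (named CVs of all
#'   fully-observed candidates)
#' @export
select_internal_standard <- function(x, qc_sample_ids, candidates,
                                     method = NULL) {
  candidates <- candidates[candidates %in% feature_ids(x)]
  if (!is.null(method)) {
    candidates <- candidates[x$method[candidates] == method]
  }
  if (!length(candidates)) {
    stop_imdsig("no internal-standard candidates for this method")
  }
  missing_s <- setdiff(qc_sample_ids, sample_ids(x))
  if (length(missing_s)) {
    stop_imdsig("QC sample(s) not in table: ", paste(missing_s, collapse = ", "))
  }
  vals <- x$intensities[qc_sample_ids, candidates, drop = FALSE]
  n_seen <- colSums(!is.na(vals))
  full <- n_seen == length(qc_sample_ids)
  if (!any(full)) {
    stop_imdsig(
      "no candidate observed in all ", length(qc_sample_ids), " QC samples; ",
      "coverage: ",
      paste(sprintf("%s=%d", candidates, n_seen), collapse = ", ")
    )
  }
  cvs <- apply(vals[, full, drop = FALSE], 2, cv_of)
  chosen <- candidates[full][which.min(cvs)]
  structure(chosen, cv = cvs)
}

#' Normalize feature intensities to an internal standard
#'
#' Divides every feature of the internal standard's acquisition method by the
#' per-sample internal-standard intensity, then removes the internal-standard
#' feature itself. Features of other methods are left untouched, so the
#' function can be applied once per method with that method's chosen
#' standard.
#'
#' @param x a [feature_table()]
#' @param is_id the internal-standard feature id
#' @param method method tag to normalize; defaults to the tag of `is_id`
#' @return a [feature_table()] without the internal-standard column
#' @export
normalize_to_internal_standard <- function(x, is_id, method = NULL) {
  if (!is_id %in% feature_ids(x)) {
    stop_imdsig("internal standard '", is_id, "' not in table")
  }
  method <- method %||% unname(x$method[is_id])
  isv <- x$intensities[, is_id]
  bad <- is.na(isv) | isv <= 0
  if (any(bad)) {
    stop_imdsig(
      "internal standard '", is_id, "' missing or non-positive in sample(s): ",
      paste(sample_ids(x)[bad], collapse = ", ")
    )
  }
  m <- x$intensities
  target <- x$method == method
  m[, target] <- m[, target, drop = FALSE] / isv
  keep <- colnames(m) != is_id
  feature_table(m[, keep, drop = FALSE], method = x$method[keep])
}

#' Impute missing intensities at the limit of detection
#'
#' Missing cells are interpreted as measurements below the limit of
#' detection and replaced per feature by an LOD estimate derived from the
#' observed data: the minimum positive observed intensity of that feature
#' (default), or half of it. Features with no observed value carry no
#' information and are dropped with a warning.
#'
#' @param x a [feature_table()]
#' @param policy `"min_observed"` or `"half_min"`
#' @return a [feature_table()] with no missing cells
#' @export
impute_lod <- function(x, policy = c("min_observed", "half_min")) {
  policy <- match.arg(policy)
  m <- x$intensities
  n_seen <- colSums(!is.na(m))
  if (any(n_seen == 0L)) {
    empty <- colnames(m)[n_seen == 0L]
    warn_imdsig(
      "dropping ", length(empty), " feature(s) with no observed value: ",
      paste(utils::head(empty, 5), collapse = ", "),
      if (length(empty) > 5) ", ..." else ""
    )
    m <- m[, n_seen > 0L, drop = FALSE]
  }
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (!any(miss)) next
    obs <- m[!miss, j]
    pos <- obs[obs > 0]
    lod <- if (length(pos)) min(pos) else 0
    if (policy == "half_min") lod <- lod / 2
    m[miss, j] <- lod
  }
  feature_table(m, method = x$method[colnames(m)])
}
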