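#' Similarity between a sample's Z-profile and an IMD signature
#'
#' Computes the normalized dot product between the sample's z-values and the
#' signature's effective reference scores over the metabolites common to
#' both. The default `"signature_norm"` normalization divides the dot
#' product by the signature's norm only, giving the length of the sample's
#' projection onto the signature direction in control-SD units: a strong,
#' correctly oriented metabolic deviation scores high, while a weak profile
#' that merely points the right way cannot. The `"cosine"` variant
#' normalizes by both norms (value in `[-1, 1]`), which is scale invariant
#' in the sample — and therefore blind to the magnitude of the deviation.
#' Signature metabolites not measured in the sample are excluded from both
#' vectors rather than zero-filled, so laboratories with partial metabolite
#' coverage can still be scored; the number of shared metabolites is
#' reported alongside.
#'
#' @param z_sample named numeric vector of the sample's z-values (from
#'   [sample_z()])
#' @param sig an [imd_signature()]
#' @param method `"signature_norm"` (default) or `"cosine"`
#' @return similarity score (numeric scalar; `NA` when no signature
#'   metabolite is measured in the sample), with attribute `n_shared`
#' @export
signature_similarity <- function(z_sample, sig,
                                 method = c("signature_norm", "cosine")) {
  method <- match.arg(method)
  if (is.null(names(z_sample))) {
    stop_imdsig("`z_sample` must be named by feature id")
  }
  sc <- effective_scores(sig)
  shared <- intersect(names(sc), names(z_sample)[!is.na(z_sample)])
  if (!length(shared)) {
    return(structure(NA_real_, n_shared = 0L))
  }
  a <- z_sample[shared]
  b <- sc[shared]
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (nb == 0 || (method == "cosine" && na == 0)) {
    return(structure(0, n_shared = length(shared)))
  }
  val <- if (method == "cosine") {
    sum(a * b) / (na * nb)
  } else {
    sum(a * b) / nb
  }
  structure(unname(val), n_shared = length(shared))
}

#' Rank candidate IMDs for an undiagnosed sample
#'
#' Scores the sample against every signature in the store and sorts the
#' candidates by similarity, descending. Ties are broken by lexicographic
#' IMD id (and flagged); signatures with no metabolite coverage in the
#' sample are placed last with a `no_coverage` flag. The top `top_k`
#' candidates (default 3, the rank-1 to rank-3 diagnoses) are highlighted
#' when printing.
#'
#' @param z_sample named numeric z-profile of the undiagnosed sample,
#'   standardized against its accompanying controls
#' @param store named list of [imd_signature()] objects
#' @param top_k number of candidates highlighted (default 3)
#' @param method similarity variant, see [signature_similarity()]
#' @return a `diagnosis_report`: data.frame with columns `rank`, `imd_id`,
#'   `similarity`, `n_shared`, `tie`, `no_coverage`, plus attributes
#'   `sample_id` and `top_k`
#' @export
rank_diagnoses <- function(z_sample, store, top_k = 3L,
                           method = c("signature_norm", "cosine")) {
  method <- match.arg(method)
  if (!length(store)) stop_imdsig("signature store is empty")
  sims <- lapply(store, function(sig) {
    signature_similarity(z_sample, sig, method = method)
  })
  df <- data.frame(
    imd_id = names(store),
    similarity = vapply(sims, as.numeric, numeric(1)),
    n_shared = vapply(sims, function(s) attr(s, "n_shared"), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  df$no_coverage <- is.na(df$similarity)
  key <- ifelse(df$no_coverage, -Inf, df$similarity)
  ord <- order(-key, df$imd_id, method = "radix")
  df <- df[ord, ]
  df$tie <- duplicated(df$similarity, incomparables = NA) |
    duplicated(df$similarity, incomparables = NA, fromLast = TRUE)
  df$rank <- seq_len(nrow(df))
  df <- df[, c("rank", "imd_id", "similarity", "n_shared", "tie", "no_coverage")]
  rownames(df) <- NULL
  structure(df,
    class = c("diagnosis_report", "data.frame"),
    sample_id = attr(z_sample, "sample_id"), top_k = as.integer(top_k)
  )
}

#' @export
print.diagnosis_report <- function(x, ...) {
  k <- min(attr(x, "top_k"), nrow(x))
  sid <- attr(x, "sample_id")
  cat(
    "Ranked IMD diagnosis", if (!is.null(sid)) paste0(" for ", sid), ": top ",
    k, " of ", nrow(x), " candidates\n",
    sep = ""
  )
  top <- as.data.frame(x)[seq_len(k), ]
  top$similarity <- signif(top$similarity, 4)
  print(top, row.names = FALSE)
  invisible(x)
}

#' Rank of the true IMD in a diagnosis report
#'
#' @param report a `diagnosis_report`
#' @param imd_id the true disorder
#' @return integer rank (1 = best), or `NA` if the IMD is not in the store
#' @export
true_rank <- function(report, imd_id) {
  i <- match(imd_id, report$imd_id)
  if (is.na(i)) {
    return(NA_integer_)
  }
  report$rank[i]
}
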