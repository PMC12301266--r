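#' Control-referenced Z-scoring
#'
#' Standardizes every feature against the mean and standard deviation (n-1
#' denominator) of the designated control samples:
#' `z = (x - mean_controls) / sd_controls`. This is the shared preprocessing
#' of signature discovery, refinement and diagnosis: a patient profile is
#' always expressed in control-SD units.
#'
#' Features whose control SD is zero would yield infinite scores; by default
#' they are dropped with a warning. The `"epsilon"` policy instead floors the
#' SD at `eps` times the feature's control mean (or `eps` if that mean is
#' zero).
#'
#' @param x a [feature_table()] or a numeric samples-by-features matrix with
#'   dimnames; must contain no missing values (impute first)
#' @param controls ids of the control samples defining the reference
#'   (at least 2)
#' @param zero_sd `"drop"` or `"epsilon"`
#' @param eps SD floor used by the `"epsilon"` policy
#' @return an object of class `zmatrix`: list with `z` (matrix), and
#'   per-feature `control_mean`, `control_sd`, plus `control_ids`
#' @examples
#' m <- matrix(rnorm(20, 100, 10), 5, 4,
#'   dimnames = list(paste0("s", 1:5), paste0("f", 1:4))
#' )
#' zm <- zscore(m, controls = c("s1", "s2", "s3"))
#' colMeans(zm$z[c("s1", "s2", "s3"), ]) # ~0
#' @export
zscore <- function(x, controls, zero_sd = c("drop", "epsilon"), eps = 1e-8) {
  zero_sd <- match.arg(zero_sd)
  m <- if (inherits(x, "feature_table")) x$intensities else x
  if (!is.matrix(m)) stop_imdsig("`x` must be a feature_table or matrix")
  missing_c <- setdiff(controls, rownames(m))
  if (length(missing_c)) {
    stop_imdsig("control(s) not in table: ", paste(missing_c, collapse = ", "))
  }
  if (length(controls) < 2L) {
    stop_imdsig("need at least 2 control samples to estimate an SD")
  }
  if (anyNA(m)) {
    stop_imdsig("matrix contains missing values; run impute_lod() first")
  }
  cm <- m[controls, , drop = FALSE]
  mu <- colMeans(cm)
  sd_ <- apply(cm, 2, stats::sd)
  zero <- sd_ == 0
  if (any(zero)) {
    if (zero_sd == "drop") {
      warn_imdsig(
        "dropping ", sum(zero), " feature(s) constant across controls: ",
        paste(utils::head(colnames(m)[zero], 5), collapse = ", "),
        if (sum(zero) > 5) ", ..." else ""
      )
      m <- m[, !zero, drop = FALSE]
      mu <- mu[!zero]
      sd_ <- sd_[!zero]
    } else {
      sd_[zero] <- pmax(eps * abs(mu[zero]), eps)
    }
  }
  z <- sweep(sweep(m, 2, mu, "-"), 2, sd_, "/")
  structure(
    list(z = z, control_mean = mu, control_sd = sd_, control_ids = controls),
    class = "zmatrix"
  )
}

#' @export
print.zmatrix <- function(x, ...) {
  cat(
    "zmatrix: ", nrow(x$z), " samples x ", ncol(x$z), " features, ",
    length(x$control_ids), " reference controls\n",
    sep = ""
  )
  invisible(x)
}

#' Extract one sample's Z-profile
#'
#' @param zm a [zscore()] result
#' @param sample_id one sample id
#' @return named numeric vector of z-values
#' @export
sample_z <- function(zm, sample_id) {
  if (!sample_id %in% rownames(zm$z)) {
    stop_imdsig("sample '", sample_id, "' not in zmatrix")
  }
  zm$z[sample_id, ]
}

#' Write a Z-matrix to TSV for inspection
#'
#' @param zm a `zmatrix`
#' @param path output path
#' @export
write_zmatrix <- function(zm, path) {
  df <- data.frame(sample_id = rownames(zm$z), zm$z, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
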