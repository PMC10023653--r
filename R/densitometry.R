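#' CRISPR editing ratio from immunoblot densitometry
#'
#' The editing ratio estimates the fraction of TARDBP alleles carrying
#' the fluorescent-tag insertion: each band signal is first normalized to
#' the lane's total-protein signal, then the ratio is the combined signal
#' of the high-molecular-weight tagged bands (72/74 kDa) divided by the
#' combined signal of all TDP-43 bands (tagged plus untagged 43 kDa).
#' A ratio of 1.0 means complete insertion across all alleles; ~0.5 means
#' half the alleles are tagged.
#'
#' @param bands `data.frame` with columns `band_label` (one of
#'   `"tagged_72_74kDa"`, `"untagged_43kDa"`, `"other"`) and `signal`
#'   (nonnegative). Multi-lane tables also carry a `lane` column — see
#'   [editing_ratios()].
#' @param total_protein_signal Positive lane total-protein signal used for
#'   normalization (a common divisor; the ratio is invariant to it for a
#'   single lane, but keeps lanes comparable).
#' @param include_other Count `"other"` bands (e.g. partial cleavage
#'   products) in the denominator as TDP-43 species (default `FALSE`).
#' @return The editing ratio in `[0, 1]`, or `NA` when there is no
#'   TDP-43 signal at all.
#' @export
editing_ratio <- function(bands, total_protein_signal,
                          include_other = FALSE) {
  if (!nrow(bands)) stop("lane has no bands", call. = FALSE)
  ok <- c("tagged_72_74kDa", "untagged_43kDa", "other")
  if (!all(bands$band_label %in% ok))
    stop("band_label must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(bands$signal)) || any(bands$signal < 0))
    stop("band signals must be finite and nonnegative", call. = FALSE)
  stopifnot_scalar(total_protein_signal, "total_protein_signal",
                   positive = TRUE)
  norm <- bands$signal / total_protein_signal
  tagged <- sum(norm[bands$band_label == "tagged_72_74kDa"])
  denom_labels <- c("tagged_72_74kDa", "untagged_43kDa",
                    if (include_other) "other")
  denom <- sum(norm[bands$band_label %in% denom_labels])
  if (denom == 0) return(NA_real_)
  tagged / denom
}

#' Editing ratios for a multi-lane densitometry table
#'
#' @param tbl `data.frame` with columns `lane`, `band_label`, `signal`,
#'   `total_protein_signal` (constant within lane).
#' @param include_other Passed to [editing_ratio()].
#' @return `data.frame` with `lane` and `editing_ratio`.
#' @export
editing_ratios <- function(tbl, include_other = FALSE) {
  lanes <- unique(tbl$lane)
  out <- lapply(lanes, function(l) {
    sub <- tbl[tbl$lane == l, , drop = FALSE]
    tp <- unique(sub$total_protein_signal)
    if (length(tp) != 1)
      stop("total_protein_signal must be constant within lane ", l,
           call. = FALSE)
    data.frame(lane = l,
               editing_ratio = editing_ratio(sub, tp, include_other))
  })
  do.call(rbind, out)
}
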