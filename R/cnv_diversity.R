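#' Alteration magnitude of a copy-number variant state
#'
#' The per-variant delta is the sum over genomic bins of the absolute
#' deviation of the predicted copy-number state from the neutral state;
#' it is zero only for a fully neutral profile.
#'
#' @param states integer vector of per-bin copy-number states.
#' @param neutral_state the neutral (diploid-equivalent) state; default
#'   3, the centre of a 6-state model.
#' @return non-negative scalar.
#' @export
variant_delta <- function(states, neutral_state = 3L) {
  stopifnot(length(states) > 0)
  sum(abs(states - neutral_state))
}

#' Construct CNV variant profiles for one sample
#'
#' @param variant_id character vector of variant identifiers.
#' @param freq per-variant fraction of the sample's tumour cells; must
#'   sum to 1 within 1e-6.
#' @param delta per-variant alteration magnitude; either supplied
#'   directly or derived from `states` via [variant_delta()].
#' @param states optional list of per-variant state vectors (used when
#'   `delta` is missing).
#' @param neutral_state passed to [variant_delta()].
#' @return data.frame of class `CNVVariantProfile` with columns
#'   `variant_id`, `freq`, `delta`.
#' @export
cnv_profiles <- function(variant_id, freq, delta = NULL, states = NULL,
                         neutral_state = 3L) {
  stopifnot(length(variant_id) == length(freq))
  if (any(freq < 0 | freq > 1)) stop("frequencies must lie in [0, 1]")
  if (abs(sum(freq) - 1) > 1e-6)
    stop("variant frequencies must sum to 1 (got ", format(sum(freq)), ")")
  if (is.null(delta)) {
    stopifnot(!is.null(states), length(states) == length(variant_id))
    delta <- vapply(states, variant_delta, numeric(1),
                    neutral_state = neutral_state)
  }
  if (any(delta < 0)) stop("delta must be non-negative")
  out <- data.frame(variant_id = variant_id, freq = freq, delta = delta,
                    stringsAsFactors = FALSE)
  class(out) <- c("CNVVariantProfile", class(out))
  out
}

#' Copy-number-weighted Shannon diversity index
#'
#' A per-sample chromosomal-instability proxy: the Shannon entropy of
#' the sample's copy-number variant states, with each variant weighted
#' by both its cell-fraction `freq` and its alteration magnitude
#' `delta`. Weights `s_i = freq_i * delta_i / sum(freq * delta)`; the
#' index is `sum(-s_i * ln(s_i))`, lying in `[0, ln(n)]` for n
#' contributing variants. Variants with zero weight are dropped before
#' normalization (the 0 * ln 0 := 0 convention); a fully neutral sample
#' scores 0 and is flagged via the `all_neutral` attribute.
#'
#' @param variants [cnv_profiles()] data.frame (or any data.frame with
#'   `freq` and `delta` columns).
#' @return scalar diversity index.
#' @export
cnv_sdi <- function(variants) {
  stopifnot(all(c("freq", "delta") %in% names(variants)))
  w <- variants$freq * variants$delta
  w <- w[w > 0]
  if (!length(w)) {
    out <- 0
    attr(out, "all_neutral") <- TRUE
    return(out)
  }
  s <- w / sum(w)
  sum(-s * log(s))
}

#' Per-sample CNV diversity from cell-level variant assignments
#'
#' Derives frequencies from per-cell variant calls and deltas from a
#' variant x bin state matrix, then evaluates [cnv_sdi()] per sample.
#'
#' @param assignments data.frame with `cell_id`, `sample_id`,
#'   `variant_id`.
#' @param state_matrix variant x bin integer matrix (rownames =
#'   variant ids).
#' @param neutral_state passed to [variant_delta()].
#' @return data.frame: `sample_id`, `n_variants`, `cnv_sdi`.
#' @export
cnv_sdi_by_sample <- function(assignments, state_matrix, neutral_state = 3L) {
  stopifnot(all(c("cell_id", "sample_id", "variant_id") %in%
                  names(assignments)))
  deltas <- apply(state_matrix, 1, variant_delta,
                  neutral_state = neutral_state)
  out <- lapply(split(assignments, assignments$sample_id), function(a) {
    tab <- table(a$variant_id)
    vid <- names(tab)
    miss <- setdiff(vid, rownames(state_matrix))
    if (length(miss)) stop("variant(s) missing from state matrix: ",
                           paste(miss, collapse = ", "))
    prof <- cnv_profiles(vid, as.numeric(tab) / sum(tab),
                         delta = deltas[vid])
    data.frame(sample_id = a$sample_id[1], n_variants = length(vid),
               cnv_sdi = as.numeric(cnv_sdi(prof)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
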