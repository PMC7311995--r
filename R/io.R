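# Adapter for interaction predictions precomputed by external RRI tools.

#' Parse externally computed interaction records
#'
#' Reads a CSV of interaction predictions produced by an external RRI
#' predictor and validates them into `rri_interaction` records. Required
#' columns: `key` (free-form lookup label, see [external_predictor]),
#' `start_a`, `end_a`, `start_b`, `end_b` (1-based inclusive boundaries),
#' `e_total`, `e_hybrid`, `ed_a`, `ed_b` (kcal/mol) and `bp_list`, a
#' whitespace-separated string of `(i,j)` tokens (1-based positions in A
#' and B). Base pairs must be antiparallel, consistent with the
#' boundaries, and the energy decomposition must satisfy
#' `e_total = e_hybrid + ed_a + ed_b`.
#'
#' The adapter deliberately consumes files rather than invoking an
#' external binary, so pipelines can plug in any predictor.
#'
#' @param path CSV path.
#' @param seq_a,seq_b Optional sequences used to fill residue letters in
#'   the parsed pairs (and validate positions); otherwise residues are
#'   recorded as `NA`.
#' @return Named list of `rri_interaction` (names from `key`); empty list
#'   for a header-only file.
#' @export
parse_external_interactions <- function(path, seq_a = NULL, seq_b = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("key", "start_a", "end_a", "start_b", "end_b", "e_total",
            "e_hybrid", "ed_a", "ed_b", "bp_list")
  if (!all(need %in% names(tab))) {
    stop(sprintf("external interaction table must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) == 0L) return(structure(list(), names = character(0)))
  for (col in c("start_a", "end_a", "start_b", "end_b", "e_total",
                "e_hybrid", "ed_a", "ed_b")) {
    if (!is.numeric(tab[[col]])) {
      stop(sprintf("column %s must be numeric", col), call. = FALSE)
    }
  }
  ca <- if (!is.null(seq_a)) seq_chars(seq_a) else NULL
  cb <- if (!is.null(seq_b)) seq_chars(seq_b) else NULL
  out <- vector("list", nrow(tab))
  for (r in seq_len(nrow(tab))) {
    toks <- regmatches(tab$bp_list[r],
                       gregexpr("\\((\\d+),(\\d+)\\)", tab$bp_list[r]))[[1L]]
    if (length(toks) == 0L) {
      stop(sprintf("row %d: bp_list has no (i,j) tokens", r), call. = FALSE)
    }
    nums <- do.call(rbind, lapply(toks, function(t) {
      as.integer(strsplit(gsub("[()]", "", t), ",", fixed = TRUE)[[1L]])
    }))
    pos_a <- nums[, 1L]; pos_b <- nums[, 2L]
    ord <- order(pos_a)
    pos_a <- pos_a[ord]; pos_b <- pos_b[ord]
    if (length(pos_a) > 1L &&
        (any(diff(pos_a) <= 0L) || any(diff(pos_b) >= 0L))) {
      stop(sprintf("row %d: base pairs are not antiparallel", r),
           call. = FALSE)
    }
    if (min(pos_a) != tab$start_a[r] || max(pos_a) != tab$end_a[r] ||
        min(pos_b) != tab$start_b[r] || max(pos_b) != tab$end_b[r]) {
      stop(sprintf("row %d: bp_list inconsistent with boundaries", r),
           call. = FALSE)
    }
    if (abs(tab$e_total[r] - (tab$e_hybrid[r] + tab$ed_a[r] +
                              tab$ed_b[r])) > 1e-6) {
      stop(sprintf("row %d: e_total does not decompose", r), call. = FALSE)
    }
    if (tab$ed_a[r] < 0 || tab$ed_b[r] < 0) {
      stop(sprintf("row %d: accessibility penalties must be >= 0", r),
           call. = FALSE)
    }
    pairs <- data.frame(
      pos_a = pos_a, pos_b = pos_b,
      nt_a = if (is.null(ca)) NA_character_ else ca[pos_a],
      nt_b = if (is.null(cb)) NA_character_ else cb[pos_b],
      stringsAsFactors = FALSE)
    out[[r]] <- new_interaction(pairs, e_hybrid = tab$e_hybrid[r],
                                ed_a = tab$ed_a[r], ed_b = tab$ed_b[r])
  }
  names(out) <- tab$key
  out
}
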